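# Summary tables, positional analysis, correlations, t-tests and PGLS.

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(4462 / 1233, 1), 3.6)
  expect_equal(round_half_up(100 * 1243 / 3987, 1), 31.2)
  expect_equal(round_half_up(-0.733, 1), -0.7)
  expect_equal(round_half_up(11.867, 1), 11.9)
  expect_equal(round_half_up(0.05, 1), 0.1)    # base round() would give 0
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(pct_of(5, 0), NA_real_)
  expect_equal(md_ad_ratio(10, 4), 2.5)
})

test_that("per-species verdict summary matches planted truth and sums up", {
  fx <- small_fixture()
  pl <- small_pipeline()
  s <- summarize_verdicts(pl$verdicts, fx$pairs, total = TRUE)
  tot <- s[s$species == "Total", ]
  truth <- fx$truth
  md_t <- truth[truth$direction == "MD", ]
  ad_t <- truth[truth$direction == "AD", ]
  expect_equal(tot$potential_md, length(unique(md_t$ortho_id)))
  expect_equal(tot$potential_ad, length(unique(ad_t$ortho_id)))
  expect_equal(tot$true_md,
               sum(md_t$klass %in% c("true_MD", "domain_switching")))
  expect_equal(tot$true_ad,
               sum(ad_t$klass %in% c("true_AD", "domain_switching")))
  expect_equal(tot$md_gene_prediction,
               sum(md_t$klass == "gene_prediction_error"))
  expect_equal(tot$md_undetermined, sum(md_t$klass == "undetermined_genome"))
  expect_equal(tot$ad_isoform, sum(ad_t$klass == "isoform_inconsistency"))
  # table identity: potential = sum of error classes + true, per species
  per <- s[s$species != "Total", ]
  expect_equal(per$potential_md,
               per$md_annotation + per$md_gene_prediction +
                 per$md_undetermined + per$true_md)
  expect_equal(per$potential_ad,
               per$ad_annotation + per$ad_isoform + per$true_ad)
})

test_that("ordinal positions class units as N-terminal, internal or C-terminal", {
  # reference with three units; ortholog shares two so it stays eligible
  mk <- function(fams_ref, fams_ortho, event_unit, direction = "MD") {
    ref <- domain_hits("R", fams_ref, seq(1, by = 120,
                                          length.out = length(fams_ref)),
                       seq(100, by = 120, length.out = length(fams_ref)))
    ortho <- domain_hits("O", fams_ortho, seq(1, by = 120,
                                              length.out = length(fams_ortho)),
                         seq(100, by = 120, length.out = length(fams_ortho)))
    verdicts <- data.frame(species = "sp", ref_id = "R", ortho_id = "O",
                           direction = direction, unit = event_unit,
                           members = event_unit, klass = "true_MD",
                           stages_run = "final", evidence = "-")
    ordinal_positions(verdicts, rbind(ref, ortho))
  }
  f3 <- c("PF00001", "PF00002", "PF00003")
  expect_equal(mk(f3, f3[-1], "PF00001")$counts["MD", "N_terminal"], 1L)
  expect_equal(mk(f3, f3[-2], "PF00002")$counts["MD", "internal"], 1L)
  expect_equal(mk(f3, f3[1:2], "PF00003")$counts["MD", "C_terminal"], 1L)
  # single-unit ortholog after merge -> event excluded
  out <- mk(f3, f3[2], "PF00001")
  expect_equal(sum(out$counts), 0L)
  expect_equal(out$n_excluded, 1L)
})

test_that("Spearman correlation reproduces hand-checkable cases", {
  # strictly monotone -> rho 1
  expect_equal(spearman_cor(1:8, (1:8)^3)$estimate, 1.0)
  # invariance under strictly monotone transforms of x (property)
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    r1 <- spearman_cor(x, y)$estimate
    expect_equal(spearman_cor(exp(2 * x), y)$estimate, r1)
  }
  # mid-ranks with ties agree with an exhaustive rank assignment
  for (rep in 1:10) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:3, 8, replace = TRUE)
    r_pkg <- spearman_cor(x, y)$estimate
    r_bf <- cor(bf_midranks(x), bf_midranks(y))
    expect_equal(r_pkg, r_bf)
  }
  # degenerate: constant vector
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$estimate))
})

test_that("exact permutation p agrees with enumeration for small n", {
  set.seed(9)
  x <- c(3, 1, 4, 1, 5)
  y <- c(9, 2, 6, 5, 3)
  r <- spearman_cor(x, y, p_method = "permutation")
  expect_gte(r$p_value, 0)
  expect_lte(r$p_value, 1)
  # perfectly monotone n = 4: p = 2/4! (both extreme orderings)
  r2 <- spearman_cor(1:4, 1:4, p_method = "permutation")
  expect_equal(r2$p_value, 2 / factorial(4))
})

test_that("paired t-test matches the closed form and the degenerate convention", {
  r <- paired_ttest(c(2, 4, 6), c(1, 2, 3)) # differences 1,2,3
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2L)
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10)
  tt <- t.test(a, b, paired = TRUE)
  r2 <- paired_ttest(a, b)
  expect_equal(r2$t, unname(tt$statistic))
  expect_equal(r2$p_value, tt$p.value)
  # a == b: NA statistic, p = 1 by convention
  r3 <- paired_ttest(1:4, 1:4)
  expect_true(is.na(r3$t))
  expect_equal(r3$p_value, 1)
})

test_that("PGLS at lambda 0 equals OLS on an ultrametric tree", {
  set.seed(31)
  tree <- ape::rcoal(13, tip.label = c("ref", paste0("t", 1:12)))
  sim <- simulate_phylo_regression(tree, "ref", slope = 1.5, intercept = 2)
  f <- pgls_fit(tree, sim$y, ref = "ref", lambda = 0)
  ols <- lm(sim$y ~ sim$x)
  expect_equal(f$estimate, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(f$r_squared, summary(ols)$r.squared, tolerance = 1e-10)
  expect_equal(f$p_value, anova(ols)[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("on a star tree PGLS equals OLS for any lambda", {
  tree <- ape::read.tree(text = "(ref:1,a:1,b:1,c:1,d:1,e:1);")
  set.seed(37)
  x <- setNames(rnorm(5), letters[1:5])
  y <- setNames(2 * x + rnorm(5, sd = 0.3), letters[1:5])
  ols <- lm(y ~ x)
  for (l in c(0, 0.5, 1)) {
    f <- pgls_fit(tree, y, x = x, lambda = l)
    expect_equal(f$estimate, unname(coef(ols)[2]), tolerance = 1e-10)
  }
})

test_that("the ML lambda maximizes the likelihood (property)", {
  set.seed(41)
  tree <- ape::rcoal(17, tip.label = c("ref", paste0("t", 1:16)))
  for (lam_true in c(0.2, 1)) {
    sim <- simulate_phylo_regression(tree, "ref", slope = 2, lambda = lam_true)
    f <- pgls_fit(tree, sim$y, ref = "ref")
    for (l0 in c(0, 0.5, 1))
      expect_gte(f$logLik + 1e-8,
                 pgls_fit(tree, sim$y, ref = "ref", lambda = l0)$logLik)
  }
})

test_that("ML lambda and slope agree with an independent GLS implementation", {
  library(nlme)
  set.seed(3)
  tree <- ape::rcoal(17, tip.label = c("ref", paste0("t", 1:16)))
  sim <- simulate_phylo_regression(tree, "ref", slope = 2, intercept = 1,
                                   sigma2 = 0.5)
  sub <- ape::keep.tip(tree, names(sim$y))
  d <- data.frame(y = sim$y, x = sim$x, sp = names(sim$y))
  # fixed lambda: the whitened GLS fit must agree exactly
  g_fix <- gls(y ~ x, data = d,
               correlation = ape::corPagel(0.6, phy = sub, form = ~sp,
                                           fixed = TRUE),
               method = "ML")
  f_fix <- pgls_fit(tree, sim$y, ref = "ref", lambda = 0.6)
  expect_equal(f_fix$estimate, unname(coef(g_fix)[2]), tolerance = 1e-8)
  expect_equal(f_fix$intercept, unname(coef(g_fix)[1]), tolerance = 1e-8)
  # ML lambda: agrees when nlme's unbounded optimum is interior to [0, 1]
  g <- gls(y ~ x, data = d,
           correlation = ape::corPagel(0.5, phy = sub, form = ~sp),
           method = "ML")
  lam_nlme <- unname(g$modelStruct$corStruct[[1]])
  expect_gt(lam_nlme, 0); expect_lt(lam_nlme, 1)
  f <- pgls_fit(tree, sim$y, ref = "ref")
  expect_equal(f$lambda, lam_nlme, tolerance = 1e-4)
  expect_equal(f$estimate, unname(coef(g)[2]), tolerance = 1e-6)
})

test_that("duplicate zero-length tips are reported as singular", {
  tree <- ape::read.tree(text = "((a:0,b:0):1,(c:1,ref:1):0.5);")
  y <- setNames(rnorm(3), c("a", "b", "c"))
  expect_error(pgls_fit(tree, y, ref = "ref"), "singular covariance.*a.*b")
})

test_that("patristic distances sum branch lengths to the reference", {
  tree <- ape::read.tree(text = "((a:1,b:2):0.5,ref:3);")
  d <- patristic_distances(tree, "ref")
  expect_equal(unname(d[c("a", "b")]), c(4.5, 5.5))
})
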