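# Post-verdict statistics: per-species summary tables, ordinal position
# analysis, Spearman correlations against assembly-quality metrics, paired
# t-tests and PGLS regression against phylogenetic distance.

#' Half-away-from-zero rounding
#'
#' Rounds halves away from zero (3.65 -> 3.7, -3.65 -> -3.7), the convention
#' of the summary tables emitted by this package, unlike base `round()`'s
#' round-half-even.
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector (`NA` preserved).
#' @examples
#' round_half_up(4462 / 1233, 1) # 3.6
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage and MD/AD ratio with table rounding
#'
#' `pct_of(x, n)` is `100 x / n` and `md_ad_ratio(md, ad)` is `md / ad`, both
#' rounded half-away-from-zero to `digits` decimals; zero denominators give
#' `NA`.
#' @param x,n,md,ad Numeric vectors (counts).
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
pct_of <- function(x, n, digits = 1) {
  ifelse(n > 0, round_half_up(100 * x / n, digits), NA_real_)
}

#' @rdname pct_of
#' @export
md_ad_ratio <- function(md, ad, digits = 1) {
  ifelse(ad > 0, round_half_up(md / ad, digits), NA_real_)
}

# Aggregated error buckets used by the summary tables. Domain switching is a
# *true* event subtype (the surviving-event columns include it; the switching
# count is also reported separately).
verdict_bucket <- function(klass) {
  ifelse(klass %in% c("annotation_inconsistent_ortho",
                      "annotation_inconsistent_ref"), "annotation",
  ifelse(klass == "gene_prediction_error", "gene_prediction",
  ifelse(klass == "isoform_inconsistency", "isoform",
  ifelse(klass == "undetermined_genome", "undetermined", "true"))))
}

BUCKET_PRECEDENCE <- c(annotation = 1L, gene_prediction = 2L, isoform = 2L,
                       undetermined = 3L, true = 4L)

#' Per-species summary of fact-checked events
#'
#' Ortholog-level counts in the style of the standard MD/AD result tables:
#' per species and direction, the number of orthologs whose events fall into
#' each bucket (inconsistent annotation; gene/isoform prediction;
#' undetermined genome; true, which includes domain switching). An ortholog
#' with several same-direction events of different outcomes is counted once,
#' under its earliest-stage bucket, so per-direction buckets always sum to
#' the potential-event ortholog count. Ratios and percentages use
#' half-away-from-zero rounding to one decimal.
#'
#' @param verdicts Verdict data.frame from [fact_check_all()] (or read back
#'   via [read_verdicts_tsv()]).
#' @param pairs Pair table used for detection.
#' @param total Append a `"Total"` row (default `TRUE`).
#' @return data.frame with per-species columns: `n_orthologs`,
#'   `potential_md`, `potential_ad`, `ratio_md_ad`,
#'   `n_orthologs_with_events`, `pct_orthologs_with_events`,
#'   `md_annotation`, `md_gene_prediction`, `md_undetermined`, `true_md`,
#'   `pct_true_md`, `ad_annotation`, `ad_isoform`, `true_ad`, `pct_true_ad`,
#'   `n_domain_switching` (event-level count).
#' @export
summarize_verdicts <- function(verdicts, pairs, total = TRUE) {
  species <- unique(pairs$species)
  if (!length(species)) {
    empty <- summary_total_row(data.frame(
      n_orthologs = 0L, potential_md = 0L, potential_ad = 0L,
      n_orthologs_with_events = 0L, md_annotation = 0L,
      md_gene_prediction = 0L, md_undetermined = 0L, true_md = 0L,
      ad_annotation = 0L, ad_isoform = 0L, true_ad = 0L,
      n_domain_switching = 0L))
    return(empty[0, , drop = FALSE])
  }
  count_bucket <- function(v, bucket) {
    length(unique(v$ortho_id[v$bucket == bucket]))
  }
  rows <- lapply(species, function(sp) {
    v <- verdicts[verdicts$species == sp, , drop = FALSE]
    n <- sum(pairs$species == sp)
    v$bucket <- verdict_bucket(v$klass)
    # ortholog-level: one bucket per (ortho, direction), earliest stage wins
    per <- lapply(split(v, paste(v$ortho_id, v$direction)), function(g) {
      g[which.min(BUCKET_PRECEDENCE[g$bucket]), , drop = FALSE]
    })
    per <- if (length(per)) do.call(rbind, per) else v[0, , drop = FALSE]
    md <- per[per$direction == "MD", , drop = FALSE]
    ad <- per[per$direction == "AD", , drop = FALSE]
    pot_md <- nrow(md); pot_ad <- nrow(ad)
    data.frame(species = sp, n_orthologs = n,
               potential_md = pot_md, potential_ad = pot_ad,
               ratio_md_ad = md_ad_ratio(pot_md, pot_ad),
               n_orthologs_with_events = length(unique(v$ortho_id)),
               pct_orthologs_with_events =
                 pct_of(length(unique(v$ortho_id)), n),
               md_annotation = count_bucket(md, "annotation"),
               md_gene_prediction = count_bucket(md, "gene_prediction"),
               md_undetermined = count_bucket(md, "undetermined"),
               true_md = count_bucket(md, "true"),
               pct_true_md = pct_of(count_bucket(md, "true"), pot_md),
               ad_annotation = count_bucket(ad, "annotation"),
               ad_isoform = count_bucket(ad, "isoform"),
               true_ad = count_bucket(ad, "true"),
               pct_true_ad = pct_of(count_bucket(ad, "true"), pot_ad),
               n_domain_switching = sum(v$klass == "domain_switching"))
  })
  out <- do.call(rbind, rows)
  if (total) out <- rbind(out, summary_total_row(out))
  rownames(out) <- NULL
  out
}

summary_total_row <- function(out) {
  cnt <- c("n_orthologs", "potential_md", "potential_ad",
           "n_orthologs_with_events", "md_annotation", "md_gene_prediction",
           "md_undetermined", "true_md", "ad_annotation", "ad_isoform",
           "true_ad", "n_domain_switching")
  s <- as.list(colSums(out[cnt]))
  data.frame(species = "Total", n_orthologs = s$n_orthologs,
             potential_md = s$potential_md, potential_ad = s$potential_ad,
             ratio_md_ad = md_ad_ratio(s$potential_md, s$potential_ad),
             n_orthologs_with_events = s$n_orthologs_with_events,
             pct_orthologs_with_events = pct_of(s$n_orthologs_with_events,
                                                s$n_orthologs),
             md_annotation = s$md_annotation,
             md_gene_prediction = s$md_gene_prediction,
             md_undetermined = s$md_undetermined, true_md = s$true_md,
             pct_true_md = pct_of(s$true_md, s$potential_md),
             ad_annotation = s$ad_annotation, ad_isoform = s$ad_isoform,
             true_ad = s$true_ad,
             pct_true_ad = pct_of(s$true_ad, s$potential_ad),
             n_domain_switching = s$n_domain_switching)
}

#' Ordinal position of surviving events within the domain architecture
#'
#' Restricted to events where both proteins of the pair have at least two
#' content units after merging; the position of the event's unit within the
#' protein that carries it (reference for MD, ortholog for AD) is classed as
#' N-terminal (ordinally first), C-terminal (ordinally last) or internal.
#'
#' @param verdicts Verdict data.frame; only true events are used
#'   (`true_MD`/`true_AD`, plus `domain_switching` when
#'   `include_switching = TRUE`).
#' @param hits Combined annotation hits for all proteins.
#' @param clans Clan map or `NULL`.
#' @param thresholds A [domfact_thresholds()] object.
#' @param include_switching Count domain-switching events too (default
#'   `FALSE`).
#' @return List with `counts` (matrix: direction x {N_terminal, internal,
#'   C_terminal}) and `n_excluded` (events failing the two-unit rule).
#' @export
ordinal_positions <- function(verdicts, hits, clans = NULL,
                              thresholds = domfact_thresholds(),
                              include_switching = FALSE) {
  thresholds <- as_thresholds(thresholds)
  keep <- verdicts$klass %in% c("true_MD", "true_AD",
                                if (include_switching) "domain_switching")
  v <- verdicts[keep, , drop = FALSE]
  byp <- split_hits(hits)
  cache <- new.env(parent = emptyenv())
  ct_of <- function(id) {
    got <- cache[[id]]
    if (is.null(got)) {
      got <- content_of(hits_for(byp, id), clans, thresholds$overlap_ratio)
      cache[[id]] <- got
    }
    got
  }
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(c("MD", "AD"),
                                   c("N_terminal", "internal", "C_terminal")))
  n_excluded <- 0L
  for (i in seq_len(nrow(v))) {
    ref_ct <- ct_of(v$ref_id[i]); ortho_ct <- ct_of(v$ortho_id[i])
    if (length(ref_ct$unit_order) < 2L || length(ortho_ct$unit_order) < 2L) {
      n_excluded <- n_excluded + 1L
      next
    }
    carrier <- if (v$direction[i] == "MD") ref_ct else ortho_ct
    members <- strsplit(v$members[i], ";", fixed = TRUE)[[1]]
    idx <- which(vapply(carrier$unit_order, function(rep)
      units_intersect(carrier$units[[rep]], list(members = members)), TRUE))
    if (!length(idx)) { n_excluded <- n_excluded + 1L; next }
    pos <- if (idx[1] == 1L) "N_terminal"
      else if (idx[1] == length(carrier$unit_order)) "C_terminal"
      else "internal"
    counts[v$direction[i], pos] <- counts[v$direction[i], pos] + 1L
  }
  list(counts = counts, n_excluded = n_excluded)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties); the
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom,
#' appropriate for the small species panels this package summarizes. An
#' exact permutation p-value is available for small n.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param p_method `"t"` (default) or `"permutation"` (exact enumeration;
#'   only for n <= 8).
#' @return List with `statistic`, `estimate` (rho), `df`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation")) {
  p_method <- match.arg(p_method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(statistic = "spearman_rho", estimate = NA_real_,
                df = n - 2L, p_value = NA_real_, n = n))
  rho <- cor(rx, ry)
  if (p_method == "t") {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  } else {
    if (n > 8) stop("exact permutation p-value supported for n <= 8")
    perms <- all_permutations(n)
    obs <- abs(rho)
    cnt <- 0L
    for (k in seq_len(nrow(perms))) {
      r <- cor(rx, ry[perms[k, ]])
      if (abs(r) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  }
  list(statistic = "spearman_rho", estimate = rho, df = n - 2L,
       p_value = min(p, 1), n = n)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) { # insert the value n at each position
    for (k in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- append(sub[k, ], n, after = pos - 1L)
    }
  }
  out
}

#' Classical paired t-test
#'
#' Two-sided paired t on the differences `a - b`, df = n - 1. Degenerate
#' inputs follow a documented convention: when the differences have zero
#' variance and zero mean (a == b) the statistic is reported as `NA` with
#' p = 1; zero variance with nonzero mean gives an infinite statistic with
#' p = 0.
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @return List with `statistic`, `estimate` (mean difference), `t`, `df`,
#'   `p_value`, `n`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0)
      return(list(statistic = "paired_t", estimate = 0, t = NA_real_,
                  df = n - 1L, p_value = 1, n = n))
    return(list(statistic = "paired_t", estimate = mean(d),
                t = sign(mean(d)) * Inf, df = n - 1L, p_value = 0, n = n))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = "paired_t", estimate = unname(tt$estimate),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = n)
}

#' Patristic distances from a reference tip
#'
#' Sum of branch lengths along the tree path between each tip and the
#' reference tip.
#' @param tree An `ape::phylo` tree.
#' @param ref Reference tip label.
#' @return Named numeric vector over the non-reference tips.
#' @export
patristic_distances <- function(tree, ref) {
  if (!ref %in% tree$tip.label) stop("reference tip '", ref, "' not in tree")
  d <- ape::cophenetic.phylo(tree)
  out <- d[ref, setdiff(tree$tip.label, ref)]
  if (any(out <= 0)) stop("non-positive patristic distance to reference")
  out
}

lambda_vcv <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

gls_loglik_fit <- function(X, y, Cl) {
  n <- length(y)
  R <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  logdet <- 2 * sum(log(diag(R)))
  # whiten: solve t(R) z = v
  Xw <- backsolve(R, X, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  yw <- backsolve(R, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(coef = fit$coefficients, rss = rss, sigma2 = sigma2, logLik = ll)
}

#' Phylogenetic generalized least squares with ML Pagel's lambda
#'
#' GLS regression of a species-level response on the patristic distance to
#' the reference species, with error covariance given by shared branch
#' lengths of the tree (Brownian model). Off-diagonal covariances are scaled
#' by Pagel's lambda; the tree-shape parameters delta and kappa are left at
#' 1. By default lambda is estimated by maximum likelihood over [0, 1]
#' (bounded one-dimensional search, tolerance 1e-6, with the boundary values
#' checked explicitly). At lambda = 0 on an ultrametric tree the fit reduces
#' to ordinary least squares.
#'
#' @param tree `ape::phylo` covering the reference and all observed species.
#' @param y Named numeric vector (names are tip labels).
#' @param ref Reference tip label (used to compute the distance predictor
#'   when `x` is not supplied; the reference itself is not an observation).
#' @param x Optional explicit predictor (named like `y`).
#' @param lambda `"ML"` (default) or a fixed value in [0, 1].
#' @return List with `estimate` (slope), `intercept`, `r_squared`, `lambda`,
#'   `logLik`, `F_statistic`, `df`, `p_value` (F-test of the slope, df 1 and
#'   n - 2), `n`.
#' @export
pgls_fit <- function(tree, y, ref = NULL, x = NULL, lambda = "ML") {
  species <- names(y)
  if (is.null(species)) stop("y must be named by species")
  if (is.null(x)) {
    if (is.null(ref)) stop("supply either x or a reference tip")
    x <- patristic_distances(tree, ref)[species]
  } else x <- x[species]
  if (!all(is.finite(y)) || !all(is.finite(x)))
    stop("y and x must be finite for all species")
  missing <- setdiff(species, tree$tip.label)
  if (length(missing)) stop("species not in tree: ",
                            paste(missing, collapse = ", "))
  sub <- ape::keep.tip(tree, species)
  C <- ape::vcv(sub)[species, species]
  # duplicate zero-length tips make the covariance singular
  for (i in seq_len(nrow(C) - 1)) for (j in seq(i + 1, nrow(C))) {
    if (C[i, j] >= min(C[i, i], C[j, j]) - 1e-12)
      stop("singular covariance: tips '", species[i], "' and '", species[j],
           "' are separated by zero branch length")
  }
  n <- length(y)
  X <- cbind(intercept = 1, distance = x)
  obj <- function(l) {
    f <- gls_loglik_fit(X, y, lambda_vcv(C, l))
    if (is.null(f)) -Inf else f$logLik
  }
  if (identical(lambda, "ML")) {
    opt <- optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    ll <- vapply(cand, obj, 0)
    lambda_hat <- cand[which.max(ll)]
  } else {
    stopifnot(is.numeric(lambda), lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
  }
  Cl <- lambda_vcv(C, lambda_hat)
  full <- gls_loglik_fit(X, y, Cl)
  if (is.null(full)) stop("covariance not positive definite at lambda = ",
                          lambda_hat)
  null <- gls_loglik_fit(X[, 1, drop = FALSE], y, Cl)
  r2 <- 1 - full$rss / null$rss
  Fstat <- (null$rss - full$rss) / (full$rss / (n - 2))
  p <- pf(Fstat, 1, n - 2, lower.tail = FALSE)
  list(statistic = "pgls", estimate = unname(full$coef["distance"]),
       intercept = unname(full$coef["intercept"]),
       r_squared = r2, lambda = lambda_hat, logLik = full$logLik,
       F_statistic = Fstat, df = c(1L, n - 2L), p_value = p, n = n)
}

#' Simulate a species-level regression with Brownian phylogenetic noise
#'
#' Draws `y = intercept + slope * x + e`, where `x` is the patristic
#' distance to the reference tip and `e` is multivariate normal with
#' covariance `sigma2` times the lambda-scaled shared-branch-length matrix.
#' Used to exercise [pgls_fit()].
#'
#' @param tree `ape::phylo`; @param ref reference tip label.
#' @param slope,intercept,sigma2,lambda Simulation parameters.
#' @return List with `x`, `y` (named vectors over non-reference tips).
#' @export
simulate_phylo_regression <- function(tree, ref, slope = 1, intercept = 0,
                                      sigma2 = 1, lambda = 1) {
  x <- patristic_distances(tree, ref)
  species <- names(x)
  sub <- ape::keep.tip(tree, species)
  C <- lambda_vcv(ape::vcv(sub)[species, species], lambda)
  L <- chol(C)
  e <- drop(crossprod(L, rnorm(length(species)))) * sqrt(sigma2)
  y <- intercept + slope * x + e
  list(x = x, y = setNames(y, species))
}
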