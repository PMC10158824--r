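# Shared builders for small in-code fixtures.

ALL_CLASSES <- c("true_md", "true_ad", "ann_inconsistent_ortho",
                 "ann_inconsistent_ref", "gene_pred_error", "isoform_case",
                 "n_region_case", "clan_switch")

per_class <- function(n) setNames(rep(as.integer(n), length(ALL_CLASSES)),
                                  ALL_CLASSES)

# memoized small fixture shared across test files (2 planted events/class)
.fixture_memo <- new.env(parent = emptyenv())
small_fixture <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.fixture_memo[[key]]))
    .fixture_memo[[key]] <- generate_fixture(
      fixture_config(seed = seed, n_pairs = 10L, events_per_class = per_class(2)))
  .fixture_memo[[key]]
}

small_pipeline <- function(seed = 11) {
  key <- paste0("p", seed)
  if (is.null(.fixture_memo[[key]]))
    .fixture_memo[[key]] <- run_fixture_pipeline(small_fixture(seed))
  .fixture_memo[[key]]
}

hits1 <- function(family, start, end, protein = "p1", evalue = NA_real_)
  domain_hits(protein, family, start, end, evalue = evalue)

# random hit list for property tests
random_hits <- function(n, n_families = 5) {
  fam <- sprintf("PF%05d", sample.int(n_families, n, replace = TRUE))
  start <- sample.int(400, n, replace = TRUE)
  len <- sample(20:120, n, replace = TRUE)
  domain_hits("pX", fam, start, start + len)
}

# a tiny clan map: two zinc-finger-like families share a clan
tiny_clans <- c(PF00096 = "CL0361", PF12874 = "CL0361", PF00250 = "CL0123")

# edge-case architectures for overlap grouping: nested, chained, repeats
overlap_edge_cases <- function() {
  list(
    nested = hits1(c("PF00001", "PF00002"), c(1, 40), c(300, 80)),
    chain = hits1(c("PF00001", "PF00002", "PF00003"),
                  c(1, 51, 101), c(100, 150, 200)),
    repeats = hits1(c("PF00001", "PF00001", "PF00002"),
                    c(1, 500, 200), c(80, 580, 300)),
    disjoint = hits1(c("PF00001", "PF00002"), c(1, 60), c(50, 100))
  )
}
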