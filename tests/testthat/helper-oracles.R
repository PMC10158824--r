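# Independent oracles used by the tests.

# Brute-force optimal local alignment: maximum over all substring pairs of
# the global affine-gap alignment score, computed by memoized recursion over
# edit operations. Deliberately different in formulation from the package's
# single-pass local DP.
bf_global_affine <- function(a, b, mat, open, ext) {
  m <- nchar(a); n <- nchar(b)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    if (i > m && j > n) return(0)
    key <- paste(i, j, prev)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- -Inf
    if (i <= m && j <= n)
      best <- max(best, mat[ac[i], bc[j]] + rec(i + 1, j + 1, "M"))
    if (i <= m)
      best <- max(best, -(if (prev == "D") ext else open + ext) + rec(i + 1, j, "D"))
    if (j <= n)
      best <- max(best, -(if (prev == "I") ext else open + ext) + rec(i, j + 1, "I"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

bf_local_score <- function(a, b, mat, open = 11, ext = 1) {
  best <- 0
  m <- nchar(a); n <- nchar(b)
  for (i1 in seq_len(m)) for (i2 in i1:m)
    for (j1 in seq_len(n)) for (j2 in j1:n)
      best <- max(best, bf_global_affine(substr(a, i1, i2), substr(b, j1, j2),
                                         mat, open, ext))
  best
}

# exhaustive mid-rank assignment: for each value, 1-based rank of smaller
# values plus half the count of equal values (plus half for itself)
bf_midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
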