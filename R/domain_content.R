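# Domain content: the list of distinct Pfam-A units of a protein after
# overlap grouping and repeat collapsing. Order and copy number are ignored;
# hits of the same family always collapse, and hits overlapping over at least
# half of the shorter hit's length are grouped into a single content unit
# (single-linkage, so grouping is independent of input order).

#' Group overlapping domain hits into content units
#'
#' Two hits are linked when they belong to the same family, or when their
#' interval overlap is at least `overlap_ratio` of the shorter hit's length.
#' Units are the connected components of this relation (single linkage), so a
#' small domain nested inside a larger one merges with it, and chained
#' overlaps form one unit even if the extremes are disjoint.
#'
#' @param hits A [domain_hits()] data.frame for a single protein.
#' @param overlap_ratio Minimum overlap as a fraction of the shorter hit
#'   (default 0.5).
#' @return A list of content units, each a list with `members` (sorted family
#'   accessions), `representative` (lexicographically smallest member),
#'   `clans` (non-NA clans of members) and `first_start` (smallest hit start).
#'   Units are ordered by representative.
#' @export
group_overlapping <- function(hits, overlap_ratio = 0.5) {
  n <- nrow(hits)
  if (!n) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
  len <- hits$end - hits$start + 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (hits$family[i] == hits$family[j]) { union_(i, j); next }
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov > 0L && ov >= overlap_ratio * min(len[i], len[j])) union_(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  units <- lapply(split(seq_len(n), comp), function(idx) {
    members <- sort(unique(hits$family[idx]))
    clans <- if ("clan" %in% names(hits))
      sort(unique(hits$clan[idx][!is.na(hits$clan[idx])])) else character()
    list(members = members, representative = members[1L],
         clans = clans, first_start = min(hits$start[idx]))
  })
  units <- unname(units)
  units[order(vapply(units, `[[`, "", "representative"))]
}

#' Compute a protein's domain content
#'
#' Attaches clan accessions from the clan map, collapses repeated families
#' (a family present k >= 1 times contributes once) and groups overlapping
#' hits into units. The output is deterministic and invariant under any
#' permutation of the input hits.
#'
#' @param hits A [domain_hits()] data.frame for one protein.
#' @param clans Named character vector (family -> clan) from
#'   [read_clans_tsv()], or `NULL`.
#' @param overlap_ratio Passed to [group_overlapping()].
#' @return Object of class `domain_content`: list with `units` (see
#'   [group_overlapping()]), `unit_order` (representatives ordered by first
#'   hit start along the protein, for positional analysis) and `ordered_hits`
#'   (hits sorted by (start, end)).
#' @examples
#' h <- domain_hits("p1", c("PF00001", "PF00002", "PF00002"),
#'                  c(1, 120, 300), c(100, 220, 400))
#' content_of(h)$units
#' @export
content_of <- function(hits, clans = NULL, overlap_ratio = 0.5) {
  if (is.null(hits) || !nrow(hits)) {
    return(structure(list(units = list(), unit_order = character(),
                          ordered_hits = empty_hits()),
                     class = "domain_content"))
  }
  if (!is.null(clans)) {
    mapped <- unname(clans[hits$family])
    hits$clan <- ifelse(is.na(mapped), NA_character_, mapped)
  }
  ord <- order(hits$start, hits$end, hits$family)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  units <- group_overlapping(hits, overlap_ratio)
  reps <- vapply(units, `[[`, "", "representative")
  starts <- vapply(units, `[[`, 0, "first_start")
  unit_order <- reps[order(starts, reps)]
  structure(list(units = setNames(units, reps), unit_order = unit_order,
                 ordered_hits = hits),
            class = "domain_content")
}

#' @export
print.domain_content <- function(x, ...) {
  cat("Domain content:", length(x$units), "unit(s)\n")
  for (u in x$units)
    cat("  ", u$representative,
        if (length(u$members) > 1L)
          paste0("{", paste(u$members, collapse = ","), "}") else "",
        "\n")
  invisible(x)
}

#' Do two content units share a Pfam clan?
#'
#' `TRUE` iff some family of `u1` and some family of `u2` map to the same
#' clan accession. Units with only unmapped families never match, including
#' against themselves.
#'
#' @param u1,u2 Content units (elements of `content_of(...)$units`).
#' @param clans Named character vector (family -> clan).
#' @return Logical scalar.
#' @export
same_clan <- function(u1, u2, clans) {
  if (is.null(clans)) return(FALSE)
  c1 <- unname(clans[u1$members]); c1 <- c1[!is.na(c1)]
  c2 <- unname(clans[u2$members]); c2 <- c2[!is.na(c2)]
  length(intersect(c1, c2)) > 0L
}

# Unit identity across proteins: units match if their member sets intersect
# (if one of several overlapping domains is present in the ortholog, the
# content is considered the same).
units_intersect <- function(u1, u2) {
  length(intersect(u1$members, u2$members)) > 0L
}

# Does `unit` intersect any unit of `content`?
unit_in_content <- function(unit, content) {
  for (u in content$units) if (units_intersect(unit, u)) return(TRUE)
  FALSE
}
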