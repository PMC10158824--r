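# Potential event detection: compare the domain contents of each ortholog
# pair and emit missing-domain (MD) and additional-domain (AD) candidates.
# MD: a unit of the reference content with no intersecting unit in the
# ortholog content. AD: the converse.

#' Filter ortholog pairs by protein length
#'
#' Removes pairs where either sequence exceeds `max_len` residues
#' (default 5,000). The number of removed pairs is attached as attribute
#' `n_removed`.
#'
#' @param pairs Pair table (`ref_id`, `ortho_id`, `species`).
#' @param seqs Named character vector covering all proteins in `pairs`.
#' @param max_len Maximum allowed protein length.
#' @return Filtered pair table with attribute `n_removed`.
#' @export
filter_proteins <- function(pairs, seqs, max_len = 5000L) {
  stopifnot(max_len > 0)
  missing <- setdiff(unique(c(pairs$ref_id, pairs$ortho_id)), names(seqs))
  if (length(missing))
    stop("no sequence for protein(s): ", paste(utils::head(missing, 3), collapse = ", "))
  keep <- nchar(seqs[pairs$ref_id]) <= max_len &
    nchar(seqs[pairs$ortho_id]) <= max_len
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

# hits_by_protein: named list protein_id -> domain_hits data.frame
split_hits <- function(hits) {
  if (!nrow(hits)) return(list())
  split(hits, hits$protein_id)
}

hits_for <- function(hits_by_protein, id) {
  h <- hits_by_protein[[id]]
  if (is.null(h)) empty_hits() else h
}

#' Detect potential MD/AD events for one ortholog pair
#'
#' @param ref_hits,ortho_hits [domain_hits()] data.frames for the reference
#'   and ortholog protein.
#' @param clans Clan map (family -> clan) or `NULL`.
#' @param thresholds A [domfact_thresholds()] object (overlap ratio and the
#'   reference-only grouping flag are honored).
#' @return data.frame with one row per event: `direction` (`"MD"`/`"AD"`),
#'   `unit` (representative family) and `members` (semicolon-joined family
#'   accessions of the unit). Zero rows when contents are identical.
#' @export
detect_events <- function(ref_hits, ortho_hits, clans = NULL,
                          thresholds = domfact_thresholds()) {
  thresholds <- as_thresholds(thresholds)
  r <- thresholds$overlap_ratio
  ref_content <- content_of(ref_hits, clans, r)
  ortho_ratio <- if (thresholds$reference_only_grouping) 1 + 1e-9 else r
  # ratio > 1 disables cross-family merging but same-family collapsing remains
  ortho_content <- content_of(ortho_hits, clans, ortho_ratio)
  ev <- list()
  for (u in ref_content$units) {
    if (!unit_in_content(u, ortho_content))
      ev[[length(ev) + 1L]] <- data.frame(direction = "MD",
                                          unit = u$representative,
                                          members = paste(u$members, collapse = ";"))
  }
  for (u in ortho_content$units) {
    if (!unit_in_content(u, ref_content))
      ev[[length(ev) + 1L]] <- data.frame(direction = "AD",
                                          unit = u$representative,
                                          members = paste(u$members, collapse = ";"))
  }
  if (!length(ev))
    return(data.frame(direction = character(), unit = character(),
                      members = character()))
  do.call(rbind, ev)
}

#' Detect potential events for all ortholog pairs
#'
#' @param pairs Pair table (`ref_id`, `ortho_id`, `species`).
#' @param hits Combined [domain_hits()] data.frame for all proteins (e.g.
#'   `read_interpro_json(...)$hits`).
#' @inheritParams detect_events
#' @return data.frame with columns `species`, `ref_id`, `ortho_id`,
#'   `direction`, `unit`, `members`.
#' @export
detect_events_all <- function(pairs, hits, clans = NULL,
                              thresholds = domfact_thresholds()) {
  byp <- split_hits(hits)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ev <- detect_events(hits_for(byp, pairs$ref_id[i]),
                        hits_for(byp, pairs$ortho_id[i]),
                        clans, thresholds)
    if (nrow(ev)) {
      ev$species <- pairs$species[i]
      ev$ref_id <- pairs$ref_id[i]
      ev$ortho_id <- pairs$ortho_id[i]
      out[[i]] <- ev
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(species = character(), ref_id = character(),
                      ortho_id = character(), direction = character(),
                      unit = character(), members = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("species", "ref_id", "ortho_id", "direction", "unit", "members")]
}

#' Per-species summary of potential events
#'
#' Counts orthologs (not events): an ortholog with two missing units counts
#' once in the MD column, and an ortholog with both an MD and an AD counts
#' once in the total. Ratios and percentages use half-away-from-zero rounding
#' to one decimal; a zero AD count gives an `NA` ratio.
#'
#' @param events Output of [detect_events_all()].
#' @param pairs Pair table used for detection.
#' @param total Append a `"Total"` row (default `TRUE`).
#' @return data.frame with columns `species`, `n_orthologs`, `potential_md`,
#'   `potential_ad`, `ratio_md_ad`, `n_orthologs_with_events`,
#'   `pct_orthologs_with_events`.
#' @export
tabulate_potential <- function(events, pairs, total = TRUE) {
  species <- unique(pairs$species)
  if (!length(species))
    return(data.frame(species = character(), n_orthologs = integer(),
                      potential_md = integer(), potential_ad = integer(),
                      ratio_md_ad = numeric(),
                      n_orthologs_with_events = integer(),
                      pct_orthologs_with_events = numeric()))
  rows <- lapply(species, function(sp) {
    ev <- events[events$species == sp, , drop = FALSE]
    n <- sum(pairs$species == sp)
    md <- length(unique(ev$ortho_id[ev$direction == "MD"]))
    ad <- length(unique(ev$ortho_id[ev$direction == "AD"]))
    tot <- length(unique(ev$ortho_id))
    data.frame(species = sp, n_orthologs = n, potential_md = md,
               potential_ad = ad, ratio_md_ad = md_ad_ratio(md, ad),
               n_orthologs_with_events = tot,
               pct_orthologs_with_events = pct_of(tot, n))
  })
  out <- do.call(rbind, rows)
  if (total) {
    s <- colSums(out[c("n_orthologs", "potential_md", "potential_ad",
                       "n_orthologs_with_events")])
    out <- rbind(out, data.frame(
      species = "Total", n_orthologs = s[["n_orthologs"]],
      potential_md = s[["potential_md"]], potential_ad = s[["potential_ad"]],
      ratio_md_ad = md_ad_ratio(s[["potential_md"]], s[["potential_ad"]]),
      n_orthologs_with_events = s[["n_orthologs_with_events"]],
      pct_orthologs_with_events = pct_of(s[["n_orthologs_with_events"]],
                                         s[["n_orthologs"]])))
  }
  rownames(out) <- NULL
  out
}
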