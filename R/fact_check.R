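# The fact-checking decision tree. Each potential event is passed through
# ordered verification stages; the first decisive stage wins and the stages
# that ran are recorded in the verdict's evidence trail.
#
#   MD: annotation reconciliation -> gene-prediction check -> genome 'N'
#       check -> final (domain switching / true MD)
#   AD: annotation reconciliation -> isoform check -> final
#
# Reference gene predictions and the reference genome are axiomatically
# trusted, so there are no genome-side checks for AD events.

VERDICT_CLASSES <- c("annotation_inconsistent_ortho", "annotation_inconsistent_ref",
                     "gene_prediction_error", "isoform_inconsistency",
                     "undetermined_genome", "domain_switching",
                     "true_MD", "true_AD")

#' Bundle the side data needed by the fact-checking stages
#'
#' @param annotations Interpro-style [domain_hits()] data.frame (or an
#'   `interpro_annotations` object) covering every protein of the pairs.
#' @param scan_hits HMM re-scan hits from [read_domtblout()].
#' @param scanned_proteins Character vector of proteins that were actually
#'   re-scanned. A protein absent from this set triggers a configuration
#'   error when its scan results are needed (distinct from "scanned, no
#'   hits"). Defaults to the proteins present in `scan_hits`, which cannot
#'   represent hit-less proteins, so supply it explicitly where possible.
#' @param ref_seqs Named character vector of reference protein sequences
#'   (needed to extract missing-domain segments).
#' @param regions Named list (by ortholog protein id) of genomic-region
#'   records: `list(gene_id=, sequence=, flank_nt=)`. A plain named character
#'   vector of sequences is also accepted.
#' @param isoform_hits [domain_hits()] data.frame for reference alternative
#'   isoforms (or an `interpro_annotations` object).
#' @param isoform_map data.frame with columns `isoform_id`, `parent_id`
#'   linking isoforms to their canonical reference protein.
#' @param corrected_hits Optional plug-in hook: [domain_hits()] for
#'   externally corrected ortholog proteins (e.g. from a spliced-alignment
#'   re-prediction). When present for an ortholog, the gene-prediction stage
#'   uses "unit found in the corrected protein at E <= evalue_max" instead of
#'   the built-in translated search.
#' @param clans Clan map from [read_clans_tsv()].
#' @param thresholds A [domfact_thresholds()] object.
#' @param scoring Substitution matrix for the translated search.
#' @return Object of class `check_resources`.
#' @export
check_resources <- function(annotations, scan_hits,
                            scanned_proteins = NULL,
                            ref_seqs = NULL, regions = NULL,
                            isoform_hits = NULL, isoform_map = NULL,
                            corrected_hits = NULL,
                            clans = NULL,
                            thresholds = domfact_thresholds(),
                            scoring = NULL) {
  if (inherits(annotations, "interpro_annotations"))
    annotations <- annotations$hits
  if (inherits(isoform_hits, "interpro_annotations"))
    isoform_hits <- isoform_hits$hits
  if (is.character(regions))
    regions <- lapply(regions, function(s)
      list(gene_id = NA_character_, sequence = s, flank_nt = 0L))
  thresholds <- as_thresholds(thresholds)
  if (is.null(scanned_proteins))
    scanned_proteins <- unique(scan_hits$protein_id)
  structure(list(hits_by_protein = split_hits(annotations),
                 scan_by_protein = split_hits(scan_hits),
                 scanned_proteins = scanned_proteins,
                 ref_seqs = ref_seqs, regions = regions,
                 isoform_hits_by_protein = split_hits(
                   if (is.null(isoform_hits)) empty_hits() else isoform_hits),
                 isoform_map = isoform_map,
                 corrected_by_protein = split_hits(
                   if (is.null(corrected_hits)) empty_hits() else corrected_hits),
                 corrected_proteins = if (is.null(corrected_hits)) character()
                   else unique(corrected_hits$protein_id),
                 clans = clans, thresholds = thresholds,
                 scoring = if (is.null(scoring)) blosum62() else scoring,
                 content_cache = new.env(parent = emptyenv())),
            class = "check_resources")
}

res_content <- function(res, protein_id) {
  cached <- res$content_cache[[protein_id]]
  if (!is.null(cached)) return(cached)
  ct <- content_of(hits_for(res$hits_by_protein, protein_id), res$clans,
                   res$thresholds$overlap_ratio)
  res$content_cache[[protein_id]] <- ct
  ct
}

ev_members <- function(ev) strsplit(ev$members, ";", fixed = TRUE)[[1]]

# best qualifying re-scan hit (E <= evalue_max) of any member family
qualifying_scan_hit <- function(res, protein_id, members) {
  if (!protein_id %in% res$scanned_proteins)
    stop("no HMM scan results for protein '", protein_id,
         "' (configuration error, distinct from a scan with no hits)")
  h <- hits_for(res$scan_by_protein, protein_id)
  h <- h[h$family %in% members & h$evalue <= res$thresholds$evalue_max, ,
         drop = FALSE]
  if (!nrow(h)) return(NULL)
  h[which.min(h$evalue), , drop = FALSE]
}

skipped_stage <- function(reason) structure(list(skipped = reason),
                                            class = "stage_skipped")

verdict_record <- function(ev, klass, stage, evidence = character()) {
  list(klass = klass, stage = stage,
       evidence = if (length(evidence))
         paste(names(evidence), unname(evidence), sep = "=", collapse = ";")
       else "-")
}

#' Stage 1: reconcile Interpro annotations against the standardized HMM re-scan
#'
#' For an MD event: if any re-scan hit of a member family on the *ortholog*
#' has E-value at or below the cutoff, the domain is actually detectable and
#' the ortholog's database annotation was inconsistent
#' (`annotation_inconsistent_ortho`). Otherwise, if *no* re-scan hit of the
#' unit on the reference passes the cutoff, the reference's annotation is not
#' supported by the standardized scan (`annotation_inconsistent_ref`). For AD
#' the rule is mirrored: an annotated gain that the re-scan cannot find on the
#' ortholog, or a "gain" that the re-scan also finds on the reference. GA
#' bit-score status, when known, is carried as evidence only; the decision
#' criterion is the per-domain E-value.
#'
#' @param ev A single event (one row of [detect_events_all()] output, as a
#'   list or one-row data.frame).
#' @param res A [check_resources()] object.
#' @return A verdict record (list with `klass`, `stage`, `evidence`) or
#'   `NULL` when this stage is not decisive.
#' @export
reconcile_annotation <- function(ev, res) {
  members <- ev_members(ev)
  if (ev$direction == "MD") {
    hit <- qualifying_scan_hit(res, ev$ortho_id, members)
    if (!is.null(hit))
      return(verdict_record(ev, "annotation_inconsistent_ortho", "annotation",
                            c(family = hit$family,
                              evalue = format(hit$evalue),
                              ga_pass = hit$ga_pass,
                              protein = ev$ortho_id)))
    refhit <- qualifying_scan_hit(res, ev$ref_id, members)
    if (is.null(refhit))
      return(verdict_record(ev, "annotation_inconsistent_ref", "annotation",
                            c(protein = ev$ref_id,
                              note = "no_scan_hit_at_threshold")))
    NULL
  } else {
    orthohit <- qualifying_scan_hit(res, ev$ortho_id, members)
    if (is.null(orthohit))
      return(verdict_record(ev, "annotation_inconsistent_ortho", "annotation",
                            c(protein = ev$ortho_id,
                              note = "no_scan_hit_at_threshold")))
    refhit <- qualifying_scan_hit(res, ev$ref_id, members)
    if (!is.null(refhit))
      return(verdict_record(ev, "annotation_inconsistent_ref", "annotation",
                            c(family = refhit$family,
                              evalue = format(refhit$evalue),
                              ga_pass = refhit$ga_pass,
                              protein = ev$ref_id)))
    NULL
  }
}

#' Stage 2 (MD): verify the ortholog's gene prediction
#'
#' Extracts the reference subsequence spanning the missing unit's annotated
#' interval (padded by `thresholds$pad` residues) and searches the ortholog's
#' genomic region (gene +/- flank) for a segment coding it, via the built-in
#' six-frame translated search. A hit covering at least `min_cov` of the
#' segment at `min_id` identity or better means the domain is encoded in the
#' genome but absent from the predicted protein: a gene prediction error.
#' When externally corrected proteins were supplied ([check_resources()]
#' `corrected_hits`), the criterion is instead "unit found in the corrected
#' protein at E <= evalue_max".
#'
#' @inheritParams reconcile_annotation
#' @return Verdict record or `NULL`; `NULL` with attribute `skipped` when no
#'   genomic region is on record for the ortholog.
#' @export
check_gene_prediction <- function(ev, res) {
  stopifnot(ev$direction == "MD")
  members <- ev_members(ev)
  if (ev$ortho_id %in% res$corrected_proteins) {
    h <- hits_for(res$corrected_by_protein, ev$ortho_id)
    h <- h[h$family %in% members & h$evalue <= res$thresholds$evalue_max, ,
           drop = FALSE]
    if (nrow(h))
      return(verdict_record(ev, "gene_prediction_error", "gene_prediction",
                            c(source = "corrected_protein",
                              family = h$family[1],
                              evalue = format(h$evalue[1]))))
    return(NULL)
  }
  region <- res$regions[[ev$ortho_id]]
  if (is.null(region))
    return(skipped_stage("no_genomic_region"))
  if (nchar(region$sequence) < 3L)
    stop("genomic region for '", ev$ortho_id, "' is shorter than 3 nt")
  refseq <- res$ref_seqs[[ev$ref_id]]
  if (is.null(refseq) || is.na(refseq))
    stop("no reference sequence for '", ev$ref_id, "'")
  refhits <- hits_for(res$hits_by_protein, ev$ref_id)
  refhits <- refhits[refhits$family %in% members, , drop = FALSE]
  if (!nrow(refhits)) return(skipped_stage("no_reference_interval"))
  lo <- max(1L, min(refhits$start) - res$thresholds$pad)
  hi <- min(nchar(refseq), max(refhits$end) + res$thresholds$pad)
  segment <- substr(refseq, lo, hi)
  if (nchar(segment) < 10L) return(skipped_stage("segment_too_short"))
  hit <- search_domain_in_region(segment, region, res$scoring,
                                 res$thresholds$gap_open,
                                 res$thresholds$gap_ext,
                                 res$thresholds$min_cov,
                                 res$thresholds$min_id)
  if (is.null(hit)) return(NULL)
  verdict_record(ev, "gene_prediction_error", "gene_prediction",
                 c(identity = sprintf("%.3f", hit$identity),
                   coverage = sprintf("%.3f", hit$coverage),
                   frame = hit$frame,
                   nt_span = paste(hit$nt_span, collapse = "-"),
                   n_stop = hit$n_stop,
                   min_cov = res$thresholds$min_cov,
                   min_id = res$thresholds$min_id))
}

#' Stage 2 (AD): search reference alternative isoforms for the gained unit
#'
#' If any known alternative isoform of the reference protein has a domain
#' content containing a unit that intersects the event's unit (family-level
#' matching; clan relationships are reserved for the domain-switching call),
#' the "gain" reflects an inconsistent choice of canonical isoform.
#'
#' @inheritParams reconcile_annotation
#' @return Verdict record naming the isoform, or `NULL`.
#' @export
check_isoforms <- function(ev, res) {
  stopifnot(ev$direction == "AD")
  if (is.null(res$isoform_map) || !nrow(res$isoform_map)) return(NULL)
  iso_ids <- res$isoform_map$isoform_id[res$isoform_map$parent_id == ev$ref_id]
  if (!length(iso_ids)) return(NULL)
  unit <- list(members = ev_members(ev))
  for (iso in iso_ids) {
    ct <- content_of(hits_for(res$isoform_hits_by_protein, iso), res$clans,
                     res$thresholds$overlap_ratio)
    if (unit_in_content(unit, ct))
      return(verdict_record(ev, "isoform_inconsistency", "isoform",
                            c(isoform = iso)))
  }
  NULL
}

#' Stage 3 (MD): undetermined ('N') genome regions
#'
#' Flags the event when the ortholog's genomic region contains at least one
#' run of `N` of length `min_run` or more: the genome sequence is locally
#' undetermined and the absence of the domain cannot be established.
#'
#' @inheritParams reconcile_annotation
#' @return Verdict record with the first qualifying run's coordinates, or
#'   `NULL`.
#' @export
check_genome_Ns <- function(ev, res) {
  stopifnot(ev$direction == "MD")
  region <- res$regions[[ev$ortho_id]]
  if (is.null(region)) return(skipped_stage("no_genomic_region"))
  m <- gregexpr("N+", region$sequence)[[1]]
  if (m[1] == -1L) return(NULL)
  lens <- attr(m, "match.length")
  ok <- which(lens >= res$thresholds$min_run)
  if (!length(ok)) return(NULL)
  i <- ok[1]
  verdict_record(ev, "undetermined_genome", "genome_n",
                 c(run_start = m[i], run_end = m[i] + lens[i] - 1L,
                   run_length = lens[i], n_runs = length(ok),
                   longest_run = max(lens[ok])))
}

# clan-mate units of `unit` in `content` that match nothing in `own_content`
unmatched_clan_mates <- function(unit, content, own_content, clans) {
  out <- list()
  for (v in content$units) {
    if (units_intersect(unit, v)) next
    if (!same_clan(unit, v, clans)) next
    if (!unit_in_content(v, own_content))
      out[[length(out) + 1L]] <- v
  }
  out
}

#' Final stage: domain switching or a true event
#'
#' Runs only when no error stage was decisive. If the counterpart protein's
#' content holds a unit of the same Pfam clan as the event's unit — a unit
#' that itself matches nothing on the event side (default mode
#' `"unmatched"`), or that is itself a complementary potential event of the
#' pair (mode `"reciprocal"`) — the event is classified as domain switching;
#' otherwise it is a true MD or true AD.
#'
#' @inheritParams reconcile_annotation
#' @param events Optional full event table of the pair's events (required for
#'   `switching_mode = "reciprocal"`).
#' @return Verdict record (always decisive).
#' @export
classify_final <- function(ev, res, events = NULL) {
  members <- ev_members(ev)
  unit <- list(members = members)
  ref_ct <- res_content(res, ev$ref_id)
  ortho_ct <- res_content(res, ev$ortho_id)
  if (ev$direction == "MD") {
    counterpart <- ortho_ct; own <- ref_ct
  } else {
    counterpart <- ref_ct; own <- ortho_ct
  }
  mates <- unmatched_clan_mates(unit, counterpart, own, res$clans)
  if (length(mates) && res$thresholds$switching_mode == "reciprocal") {
    opp <- if (ev$direction == "MD") "AD" else "MD"
    mates <- Filter(function(v) {
      if (is.null(events) || !nrow(events)) return(FALSE)
      sel <- events$ref_id == ev$ref_id & events$ortho_id == ev$ortho_id &
        events$direction == opp
      any(vapply(which(sel), function(i)
        units_intersect(v, list(members = ev_members(events[i, ]))), TRUE))
    }, mates)
  }
  if (length(mates)) {
    v <- mates[[1]]
    shared <- intersect(unname(res$clans[members])[!is.na(res$clans[members])],
                        unname(res$clans[v$members])[!is.na(res$clans[v$members])])
    return(verdict_record(ev, "domain_switching", "final",
                          c(clan = shared[1], partner = v$representative)))
  }
  verdict_record(ev, if (ev$direction == "MD") "true_MD" else "true_AD",
                 "final")
}

#' Run the full fact-checking decision tree over all events
#'
#' Applies the staged protocol to every potential event. The first decisive
#' stage wins; every verdict records which stages ran (including skipped
#' stages, e.g. a missing genomic region). Events are independent, so the
#' result is invariant under any reordering of the input.
#'
#' @param events Event table from [detect_events_all()].
#' @param res A [check_resources()] object.
#' @return Verdict data.frame (all columns character): the event columns plus
#'   `klass`, `stages_run` (comma-joined) and `evidence`
#'   (semicolon-joined `key=value` pairs).
#' @export
fact_check_all <- function(events, res) {
  n <- nrow(events)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ev <- as.list(events[i, ])
    stages <- character()
    unwrap <- function(v, name) {
      if (inherits(v, "stage_skipped")) {
        stages <<- c(stages, paste0(name, "(", v$skipped, ")"))
        NULL
      } else {
        stages <<- c(stages, name)
        v
      }
    }
    v <- unwrap(reconcile_annotation(ev, res), "annotation")
    if (is.null(v) && ev$direction == "MD") {
      v <- unwrap(check_gene_prediction(ev, res), "gene_prediction")
      if (is.null(v))
        v <- unwrap(check_genome_Ns(ev, res), "genome_n")
    } else if (is.null(v) && ev$direction == "AD") {
      v <- check_isoforms(ev, res)
      stages <- c(stages, "isoform")
    }
    if (is.null(v)) {
      v <- classify_final(ev, res, events)
      stages <- c(stages, "final")
    }
    out[[i]] <- data.frame(species = ev$species, ref_id = ev$ref_id,
                           ortho_id = ev$ortho_id, direction = ev$direction,
                           unit = ev$unit, members = ev$members,
                           klass = v$klass,
                           stages_run = paste(stages, collapse = ","),
                           evidence = v$evidence,
                           stringsAsFactors = FALSE)
  }
  if (!n)
    return(as.data.frame(setNames(rep(list(character()),
                                      length(VERDICT_COLUMNS)),
                                  VERDICT_COLUMNS)))
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}
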