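# Built-in translated search: six-frame translation of a genomic region and
# local protein alignment of a reference domain segment against each frame.
# This is the package's stand-in for an external TBLASTN/spliced-alignment
# step; spliced alignment is out of scope, so an intron-split domain is found
# only through its best single exon (see the methods vignette). Externally
# computed corrected proteins can be supplied instead via the plug-in hook of
# check_resources().

#' BLOSUM62 substitution matrix (with stop-codon scores)
#'
#' The classic BLOSUM62 matrix as distributed with Biostrings, which includes
#' the `'*'` (stop) character scored at -4 against all residues, so that
#' translated frames containing stop codons can still align near exon
#' boundaries instead of being forbidden outright.
#' @return Numeric matrix with dimnames over the protein alphabet.
#' @export
blosum62 <- function() {
  if (is.null(.domfact_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .domfact_cache$BLOSUM62 <- e$BLOSUM62
  }
  .domfact_cache$BLOSUM62
}

codon_table <- function() {
  if (is.null(.domfact_cache$codons))
    .domfact_cache$codons <- Biostrings::GENETIC_CODE
  .domfact_cache$codons
}

translate_frame <- function(seq, offset) {
  L <- nchar(seq)
  n_codons <- (L - offset) %/% 3L
  if (n_codons < 1L) return(list(peptide = "", starts = integer()))
  starts <- offset + 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(codon_table()[codons])
  aa[is.na(aa)] <- "X" # any codon containing N (or other ambiguity)
  list(peptide = paste(aa, collapse = ""), starts = starts)
}

#' Six-frame translation of a genomic region
#'
#' Translates all six reading frames under the standard genetic code. Codons
#' containing `N` translate to `'X'`; stop codons are kept as `'*'`. Reverse
#' frames translate the reverse complement. Each frame records, for every
#' peptide position, the forward-strand coordinate of the codon's lowest
#' base, so alignment spans can be mapped back to the region.
#'
#' @param region A DNA string over `{A,C,G,T,N}`, or a list with a
#'   `sequence` element (a genomic region record).
#' @return List of six frames (`+1,+2,+3,-1,-2,-3`), each a list with
#'   `frame`, `peptide` and `nt_lo` (integer vector, forward coordinates).
#' @examples
#' six_frame_translate("ATGGCC")[[1]]$peptide # "MA"
#' @export
six_frame_translate <- function(region) {
  seq <- if (is.list(region)) region$sequence else region
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 3L) stop("region shorter than 3 nt cannot be translated")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- vector("list", 6L)
  for (k in 0:2) {
    tr <- translate_frame(seq, k)
    out[[k + 1L]] <- list(frame = k + 1L, peptide = tr$peptide,
                          nt_lo = tr$starts)
  }
  for (k in 0:2) {
    tr <- translate_frame(rc, k)
    # codon at revcomp positions p..p+2 covers forward positions
    # (L - p - 1) .. (L - p + 1); the lowest is L - (p + 2) + 1
    out[[k + 4L]] <- list(frame = -(k + 1L), peptide = tr$peptide,
                          nt_lo = L - (tr$starts + 2L) + 1L)
  }
  out
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman-Gotoh with affine gaps: a gap of length k costs
#' `gap_open + k * gap_ext`. Traceback is deterministic (ties prefer the
#' diagonal, then the vertical, then the horizontal move). Characters absent
#' from the scoring matrix alphabet are treated as `'X'`.
#'
#' @param query,target Protein strings (nonempty).
#' @param scoring Substitution matrix with dimnames (default [blosum62()]).
#' @param gap_open,gap_ext Affine gap penalties (defaults 11 and 1).
#' @return Object of class `local_alignment`: list with `score`, `identity`
#'   (identical columns / alignment columns, gaps included), `query_span`,
#'   `target_span` (1-based closed intervals; `NA` when the best score is 0),
#'   and the aligned strings. `n_stop` counts `'*'` characters among aligned
#'   target residues (a frameshift/intron signal in translated searches).
#' @export
local_align <- function(query, target, scoring = blosum62(),
                        gap_open = 11, gap_ext = 1) {
  stopifnot(nzchar(query), nzchar(target))
  alphabet <- paste(rownames(scoring), collapse = "")
  if (!grepl("X", alphabet, fixed = TRUE))
    stop("scoring matrix must include an 'X' row/column")
  r <- .sw_align(toupper(query), toupper(target), scoring, alphabet,
                 gap_open, gap_ext)
  identity <- if (r$n_cols > 0L) r$n_ident / r$n_cols else 0
  structure(list(score = r$score, identity = identity,
                 query_span = c(r$qstart, r$qend),
                 target_span = c(r$tstart, r$tend),
                 n_ident = r$n_ident, n_cols = r$n_cols,
                 n_stop = lengths(regmatches(r$t_aln,
                                             gregexpr("\\*", r$t_aln))),
                 query_aligned = r$q_aln, target_aligned = r$t_aln),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("Local alignment: score %.1f, identity %.3f, query %d-%d, target %d-%d\n",
              x$score, x$identity, x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2]))
  invisible(x)
}

#' Search a genomic region for a sequence coding a protein domain
#'
#' Translates the region in all six frames and locally aligns the domain
#' segment against each. The best-scoring alignment (ties resolved in frame
#' order +1, +2, +3, -1, -2, -3) is returned only if its query coverage and
#' identity meet the thresholds. Stop codons inside the alignment are allowed
#' but counted (`n_stop`), as a possible intron or frameshift signal.
#'
#' @param domain_seq Protein segment to search for (>= 10 residues).
#' @param region DNA string or genomic-region record (list with `sequence`).
#' @param scoring,gap_open,gap_ext Passed to [local_align()].
#' @param min_cov Minimum aligned fraction of `domain_seq` (default 0.5).
#' @param min_id Minimum alignment identity (default 0.4).
#' @return `NULL` if no frame clears both thresholds; otherwise the best
#'   [local_align()] result augmented with `frame`, `coverage` and `nt_span`
#'   (forward-strand coordinates of the aligned codons).
#' @export
search_domain_in_region <- function(domain_seq, region, scoring = blosum62(),
                                    gap_open = 11, gap_ext = 1,
                                    min_cov = 0.5, min_id = 0.4) {
  if (nchar(domain_seq) < 10L)
    stop("domain segment must be at least 10 residues")
  frames <- six_frame_translate(region)
  best <- NULL
  for (fr in frames) {
    if (!nzchar(fr$peptide)) next
    aln <- local_align(domain_seq, fr$peptide, scoring, gap_open, gap_ext)
    if (aln$score <= 0) next
    if (is.null(best) || aln$score > best$score) {
      aln$frame <- fr$frame
      aln$nt_span <- {
        lo <- fr$nt_lo[aln$target_span[1]]
        hi <- fr$nt_lo[aln$target_span[2]]
        c(min(lo, hi), max(lo, hi) + 2L)
      }
      best <- aln
    }
  }
  if (is.null(best)) return(NULL)
  best$coverage <- (best$query_span[2] - best$query_span[1] + 1L) /
    nchar(domain_seq)
  if (best$coverage < min_cov || best$identity < min_id) return(NULL)
  class(best) <- c("domain_search_hit", "local_alignment")
  best
}
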