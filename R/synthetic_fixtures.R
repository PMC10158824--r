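# Seeded generator of complete miniature datasets covering every input
# format, with planted ground-truth events and errors of every verdict
# class. Fixtures test the classification logic of the protocol, not
# homology-detection power: domain sequences are random per family and no
# phylogenetic sequence evolution is modelled.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

FIXTURE_CLASSES <- c("true_md", "true_ad", "ann_inconsistent_ortho",
                     "ann_inconsistent_ref", "gene_pred_error",
                     "isoform_case", "n_region_case", "clan_switch")

#' Configuration for the synthetic fixture generator
#'
#' Defaults define the generator's standing study conditions: three species,
#' forty ortholog pairs each, a pool of forty Pfam-like families (lengths
#' uniform on 40-200 aa, the typical Pfam range) of which twelve are grouped
#' two-per-clan, genomic regions with 1,000 nt flanks, and ten planted events
#' per verdict class.
#'
#' @param n_species Number of non-reference species.
#' @param n_pairs Ortholog pairs per species.
#' @param n_families Size of the domain family pool.
#' @param n_clans Number of two-family clans (uses the first `2 * n_clans`
#'   families).
#' @param domain_len_range,linker_len_range Uniform ranges (aa) for domain
#'   and inter-domain linker lengths.
#' @param arch_range Number of distinct domains per reference protein.
#' @param flank_nt Flank added on each side of a gene region (default 1000).
#' @param events_per_class Named integer vector of planted events per verdict
#'   class (names from the fixture class set).
#' @param seed Integer seed fixing all outputs.
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(n_species = 3L, n_pairs = 40L,
                           n_families = 40L, n_clans = 6L,
                           domain_len_range = c(40L, 200L),
                           linker_len_range = c(5L, 30L),
                           arch_range = c(2L, 4L),
                           flank_nt = 1000L,
                           events_per_class = NULL,
                           seed = 1L) {
  if (is.null(events_per_class))
    events_per_class <- setNames(rep(10L, length(FIXTURE_CLASSES)),
                                 FIXTURE_CLASSES)
  stopifnot(all(names(events_per_class) %in% FIXTURE_CLASSES),
            all(events_per_class >= 0),
            n_species >= 1, n_pairs >= 1, n_families >= 4,
            flank_nt >= 0)
  full <- setNames(rep(0L, length(FIXTURE_CLASSES)), FIXTURE_CLASSES)
  full[names(events_per_class)] <- as.integer(events_per_class)
  if (full[["clan_switch"]] > 0 && n_clans < 1)
    stop("clan_switch planting requires a nonempty clan pool")
  if (sum(full) > n_species * n_pairs)
    stop("more planted events than ortholog pairs")
  if (2L * n_clans + 2L > n_families)
    stop("family pool too small for the requested clan count")
  structure(list(n_species = as.integer(n_species),
                 n_pairs = as.integer(n_pairs),
                 n_families = as.integer(n_families),
                 n_clans = as.integer(n_clans),
                 domain_len_range = as.integer(domain_len_range),
                 linker_len_range = as.integer(linker_len_range),
                 arch_range = as.integer(arch_range),
                 flank_nt = as.integer(flank_nt),
                 events_per_class = full,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# codons per amino acid, stops excluded
synonymous_codons <- function() {
  if (is.null(.domfact_cache$syn)) {
    gc <- codon_table()
    gc <- gc[gc != "*"]
    .domfact_cache$syn <- split(names(gc), unname(gc))
  }
  .domfact_cache$syn
}

#' Back-translate a protein to DNA with random synonymous codons
#'
#' Uniform choice among the synonymous codons of each residue (seeded by the
#' caller's RNG state); no codon-usage bias is modelled.
#' @param aa Protein string (standard 20 residues).
#' @return DNA string of length `3 * nchar(aa)`.
#' @export
back_translate <- function(aa) {
  syn <- synonymous_codons()
  res <- strsplit(aa, "")[[1]]
  bad <- setdiff(unique(res), names(syn))
  if (length(bad)) stop("cannot back-translate residue(s): ",
                        paste(bad, collapse = ", "))
  paste(vapply(res, function(r) {
    cods <- syn[[r]]
    cods[sample.int(length(cods), 1L)]
  }, ""), collapse = "")
}

#' Plant a back-translated domain copy into a genomic region
#'
#' Splices the back-translated domain segment into the region at
#' `insert_at` (default: 60 nt past the end of the coding body, i.e. inside
#' the 3' flank, mirroring an unannotated downstream exon). Optionally the
#' copy is split by an intron-like spacer, and codon-level mutations can be
#' applied at a given rate (each mutated codon is replaced by a codon of a
#' random different residue).
#'
#' @param region Genomic-region record (list with `sequence`) or DNA string.
#' @param domain_aa Protein sequence of the domain segment.
#' @param insert_at 1-based position after which the copy is inserted
#'   (`NULL` for the default).
#' @param intron_len Length of an intron-like spacer splitting the copy in
#'   half (0 = contiguous).
#' @param mutation_rate Fraction of codons mutated.
#' @return The region with modified `sequence`, plus `planted_span`.
#' @export
plant_gene_error <- function(region, domain_aa, insert_at = NULL,
                             intron_len = 0L, mutation_rate = 0) {
  rec <- if (is.list(region)) region else
    list(gene_id = NA_character_, sequence = region, flank_nt = 0L)
  if (nchar(rec$sequence) < 3L) stop("region too short to plant into")
  dna <- back_translate(domain_aa)
  if (mutation_rate > 0) {
    n_cod <- nchar(dna) %/% 3L
    k <- round(mutation_rate * n_cod)
    if (k > 0) {
      idx <- sample.int(n_cod, k)
      syn <- synonymous_codons()
      res <- strsplit(domain_aa, "")[[1]]
      for (i in idx) {
        other <- sample(setdiff(names(syn), res[i]), 1L)
        cods <- syn[[other]]
        substr(dna, 3L * i - 2L, 3L * i) <- cods[sample.int(length(cods), 1L)]
      }
    }
  }
  if (intron_len > 0) {
    half <- 3L * ((nchar(dna) %/% 3L) %/% 2L)
    dna <- paste0(substr(dna, 1L, half), random_dna(intron_len),
                  substr(dna, half + 1L, nchar(dna)))
  }
  if (is.null(insert_at))
    insert_at <- nchar(rec$sequence) - rec$flank_nt + 60L
  insert_at <- min(max(insert_at, 1L), nchar(rec$sequence))
  rec$sequence <- paste0(substr(rec$sequence, 1L, insert_at), dna,
                         substr(rec$sequence, insert_at + 1L,
                                nchar(rec$sequence)))
  rec$planted_span <- c(insert_at + 1L, insert_at + nchar(dna))
  rec
}

# assemble a protein from an ordered family architecture
assemble_protein <- function(protein_id, arch, pool, linker_range) {
  linker <- function() random_aa(sample(seq(linker_range[1], linker_range[2]), 1L))
  seq <- linker()
  rows <- vector("list", length(arch))
  for (k in seq_along(arch)) {
    dom <- pool$consensus[[arch[k]]]
    start <- nchar(seq) + 1L
    seq <- paste0(seq, dom)
    rows[[k]] <- data.frame(protein_id = protein_id, family = arch[k],
                            clan = NA_character_, start = start,
                            end = nchar(seq), evalue = NA_real_,
                            ga_pass = "unknown", source = "synthetic",
                            stringsAsFactors = FALSE)
    seq <- paste0(seq, linker())
  }
  list(sequence = seq, hits = do.call(rbind, rows))
}

scan_evalue <- function() 10^-runif(1, 6, 30)

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Builds, for each species, a set of ortholog pairs against a synthetic
#' reference proteome. Most pairs have identical domain contents; the
#' configured numbers of pairs carry exactly one planted event or error of
#' each verdict class, constructed so that the fact-checking protocol's
#' stages see consistent evidence (the re-scan table reflects what is truly
#' encoded in each protein, region sequences are back-translations of the
#' ortholog proteins with 1,000 nt flanks, planted gene-prediction errors
#' embed a back-translated domain copy downstream of the coding body, and
#' undetermined-genome cases carry an N run at the expected domain locus).
#' Annotation-class and clan-switch plants alternate between MD and AD
#' flavors; a clan-switch pair yields two truth rows (the MD and the
#' complementary AD, both `domain_switching`). All outputs are reproducible
#' bit-for-bit from the seed.
#'
#' @param config A [fixture_config()].
#' @return Object of class `domfact_fixture`: list with `pairs`, `proteins`
#'   (named sequences), `annotations` (Interpro-style hits), `isoform_hits`,
#'   `isoform_map`, `isoform_seqs`, `scan_hits`, `scanned_proteins`,
#'   `regions`, `clans`, `metadata`, `tree`, `truth` and `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  nf <- config$n_families
  families <- sprintf("PF9%04d", seq_len(nf))
  pool <- list(
    length = setNames(sample(seq(config$domain_len_range[1],
                                 config$domain_len_range[2]),
                             nf, replace = TRUE), families),
    consensus = setNames(vector("list", nf), families))
  for (f in families) pool$consensus[[f]] <- random_aa(pool$length[[f]])
  clanned <- families[seq_len(2L * config$n_clans)]
  clans <- setNames(rep(sprintf("CL9%03d", seq_len(config$n_clans)), each = 2L),
                    clanned)
  unclanned <- setdiff(families, clanned)

  species <- sprintf("species_%02d", seq_len(config$n_species))
  ref_label <- "reference"
  tree <- ape::rcoal(config$n_species + 1L,
                     tip.label = c(ref_label, species))
  metadata <- data.frame(
    species = species,
    contig_n50 = round(10^runif(config$n_species, 4.5, 7.5)),
    busco_complete = round_half_up(runif(config$n_species, 75, 99.9), 1),
    n_coding_genes = sample(5000:25000, config$n_species),
    n_orthologs = config$n_pairs,
    mean_pct_identity = round_half_up(runif(config$n_species, 25, 99), 1))

  # plant plan: class per (species, pair) slot, row-wise round-robin
  plan <- rep("none", config$n_species * config$n_pairs)
  k <- 1L
  for (cls in FIXTURE_CLASSES) {
    n <- config$events_per_class[[cls]]
    if (n > 0) { plan[seq(k, k + n - 1L)] <- cls; k <- k + n }
  }
  # spread plants across species deterministically
  slot_species <- rep(species, times = config$n_pairs)[seq_along(plan)]

  proteins <- character()
  isoform_seqs <- character()
  ann_rows <- list(); iso_rows <- list(); iso_map <- list()
  scan_rows <- list(); truth_rows <- list()
  pair_rows <- list()
  regions <- list()
  flavor_toggle <- 0L

  add_scan <- function(protein_id, hits, drop_families = character(),
                       weak_families = character()) {
    h <- hits[!(hits$family %in% drop_families), , drop = FALSE]
    if (!nrow(h)) return(NULL)
    h$evalue <- vapply(seq_len(nrow(h)), function(i) scan_evalue(), 0)
    if (length(weak_families)) {
      w <- h$family %in% weak_families
      h$evalue[w] <- 0.5
    }
    h$source <- "hmm_scan"
    h
  }

  for (i in seq_along(plan)) {
    cls <- plan[i]
    sp <- slot_species[i]
    ref_id <- sprintf("REF%05d", i)
    ortho_id <- sprintf("ORT%05d", i)
    gene_id <- paste0("gene_", ortho_id)
    n_dom <- sample(seq(config$arch_range[1], config$arch_range[2]), 1L)
    if (cls == "clan_switch") {
      clan_idx <- sample.int(config$n_clans, 1L)
      d <- clanned[2L * clan_idx - 1L]
      d2 <- clanned[2L * clan_idx]
      arch <- c(sample(unclanned, n_dom - 1L), d)
    } else {
      arch <- sample(unclanned, n_dom)
      d <- arch[length(arch)] # planted target: last domain of the architecture
      d2 <- NA_character_
    }
    ref <- assemble_protein(ref_id, arch, pool, config$linker_len_range)
    ref_json <- ref$hits
    ref_scan_weak <- character()
    ortho_arch <- arch
    ortho_json_drop <- character()
    ortho_scan_drop <- character()
    extra <- NA_character_ # AD-side planted family
    plant_region <- "plain"
    flavor <- "MD"
    if (cls %in% c("ann_inconsistent_ortho", "ann_inconsistent_ref")) {
      flavor <- if (flavor_toggle %% 2L == 0L) "MD" else "AD"
      flavor_toggle <- flavor_toggle + 1L
    }
    if (cls == "true_md" || cls == "gene_pred_error" || cls == "n_region_case") {
      ortho_arch <- setdiff(arch, d)
      ortho_scan_drop <- d
      if (cls == "gene_pred_error") plant_region <- "exon"
      if (cls == "n_region_case") plant_region <- "nrun"
    } else if (cls == "true_ad") {
      extra <- sample(setdiff(unclanned, arch), 1L)
      ortho_arch <- c(arch, extra)
    } else if (cls == "ann_inconsistent_ortho" && flavor == "MD") {
      # ortholog truly carries the domain; only its database record omits it
      ortho_json_drop <- d
    } else if (cls == "ann_inconsistent_ortho" && flavor == "AD") {
      # ortholog record claims a gain the re-scan cannot find
      extra <- sample(setdiff(unclanned, arch), 1L)
      # annotation row added below; sequence and scan do not carry it
    } else if (cls == "ann_inconsistent_ref" && flavor == "MD") {
      # reference record claims the domain, re-scan does not support it
      ortho_arch <- setdiff(arch, d)
      ortho_scan_drop <- d
      ref_scan_weak <- d
    } else if (cls == "ann_inconsistent_ref" && flavor == "AD") {
      # gain is real in the ortholog but the re-scan also finds it on the
      # reference (the reference record simply omits it)
      extra <- sample(setdiff(unclanned, arch), 1L)
      ortho_arch <- c(arch, extra)
    } else if (cls == "isoform_case") {
      extra <- sample(setdiff(unclanned, arch), 1L)
      ortho_arch <- c(arch, extra)
    } else if (cls == "clan_switch") {
      ortho_arch <- c(setdiff(arch, d), d2)
      ortho_scan_drop <- d
    }
    ortho <- assemble_protein(ortho_id, ortho_arch, pool,
                              config$linker_len_range)
    ortho_json <- ortho$hits[!(ortho$hits$family %in% ortho_json_drop), ,
                             drop = FALSE]
    ortho_scan_src <- ortho$hits
    if (cls == "ann_inconsistent_ortho" && flavor == "AD") {
      # fabricate the bogus annotation row (not backed by sequence or scan)
      fake_start <- nchar(ortho$sequence) + 10L
      ortho_json <- rbind(ortho_json, data.frame(
        protein_id = ortho_id, family = extra, clan = NA_character_,
        start = fake_start, end = fake_start + pool$length[[extra]] - 1L,
        evalue = NA_real_, ga_pass = "unknown", source = "synthetic",
        stringsAsFactors = FALSE))
    }
    ref_scan <- add_scan(ref_id, ref$hits, weak_families = ref_scan_weak)
    if (cls == "ann_inconsistent_ref" && flavor == "AD") {
      # re-scan finds the gained family on the reference too
      ref_scan <- rbind(ref_scan, data.frame(
        protein_id = ref_id, family = extra, clan = NA_character_,
        start = 1L, end = pool$length[[extra]],
        evalue = 10^-runif(1, 6, 12), ga_pass = "unknown",
        source = "hmm_scan", stringsAsFactors = FALSE))
    }
    ortho_scan <- add_scan(ortho_id, ortho_scan_src,
                           drop_families = ortho_scan_drop)

    # genomic region: back-translated ortholog CDS with flanks
    cds <- back_translate(ortho$sequence)
    flank5 <- random_dna(config$flank_nt)
    flank3 <- random_dna(config$flank_nt)
    region <- list(gene_id = gene_id, sequence = paste0(flank5, cds, flank3),
                   flank_nt = config$flank_nt)
    if (plant_region == "exon") {
      seg_rows <- ref$hits[ref$hits$family == d, , drop = FALSE]
      seg <- substr(ref$sequence, seg_rows$start[1], seg_rows$end[1])
      region <- plant_gene_error(region, seg)
    } else if (plant_region == "nrun") {
      at <- nchar(region$sequence) - config$flank_nt + 60L
      substr(region$sequence, at, at + 29L) <- strrep("N", 30L)
    }
    regions[[ortho_id]] <- region

    if (cls == "isoform_case") {
      iso_id <- paste0(ref_id, "-iso2")
      iso <- assemble_protein(iso_id, c(arch, extra), pool,
                              config$linker_len_range)
      isoform_seqs[[iso_id]] <- iso$sequence
      iso_rows[[length(iso_rows) + 1L]] <- iso$hits
      iso_map[[length(iso_map) + 1L]] <-
        data.frame(isoform_id = iso_id, parent_id = ref_id)
    }

    proteins[[ref_id]] <- ref$sequence
    proteins[[ortho_id]] <- ortho$sequence
    ann_rows[[length(ann_rows) + 1L]] <- ref_json
    ann_rows[[length(ann_rows) + 1L]] <- ortho_json
    if (!is.null(ref_scan)) scan_rows[[length(scan_rows) + 1L]] <- ref_scan
    if (!is.null(ortho_scan)) scan_rows[[length(scan_rows) + 1L]] <- ortho_scan
    pair_rows[[length(pair_rows) + 1L]] <-
      data.frame(ref_id = ref_id, ortho_id = ortho_id, species = sp)

    truth_class <- switch(cls,
      true_md = "true_MD", true_ad = "true_AD",
      ann_inconsistent_ortho = "annotation_inconsistent_ortho",
      ann_inconsistent_ref = "annotation_inconsistent_ref",
      gene_pred_error = "gene_prediction_error",
      isoform_case = "isoform_inconsistency",
      n_region_case = "undetermined_genome",
      clan_switch = "domain_switching", NULL)
    if (!is.null(truth_class)) {
      dir <- if (cls %in% c("true_ad", "isoform_case") ||
                 (cls %in% c("ann_inconsistent_ortho", "ann_inconsistent_ref") &&
                  flavor == "AD")) "AD" else "MD"
      fam <- if (dir == "AD") extra else d
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(species = sp, ref_id = ref_id, ortho_id = ortho_id,
                   direction = dir, family = fam, klass = truth_class)
      if (cls == "clan_switch")
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(species = sp, ref_id = ref_id, ortho_id = ortho_id,
                     direction = "AD", family = d2, klass = "domain_switching")
    }
  }

  pairs_df <- do.call(rbind, pair_rows)
  structure(list(
    config = config,
    pairs = pairs_df,
    proteins = unlist(proteins),
    isoform_seqs = if (length(isoform_seqs)) unlist(isoform_seqs) else character(),
    annotations = do.call(rbind, ann_rows),
    isoform_hits = if (length(iso_rows)) do.call(rbind, iso_rows) else empty_hits(),
    isoform_map = if (length(iso_map)) do.call(rbind, iso_map) else
      data.frame(isoform_id = character(), parent_id = character()),
    scan_hits = if (length(scan_rows)) do.call(rbind, scan_rows) else empty_hits(),
    scanned_proteins = unique(c(pairs_df$ref_id, pairs_df$ortho_id)),
    regions = regions,
    clans = clans,
    metadata = metadata,
    tree = tree,
    truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(species = character(), ref_id = character(),
                 ortho_id = character(), direction = character(),
                 family = character(), klass = character())),
    class = "domfact_fixture")
}

#' Write a fixture to disk in every external format
#'
#' Emits the flat-dialect Interpro-style JSON (with one decoy non-Pfam
#' signature per species to exercise signature filtering), protein and
#' region FASTA, a domtblout re-scan table, the clans TSV, pair table,
#' species metadata, Newick tree, isoform annotations/map and the truth
#' table. Byte-identical for a given fixture.
#'
#' @param fixture A `domfact_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(annotations = file.path(dir, "annotations.json"),
             isoforms = file.path(dir, "isoforms.json"),
             isoform_map = file.path(dir, "isoform_map.tsv"),
             proteins = file.path(dir, "proteins.fasta"),
             regions = file.path(dir, "regions.fasta"),
             region_map = file.path(dir, "region_map.tsv"),
             scan = file.path(dir, "scan.domtblout"),
             clans = file.path(dir, "clans.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             metadata = file.path(dir, "species_metadata.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.tsv"))

  species_of <- c(setNames(fixture$pairs$species, fixture$pairs$ref_id),
                  setNames(fixture$pairs$species, fixture$pairs$ortho_id))
  decoy_for <- fixture$pairs$ref_id[!duplicated(fixture$pairs$species)]
  json_entries <- function(hits, ids) {
    lapply(ids, function(id) {
      h <- hits[hits$protein_id == id, , drop = FALSE]
      sigs <- lapply(seq_len(nrow(h)), function(k)
        list(accession = h$family[k], source_database = "pfam",
             locations = list(list(start = h$start[k], end = h$end[k]))))
      if (id %in% decoy_for)
        sigs <- c(sigs, list(list(accession = "SM00339",
                                  source_database = "smart",
                                  locations = list(list(start = 1, end = 50)))))
      list(protein_id = id, species = unname(species_of[id]) %||% "reference",
           source_db = "synthetic", signatures = sigs)
    })
  }
  all_ids <- c(fixture$pairs$ref_id, fixture$pairs$ortho_id)
  jsonlite::write_json(json_entries(fixture$annotations, all_ids),
                       paths[["annotations"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(json_entries(fixture$isoform_hits,
                                    unique(fixture$isoform_map$isoform_id)),
                       paths[["isoforms"]], auto_unbox = TRUE, digits = NA)
  utils::write.table(fixture$isoform_map, paths[["isoform_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(c(fixture$proteins, fixture$isoform_seqs), paths[["proteins"]])
  region_seqs <- vapply(fixture$regions, `[[`, "", "sequence")
  names(region_seqs) <- vapply(fixture$regions, `[[`, "", "gene_id")
  write_fasta(region_seqs, paths[["regions"]])
  utils::write.table(
    data.frame(ortho_id = names(fixture$regions),
               gene_id = vapply(fixture$regions, `[[`, "", "gene_id"),
               flank_nt = vapply(fixture$regions, `[[`, 0L, "flank_nt")),
    paths[["region_map"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_domtblout(fixture$scan_hits, paths[["scan"]])
  write_clans_tsv(fixture$clans, paths[["clans"]])
  utils::write.table(fixture$pairs, paths[["pairs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$metadata, paths[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(fixture$tree, paths[["tree"]])
  utils::write.table(fixture$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Run detection and fact-checking on an in-memory fixture
#'
#' @param fixture A `domfact_fixture`.
#' @param thresholds A [domfact_thresholds()] object.
#' @return List with `events`, `verdicts` and the `check_resources` object.
#' @export
run_fixture_pipeline <- function(fixture, thresholds = domfact_thresholds()) {
  events <- detect_events_all(fixture$pairs, fixture$annotations,
                              fixture$clans, thresholds)
  res <- check_resources(annotations = fixture$annotations,
                         scan_hits = fixture$scan_hits,
                         scanned_proteins = fixture$scanned_proteins,
                         ref_seqs = fixture$proteins,
                         regions = fixture$regions,
                         isoform_hits = fixture$isoform_hits,
                         isoform_map = fixture$isoform_map,
                         clans = fixture$clans,
                         thresholds = thresholds)
  verdicts <- fact_check_all(events, res)
  list(events = events, verdicts = verdicts, resources = res)
}

#' Per-class precision and recall against planted truth
#'
#' Matches verdicts to truth rows on (ortholog, direction, planted family in
#' the verdict's unit members). For each verdict class: precision = matched
#' verdicts / all verdicts of the class, recall = matched truth rows / all
#' truth rows of the class.
#'
#' @param fixture A `domfact_fixture`.
#' @param verdicts Verdicts from [run_fixture_pipeline()] (recomputed when
#'   omitted).
#' @param thresholds Passed through when recomputing.
#' @return data.frame with `klass`, `planted`, `called`, `matched`,
#'   `precision`, `recall`.
#' @export
planted_recovery <- function(fixture, verdicts = NULL,
                             thresholds = domfact_thresholds()) {
  if (is.null(verdicts))
    verdicts <- run_fixture_pipeline(fixture, thresholds)$verdicts
  truth <- fixture$truth
  truth_key <- paste(truth$ortho_id, truth$direction, truth$family,
                     truth$klass)
  vkeys <- lapply(seq_len(nrow(verdicts)), function(i) {
    members <- strsplit(verdicts$members[i], ";", fixed = TRUE)[[1]]
    paste(verdicts$ortho_id[i], verdicts$direction[i], members,
          verdicts$klass[i])
  })
  matched_v <- vapply(vkeys, function(k) any(k %in% truth_key), TRUE)
  all_vkeys <- unlist(vkeys)
  classes <- sort(unique(c(truth$klass, verdicts$klass)))
  rows <- lapply(classes, function(cl) {
    planted <- sum(truth$klass == cl)
    called <- sum(verdicts$klass == cl)
    matched <- sum(matched_v & verdicts$klass == cl)
    recall_hit <- sum(truth_key[truth$klass == cl] %in% all_vkeys)
    data.frame(klass = cl, planted = planted, called = called,
               matched = matched,
               precision = if (called > 0) matched / called else NA_real_,
               recall = if (planted > 0) recall_hit / planted else NA_real_)
  })
  do.call(rbind, rows)
}
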