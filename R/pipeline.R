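# File-level pipeline commands wiring the modules into the full workflow:
# detect -> factcheck -> stats, plus simulate. Intermediate TSVs are the
# contract between stages, so partial reruns are cheap. Every run writes a
# machine-readable manifest (config hash, package version, seed).

#' Load a run configuration
#'
#' Accepts a YAML file path or a named list. Recognized keys: input paths
#' (`annotations`, `proteins_fasta`, `clans`, `pairs`, `scan`,
#' `regions_fasta`, `region_map`, `isoforms`, `isoform_map`, `metadata`,
#' `tree`), `out_dir`, `seed`, `species_exclude` (per-analysis blacklist for
#' the correlation stage), `reference` (reference tip label for PGLS) and a
#' `thresholds` sub-list passed to [domfact_thresholds()].
#'
#' @param config Path to a YAML file, or a named list.
#' @return Normalized config list with a `thresholds` object.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$thresholds <- as_thresholds(config$thresholds)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  config
}

need_path <- function(config, key) {
  p <- config[[key]]
  if (is.null(p)) stop("config is missing required path '", key, "'")
  if (!file.exists(p)) stop("config path '", key, "' does not exist: ", p)
  p
}

write_manifest <- function(config, out_dir, command) {
  cfg <- config
  cfg$thresholds <- unclass(cfg$thresholds)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(command = command,
                   package = "domfact",
                   version = as.character(utils::packageVersion("domfact")),
                   seed = config$seed %||% NA,
                   config = cfg,
                   config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

load_regions <- function(config) {
  if (is.null(config$regions_fasta)) return(NULL)
  seqs <- read_fasta(need_path(config, "regions_fasta"), "dna")
  map <- utils::read.delim(need_path(config, "region_map"), sep = "\t",
                           colClasses = c(ortho_id = "character",
                                          gene_id = "character"))
  regions <- lapply(seq_len(nrow(map)), function(i)
    list(gene_id = map$gene_id[i], sequence = seqs[[map$gene_id[i]]],
         flank_nt = map$flank_nt[i]))
  setNames(regions, map$ortho_id)
}

#' Detect potential events from input files
#'
#' Reads annotations, sequences, the clan map and the pair table; applies the
#' protein length filter; writes `potential_events.tsv`,
#' `potential_summary.tsv` and a run manifest to `out_dir`.
#'
#' @param config See [load_run_config()].
#' @return Invisibly, a list with `events`, `summary` and the filtered
#'   `pairs`.
#' @export
cmd_detect <- function(config) {
  config <- load_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_interpro_json(need_path(config, "annotations"))
  seqs <- read_fasta(need_path(config, "proteins_fasta"), "protein")
  clans <- read_clans_tsv(need_path(config, "clans"))
  pairs <- read_pair_table(need_path(config, "pairs"))
  pairs <- filter_proteins(pairs, seqs, config$thresholds$max_protein_len)
  events <- detect_events_all(pairs, ann$hits, clans, config$thresholds)
  summary <- tabulate_potential(events, pairs)
  utils::write.table(events, file.path(config$out_dir, "potential_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary, file.path(config$out_dir, "potential_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, config$out_dir, "detect")
  invisible(list(events = events, summary = summary, pairs = pairs))
}

#' Fact-check potential events from input files
#'
#' Runs [cmd_detect()]'s detection step, then the full fact-checking
#' protocol; writes `verdicts.tsv`, the per-species `summary.tsv` and a run
#' manifest.
#'
#' @param config See [load_run_config()]; additionally requires `scan` and
#'   accepts `regions_fasta`/`region_map` and `isoforms`/`isoform_map`.
#' @return Invisibly, a list with `events`, `verdicts`, `summary`.
#' @export
cmd_factcheck <- function(config) {
  config <- load_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_interpro_json(need_path(config, "annotations"))
  seqs <- read_fasta(need_path(config, "proteins_fasta"), "protein")
  clans <- read_clans_tsv(need_path(config, "clans"))
  pairs <- read_pair_table(need_path(config, "pairs"))
  pairs <- filter_proteins(pairs, seqs, config$thresholds$max_protein_len)
  scan <- read_domtblout(need_path(config, "scan"))
  regions <- load_regions(config)
  iso_hits <- if (!is.null(config$isoforms))
    read_interpro_json(need_path(config, "isoforms"))$hits else NULL
  iso_map <- if (!is.null(config$isoform_map))
    utils::read.delim(need_path(config, "isoform_map"), sep = "\t",
                      colClasses = "character") else NULL
  events <- detect_events_all(pairs, ann$hits, clans, config$thresholds)
  res <- check_resources(annotations = ann$hits, scan_hits = scan,
                         scanned_proteins = unique(c(pairs$ref_id,
                                                     pairs$ortho_id)),
                         ref_seqs = seqs, regions = regions,
                         isoform_hits = iso_hits, isoform_map = iso_map,
                         clans = clans, thresholds = config$thresholds)
  verdicts <- fact_check_all(events, res)
  summary <- summarize_verdicts(verdicts, pairs)
  write_verdicts_tsv(verdicts, file.path(config$out_dir, "verdicts.tsv"))
  utils::write.table(summary, file.path(config$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, config$out_dir, "factcheck")
  invisible(list(events = events, verdicts = verdicts, summary = summary))
}

#' Post-verdict statistics from a fact-check run
#'
#' Reads the per-species summary written by [cmd_factcheck()] together with
#' species metadata (and a Newick tree, when supplied), and writes
#' `stats.tsv`: Spearman correlations of contig N50 and BUSCO completeness
#' against potential/true MD and AD counts, paired t-tests of MD% vs AD%
#' before and after fact-checking, and PGLS of event counts against
#' patristic distance. Species on the `species_exclude` blacklist are
#' dropped from every analysis.
#'
#' @param config See [load_run_config()]; requires `metadata` and the
#'   fact-check `out_dir` (reads `summary.tsv` from it); optional `tree` and
#'   `reference`.
#' @return Invisibly, the stats data.frame.
#' @export
cmd_stats <- function(config) {
  config <- load_run_config(config)
  summary_path <- file.path(config$out_dir, "summary.tsv")
  if (!file.exists(summary_path))
    stop("no summary.tsv in out_dir; run cmd_factcheck first")
  s <- utils::read.delim(summary_path, sep = "\t")
  s <- s[s$species != "Total", , drop = FALSE]
  meta <- read_species_metadata(need_path(config, "metadata"))
  excl <- config$species_exclude %||% character()
  s <- s[!(s$species %in% excl), , drop = FALSE]
  meta <- meta[match(s$species, meta$species), , drop = FALSE]
  rows <- list()
  add <- function(name, r) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = name, estimate = r$estimate %||% NA_real_,
      statistic = r$t %||% r$F_statistic %||% NA_real_,
      p_value = r$p_value, n = r$n)
  }
  if (nrow(s) >= 3) {
    for (metric in c("contig_n50", "busco_complete")) {
      for (col in c("potential_md", "potential_ad", "true_md", "true_ad")) {
        add(paste0("spearman_", metric, "_vs_", col),
            spearman_cor(meta[[metric]], s[[col]]))
      }
    }
  }
  if (nrow(s) >= 2) {
    add("paired_t_potential_md_pct_vs_ad_pct",
        paired_ttest(100 * s$potential_md / s$n_orthologs,
                     100 * s$potential_ad / s$n_orthologs))
    add("paired_t_true_md_pct_vs_ad_pct",
        paired_ttest(100 * s$true_md / s$n_orthologs,
                     100 * s$true_ad / s$n_orthologs))
  }
  if (!is.null(config$tree) && nrow(s) >= 3) {
    tree <- ape::read.tree(need_path(config, "tree"))
    ref <- config$reference %||% "reference"
    for (col in c("potential_md", "potential_ad", "true_md", "true_ad")) {
      y <- setNames(as.numeric(s[[col]]), s$species)
      r <- pgls_fit(tree, y, ref = ref)
      rows[[length(rows) + 1L]] <- data.frame(
        analysis = paste0("pgls_", col, "_vs_distance"),
        estimate = r$r_squared, statistic = r$lambda,
        p_value = r$p_value, n = r$n)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(config$out_dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, config$out_dir, "stats")
  invisible(out)
}

#' Generate and write a synthetic dataset
#'
#' @param config List (or YAML path) with `out_dir`, `seed` and optional
#'   [fixture_config()] fields under `fixture`.
#' @return Invisibly, the fixture object.
#' @export
cmd_simulate <- function(config) {
  config <- load_run_config(config)
  args <- config$fixture %||% list()
  args$seed <- config$seed %||% args$seed %||% 1L
  fixture <- generate_fixture(do.call(fixture_config, args))
  write_fixture(fixture, config$out_dir)
  write_manifest(config, config$out_dir, "simulate")
  invisible(fixture)
}

#' Bundled published summary-count tables
#'
#' Plain-TSV copies of the per-species summary counts from a genome-wide
#' study of domain gain/loss fact-checking in 9 non-human primates (NHP,
#' reference: human) and 20 non-*S. cerevisiae* fungi (NSF, reference:
#' *S. cerevisiae*). Used as inputs for validating the package's table
#' arithmetic (ratios, percentages, row-sum identities) against printed
#' values; the package does not recompute the underlying event counts, which
#' would require full database downloads and HMM scans.
#'
#' @param dataset `"nhp"` or `"nsf"`.
#' @param table One of `"species"` (assembly metadata and ortholog counts),
#'   `"potential"` (potential MD/AD per species), `"md"` (MD fact-check
#'   outcome counts), `"ad"` (AD outcome counts).
#' @return data.frame.
#' @export
published_counts <- function(dataset = c("nhp", "nsf"),
                             table = c("species", "potential", "md", "ad")) {
  dataset <- match.arg(dataset)
  table <- match.arg(table)
  path <- system.file("extdata", "published_counts",
                      paste0(dataset, "_", table, ".tsv"),
                      package = "domfact", mustWork = TRUE)
  utils::read.delim(path, sep = "\t")
}
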