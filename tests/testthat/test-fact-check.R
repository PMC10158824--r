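# The fact-checking decision tree: stage rules, precedence, partition and
# planted-truth recovery.

# minimal hand-built resources around one MD and one AD event
mk_event <- function(direction, unit = "PF08430", ref = "R1", ortho = "O1") {
  list(species = "sp", ref_id = ref, ortho_id = ortho,
       direction = direction, unit = unit, members = unit)
}

base_resources <- function(ref_scan_e = 1e-20, ortho_scan_e = NULL,
                           clans = NULL, regions = NULL, ...) {
  ann <- rbind(hits1("PF08430", 10, 90, protein = "R1"),
               hits1("PF00250", 120, 200, protein = "R1"),
               hits1("PF00250", 120, 200, protein = "O1"))
  scan <- empty_hits()
  if (!is.null(ref_scan_e))
    scan <- rbind(scan, hits1("PF08430", 10, 90, protein = "R1",
                              evalue = ref_scan_e))
  if (!is.null(ortho_scan_e))
    scan <- rbind(scan, hits1("PF08430", 12, 88, protein = "O1",
                              evalue = ortho_scan_e))
  scan$source <- "hmm_scan"
  check_resources(annotations = ann, scan_hits = scan,
                  scanned_proteins = c("R1", "O1"),
                  ref_seqs = c(R1 = random_protein(220)),
                  regions = regions, clans = clans, ...)
}

test_that("a qualifying re-scan hit on the ortholog explains away an MD", {
  set.seed(1)
  res <- base_resources(ortho_scan_e = 1.6e-08)
  v <- reconcile_annotation(mk_event("MD"), res)
  expect_equal(v$klass, "annotation_inconsistent_ortho")
  expect_match(v$evidence, "1.6e-08")
})

test_that("an unverifiable reference annotation is flagged for MD", {
  set.seed(1)
  res <- base_resources(ref_scan_e = 0.5) # above the 0.01 cutoff
  v <- reconcile_annotation(mk_event("MD"), res)
  expect_equal(v$klass, "annotation_inconsistent_ref")
})

test_that("reconciliation passes when ortholog lacks and reference has the domain", {
  set.seed(1)
  res <- base_resources(ref_scan_e = 1e-20, ortho_scan_e = 0.5)
  expect_null(reconcile_annotation(mk_event("MD"), res))
})

test_that("AD reconciliation mirrors the MD rules", {
  set.seed(1)
  # ortholog annotated with a gain the re-scan cannot find
  res <- base_resources(ortho_scan_e = NULL)
  v <- reconcile_annotation(mk_event("AD"), res)
  expect_equal(v$klass, "annotation_inconsistent_ortho")
  # re-scan finds the "gain" on the reference too
  res2 <- base_resources(ref_scan_e = 3.2e-08, ortho_scan_e = 2e-10)
  v2 <- reconcile_annotation(mk_event("AD"), res2)
  expect_equal(v2$klass, "annotation_inconsistent_ref")
  # genuinely ortholog-only -> undecided at this stage
  res3 <- base_resources(ref_scan_e = NULL, ortho_scan_e = 2e-10)
  expect_null(reconcile_annotation(mk_event("AD"), res3))
})

test_that("missing scan results are a configuration error, not 'no hits'", {
  set.seed(1)
  res <- base_resources()
  res$scanned_proteins <- "R1"
  expect_error(reconcile_annotation(mk_event("MD"), res),
               "configuration error")
})

test_that("a planted exon turns an MD into a gene prediction error; scrambled does not", {
  set.seed(13)
  ref_seq <- random_protein(220)
  dom_seg <- substr(ref_seq, 10, 90)
  region_hit <- list(gene_id = "g1",
                     sequence = paste0(random_dna_str(400),
                                       back_translate(dom_seg),
                                       random_dna_str(400)),
                     flank_nt = 0L)
  region_miss <- list(gene_id = "g1", sequence = random_dna_str(1000),
                      flank_nt = 0L)
  mk_res <- function(region) {
    r <- base_resources(regions = setNames(list(region), "O1"))
    r$ref_seqs <- c(R1 = ref_seq)
    r
  }
  v <- check_gene_prediction(mk_event("MD"), mk_res(region_hit))
  expect_equal(v$klass, "gene_prediction_error")
  expect_match(v$evidence, "identity=")
  expect_null(check_gene_prediction(mk_event("MD"), mk_res(region_miss)))
})

test_that("isoform matching is family-level; clan-mates do not count", {
  set.seed(1)
  iso_hits <- rbind(hits1("PF00250", 1, 80, protein = "R1-iso2"),
                    hits1("PF00096", 100, 130, protein = "R1-iso2"))
  iso_map <- data.frame(isoform_id = "R1-iso2", parent_id = "R1")
  res <- base_resources(ref_scan_e = NULL, ortho_scan_e = 1e-12,
                        clans = tiny_clans)
  res$isoform_hits_by_protein <- split(iso_hits, iso_hits$protein_id)
  res$isoform_map <- iso_map
  # gained family present in the isoform -> isoform inconsistency
  v <- check_isoforms(mk_event("AD", unit = "PF00096"), res)
  expect_equal(v$klass, "isoform_inconsistency")
  expect_match(v$evidence, "R1-iso2")
  # same clan, different family (PF12874 ~ PF00096): NOT an isoform match
  expect_null(check_isoforms(mk_event("AD", unit = "PF12874"), res))
  # no isoforms on record
  res$isoform_map <- NULL
  expect_null(check_isoforms(mk_event("AD", unit = "PF00096"), res))
})

test_that("N runs in the genomic region are detected with run coordinates", {
  set.seed(1)
  region <- list(gene_id = "g", sequence = "ACGTNNNNNNACGT", flank_nt = 0L)
  res <- base_resources(regions = setNames(list(region), "O1"))
  v <- check_genome_Ns(mk_event("MD"), res)
  expect_equal(v$klass, "undetermined_genome")
  expect_match(v$evidence, "run_start=5;run_end=10")
  # N-free region
  res2 <- base_resources(regions = list(O1 = list(gene_id = "g",
                                                  sequence = "ACGTACGT",
                                                  flank_nt = 0L)))
  expect_null(check_genome_Ns(mk_event("MD"), res2))
  # below the minimum run length
  res3 <- base_resources(regions = setNames(list(region), "O1"),
                         thresholds = domfact_thresholds(min_run = 10))
  expect_null(check_genome_Ns(mk_event("MD"), res3))
})

test_that("final stage separates domain switching from true events", {
  set.seed(1)
  # ortholog holds PF12874, same clan as the missing PF00096
  ann <- rbind(hits1("PF00096", 10, 40, protein = "R1"),
               hits1("PF00250", 120, 200, protein = "R1"),
               hits1("PF00250", 120, 200, protein = "O1"),
               hits1("PF12874", 10, 45, protein = "O1"))
  res <- check_resources(annotations = ann, scan_hits = empty_hits(),
                         scanned_proteins = c("R1", "O1"),
                         clans = tiny_clans)
  v <- classify_final(mk_event("MD", unit = "PF00096"), res)
  expect_equal(v$klass, "domain_switching")
  expect_match(v$evidence, "CL0361")
  expect_match(v$evidence, "partner=PF12874")
  # no clan relative in the counterpart -> true event
  res2 <- check_resources(annotations = ann[-4, ], scan_hits = empty_hits(),
                          scanned_proteins = c("R1", "O1"), clans = tiny_clans)
  expect_equal(classify_final(mk_event("MD", unit = "PF00096"), res2)$klass,
               "true_MD")
  # unmapped family on the AD side -> true AD
  expect_equal(classify_final(mk_event("AD", unit = "PF00777"), res2)$klass,
               "true_AD")
})

test_that("reciprocal switching mode requires a complementary event", {
  set.seed(1)
  ann <- rbind(hits1("PF00096", 10, 40, protein = "R1"),
               hits1("PF12874", 10, 45, protein = "O1"))
  mk <- function(mode) check_resources(
    annotations = ann, scan_hits = empty_hits(),
    scanned_proteins = c("R1", "O1"), clans = tiny_clans,
    thresholds = domfact_thresholds(switching_mode = mode))
  ev <- mk_event("MD", unit = "PF00096")
  events_with <- data.frame(species = "sp", ref_id = "R1", ortho_id = "O1",
                            direction = c("MD", "AD"),
                            unit = c("PF00096", "PF12874"),
                            members = c("PF00096", "PF12874"))
  events_without <- events_with[1, ]
  expect_equal(classify_final(ev, mk("reciprocal"), events_with)$klass,
               "domain_switching")
  expect_equal(classify_final(ev, mk("reciprocal"), events_without)$klass,
               "true_MD")
  expect_equal(classify_final(ev, mk("unmatched"), events_without)$klass,
               "domain_switching")
})

test_that("stages short-circuit and the evidence trail records them", {
  set.seed(1)
  res <- base_resources(ortho_scan_e = 1e-10)
  out <- fact_check_all(data.frame(species = "sp", ref_id = "R1",
                                   ortho_id = "O1", direction = "MD",
                                   unit = "PF08430", members = "PF08430"),
                        res)
  expect_equal(out$klass, "annotation_inconsistent_ortho")
  expect_equal(out$stages_run, "annotation")
})

test_that("gene prediction takes precedence over an N run (documented order)", {
  set.seed(19)
  ref_seq <- random_protein(220)
  dom_seg <- substr(ref_seq, 10, 90)
  region <- list(gene_id = "g",
                 sequence = paste0(random_dna_str(300), back_translate(dom_seg),
                                   random_dna_str(100), strrep("N", 40),
                                   random_dna_str(100)),
                 flank_nt = 0L)
  res <- base_resources(regions = setNames(list(region), "O1"))
  res$ref_seqs <- c(R1 = ref_seq)
  out <- fact_check_all(data.frame(species = "sp", ref_id = "R1",
                                   ortho_id = "O1", direction = "MD",
                                   unit = "PF08430", members = "PF08430"),
                        res)
  expect_equal(out$klass, "gene_prediction_error")
  expect_equal(out$stages_run, "annotation,gene_prediction")
})

test_that("an MD without a genomic region records the skipped stages", {
  set.seed(1)
  res <- base_resources() # no regions at all
  out <- fact_check_all(data.frame(species = "sp", ref_id = "R1",
                                   ortho_id = "O1", direction = "MD",
                                   unit = "PF08430", members = "PF08430"),
                        res)
  expect_equal(out$klass, "true_MD")
  expect_match(out$stages_run, "gene_prediction\\(no_genomic_region\\)")
  expect_match(out$stages_run, "genome_n\\(no_genomic_region\\)")
})

test_that("every event gets exactly one verdict from the known classes", {
  pl <- small_pipeline()
  expect_equal(nrow(pl$verdicts), nrow(pl$events))
  expect_true(all(pl$verdicts$klass %in%
                    c("annotation_inconsistent_ortho",
                      "annotation_inconsistent_ref", "gene_prediction_error",
                      "isoform_inconsistency", "undetermined_genome",
                      "domain_switching", "true_MD", "true_AD")))
  expect_true(all(pl$verdicts$klass[pl$verdicts$direction == "MD"] != "true_AD"))
  expect_true(all(pl$verdicts$klass[pl$verdicts$direction == "AD"] != "true_MD"))
})

test_that("verdicts are invariant under event order (property)", {
  pl <- small_pipeline()
  fx <- small_fixture()
  res <- check_resources(annotations = fx$annotations,
                         scan_hits = fx$scan_hits,
                         scanned_proteins = fx$scanned_proteins,
                         ref_seqs = fx$proteins, regions = fx$regions,
                         isoform_hits = fx$isoform_hits,
                         isoform_map = fx$isoform_map, clans = fx$clans)
  set.seed(5)
  shuffled <- pl$events[sample(nrow(pl$events)), ]
  v2 <- fact_check_all(shuffled, res)
  key <- function(v) {
    v <- v[order(v$ortho_id, v$direction, v$unit), ]
    paste(v$ortho_id, v$direction, v$unit, v$klass)
  }
  expect_equal(key(v2), key(pl$verdicts))
})

test_that("raising the E-value cutoff only moves MD events into the annotation class", {
  fx <- small_fixture()
  v1 <- run_fixture_pipeline(fx, domfact_thresholds(evalue_max = 0.01))$verdicts
  v2 <- run_fixture_pipeline(fx, domfact_thresholds(evalue_max = 1))$verdicts
  n1 <- sum(v1$klass == "annotation_inconsistent_ortho" & v1$direction == "MD")
  n2 <- sum(v2$klass == "annotation_inconsistent_ortho" & v2$direction == "MD")
  expect_gte(n2, n1)
  # and never the reverse: events in the class at 0.01 stay there at 1
  k1 <- with(v1[v1$klass == "annotation_inconsistent_ortho" &
                  v1$direction == "MD", ],
             paste(ortho_id, unit))
  k2 <- with(v2[v2$klass == "annotation_inconsistent_ortho" &
                  v2$direction == "MD", ],
             paste(ortho_id, unit))
  expect_true(all(k1 %in% k2))
})

test_that("planted single-cause errors are recovered with precision and recall 1", {
  rec <- planted_recovery(small_fixture(), small_pipeline()$verdicts)
  expect_true(all(rec$precision == 1))
  expect_true(all(rec$recall == 1))
  expect_equal(sum(rec$planted), nrow(small_fixture()$truth))
})

test_that("the corrected-protein hook overrides the translated search", {
  set.seed(1)
  corrected <- hits1("PF08430", 5, 85, protein = "O1", evalue = 1e-9)
  corrected$source <- "hmm_scan"
  res <- base_resources(corrected_hits = corrected)
  v <- check_gene_prediction(mk_event("MD"), res)
  expect_equal(v$klass, "gene_prediction_error")
  expect_match(v$evidence, "corrected_protein")
})
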