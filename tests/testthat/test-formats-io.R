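# Readers and writers: coordinate conventions, signature filtering, error
# reporting and round-trips.

write_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

test_that("Interpro JSON reader keeps Pfam-A only and counts dropped signatures", {
  p <- write_tmp(c(
    '[{"protein_id":"P1","species":"sp","source_db":"swissprot",',
    ' "signatures":[{"accession":"PF00250","source_database":"pfam",',
    '   "locations":[{"start":115,"end":202}]},',
    '  {"accession":"SM00339","source_database":"smart",',
    '   "locations":[{"start":110,"end":210}]}]},',
    ' {"protein_id":"P2","species":"sp","source_db":"trembl","signatures":[]}]'),
    ".json")
  ann <- read_interpro_json(p)
  expect_equal(nrow(ann$proteins), 2L)
  expect_equal(ann$hits$family, "PF00250")
  expect_equal(ann$hits$start, 115L)
  expect_equal(ann$hits$end, 202L)
  expect_equal(ann$report$n_dropped_signatures, 1L)
  expect_equal(ann$proteins$n_pfam_hits, c(1L, 0L))
})

test_that("Interpro API dialect parses and versioned accessions are stripped", {
  p <- write_tmp(c(
    '{"results":[{"metadata":{"accession":"P9","source_database":"reviewed"},',
    ' "entry_subset":[{"accession":"PF00096.29","source_database":"pfam",',
    '  "entry_protein_locations":[{"fragments":[{"start":5,"end":30},',
    '   {"start":40,"end":66}]}]}]}]}'), ".json")
  ann <- read_interpro_json(p)
  expect_equal(nrow(ann$hits), 2L)  # one hit per fragment
  expect_equal(unique(ann$hits$family), "PF00096")
})

test_that("malformed entries are skipped and logged, never silently dropped", {
  p <- write_tmp(c(
    '[{"protein_id":"A","signatures":[{"accession":"PF00001",',
    '   "locations":[{"start":1,"end":50}]}]},',
    ' {"protein_id":"B","signatures":[{"accession":"PF00002",',
    '   "locations":[{"start":60,"end":20}]}]},',
    ' {"protein_id":"C","signatures":[{"accession":"PF00003",',
    '   "locations":[{"start":5,"end":25}]}]}]'), ".json")
  ann <- read_interpro_json(p)
  expect_equal(ann$proteins$protein_id, c("A", "C"))
  expect_equal(ann$report$skipped$protein_id, "B")
  expect_error(read_interpro_json(write_tmp("{not json", ".json")),
               "malformed JSON")
})

test_that("domtblout parser uses the per-domain independent E-value", {
  row <- paste("ORT1 - 300 fhlN PF08430.12 80 1e-12 55.1 0.0 1 1 2e-09",
               "1.6e-08 50.2 0.0 1 80 115 194 110 200 0.95 -")
  p <- write_tmp(c("# comment", row))
  hits <- read_domtblout(p)
  expect_equal(hits$evalue, 1.6e-08)
  expect_equal(hits$family, "PF08430")
  expect_equal(hits$start, 115L)
  expect_equal(hits$end, 194L)
  expect_equal(hits$ga_pass, "unknown")
  # GA thresholds set the flag when supplied
  hits2 <- read_domtblout(p, ga_thresholds = c(PF08430 = 40))
  expect_equal(hits2$ga_pass, "yes")
  hits3 <- read_domtblout(p, ga_thresholds = c(PF08430 = 60))
  expect_equal(hits3$ga_pass, "no")
})

test_that("domtblout: comment-only file, threshold neutrality, column errors", {
  expect_equal(nrow(read_domtblout(write_tmp(c("# a", "# b")))), 0L)
  rows <- vapply(1:5, function(i) {
    ev <- if (i <= 2) "0.5" else "1e-20"
    paste("P", "-", "100", "q", sprintf("PF%05d.1", i), "50 1", "10 0 1 1",
          ev, ev, "10 0 1 50 1 50 1 50 0.9 -")
  }, "")
  hits <- read_domtblout(write_tmp(rows))
  expect_equal(nrow(hits), 5L)         # thresholding happens downstream
  expect_equal(sum(hits$evalue > 0.01), 2L)
  expect_error(read_domtblout(write_tmp("too few columns here")),
               "line 1")
})

test_that("clans TSV: mapping, empty clans, duplicates", {
  p <- write_tmp(c("PF00628\tCL0569\tTIM\tPHD\tdesc",
                   "PF00096\t\tx\tzf-C2H2\tdesc",
                   "PF00628\tCL0569\tTIM\tPHD\tdesc"))
  map <- read_clans_tsv(p)
  expect_equal(unname(map["PF00628"]), "CL0569")
  expect_false("PF00096" %in% names(map))
  expect_length(map, 1L)
  expect_error(read_clans_tsv(write_tmp(c("PF00628\tCL0569",
                                          "PF00628\tCL0001"))),
               "conflicting")
})

test_that("FASTA reader normalizes case, strips stops, validates alphabet", {
  expect_equal(read_fasta(write_tmp(c(">x", "acgt")), "dna"), c(x = "ACGT"))
  m <- read_fasta(write_tmp(c(">a desc", "MKLV*", ">b", "mklv")), "protein")
  expect_equal(m, c(a = "MKLV", b = "MKLV"))
  expect_error(read_fasta(write_tmp(c(">a", "MKJLV")), "protein"),
               "'J' at position 3")
  expect_error(read_fasta(write_tmp(c(">a", "ACGT", ">a", "ACGT")), "dna"),
               "duplicate")
  expect_error(read_fasta(write_tmp(c(">a", "ACGU")), "dna"), "illegal")
})

test_that("both annotation sources yield the same 1-based closed intervals", {
  jp <- write_tmp(c('[{"protein_id":"P1","signatures":[{"accession":"PF00250",',
                    '"locations":[{"start":115,"end":202}]}]}]'), ".json")
  dp <- write_tmp(paste("P1 - 300 fh PF00250.10 88 1e-12 55 0 1 1 1e-12 1e-12",
                        "55 0 1 88 115 202 110 210 0.95 -"))
  a <- read_interpro_json(jp)$hits
  b <- read_domtblout(dp)
  expect_equal(a[c("start", "end")], b[c("start", "end")])
})

test_that("verdict TSV round-trips all fields exactly", {
  v <- small_pipeline()$verdicts
  expect_gt(nrow(v), 0)
  p <- tempfile(fileext = ".tsv")
  write_verdicts_tsv(v, p)
  v2 <- read_verdicts_tsv(p)
  ord <- function(d) {
    d <- d[order(d$species, d$ref_id, d$unit, d$direction), ]
    rownames(d) <- NULL
    d
  }
  expect_identical(ord(v)[names(v2)], ord(v2))
  # empty verdicts -> header-only file
  p0 <- tempfile(fileext = ".tsv")
  write_verdicts_tsv(v[0, ], p0)
  expect_length(readLines(p0), 1L)
  expect_equal(nrow(read_verdicts_tsv(p0)), 0L)
})

test_that("pair table enforces one-to-one orthology", {
  p <- write_tmp(c("ref_id\tortho_id\tspecies", "R1\tO1\tsp", "R1\tO2\tsp"))
  expect_error(read_pair_table(p), "one-to-one")
  p2 <- write_tmp(c("ref_id\tortho_id\tspecies", "R1\tO1\tsp1", "R1\tO2\tsp2"))
  expect_equal(nrow(read_pair_table(p2)), 2L)
})
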