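Package: domfact
Title: Fact-Checking Protein Domain Gain and Loss Events in One-to-One Orthologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes true protein-domain gain and loss events between a
    reference proteome and its one-to-one orthologs from false events caused by
    annotation errors. Compares Pfam-A domain contents of ortholog pairs
    (overlap grouping, repeat collapsing), detects potential missing-domain and
    additional-domain events, and classifies each event with a staged
    fact-checking protocol: reconciliation against standardized HMM re-scans,
    verification of gene and isoform predictions via a built-in six-frame
    translated local-alignment search of the genomic region, detection of
    undetermined ('N') genome regions, and clan-based domain-switching calls.
    Includes downstream event statistics (per-species summary tables, ordinal
    position analysis, Spearman correlations against assembly quality metrics,
    paired t-tests, and phylogenetic generalized least squares with
    maximum-likelihood Pagel's lambda), plus a seeded synthetic-fixture
    generator that plants ground-truth events and errors of every class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    ape,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme
Config/testthat/edition: 3
NeedsCompilation: yes
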