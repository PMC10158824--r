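---
title: "Fact-checking protein domain gain and loss events between orthologs"
author: "domfact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fact-checking protein domain gain and loss events between orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domfact)
```

## The problem

Comparing the Pfam-A domain architectures of one-to-one orthologs is a
standard way to find lineage-specific protein innovations: a domain present
in a reference protein but absent from its ortholog is a candidate domain
loss (a *missing domain*, MD), and the converse is a candidate gain (an
*additional domain*, AD). Naively, public database annotations suggest such
events are common. Most of them, however, are artifacts of the annotation
pipeline itself: domain annotations applied inconsistently between species,
genes predicted with missing exons, canonical isoforms chosen differently
across species, or genome assemblies with undetermined stretches where the
domain-coding sequence would be.

`domfact` implements an automated fact-checking protocol that takes each
potential MD/AD event through a series of verification stages and assigns it
either to a specific error class or to the set of surviving, credible
events. The package assumes a high-quality, well-annotated *reference*
proteome (the role played by human or *S. cerevisiae* in genome-scale
applications of this kind of protocol) whose gene predictions and genome are
trusted axiomatically; all genome-side checks are therefore applied only to
the non-reference ortholog.

## Domain content

The unit of comparison is a protein's **domain content**: the set of
distinct Pfam-A units, deliberately insensitive to domain order and copy
number. Two reductions produce it:

* **Repeat collapsing.** A family occurring $k \ge 1$ times contributes one
  unit. An architecture D1–D2–D2 and an architecture D2–D1–D2 have the same
  content $\{D1, D2\}$.
* **Overlap grouping.** Hits that overlap over at least half of their
  lengths are grouped into a single unit. We normalize by the *shorter* of
  the two hits (a small domain nested inside a large one must merge — that
  is the permissive reading consistent with treating overlapping annotations
  as one entry), and we take the transitive closure (single linkage), so
  chained overlaps form one unit regardless of input order. The overlap
  ratio (default 0.5) is configurable.

Two units in different proteins *match* when their member-family sets
intersect: if one of several overlapping domains is present in the ortholog,
the content is considered the same. Overlap grouping is applied symmetrically
to both proteins of a pair by default; a `reference_only_grouping` flag
restores the stricter reference-only behavior for users who want the literal
asymmetric rule.

Potential events follow directly: each reference unit with no matching
ortholog unit is one MD candidate; each ortholog unit with no matching
reference unit is one AD candidate. Proteins longer than 5,000 residues are
filtered out beforehand. Counting granularity matters: the per-species
summary tables count *orthologs* presenting at least one MD (or AD), while
the event list retains one row per unit, and an ortholog with both an MD and
an AD counts once in the "orthologs with events" total.

## The decision tree

Each event passes through ordered stages; the first decisive stage wins and
every verdict records the stages that ran.

**MD events:** annotation reconciliation → gene-prediction check → genome
'N' check → final call.
**AD events:** annotation reconciliation → isoform check → final call.

1. **Annotation reconciliation.** All proteins of event-bearing pairs are
   assumed re-scanned against the Pfam HMM library under a standardized
   protocol (the package consumes HMMER domtblout files; it does not run
   hmmsearch). For an MD, a re-scan hit of the missing family on the
   *ortholog* at per-domain independent E-value ≤ 0.01 means the domain is
   detectable and only the database record was inconsistent
   (`annotation_inconsistent_ortho`). Failing that, if *no* re-scan hit on
   the reference reaches the cutoff, the reference's own annotation is
   unsupported (`annotation_inconsistent_ref`). AD events mirror the rule.
   The protocol names both an E-value cutoff and the curated GA bit-score
   option; these are mutually exclusive in a single scan invocation, so the
   decision criterion here is the E-value (which is also what makes
   "detectable at a more permissive threshold" a meaningful diagnosis), and
   GA-pass status is carried as evidence metadata only. Raising `evalue_max`
   can only move MD events *into* the ortholog-annotation class, never out
   of it — a monotonicity the tests assert.
2. **Gene prediction (MD only).** The reference subsequence spanning the
   missing unit's annotated interval (± `pad` = 10 residues) is searched
   against the ortholog's genomic region — the gene extended by 1,000 nt on
   each side — using the built-in translated search (below). A hit covering
   ≥ 50% of the segment at ≥ 40% identity means the genome encodes the
   domain even though the predicted protein lacks it: a
   `gene_prediction_error`. These permissive thresholds mirror the
   sensitivity of a TBLASTN-style search at close-to-moderate divergence;
   both are configurable and are echoed in every evidence record. A hook
   accepts externally re-predicted ("corrected") proteins with their own
   re-scan results, in which case this stage instead asks whether the unit
   is found in the corrected protein at E ≤ 0.01.
3. **Genome completeness (MD only).** If the region contains a run of `N`
   of length ≥ `min_run`, the absence of the domain cannot be established
   (`undetermined_genome`). `min_run` defaults to 1 — any undetermined
   nucleotide counts — because that is the protocol's stated behavior;
   it is configurable because isolated N's in distant flanks are often
   benign.
4. **Isoforms (AD only).** If any known alternative isoform of the
   reference protein contains a unit matching the gained unit (family-level
   matching — clan relationships are deliberately reserved for the
   switching call), the gain reflects an inconsistent canonical-isoform
   choice (`isoform_inconsistency`).
5. **Final call.** Surviving events are either **domain switching** — the
   counterpart protein carries a different family from the same Pfam clan —
   or true events (`true_MD` / `true_AD`). Whether switching requires the
   clan-mate to be a reciprocal event of the pair or merely to be present
   unmatched is genuinely ambiguous; the default mode (`"unmatched"`)
   requires the clan-mate unit to match nothing on the event side, and a
   `"reciprocal"` mode requiring a complementary AD/MD of the same pair is
   also implemented.

Stage order resolves ties: an MD with both a recoverable exon and an N run
is classed as a gene prediction error, with the dual evidence visible in the
evidence trail. Events are processed independently, so shuffling the event
list never changes a verdict (asserted as a property test). In the summary
tables the true-event columns include domain switching (switching is a
subtype of surviving events; it is also counted separately), so each
direction's error classes and true events partition the potential events
exactly — the row-sum identity the tests check on both synthetic data and
the bundled published counts.

When one ortholog has several same-direction events with different
outcomes, the per-species ortholog-level tables count it once under its
earliest-stage class (annotation before gene/isoform before undetermined
before true), keeping the partition identity exact at ortholog granularity.

## The translated search

The built-in stand-in for an external TBLASTN/spliced-alignment step is a
six-frame translation of the genomic region followed by local protein
alignment:

* Translation uses the standard genetic code; codons containing `N`
  translate to `X`; reverse frames translate the reverse complement, and
  each frame keeps a map from peptide position back to forward-strand
  nucleotide coordinates.
* Alignment is Smith–Waterman–Gotoh with affine gaps (a gap of length $k$
  costs $11 + k$), BLOSUM62 scoring, implemented in C++ with a
  deterministic traceback (ties prefer the diagonal, then the vertical,
  then the horizontal move). Stop codons are scored at −4 rather than
  forbidden, so exons abutting the alignment boundary still align; stops
  inside an accepted alignment are counted and reported as a possible
  intron or frameshift signal.
* There is **no spliced alignment**: an intron-split domain is found only
  through its best single exon, which must alone clear the coverage
  threshold. This is a deliberate scope boundary — the corrected-protein
  hook covers full-fidelity re-prediction — and the fixture generator's
  intron-split plants document the behavior.

The aligner is verified against two independent routes: a brute-force
enumerator (maximum over all substring pairs of an exhaustively recursed
global affine score) on small sequences, and `Biostrings::pairwiseAlignment`
on random pairs. At the default acceptance thresholds a 50-residue query
finds roughly one marginal chance alignment per hundred random 600-nt
regions (41% identity over ~29 columns is attainable by chance); the
false-positive test therefore asserts a rate at the percent level rather
than exactly zero.

## Statistics

* **Summary tables** use half-away-from-zero rounding to one decimal for
  every ratio and percentage (4462/1233 → 3.6), matching the convention of
  the published tables the package validates against; zero denominators
  yield `NA`.
* **Ordinal positions** of surviving events are classed N-terminal /
  internal / C-terminal within the carrier protein's unit order, restricted
  to pairs where both proteins retain ≥ 2 units after merging.
* **Spearman correlations** (assembly N50 and BUSCO completeness against
  event counts) use mid-ranks and a t-approximation p-value with
  $n - 2$ df, appropriate at $n = 9$ or 20 species; an exact permutation
  p-value is available behind a flag for $n \le 8$. A per-analysis species
  blacklist supports excluding outlier taxa (e.g. intracellular parasites
  with degenerate proteomes) without hard-coding them.
* **Paired t-tests** compare per-species MD% and AD% before and after
  fact-checking; df is $n - 1$. Degenerate inputs follow a documented
  convention (zero-variance, zero-mean differences: statistic `NA`, p = 1).
* **PGLS** regresses per-species event counts on patristic distance to the
  reference, with Brownian shared-branch-length covariance; Pagel's λ
  scales the off-diagonals and is estimated by maximum likelihood over
  [0, 1] (bounded search, tolerance 1e-6, boundaries checked explicitly;
  δ and κ are left at 1). At λ = 0 on an ultrametric tree the fit reduces
  to OLS exactly, a limit the tests verify, and the implementation is
  cross-checked against `nlme::gls` with `ape::corPagel`. $R^2$ and the
  slope's F-test come from the whitened regression against the
  GLS intercept-only null at the estimated λ. Duplicated zero-length tips
  make the covariance singular and are reported by name.

## The synthetic data generator

`generate_fixture()` produces a complete miniature dataset in every input
format — flat Interpro-style JSON (schema: an array of
`{protein_id, species, source_db, signatures: [{accession,
source_database, locations: [{start, end}]}]}` entries, with a decoy
non-Pfam signature per species to exercise filtering), protein and region
FASTA, a domtblout re-scan table, clans TSV, pair table, species metadata,
Newick tree — together with a truth table of planted events.

Its defaults are the generator's standing study conditions: 3 species × 40
pairs, a pool of 40 families with lengths uniform on 40–200 aa (the typical
Pfam range, so overlap and merge edge cases arise naturally), 12 families
grouped two-per-clan, 1,000 nt genomic flanks, and 10 planted events per
verdict class. Each planted pair carries exactly one cause: the re-scan
table reflects what is truly encoded in each protein, except where a plant
prescribes an inconsistency (e.g. an ortholog whose sequence carries a
domain its JSON record omits, or a reference record the re-scan cannot
support at E ≤ 0.01, modelling a weak divergent domain scored at E = 0.5).
Gene-prediction plants splice a back-translated copy of the reference
domain segment 60 nt past the coding body — an unannotated downstream exon
— using uniform synonymous codon choice; undetermined-genome plants carry a
30-nt N run at the same locus; clan-switch plants replace a clanned family
by its clan partner, yielding both an MD and a complementary AD verdict
(two truth rows). Everything is reproducible bit-for-bit from the seed.

What the fixtures do *not* emulate is homology detection under real
divergence: domain sequences are random per family, linkers are random, and
no phylogenetic sequence evolution is modelled. Passing the planted-truth
tests therefore demonstrates that the classification logic is correct and
deterministic, not that the translated search would recover diverged exons
in real genomes — that power question belongs to the underlying search
tools the protocol consumes.

## Validation against published counts

The package bundles (as plain TSV under `inst/extdata/published_counts/`)
the per-species summary counts of a genome-scale application of this
protocol to 9 non-human primates versus human and 20 fungi versus
*S. cerevisiae*. These printed counts are used as *inputs*: the
table-arithmetic layer reproduces every derivable ratio and percentage
(MD/AD ratios for all 29 species; the 9.2% / 31.2% surviving-MD and
32.2% / 57.1% surviving-AD totals; the 0.5% post-filter NHP event rate),
the Spearman layer reproduces the −0.7 N50/MD correlation, and the row-sum
partition identity holds wherever the source tables are internally
consistent. A handful of printed cells are not reconcilable with their own
rows (two fungal AD rows, the Gibbon percentages, and the
orthologs-with-events percentages, which count each ortholog once and are
therefore only bounded above by the sum of the printed MD and AD counts);
these are excluded from exact assertions, and the package's own
`tabulate_potential()` follows the union semantics. The absolute event
counts themselves are not recomputable at desk scale — they require
database-wide downloads and HMM scans — which is exactly why the test
strategy pairs printed-count arithmetic with planted-truth recovery on
synthetic data.

Problem sizes used by the default test and acceptance runs: fixtures of
120 ortholog pairs with 10 planted events per class; alignment-oracle
checks over all 1,521 pairs of length ≤ 3 sequences on a 3-letter alphabet
plus seeded random pairs up to length 8; 200 PGLS replicates on a 16-tip
coalescent tree. These sizes make the full suite run in well under a minute
while still exercising every stage of the protocol end to end.

## Known limitations

* Pairwise, reference-anchored comparison: a surviving MD says the domain
  is credibly absent from the ortholog relative to the reference; it cannot
  by itself distinguish loss in one lineage from gain in the other, nor
  does it model ancestral states.
* Domain-content granularity ignores order, copy number, fusion/fission and
  shuffling by design.
* The built-in translated search is unspliced and segment-level; deep
  intron fragmentation of a domain can push the best exon below the
  coverage threshold (such events then fall through to the genome check or
  survive as candidate true events).
* One-to-one orthology is taken as given; orthologs with radically
  different architectures that ortholog inference missed are invisible
  here.
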