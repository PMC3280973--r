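---
title: "Methods: scanning cryptic RSSs and dissecting RAG-mediated deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning cryptic RSSs and dissecting RAG-mediated deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragdelscan)
```

## The biological model

During V(D)J recombination the RAG recombinase cleaves DNA at recombination
signal sequences (RSSs): a conserved heptamer (consensus `CACAGTG`) and
nonamer (consensus `ACAAAAACC`) separated by a poorly conserved spacer of
12±1 bp (a "12-RSS") or 23±1 bp (a "23-RSS"). Efficient recombination joins
one 12-RSS with one 23-RSS (the 12/23 rule). Near-consensus "cryptic" RSSs
outside the antigen-receptor loci can be targeted illegitimately; when two
cryptic RSSs face each other in opposite orientation on the same
chromosome, RAG cleavage followed by non-homologous end joining deletes the
intervening DNA and leaves a coding joint that typically carries a few
random, non-templated nucleotides added by TdT.

`ragdelscan` implements the computational side of establishing this
mechanism for a recurrently deleted two-exon gene in B-cell precursor
acute lymphoblastic leukemia (BCP-ALL): a cluster of focal deletions whose
telomeric breakpoints pile up in a ~33 bp region of the second exon (with
the majority inside a 10 bp core) next to a 23-class RSS, while the
centromeric breakpoints fall at eight recurrent positions 101--557 kb
away, seven of which carry a 12-class cryptic RSS. Because each deletion
junction is unique in its exact breakpoints and inserted nucleotides,
counting distinct junctions within one patient counts independently arisen
subclones.

The package has five analysis layers, each usable on its own:

1. **RSS scanning** (`scan_rss()`, `pair_rss()`, `annotate_breakpoints()`),
2. **junction decomposition** (`decompose_junction()`,
   `cluster_breakpoints()`, `hotspot_window()`, `classify_deletion()`,
   `count_unique_junctions()`),
3. **cohort statistics** (`build_tables()`, `chi_square_2x2()`,
   `fisher_exact_2x2()`, `cohort_enrichment()`, `subclonal_summary()`),
4. **ChIP / qPCR quantification** (`pct_recovery()`, `delta_delta_ct()`,
   `compare_groups()`),
5. a **synthetic-data generator** (`simulate_locus()`,
   `simulate_deletion()`, `simulate_cohort()`, `simulate_chip_ct()`,
   `simulate_qpcr_ct()`) that provides ground truth for all of the above,
   orchestrated end to end by `run_full()`.

## RSS scanning and scoring

`scan_rss()` enumerates every heptamer/spacer/nonamer window on both
strands for spacer lengths 11--13 and 22--24 and scores each window by
position-wise mismatches against the consensus. Design choices:

* **CAC anchor** (`require_cac = TRUE`). The first three heptamer bases are
  the functional requirement for RAG cleavage and are conserved in every
  validated breakpoint motif we model, so candidates must begin `CAC` in
  reading orientation. The flag can be dropped for exploratory scans.
* **Mismatch thresholds.** Defaults admit every validated breakpoint motif
  with zero margin: heptamer ≤ 3 mismatches (the worst validated heptamer,
  `CACTGCA`, has 3) and nonamer ≤ 6 (the worst validated nonamer,
  `CCAGGACAT`, has 6). Raising thresholds never removes candidates
  (monotonicity is property-tested).
* **Score `2·heptamer_mm + nonamer_mm`.** Nothing in the source ranks
  candidates numerically; the heptamer is weighted double because cleavage
  chemistry acts at the heptamer. Weights are arguments, not constants.
* **Coordinates** are 0-based half-open on the plus strand. A minus-strand
  candidate reports the plus-strand interval it occupies plus a strand
  flag; its heptamer/nonamer sequences are reported in reading
  orientation.

`pair_rss()` keeps only pairs with different spacer classes whose
heptamers face each other across the would-be-deleted segment: the left
partner on the plus strand and the right partner on the minus strand, with
disjoint footprints. Both RSS footprints are excised with the deleted DNA,
so the predicted deletion runs from the plus partner's footprint start to
the minus partner's footprint end.

`annotate_breakpoints()` assigns each breakpoint the lowest-scoring
candidate whose cleavage edge lies within a window (default 50 bp), with
ties broken by distance and then by leftmost position. A breakpoint may
legitimately have no candidate: one of the eight recurrent centromeric
breakpoints has no detectable RSS, and the annotator reports it as absent
rather than forcing a match.

## Junction decomposition

`decompose_junction()` explains a deletion-spanning junction read as
*proximal flank + inserted nucleotides + distal flank* by greedy maximal
exact matching: the proximal breakpoint is the longest junction prefix
matching the proximal reference's prefix, the distal side is the longest
junction suffix found in the distal reference, and the unexplained middle
is the non-templated insertion. Conventions worth stating precisely:

* **Ambiguity is resolved greedily.** When an insertion happens to start
  with the same base the proximal reference continues with, two
  decompositions reconstruct the junction equally well; the maximal-prefix
  rule picks the one with the longest proximal match, deterministically.
  The generator's `non_extendable` option (default on) resamples such
  insertions so that simulated ground truth stays unique; with it on,
  parameter recovery is exact by construction and verified at
  10,000 events in the test suite.
* **Microhomology.** When prefix and suffix matches overlap, the overlap
  is reported as microhomology with the canonical split at the
  proximal-most position and an empty insertion. The source data reports
  only insertions, so microhomology handling is a defined extension: the
  generator does not plant controlled-length microhomologies (zero-length
  insertions produce whatever overlap the flanks naturally share), and the
  decomposer's microhomology path is exercised with constructed cases.
* **Anchoring.** Each junction end must match at least `min_anchor`
  (default 10) exact bases, reflecting the long exact anchors implied by
  breakpoint-spanning PCR assays. Reads failing on both sides are flagged
  `"unrelated"` — an observed outcome for one amplicon in the source
  screen — rather than raising an error; one-sided failures are
  `"partial_anchor"`.

`cluster_breakpoints()` is single-linkage clustering with a 10 bp default
tolerance. The recurrent deletion types are kilobases apart, so the value
is uncritical, but it must be fixed for deterministic Roman-numeral labels
ordered by position. `classify_deletion()` matches new breakpoints to a
catalog within 50 bp (ties to the lower-position cluster; anything
farther — such as a breakpoint 2 kb downstream in the 3'UTR — is
`"novel"`). `hotspot_window()` computes the minimal contiguous interval
holding at least `ceiling(fraction · n)` breakpoints by sliding a k-window
over the sorted positions; it equals an exhaustive search over all
intervals (property-tested) with ties broken leftmost, and inclusive
lengths (a single position has length 1).

## Cohort statistics

`chi_square_2x2()` is Pearson's chi-square *without* continuity
correction — the uncorrected statistic is what reproduces the reported
cohort P-values from their printed counts — and matches the closed form
$N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$. `fisher_exact_2x2()`
computes the two-sided P by minimum-likelihood summation of hypergeometric
table probabilities (the common package definition; a doubling variant is
behind a flag) and is tested against brute-force enumeration for all
tables with total ≤ 200.

The reference analysis used Fisher "when sample groups were small" without
defining small. The textbook expected-count rule (any expected cell < 5)
turns out to contradict the reported test choices: a 23-sample subgroup
has an expected cell of 2.1 yet was analyzed by chi-square. A group-size
rule — smallest table margin below 20 — selects exactly the one subgroup
reported with Fisher's test and nothing else, so `contingency_test()`
defaults to it (`threshold = 20`), with the expected-count rule available
via `small_rule = "expected"`.

`build_tables()` cross-tabulates group membership against deletion status,
excluding rows with missing group values (cohort classifications overlap
and have missing entries, so per-classification totals differ), and
accepts either per-sample rows or pre-aggregated counts via `weight`. The
packaged fixture `cohort_counts()` carries the published per-classification
counts in that aggregated layout.

## ChIP and qPCR quantification

Percent recovery is `dilution · 2^(Ct_input − Ct_ChIP) · 100`; it is
strictly increasing in the Ct difference and linear in dilution, values
above 100% are allowed but flagged. Relative expression is
`2^−ΔΔCt` with technical replicates averaged per (sample, gene) before any
subtraction and the calibrator mapping to exactly 1. Fold changes are
invariant under a plate-wide constant shift of one gene's Cts across all
samples, but *not* under per-sample shifts — the test suite asserts
exactly that property, since a sloppier invariance claim would be false.
`compare_groups()` is the classical pooled-variance Student t-test (the
method named by the source analysis), two-sided, with Welch behind a flag
and the convention P = 1 for two zero-variance groups with equal means.
No error propagation from replicate Cts is attempted.

## What the generator emulates — and what it does not

`simulate_locus()` builds a locus whose geometry scales with
`scale_factor`: at scale 1 the eight centromeric target sites sit
101--557 kb from the hotspot (endpoints fixed, interior spacing even —
the true interior positions are not modeled); at the default test scale
0.01 the locus is ~6.6 kb. Fixed-size features (exons, motifs, flanks) do
not scale. The background is i.i.d. uniform ACGT, rejection-sampled until
it contains no zero-mismatch RSS candidate, so embedded truth is
unambiguous at mismatch 0 while realistic near-consensus noise remains.
Scales small enough for site footprints to collide raise an error naming
the minimal feasible scale.

`simulate_deletion()` draws a distal site uniformly, adds a uniform
1--10 nt TdT insertion (the source reports "random addition of single
nucleotides" with no distribution; length 0 is allowed by configuration),
and jitters breakpoints around the RSS cleavage edges to emulate end
processing: the telomeric breakpoint falls in a 10 bp core with
probability 0.75 and otherwise in the surrounding 33 bp region, the
centromeric breakpoint gets ±5 bp. This reproduces the observed hotspot
geometry as *distributional* truth, so a finite cohort's 75%-window is
near 10 bp but fluctuates.

`simulate_cohort()` uses the published subgroup sizes (160 hyperdiploid,
142 ETV6-RUNX1, 23 BCR-ABL1, 17 MLL, 180 other, 200 unknown = 722 BCP-ALL,
plus 109 T-ALL and 26 normal controls) and the published per-subgroup
clonal-deletion rates (3.1%, 19.0%, 26.1%, 0%, 7.2%, 7.0%), whose weighted
mean of 9.0% reproduces the overall prevalence. Deletion-positive samples
carry 1--4 independent deletion clones with probabilities
(0.73, 0.18, 0.06, 0.03), so ~27% of positives are multiclonal and four
clones are possible, as observed. Clonal fractions come from a symmetric
Dirichlet over the clones plus a residual normal compartment,
rejection-sampled so clonal samples have a major clone at or above the
MLPA detection fraction and subclonal-only samples stay below it. The
detection thresholds — MLPA at 30% clonal fraction, breakpoint-spanning
PCR at 1% — are modeling constructs (a bulk probe-ratio assay versus an
amplification assay), configurable and not measured values. Samples
without a clonal deletion carry PCR-only subclones at rate 0.18, the rate
observed in the published MLPA-negative screen. T-ALL and normal samples
never carry deletions.

Not emulated: real genome coordinates and sequences, MLPA probe chemistry
or intensity data, SNP-array segmentation, relapse dynamics beyond the
cohort structure, sequencing errors in junction reads, and chromatin
state. Passing recovery tests therefore demonstrates the *pipeline's*
correctness on data with the assumed structure, not robustness to
real-world noise sources the generator omits.

`simulate_chip_ct()` / `simulate_qpcr_ct()` invert the two quantification
formulas exactly and add Gaussian Ct noise (default σ = 0.1 cycles). The
ChIP truth table's magnitudes are invented (the source shows them only
graphically) but keep the qualitative contrast: shared promoter H3K4me3,
B-lineage-specific H3K4me3 at the exon-2 hotspot.

## Determinism and numerical conventions

Every stochastic stage derives a child seed from the master seed by a
fixed stage-name hash, so identical configurations give byte-identical
outputs and stages can be rerun in isolation. All internal coordinates are
0-based half-open; BED output keeps that convention, VCF output is 1-based
per its specification. Sorting tie-breaks (score, then position, then
strand) are fixed so results are reproducible across platforms.

## Problem sizes in the shipped tests

The test suite runs the full default cohort (857 samples) once,
decomposes 10,000 simulated junctions for the exact-recovery check,
compares the scanner against a naive exhaustive enumerator on 100 random
2 kb sequences, and checks Fisher's test against brute-force enumeration
on 1,000 random tables with totals up to 200 — sizes chosen to make
binomial 3σ bands tight relative to the effects being recovered while the
whole suite stays in the low minutes. `scripts/acceptance.R` recomputes
the headline quantities at similar sizes.

## Known limitations

* The scanner scores by mismatch counts, not an information-content or
  cleavage-efficiency model; it ranks candidates sensibly but does not
  predict recombination rates.
* The even interior spacing of distal sites is a simplification; only the
  101 and 557 kb endpoints are constrained by the modeled system.
* Junction decomposition assumes the proximal reference is given
  break-aligned (the junction's first base is the reference's first
  base); aligning junction reads to arbitrary genomic context is a
  split-read alignment problem out of scope here.
* Enrichment P-values are reported unadjusted across subgroups, matching
  the reference analysis; no multiple-testing correction is applied.
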