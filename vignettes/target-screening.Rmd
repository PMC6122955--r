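---
title: "Screening transcription-factor targets and their survival associations"
author: "tfTargetScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening transcription-factor targets and their survival associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfTargetScreen)
```

## The scientific question

A transcription factor suspected of maintaining a stem-like tumour cell
state raises two linked questions: *which genes does it directly
regulate*, and *do those targets matter for patients*? This package
implements the computational chain that answers both from four
complementary data types: nascent-RNA knockdown contrasts (which genes
change transcription when the factor is depleted), ChIP-seq peak calls
(where the factor binds), promoter sequence (is the factor's recognition
site over-represented near the regulated genes), and a tumour cohort
with expression and follow-up (are the targets associated with
survival). A target nominated by all lines of evidence — down after
knockdown in two independent cell lines, bound near its TSS in
replicated ChIP, motif-bearing, and prognostic — is a far stronger
candidate than one nominated by any single assay.

## Differential transcription

Per (cell line, shRNA) contrast the input is a per-gene table of
knockdown-versus-control statistics (log2 fold change, p, adjusted p,
mean RPKM, gene length), as produced by count-based differential
testing; this package consumes such tables rather than refitting the
count model. A gene passes one contrast when

* mean RPKM > 0.25 (transcribed at all),
* gene length ≥ 300 b (short genes have unstable nascent-RNA coverage),
* |log2 FC| > 0.58, i.e. 1.5-fold, and
* Benjamini–Hochberg adjusted p < 0.1.

All four bounds are applied strictly as printed: a gene at exactly the
threshold fails (the length bound is the inclusive "minimum 300").
Missing adjusted p-values fail the gene rather than erroring, since
count-model output routinely censors low-information genes. The FDR
method is fixed to Benjamini–Hochberg (`bhAdjust`, delegating to
`stats::p.adjust`); the source analyses say only "FDR-adjusted", and BH
is the field default.

The cross-cell-line rule requires a passing contrast with the *same
sign* in at least one shRNA of **every** cell line. Genes down after
knockdown form the factor-**upregulated** set, genes up form the
**downregulated** set; a gene qualifying in opposite directions across
cell lines is recorded as conflicted and joins neither set, keeping the
two sets disjoint by construction. A variant reading of the selection
rule (adjusted p required in only one named cell line) exists in the
source description; the explicit four-filter checklist applied per
contrast was implemented as the single rule, and the conflict-handling
above is the package's own choice.

## Peak-to-gene binding classification

Peaks are first filtered against blacklist regions (any shared base
removes the peak) and genes are restricted to the expressed set (mean
nascent RPKM > 0.25), because assigning a peak to a silent gene's TSS is
biologically meaningless in this design. Each peak is then assigned to
the closest expressed TSS on its chromosome, measuring distance from the
peak summit when the caller provides one and from the interval midpoint
otherwise. The assignment is *reciprocal*: a gene's candidate peaks are
exactly the peaks assigned to it, so a peak that is closer to some other
gene never supports a call, even if it lies inside the window. Ties
between equidistant TSSs break toward the lexicographically smaller gene
id, making results order-independent.

Per replicate, a gene is **proximal** when its nearest candidate peak
lies within ±5 kb of the TSS (inclusive), else **distal** within
±100 kb, else none. The cross-cell-line consensus is:

1. proximal, when at least one replicate in *each* cell line is
   proximal;
2. otherwise distal, when at least one replicate in each cell line is
   distal **and** no replicate anywhere is proximal (a gene with mixed
   proximal and distal replicate calls that fails rule 1 is demoted to
   neither — its replicates are then not uniformly distal);
3. otherwise neither (including genes with no assigned peak).

The proximal rule is evaluated first; the alternative precedence would
send many solidly proximal genes to "neither" whenever a single
replicate saw only a distal peak. Note rule 2 deliberately tolerates a
replicate with *no* peak (dropout) while rejecting one with a
*proximal* peak: absence of evidence differs from conflicting evidence.

`commonPeaks` implements the complementary peak-level view (a peak is
reproducible when it overlaps a peak from at least one replicate of the
other cell line); both views are exposed because summaries of binding
have been phrased both ways. Enhancer context is annotated by merging
strong-enhancer segmentation intervals across cell lines
(`mergeIntervals`) and flagging genes whose assigned peaks overlap any
merged region.

## Motif over-representation

Promoter windows are `[TSS − w, TSS + w)` with `w = 5000` by default,
reverse-complemented for minus-strand genes so "upstream" is
strand-consistent. Scanning supports two motif forms. An IUPAC consensus
(the motivating one is the stringent 14-base `DGTTAATNATTAAC`) matches a
position when every sequence base falls in the position's degeneracy
class; an `N` in the *sequence* matches nothing, including motif `N` —
masked bases never create hits. A position weight matrix matches when
the relative score `(S − S_min) / (S_max − S_min)` reaches the
threshold (default 0.85). Reverse-strand hits are found on the reverse
complement and reported in forward coordinates; overlapping hits all
count.

Enrichment of a motif in a foreground gene set against a background set
uses a per-nucleotide binomial model: with `x_b` background hits over
`L_b` scanned positions (both strands), `p = x_b / L_b`,
`mu = L_t * p`, `sigma = sqrt(L_t * p * (1 − p))` and
`z = (x_t − mu) / sigma`, with no continuity correction; an exact
two-sided binomial p-value is reported alongside, since the z-score
variant used by promoter-scanning web services is not uniquely
documented. A degenerate background rate (0 or 1) leaves z undefined
and flagged rather than fabricating a value. The published
phylogenetic-conservation filter is *not* implemented — it requires
external alignment tracks — so absolute z values here are not
comparable to conservation-filtered ones.

Two numerical facts shape how the package is exercised at desk scale:

* **Exact matches of a stringent 14-mer are rare.** Under i.i.d. bases
  at 40% GC the per-position match probability of the consensus is
  about `2e-7`, so a background of a few hundred 10-kb windows
  typically contains *zero* exact hits and the z-score is degenerate.
  Enrichment comparisons therefore scan the consensus as an indicator
  position matrix at the 85% relative threshold (`consensusToPwm`),
  which tolerates up to two mismatching positions — the same
  matrix-at-85% idiom the motivating analysis ran — and keeps the
  background rate well defined. The exact consensus scanner remains the
  primitive for site-level questions (e.g. verifying planted insertions
  or the 8× tandem reporter construct, which yields exactly one
  forward-strand hit per 21-base repeat unit).
* **A palindromic motif double-counts.** The consensus is nearly its
  own reverse complement, so each physical site contributes a forward
  and a reverse hit; counts then overdisperse relative to the binomial
  model (observed sd of null z ≈ 1.6). This is a property of that
  motif, not of the statistic, and is why the package's null
  calibration of z is demonstrated with shuffled, generally
  non-palindromic motifs (sd ≈ 1.3, |z| < 3 in ~97% of null
  foregrounds). Users ranking near-palindromic motifs should treat the
  binomial z as anti-conservative in absolute terms and rely on the
  ranking against matched decoys, which shares the artefact.

Ranking is by z descending, undefined z last, ties broken by the number
of foreground genes with a hit and then by name.

## Survival association and the gene-set permutation test

Expression enters the Cox model as `log10(x + 1)` (the constant
preserves zeros). Cohort samples whose histology matches any of five
neuroendocrine exclusion labels (case-insensitive, whitespace
normalized; `neuroendocrineExclusionLabels()`) are removed first,
restricting to the adenocarcinoma biology under study. Each gene is fit
in a univariate Cox proportional-hazards model via the survival package
with Efron tie handling (Breslow by flag); hazard ratio > 1 is
association with *reduced* survival. Within the tested gene set,
Wald p-values are BH-adjusted and each gene receives the signed score
`−log10(q)`, positive for reduced survival — the package's sign
convention for ranked bar displays. A constant covariate is an error; a
monotone likelihood is flagged non-converged with |beta| capped at 15
rather than failing the whole set.

The permutation test scores a signature by the fraction of its genes
significant in the tested direction at an FDR threshold (0.1 or 0.25),
and draws N same-size sets from the expressed background — genes with
nascent RPKM > 0.5 in at least one replicate of both cell lines — each
scored *identically*, with the FDR re-computed inside every drawn set;
re-using the observed set's adjustment would bias the null. Per-gene
Cox fits are computed once and cached across permutations; since only
`wald_p` and the hazard direction enter the score, caching cannot change
results (a property the tests assert). The empirical p-value is the
add-one estimator `(1 + #{null ≥ observed}) / (N + 1)`, which never
returns zero. At the default N = 10,000 the relative standard error of
an estimated p near 0.05 is `sqrt(0.95 / (10000 × 0.05)) ≈ 0.044`,
below the 10% design bound (`permutationRelativeSe`).

Two design subtleties surfaced in calibrating this test at small scale
and are worth knowing when applying it:

* Null draws share the cohort's per-gene fits with the observed set, so
  a draw containing the same significant gene *ties* with it. The tie
  mass is roughly the set-to-background size ratio `m / |bg|`; if that
  ratio is not well below the significance level of interest, small
  empirical p-values are unattainable no matter how many permutations
  are run. Signatures should therefore be small relative to the
  background (the package's calibration checks use 10 of 250).
* Under a null cohort the fraction-significant statistic is highly
  discrete (mostly 0), so the empirical p is conservative; calibration
  should be read as "at most nominal", not exactly nominal.

## The synthetic-data generators

Every generator is deterministic given one integer seed; per-(cell
line, replicate) sub-streams are derived arithmetically from it
(`seed + 104729·i + 7919·j`, reduced modulo a large prime), so a bundle
is reproducible byte for byte. Defaults define the desk-scale study
conditions: 200 genes on two chromosomes (log-normal lengths, median
~20 kb, sdlog 2 so a small tail fails the 300-b filter; exponential TSS
spacing, mean 50 kb), two cell lines × two ChIP replicates (peak width
300 b, placement sd 200 b around the TSS, 10% dropout, 5 background
peaks/Mb), two knockdown shRNAs per line (|log2 FC| = 1.5 effects,
Normal noise sd 0.2; null p-values exactly uniform by construction
because p is the two-sided Normal tail of the simulated fold change),
promoters of ±5 kb at 40% GC with exact-consensus insertions in motif
genes, and a 300-patient cohort. Survival times are exponential with
rate `baseline × exp(sum(beta_g z_g))` where `z_g` is the z-scored
`log10(x + 1)` covariate — the same transform the analysis applies — so
planted `beta` values are recovered on the analysis scale; censoring is
an independent exponential, and 10% of samples carry an excluded
histology label so the cohort filter is exercised.

What the simulation does **not** emulate: read-level noise and peak
callers (peaks are placed, not called), correlated expression between
genes, LD-like structure among promoters, non-proportional hazards,
informative censoring, and a genome-scale motif background of tens of
thousands of genes. Passing tests therefore demonstrate correctness
of the *computational chain* and its statistical calibration under the
stated generative model, not performance on real sequencing data.

## Numerical and testing choices

Coordinates are BED 0-based half-open on disk and 1-based closed
(GenomicRanges) in memory, converted only at the reader/writer boundary,
so write/read round trips are exact. All threshold comparisons are
strict as printed; window bounds are inclusive. Cox fits use
`coxph` with `eps = 1e-9`, max 50 iterations. Test oracles are
independent re-derivations: interval operations against enumerated base
sets, BH against a literal step-up loop, peak annotation against an
`O(n·m)` nested-loop reimplementation (200 random instances), Cox
against a two-stage grid search of the Efron partial likelihood, the
permutation test against exhaustive subset enumeration on a 6-gene
background, and the scanner against a position-by-position IUPAC
matcher. Heavier statistical properties run at reduced but stated
sizes: Cox recovery with 50 cohorts of n = 1000 at beta = 0.8
(mean error tolerance ±0.15), Wald-p uniformity over 500 null genes,
permutation calibration over 200 runs at N = 500, motif recovery over
20 seeded runs and null calibration over 200 foreground draws from 40
unplanted pools, and end-to-end planted-truth recovery on a 100-gene,
200-patient bundle with N = 500.

## Known limitations

* The binomial z ignores within-gene clustering and palindromic strand
  pairing of hits (overdispersion; see above).
* The conservation filter of the original motif analysis is out of
  scope, so motif rankings are comparable only within a run.
* Only univariate Cox models are fitted; no stratification, covariate
  adjustment, or proportional-hazards diagnostics.
* The DE stage consumes externally computed per-gene statistics; it
  does not fit count models.
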