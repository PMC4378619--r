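---
title: "Methods: calling and quantifying termination read-through"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and quantifying termination read-through}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termread)
```

`termread` analyses strand-specific RNA-seq coverage around short RNAPII
transcripts (snRNAs, snoRNAs, CUTs) whose termination depends on the
NNS pathway and the nuclear exosome. This vignette documents the models,
the parameters that matter, the synthetic-data generator the tests rely on,
and the design choices made where the underlying manual workflow left the
rules implicit.

## Coordinate conventions

All coordinates are 0-based half-open (BED convention) on both strands;
GTF input is converted at the boundary (`start - 1`). A feature's 3′ end is
`end` on the plus strand and `start` on the minus strand. Strand-specific
coverage is stored as one dense per-base vector per strand per contig.
A "stranded bedGraph" encoding minus-strand signal as negative values is
accepted and split, with absolute values taken — a common dialect in
strand-specific RNA-seq.

## Extension calling

The manual procedure this formalizes inspects per-genotype coverage tracks
and annotates an extended transcript (ET) from just after the parent's
annotated 3′ end "until continuous reads on the same strand are no longer
detected", with two positional exceptions: tandem (tail-to-head)
neighbors end the annotation just before their TSS, and intron-hosted
parents end it at the host exon's 5′ boundary.

"Continuous reads" has no unique formalization, so the caller exposes it as
two parameters:

* `min_coverage` (θ, reads; default 5) — a base counts as covered when its
  per-base coverage is ≥ θ.
* `max_gap` (g, nt; default 25) — the longest run of sub-threshold bases
  bridged without ending the call.

Defaults were fixed once against the generator's design depth (50× over the
mature span, hence 40× over an extension with read-through fraction
ρ = 0.8): at those depths a Poisson track essentially never dips below
θ = 5 inside a real extension, and never rises above it outside one, so
boundary calls are insensitive to both values over a wide range. Two guard
rails complete the rule set: `max_extension` (default 5,000 nt, longer than
any read-through transcript the method is expected to meet) and
`min_et_length` (default 25 nt; shorter calls are reported as
`none_called`, since a handful of covered bases past an annotation is
indistinguishable from annotation slack).

Two deliberate asymmetries:

* **Tail-to-tail neighbors impose no positional cap.** A convergent gene's
  TSS is exactly what a read-through transcript may cross, and that
  crossing is the signal the interference classifier consumes. Capping
  there would make interference undetectable by construction.
* **Replicate handling.** The pipeline calls extensions on coverage pooled
  across replicates of a condition. Pooling stabilizes the boundary (the
  effective depth multiplies by the replicate count) and mirrors inspecting
  one track per genotype; per-replicate calling remains available by
  passing single-replicate tracks to `call_extension()`.

Orientation of the (feature, nearest-downstream-neighbor) pair is
classified geometrically: intersecting spans are `overlapping`; same-strand
downstream neighbors are `tail_to_head`; opposite-strand neighbors are
`tail_to_tail` when the neighbor end proximal to the feature's 3′ end is
the neighbor's own 3′ end (ties, possible only for degenerate geometries,
resolve to `tail_to_tail`), `divergent` otherwise.

## Percent extension

The extension burden of a transcript is the area ratio

\[
\mathrm{percent} \;=\; 100 \cdot
  \frac{A(\mathrm{ET})}{A(\mathrm{parent} \cup \mathrm{ET})},
\qquad A(I) = \sum_{i \in I} c_i ,
\]

with \(c_i\) the per-base coverage. The rectangle-rule sum is exact here —
coverage is already a per-base step function, so a trapezoid correction
would only blur the interval edges. The ratio is invariant under scaling
the whole track, an empty ET gives 0, and a zero denominator is an explicit
error rather than `NaN`. Under the rectangular read-through model with
mature length \(L_m\), extension length \(L_e\) and read-through fraction
\(\rho\), the expected value is \(100\,\rho L_e /(L_m + \rho L_e)\);
inverting this at the called ET gives the estimator
\(\hat\rho = p L_m / (L_e (1 - p))\), \(p = \mathrm{percent}/100\), which
the acceptance checks require to recover simulated ρ within ±0.02 at 50×
depth.

## Differential expression

The DE stage re-implements the count-based machinery usually delegated to
edgeR, so the pipeline is self-contained and each piece independently
testable:

* **TMM normalization.** Pairwise against a reference sample (chosen by the
  75th-percentile rule): M-values trimmed 30 % two-sided, log-abundances
  trimmed 5 % two-sided, precision-weighted by the asymptotic binomial
  variance, factors rescaled to geometric mean 1. The implementation agrees
  with an independent literal recomputation (and with edgeR) to 1e-10.
  One subtlety: because the precision weights depend on library depth,
  rescaling one library by 4× reproduces per-sample normalized counts only
  to ≈1 %, not exactly — a property shared by any weighted trimmed mean,
  asserted at that tolerance rather than hidden.
* **Common dispersion.** Method of moments pooled over features:
  \(\hat\varphi = \max\{0, \sum_f (v_f - m_f) / \sum_f m_f^2\}\) over
  within-group means and variances of normalized counts. No tagwise or
  empirical-Bayes shrinkage is implemented — a documented divergence from
  edgeR defaults that matters little at a common dispersion of ~0.05–0.1
  with 4 replicates, and keeps the estimator exactly testable by
  simulation.
* **Exact NB test.** Counts are rescaled to the geometric-mean effective
  library size and summed per group; conditional on the total, the
  two-sided p-value sums the probabilities of all splits no more likely
  than the observed one (minimum-likelihood rule, ties included, with a
  1 + 1e-10 relative guard against floating-point tie misses). With
  \(\varphi = 0\) the conditional law is exactly binomial, which the tests
  verify by brute-force enumeration over all totals ≤ 50. All-zero
  features return p = 1, log2fc = 0.
* **Fold changes.** `log2((mean_treatment + 0.5) / (mean_reference + 0.5))`
  — the 0.5 pseudo-count keeps fold changes finite at zero counts.
* **Thresholds.** Up/down labels need |log2fc| ≥ log2(1.5), p < 0.05 and
  FDR ≤ 0.1 jointly. The fold-change cut is kept at log2(1.5) ≈ 0.585
  exactly (reported elsewhere rounded to 0.6) and is config-exposed.
  FDR is Benjamini–Hochberg via `stats::p.adjust`.

Per-feature group comparisons for figure-style bar plots use the unpaired
two-tailed Student's (pooled-variance) t-test with the conventional star
levels (p < 0.05, < 0.01, < 0.001); two constant equal groups give p = 1 by
convention. Cross-platform agreement is summarized by the Pearson
correlation of log2 fold changes over the shared feature ids.

## Interference classification

Candidate pairs are formed from each ET call and the nearest annotation at
least partly downstream of the parent's 3′ end within `max_pair_distance`
(default 1,000 nt — comfortably covering the convergent-gene geometries
that motivate the analysis, while excluding unrelated loci). The verdict
table is deliberately strict:

| TSS covered | target label | verdict              |
|-------------|--------------|----------------------|
| yes         | down         | `interference`       |
| yes         | up/unchanged | `candidate_no_effect`|
| no          | any          | `no_overlap`         |

"TSS covered" means the parent-plus-ET span contains the TSS base itself
(the target's 5′-most base in its own orientation); a configurable upstream
margin (default 0) admits promoter-window variants. The hard invariant —
no `interference` verdict without TSS overlap — is fuzzed over 10⁴ random
geometries in the tests. Tandem targets remain eligible but are flagged
`ambiguous_same_strand`: with strand-specific data, reads over a
same-strand downstream gene cannot be attributed between that gene and a
long read-through transcript.

Antisense annotations are built by flipping the strand of each ORF coding
region and prefixing the id with `AS_`; UTRs are excluded by contract
(inputs are CDS spans), and re-application is an error rather than a
silent `AS_AS_` id.

## Occupancy metrics

Published occupancy comparisons at termination zones are qualitative
(arrows on browser tracks); the two metrics here were chosen for exact
testability:

* **Downstream occupancy ratio** — total mutant over total wild-type
  signal in the strand-aware window `[3′ end, 3′ end + W)`, W = 500 nt by
  default (inside the termination zone, shorter than typical read-through
  transcripts), with a pseudo-signal ε = 1 per window so the ratio is
  always defined. Tracks are compared after `per_million` scaling; the
  normalization used by published figures is unstated, so per-million is
  this package's default.
* **Centroid shift** — the difference of signal-weighted mean positions in
  an analysis window, sign-flipped on the minus strand so positive is
  always 3′-ward. It is exactly linear under translation and invariant
  under positive scaling of either track; these identities hold to machine
  precision and are tested as such. Exact recovery of a planted shift
  requires the window to contain only the (translated) termination peak;
  with additional static background in the window the estimate is
  attenuated by the background's mass fraction, which is why the recovery
  tests use long parents and zero body level.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, with
defaults fixed at the study design it mirrors: two genotypes
(`wildtype`, `mutant`), **4 replicates each**, snRNA-scale parents
(150 nt) at 50× coverage (λ = 200 expected reads, coverage scale 0.25),
NB dispersion φ = 0.05, read-through fractions ρ = 0 (wild type) and 0.8
(mutant), 600 nt extensions, convergent genes whose TSS sits inside the
extension span, interference coefficient κ = 0.6, and a 150 nt mutant
occupancy shift.

* **Loci.** Three layouts — tail-to-tail, tail-to-head, isolated — placed
  in non-overlapping blocks; minus-strand loci are exact mirror images of
  the plus-strand construction, which the mirror-symmetry tests exploit.
* **Coverage.** Expected depth is `c·λ` over the mature span, `c·λ·ρ` over
  the extension, plus `c·λ·π` over a pre-RNA segment (processing
  intermediates, default off); observed coverage is Poisson per base, with
  a `noise = FALSE` switch for exact tests. An optional linear taper over
  the distal fraction of the extension emulates heterogeneous 3′ ends;
  the default is rectangular for testability.
* **Counts.** `NB(mean = s_j · λ_f · m, dispersion = φ)` with library-size
  factors `s_j` log-uniform in [0.5, 2] to exercise normalization, and `m`
  encoding interference (`1 − κ` for a convergent gene whose TSS the
  extension covers) and planted DE effects. φ = 0 selects a Poisson
  branch.
* **Occupancy.** Gaussian initiation and termination peaks (height 100,
  sd 25) plus a uniform body level; the termination peak center moves
  `occupancy_shift` nt 3′-ward in the mutant and the extension-span level
  scales with `(1 + ρ_mut)/(1 + ρ_wt)`.
* **Determinism.** Every output is a pure function of the config including
  its seed; sub-seeds are derived per stage, condition and replicate.

What passing these tests does **not** show about real data: the generator
has no mappability artifacts, no 3′-end heterogeneity beyond the optional
taper, no overlapping transcription units beyond the planted layouts, no
batch structure, and rectangular (not sloped) extension coverage. Results
on real tracks will degrade gracefully with depth and with deviations from
these assumptions, and θ/g may need retuning below ~20× depth.

## Problem sizes and tolerances in the test suite

The suite runs at desk scale, chosen to keep the full run under a few
minutes while leaving comfortable statistical margins: 200 loci for
boundary recovery (error ≤ g + 5 nt in ≥ 95 %), 100 loci / 100 replicates
for ρ-recovery (±0.02) and interference precision/recall (≥ 0.9), 2,000
features for type-I error ([0.03, 0.07] at nominal 0.05), FDR (≤ 0.15
empirical at BH 0.1) and dispersion recovery ([0.07, 0.13] at φ = 0.1),
exhaustive enumeration for the orientation rule table and the φ = 0
binomial oracle (totals ≤ 50, agreement to 1e-12), and byte-identity for
the end-to-end demo run. `scripts/acceptance.R` recomputes the same
quantities from scratch under any `--seed`.

## Known limitations

* Tagwise dispersion shrinkage and GLM designs are out of scope; only
  two-group comparisons are supported.
* The caller is not splice-aware and does not assemble transcripts de
  novo; 5′ ends are taken from the annotation.
* Chimeric read-through transcripts (a parent reading into a same-strand
  gene) cannot be resolved from strand-specific coverage alone; such pairs
  are flagged ambiguous rather than resolved.
* ChIP-exo peak calling, footprint modeling and cross-linking bias
  correction are not attempted; the occupancy metrics are summary
  statistics, not peak models.
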