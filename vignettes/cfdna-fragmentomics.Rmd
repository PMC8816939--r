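---
title: "Fragmentomic ctDNA enrichment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentomic ctDNA enrichment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctfrag)
```

`ctfrag` annotates plasma cfDNA fragments with three variant-independent
properties — size, position of the cleavage sites relative to nucleosome
dyads, and a learned end-motif score — and quantifies how strongly any
selection on those properties enriches circulating tumor DNA. This
vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the synthetic
cohorts can and cannot tell you about real data.

## Coordinate and site conventions

Fragments are BED-style: 0-based, half-open, `size = end − start`. The
analysis keeps autosomes (`chr1`..`chr22`, with or without the `chr`
prefix) and sizes 1–800 bp; since `end > start` is required, a "0 bp"
fragment cannot exist and the filter is effectively 1–800. The *start
site* is the `start` coordinate; the *end site* is `end − 1`, the last
covered base — the half-open `end` itself is not part of the molecule,
and using a covered base keeps the two sites symmetric.

The 16 default size bins follow the published catalogue (0–52 through
325–400 bp). The 53–64 and 64–73 bp bins share the boundary 64 verbatim;
when a single bin must be assigned, membership resolves lowest-bin-first.
This is a deliberate, documented tie-break — the original bin list is
reproduced as printed rather than "repaired", because the two
underpopulated bins are dropped from enrichment analyses anyway (they
cannot fill a shallow-WGS replicate).

## Dyad annotation

A nucleosome track is a sorted set of dyad coordinates per chromosome
(from a BED file of calls, dyad = interval midpoint, or from the
simulator). Each site is matched to its nearest dyad independently by
binary search; the signed distance is `site − dyad` (positive =
downstream). Two choices the data cannot dictate are made explicit:
equidistant ties break to the lower-coordinate dyad, and fragments on
chromosomes without dyads are excluded from dyad analyses (with a
logged count) rather than failing the run. A fragment is
`core`-terminated when both sites lie within ±75 bp of a dyad (the
nucleosome core), `linker` when both lie outside, `mixed` otherwise;
shrinking the window can only demote fragments away from `core`, never
promote them. A linear-scan oracle in the test suite pins the binary
search to exact agreement.

## End-motif PWMs and the bias score

For every fragment the ±10 bp reference context around each site is
extracted — 21 positions, site at index 0 — and summarized into
per-position k-mer frequency matrices: 4×21 (k = 1), 16×20 (k = 2),
64×19 (k = 3). k-mers are anchored at their first base, so the last
k − 1 flank positions are excluded (they would need bases beyond the
window). Columns sum to 1 (tested at 1e−9); contexts containing
non-ACGT bases or running off a chromosome edge are skipped and
counted, never fractionally distributed — this keeps the downstream
indicator vectors strictly binary. Both sites are read from the plus
strand with no reverse complementing: the two PWMs then share one
coordinate frame and remain directly comparable. Orientation-aware
extraction would be a meaningful extension for real libraries where
fragment strand is known.

Scoring works on bootstrap replicates: R random subsamples of the
healthy pool and R of a designated tumor sample each yield a vectorized
PWM row (index space 84 / 320 / 1216); the replicate matrix is
column-mean-centred — no variance scaling, since all entries are
same-unit frequencies and scaling would inflate rare-k-mer noise — and
its first right singular vector taken as the loading vector. PC1
separates the two cohorts' replicates; the loading sign is fixed so
healthy replicates project positive, because the rotation returned by
any SVD is arbitrary and silent sign flips would invert the score's
meaning. Loadings are used at unit norm exactly as the decomposition
returns them. A fragment's score is the dot product of its binary
(k-mer, position) indicators with the loadings, summed over start and
end sites; it is linear in the loadings and additive across the two
sites. Degenerate training input (cohorts with identical replicate
PWMs) raises an explicit error rather than returning an arbitrary
direction.

The two-sample Kolmogorov–Smirnov statistic ranks k-mer orders: the
order whose score distribution best separates held-out healthy from
tumor fragments wins. On the default synthetic cohorts, and in the
study design this package re-implements, k = 3 wins, so tri-nucleotide
scores are the pipeline default. Published score cutoffs (±0.3, ±0.15,
0, ±0.2) are applied inclusively.

## Tumor fraction from shallow coverage

The copy-number module reproduces the contract of the established sWGS
tumor-fraction estimators in a self-contained form:

1. fragments are counted in fixed-width bins by midpoint (1 Mb default;
   40–100 kb at desk scale so that ~0.1× replicates still put
   hundreds of fragments per bin);
2. a panel of normals (PoN) built from control replicates *processed
   under the identical feature selection* stores per-bin median and MAD
   of `log2((count + 0.5)/total)`; bins with median raw count < 10 or
   MAD in the top 1% are masked. The selection-matched PoN is what
   absorbs selection-induced coverage bias — the reason no explicit
   GC/mappability correction is needed here (the synthetic genome is
   composition-controlled; adding such corrections is a noted extension
   point for real genomes);
3. per-bin log2 ratios against the PoN median are segmented with a
   3-state Gaussian HMM (loss/neutral/gain, self-transition 0.99,
   shared SD estimated from the central 80% of ratios, floor 1e−3),
   decoded per chromosome by Viterbi; an exhaustive-enumeration oracle
   verifies the decoder on small instances;
4. aberrant segments are inverted under single-copy events —
   `f = 2(2^r − 1)` for gains, `f = 2(1 − 2^r)` for losses — and
   combined as a bin-length-weighted mean, clipped to [0, 1].

With state means fixed at one amplitude, low-fraction events are
undetectable: a 10% tumor fraction shifts a gained bin by only ~0.07,
which a decoder with means at ±0.26/−0.32 will always label neutral.
`tumor_fraction()` therefore scans a grid of candidate fractions
f ∈ {0.05, …, 0.8}, sets the means to `log2(1 ± f/2)`, and keeps the
decode with the highest Viterbi log-probability — the same
solution-scan idea the established estimators use, reduced to
single-copy events. The reported value is recomputed from the decoded
segments' observed ratios, so it is not quantized to the grid.
`segment_bins()` retains the fixed-means parameterization as its
documented default for direct use.

Two guards keep the estimator honest on flat genomes, where the best
spurious decode otherwise converts masked-bin escapees into a small
positive fraction: a nonzero call requires at least 10% of bins
aberrant *and* a Viterbi log-likelihood gain over the all-neutral path
of at least 30. On the synthetic null the spurious gains sit several
fold below that joint threshold while a 10% planted fraction sits
several fold above it; both margins are exercised by the test suite.

## CISBEP

The enrichment procedure applies a selector to patient and control
cohorts, draws `n_reps` down-samples of `n` fragments per arm
(defaults 10 × 2.2 million, the ~0.1× scale; synthetic tests use
reduced sizes), builds the selection-matched PoN from the selected
controls, estimates a tumor fraction per selected patient replicate,
repeats with no selection for the baseline arm, and reports
median(selected)/median(baseline). Design choices:

* **Down-sampling is without replacement.** The procedure emulates
  drawing a shallow replicate from a much deeper pool; sampling with
  replacement would create duplicate fragments and artificial count
  inflation in bins. A selection that retains fewer than `n` control
  fragments is an error naming both sizes — mirroring the rule that
  underpopulated size bins are excluded from analysis — never a silent
  fallback to replacement.
* **One seed block, both arms.** A master seed spawns per-replicate
  streams recorded in the result; the selected and baseline arms share
  the block, so the identity selector reproduces the baseline exactly
  (relative fraction 1) and selector comparisons are paired.
* **The baseline arm is shared** across all selectors for one patient
  (`compare_selectors()`), so relative fractions are comparable within
  a table. Whether the original analysis redrew baseline replicates per
  feature is not knowable from the outside; sharing is the
  lower-variance choice and is stated in the result.
* **Zero baselines.** Healthy-only cohorts give a 0/0 ratio, reported
  as 0 (selection must not fabricate signal); a zero baseline with a
  nonzero selected median is flagged `undefined` rather than reported
  as infinite.

## Aggregated MAF

Fragments covering a designated point-mutation locus (half-open:
`start ≤ pos < end`) carry externally supplied mutant/wild-type flags —
this module deliberately consumes flags rather than calling bases, so
it stays independent of read-level qualities. MAF = mutant/total over
selected fragments, pooled across patients by summed counts (so pooling
then selecting equals selecting then pooling). Results under 25
selected fragments are flagged low-depth but still returned — thin
combined selections are exactly the interesting ones — and empty
selections are `undefined`, as is a relative MAF against a zero
baseline. Insertions and multi-allelic loci are out of scope.

## The synthetic cohorts

`simulation_config()` defines the study conditions; `make_test_cohort()`
materializes them on disk (FASTA, BED, truth JSON), byte-identically per
seed. Defaults, with units and rationale:

| Parameter | Default | Why |
|---|---|---|
| genome | 2 autosomes × 20 Mb, i.i.d. uniform ACGT | large enough for ~1,000 copy-number bins at 40 kb; composition-controlled so motif signal is attributable |
| dyad spacing | 187 ± 15 bp | canonical nucleosome repeat length |
| healthy sizes | 0.8·N(167, 15) + 0.2·N(334, 20) | mono-nucleosomal mode at 167 bp, di-nucleosome peak |
| tumor sizes | 0.35·U(74, 144) + 0.5·N(145, 15) + 0.15·N(300, 20) | short-fragment enrichment and left-shifted peaks |
| cleavage placement | healthy: linker with p = 0.6; tumor: core with p = 0.7 (±75 bp) | tumor ends concentrate near dyads |
| motif bias | `beta_mono` 0.12, `beta_tri` 0.35 | see below |
| CNA layout | one gain (copy 3) + one loss (copy 1), each 20% of a chromosome | single-copy events over enough genome to estimate from |
| mutation locus | copy-neutral position; tumor fragments covering it mutant with p = 1 | MAF tracks enrichment without copy-number distortion at the locus |

Fragments are built by sampling a dyad (copy-number-weighted for
tumor), a dyad-relative start offset, and a size; the candidate is then
accepted or rejected against origin-specific trinucleotide weights
evaluated on the *fixed reference* at both cleavage sites. Rejection
sampling is the crucial design decision: the motif signal ends up
genuinely encoded in genomic sequence, so the PWM/PCA machinery is
tested on exactly the kind of signal it assumes, rather than on
sequences rewritten to order. The weight model combines a central-base
AT-vs-CG preference (strength `beta_mono`) with a trinucleotide-parity
term (strength `beta_tri`) whose mono- and di-nucleotide marginals
vanish by construction — guaranteeing that discrimination grows with
k-mer order, the property the score comparison relies on. The strengths
were fixed once so that cohort-level score overlap is heavy (KS
statistic of a few tenths at desk scale), in the spirit of the modest
separations reported for real plasma, and so that the published ±0.2
cutoffs select usable fractions on both sides; an acceptance rate
below 1% aborts with advice to reduce the bias. Explicit 64-entry
weight tables can replace the parametric form. Switching any bias off
(`w_short = 0`, equal core probabilities, zero betas) removes the
corresponding separation, which the tests use to show selections do not
fabricate enrichment.

A mixture "patient" makes each fragment tumor-origin independently with
probability f\*, retaining origin as a hidden truth column that only
evaluation code reads.

**What the simulator does not emulate:** GC and mappability bias,
chromatin-state heterogeneity across tissues, read-level artifacts
(sequencing error, duplicates, trimming), strand-aware end chemistry,
subclonal or multi-copy CNAs, and sex chromosomes. Passing tests
therefore demonstrate that the pipeline recovers the structures it
models from data that genuinely contains them — not that real plasma
libraries are free of the confounders above. On real data the
selection-matched PoN absorbs some of these (as it does here for
selection-induced bias), but GC correction in particular is an explicit
extension point.

## Problem sizes in the test suite

Unit tests run on a 2 × 1 Mb world (400k healthy / 120k tumor
fragments). The end-to-end validation uses the default 2 × 20 Mb
conditions: a 2.5 M-fragment healthy pool and 600k tumor pool; the
null-control and parameter-recovery blocks use 10 replicates of 200,000
fragments over 40 kb bins (the ~0.1× scale) with planted fractions
f\* ∈ {0.1, 0.2, 0.3, 0.5}; the selection-directionality block compares
six selectors at 5 replicates of 30,000 fragments over 100 kb bins on a
f\* = 0.4 patient mixture. At these scales the per-bin Poisson noise
leaves severalfold margins on every detection threshold. The combined
size-and-score selector in that block uses score ≤ 0: tails at ≤ −0.2
joint with the size bin would retain fewer control fragments than one
replicate at desk scale — real studies solve this with
billion-fragment control pools, a desk simulation by relaxing the
conjunction's cutoff (score < 0 is itself one of the published MAF
cutoffs). `scripts/acceptance.R` re-runs the healthy-only null at the
full 40 Mb / 200k scale and writes the median estimated tumor fraction
(expected: 0).

## Known limitations

* Single-copy CNA model only: no ploidy search, no subclone fractions,
  no allele-specific states; heavily aneuploid genomes would need the
  full established estimators this module's contract mirrors.
* PC1 is a linear, two-cohort discriminant; per-tissue or regularized
  alternatives are out of scope by design.
* The KS ranking of k-mer orders is a property of the cohorts at hand;
  with very small training replicates the k = 3 loadings are noisy and
  the ordering can tighten.
* Printed statistics from the original patient cohorts (relative
  fractions, KS values) are measurements on restricted-access data;
  this package reproduces the procedures and their qualitative
  behavior on synthetic cohorts, not those numbers.
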