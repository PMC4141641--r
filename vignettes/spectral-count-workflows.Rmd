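---
title: "Methods: spectral-count interactome filtering and companion assays"
author: "apmskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-count interactome filtering and companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmskit)
```

This vignette is the package's account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not
demonstrate about real data.

## 1. The AP-MS filtering model

Spectral counting treats the number of MS/MS events assigned to a
protein as a proxy for its abundance in the purified material. The
workflow assumes a paired design: R independent purifications
(biological replicates), each performed with the tagged bait and with an
empty-vector mock control, each sample run T times on the instrument.

The stages, and why they are in this order:

* **Technical collapsing** sums counts over the T runs of a sample.
  Spectral counts are event tallies, so summing — not averaging — is the
  combination rule that preserves integrality and total counts. The
  workflow this package systematizes does not prescribe a rule; summing
  is the package's choice and is asserted by a conservation test.
* **Background subtraction** computes `d_i = bait_i − mock_i` within
  each replicate and sums to `S`. Pairing within replicates (rather than
  subtracting grand totals) keeps replicate-specific background — a
  sticky prep, an unusually deep run — from leaking across replicates;
  the grand total of `S` over all proteins nevertheless equals total
  bait minus total mock counts, which the tests use as an invariant.
* **Negative filter**: `S < 0` means the protein was overall more
  abundant without the bait, the signature of nonspecific binding.
  `S = 0` is retained at this stage — the rule drops strictly negative
  sums — but such proteins cannot survive the abundance filter, so the
  choice only affects the intermediate stage count.
* **Abundance filter** removes `S ≤ ceiling(mean(S))`, the mean taken
  over the negative-filter survivors. Using the ceiling reconciles a
  fractional mean with integer counts (a mean of 9.94 cuts at 10);
  because sub-mean counts are where nonspecific associations
  concentrate, the default is deliberately aggressive, and an explicit
  integer threshold can be supplied instead.
* **Redundancy collapsing** merges accessions that the identified
  peptides cannot distinguish (typically isoforms), adding bait and mock
  counts per replicate and recomputing `S`. The merged group needs one
  molecular weight for normalization; the member contributing the
  largest `S` acts as the representative isoform. This is a convention —
  alternatives (longest isoform, count-weighted mean MW) change scores
  by at most the MW spread within an isoform family.
* **MW normalization and scoring.** Expected spectral counts grow
  roughly linearly with protein length, hence with molecular weight, so
  summed counts are divided by MW (per kDa) before abundances are
  compared across proteins. Two background corrections are computed:
  the difference `diff_score = (Σbait − Σmock)/MW` and the fold
  enrichment `ratio_score = Σbait/(Σmock + c)`. The pseudocount
  `c = 1` raw mock count (added before normalization; MW cancels in the
  ratio) makes the enrichment finite for proteins never seen in mock —
  zero-mock handling has to be a package decision, and one raw count is
  the smallest observable unit. The difference score is computed
  without the pseudocount, since a difference needs no protection
  against division by zero.
* **Double ranking.** Both scores are sorted descending with
  deterministic tie-breaking (the other score, then the group key
  lexicographically) so output is identical across platforms; the top-n
  intersection quantifies how much the two background-correction
  philosophies agree.

Replicate reproducibility is summarized before any filtering:
"detected in replicate i" means a bait-channel count above zero after
technical collapsing (the mock channel plays no role in detection), and
the full `2^R − 1` Venn-region partition plus detected-in-≥k tallies are
reported.

## 2. The expression-array stages

* **Detection filtering** consumes the platform's per-probe, per-sample
  detection p-value (it does not recompute it; bead-level processing is
  out of scope) and keeps probes with `p < 0.05` in at least one
  sample. Both the cutoff and the minimum sample count are parameters.
* **Quantile normalization** uses the classic rank-mean construction:
  sort each array, average across arrays at each rank to obtain the
  reference distribution, and reassign by original rank. Ties within an
  array receive the mean of their rank-group's reference values, which
  makes the transform well defined and idempotent; on tie-free data it
  agrees exactly with `limma::normalizeQuantiles`, which the test suite
  uses as an independent reference. Normalization is computed jointly
  over all arrays of the experiment, not per timepoint, so both
  timepoints live on one scale.
* **Welch testing.** Each probe is tested with the unequal-variance t
  statistic and Welch–Satterthwaite degrees of freedom, two-sided, on
  the normalized linear-scale replicate values. With duplicate arrays
  (n = 2 per group) the Satterthwaite df is at most 2 and typically
  near 1 whenever the two group variances differ, so even very large
  fold changes can carry p-values above 0.05 — a structural limit of
  duplicate designs, not a defect of the statistic. The pipeline
  therefore exposes the replicate grouping: per timepoint (n = 2 vs 2,
  the default, matching how such experiments are usually reported) or
  pooled across timepoints (n = 4 vs 4), appropriate when the response
  is expected to persist between the timepoints. Degenerate inputs are
  conventions, not errors: zero variance in both groups yields p = 1
  for equal means and p = 0 otherwise.
* **Fold change and list assembly.** Fold changes are ratios of
  post-normalization linear-scale condition means, reported in the
  signed convention (`+r` for increases, `−1/r` mapped to `−r`-style
  values for decreases). Lists are cut at `|FC| > threshold` (strict,
  so a fold of exactly 5.0 is excluded from the 5× list) and
  `p ≤ 0.05` (inclusive), with 3× and 5× lists assembled by default; no
  multiple-testing correction is applied, mirroring the workflow this
  implements. The 5× list is provably a subset of the 3× list, which
  the tests assert.
* **Volcano coordinates** (`sign(FC)·log2|FC|`, `−log10 p`) are derived
  columns only; nothing is filtered at that step.

## 3. qPCR relative quantification

Threshold cycles convert to relative starting amounts as
`X0 = E^(−ct)` with amplification efficiency `E = 2` by default
(perfect doubling; per-primer efficiencies can be supplied but are not
estimated — there is no standard-curve module). Each gene is normalized
to a reference gene (GAPDH by default) within its condition and
technical replicate, and the treatment/control ratio is log2
transformed; at `E = 2` this is the familiar `−ΔΔct`. Replicates are
summarized as the arithmetic mean and the sample (n−1) standard
deviation; a single replicate reports sd 0 with a logged note rather
than NA, so downstream tables stay numeric. Two invariances pin the
arithmetic down: swapping conditions negates the ratio, and adding any
constant to every ct (a plate-wide shift) leaves it unchanged.

## 4. Overlap statistics

Gene-list comparisons are deliberately minimal: an explicit universe,
exact tails, no hidden platform background. The overlap of two lists of
sizes a and b in a universe of size U is tested with the hypergeometric
upper tail `P(X ≥ k)`; the direction structure of a signed overlap is
tested with a binomial fair-coin tail on the count of same-direction
(or, for mirror-image comparisons, opposite-direction) pairs. Both are
one-sided by default because enrichment in a stated direction is the
hypothesis; a two-sided variant is a flag. Symbols are upper-cased and
whitespace-stripped before matching, and cross-species comparisons are
the caller's responsibility (supply an ortholog-mapped list; the package
matches symbols as given). Inverse-signature reporting gives, per
direction stratum of list B, the fraction of overlap genes regulated
oppositely in list A; an empty stratum is reported as absent rather
than 0. The EdU-style proliferation helper pools positive and total
cell counts over a well's images before dividing — the pooled estimator
weights images by cell count, unlike a mean of per-image percentages.

## 5. What the synthetic data emulates

`simulate_apms()` reproduces the structure of the pull-down design:
4 biological replicates × {mock, bait} × 3 technical runs by default,
integer counts per run drawn Poisson with mean
`background_mean × MW/100 kDa` (so counts scale linearly with protein
size), log-normal molecular weights, bait means multiplied by
`1 + enrichment_factor` for planted interactors, and per-replicate
dropout zeroing an interactor's bait counts to exercise the Venn logic.
A negative-binomial size parameter is available for over-dispersion but
the default is Poisson: the dispersion of real spectral counts is not
something the emulated workflow documents, so the default is pragmatic,
not fitted. Default `background_mean = 2` per technical run per
100 kDa and `enrichment_factor = 10` describe a clean pull-down with a
strongly enriched bait complex — counts in the tens for true
interactors, single digits for background, which is the regime the
filtering chain is designed for.

`simulate_expression()` builds duplicate two-condition arrays at two
timepoints (7 and 10 h labels) as
`intensity = 2^(baseline + effect + noise)` with planted fold changes
applied at both timepoints, and fabricated detection p-values (uniform
below 0.05 for expressed probes, uniform on [0.05, 1] for an
undetected fraction) — fabricated because the platform's detection
computation is consumed, never reimplemented. `simulate_qpcr()` lowers
the treatment-condition ct of each gene by its planted log2 ratio while
keeping the reference gene flat, so the quantification stage recovers
the planted value exactly at zero noise.

What the generators do **not** emulate: correlated background between
mock and bait (each protein's channels are drawn independently),
peptide-level identification noise, protein FDR, probe
cross-hybridization, batch or chip effects, and intensity-dependent
array noise. Passing recovery tests therefore demonstrates that the
pipeline arithmetic is correct and that effects of the planted
magnitude are recoverable under idealized noise — not that the
thresholds are well calibrated for any particular instrument.

Two interactions between generator and pipeline are worth knowing.
First, quantile normalization compresses the extremes of the intensity
distribution, so a planted down-regulated probe whose baseline sits at
the very bottom of the distribution can come back with a measured fold
change well below its planted value; the recovery tests assess planted
5-fold changes at the 3-fold list for this reason (and because a
planted linear fold of exactly 5 straddles the strict `> 5` cutoff
under noise). Second, recovery of 5-fold effects at noise sd 0.1 uses
the pooled-timepoint Welch grouping: the generator plants persistent
effects, and duplicate-only testing is df-limited as described above.

## 6. Problem sizes and determinism

Every simulation flows from one explicit integer seed through a private
RNG stream (the caller's `.Random.seed` is saved and restored), so
identical configs give bit-identical outputs and CLI runs with the same
seed write byte-identical files. The test suite runs on deliberately
modest sizes — 300-protein / 20-interactor AP-MS tables, 2,000-probe
arrays with 100 planted changes, 100 random ≤ 20-protein tables for the
straight-line oracle comparison, universes ≤ 12 for exhaustive
hypergeometric enumeration — sizes at which exact oracles are cheap and
the suite completes in well under a minute while exercising every
branch of the pipeline. The same quantities are recomputed by
`scripts/acceptance.R` at run time; nothing in the tests asserts an
empirical number the code does not itself compute.

## 7. Known limitations

* The abundance filter's auto threshold depends on the mean of `S`,
  which is sensitive to how many background proteins survive the
  negative filter; with very clean data (few negatives) the cutoff
  rises and true low-abundance interactors are lost. The threshold is
  exposed for exactly this case.
* Grouping by gene symbol is the default redundancy key; it cannot
  separate distinct proteins sharing a symbol, and a curated
  `protein_id → group` map should be supplied when that matters.
* Duplicate-array Welch tests have near-floor degrees of freedom (see
  above); treat per-timepoint p-values from duplicates as screening
  statistics, not calibrated error rates — particularly with no
  multiple-testing correction, which is faithful to the emulated
  workflow but generous by modern standards.
* Quantile normalization assumes the arrays share a global intensity
  distribution; it will erase genuine global shifts between conditions.
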