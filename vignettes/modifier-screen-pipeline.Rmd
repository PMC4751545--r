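---
title: "Methods: ordinal wing-score screening and polytene fluorescence quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordinal wing-score screening and polytene fluorescence quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modscreen)
```

## The screening model

A gain-of-function wing phenotype (ectopic vein material) is scored per
wing on an ordinal 0–5 scale: the number of scoreable wing cells carrying
ectopic veins. Blistered wings cannot be placed on that axis and receive
the unordered category B; they are counted (`n_scored`) but excluded from
rank statistics (`n_analyzed`). A candidate hairpin is compared to the
control hairpin of its vector class by the Mann–Whitney rank-sum test on
the ordinal scores.

### Test variant

The data are heavily tied — six categories, dozens of wings — so the exact
choice of variant matters:

* **Statistic.** `U` by pair counting with half-credit for ties,
  equivalently the midrank rank-sum identity (`u_statistic()` implements
  both; a property test asserts their agreement).
* **Variance.** The tie-corrected null variance
  `Var[U] = (n1 n2/12)[(n+1) − Σ(t³−t)/(n(n−1))]` over pooled tie groups
  `t`.
* **Sidedness and correction.** Two-sided normal tail without continuity
  correction. This combination is the one that reproduces the published
  long-hairpin screen column to three decimals; the original report does
  not name its software or sidedness, so the variant was fixed by that
  reproduction and then validated against exact enumeration.
* **Significance.** `alpha = 0.05` by default: the source screen treats
  p = 0.062 as not significant and p < 0.001 as significant, consistent
  with the conventional threshold.
* **Blister calls.** A candidate with ≥ 25% blistered wings (fraction of
  all scored wings, computed before exclusion) is called
  `blister_interaction` regardless of its p-value. In the screen data the
  only blister-rich genotype has 55% blistered wings while all others are
  below ~8%, so the default threshold separates the regimes cleanly.
* **No multiple-testing correction** is applied; the screen reports raw
  per-candidate p-values and so does `screen_report()`.

### Exact mode and its oracle

For small samples `rank_sum_test(..., method = "exact_permutation")`
enumerates candidate count allocations over the pooled tied categories,
weighting each allocation by its multivariate hypergeometric multiplicity,
and reports the proportion of assignments with `|U − E[U]|` at least the
observed value. Ties carry the same half-credit as the approximate mode,
so both modes share one statistic definition. An independent brute-force
oracle (`exact_oracle_p()`, direct iteration over `combn()` assignments
with a pairwise comparison matrix) shares no code with it; the test suite
asserts their equality to 1e-9 on hundreds of random tables.

### Quality of the normal approximation

Exact two-sided p-values are discrete: the smallest attainable value is
`2/choose(n, n1)`. With one wing per group the exact p is 1 while the
normal approximation gives 0.32; such deviations are a property of
discreteness, not an implementation defect. The suite therefore judges
approximation quality where it has decision meaning — both groups of at
least 4 wings, the smallest size at which the exact test can reach
significance at alpha = 0.05 at all — and asserts that the approximate p
is within 0.12 of exact on at least 90% of random tables and reaches the
same significance call on at least 90%. In the screen's own regime
(≥ 11 wings per group) the two modes agree far more tightly.

### The inconsistent short-hairpin table

The packaged short-hairpin count table
(`inst/extdata/valium20_counts.csv`) is internally inconsistent as printed
in its source: one enhancer row duplicates the control row verbatim
(which can only produce p = 1), and the published p-values of the four
non-significant rows are not regenerated from the printed counts under
the variant that reproduces the long-hairpin table exactly. The counts
are shipped verbatim with a warning header, the package makes no attempt
to guess corrected counts, and a regression test asserts the
non-reproduction so that any future "fix" is flagged rather than silently
absorbed.

## The wing-score simulator

`simulate_wing_scores()` draws wings from a proportional-odds
(cumulative-logit shift) model: the baseline cumulative probabilities
`F_j` become `plogis(qlogis(F_j) − delta)`, so `delta > 0` moves mass
toward higher scores (enhancer-like), `delta < 0` toward lower
(suppressor-like). This matches how the screen interprets modifiers — as
directional shifts of severity, not category-specific effects. Blistering
is independent of the ordinal score with probability `blister_prob`,
mirroring its separate scoring and exclusion.

Defaults are the screen's baseline regime: the control distribution is
the empirical long-hairpin control row, counts (0, 5, 20, 35, 7, 0) over
67 wings. The type-I calibration test runs the full pipeline on 1,000
null draws at 30 vs 67 wings (the screen's sample-size regime) and checks
the rejection rate at alpha = 0.05 stays within two binomial standard
errors of 0.05.

A degenerate baseline with all mass in one category is rejected: there is
no interior cumulative cutpoint to shift, so the effect model is
vacuous there.

## The polytene-spread simulator

`simulate_polytene_spread()` emulates the features the quantifier must
handle, not cytological realism:

* **Geometry.** `n_arms` (default 4) smooth random arm paths radiate from
  a chromocenter-like origin in a 128×128 frame; unit steps with a slowly
  drifting heading (sd 0.08 rad/step), `arm_length` 45 px,
  `arm_halfwidth` 3.5 px. The ground-truth mask is exactly the pixels
  within the half-width of an arm path; a sigmoid edge profile (soft over
  ±1 px) renders intensity.
* **DAPI banding.** Bands sit on a jittered regular grid along each arc
  (7 bands/arm, jitter 30% of spacing, Gaussian profile sd 1.6 px);
  intensity is `0.35 + 0.6·band(s)` on-chromosome, so interbands stay
  well above background and banding is cosmetic except as colocalization
  ground truth.
* **Antibody channels.** Each channel lights a configured fraction of the
  bands (default 0.6) at peak `scale` 0.8, multiplied by the group
  multiplier — the knob that emulates knockdown-induced reduction. With
  two channels, `shared_band_fraction` fixes the fraction of shared band
  positions for colocalization ground truth.
* **Nuisance signal.** Off-chromosome speckles (Poisson count, mean 15
  per channel, amplitude 0.5, placed > half-width + 2 px from any path)
  emulate nonspecific antibody staining the mask must reject; additive
  Gaussian read noise (sd 0.02) and optional Poisson photon noise
  complete the photometry. Intensities live on a [0, 1] scale.

Not modelled, deliberately: optical PSF/deconvolution, chromocenter
texture, exposure drift between channels (the workflow assumes identical
exposure times), and band-level cytology. Passing tests therefore show
the pipeline's arithmetic and masking are sound on images with known
truth — they do not certify segmentation accuracy on real squashes,
where manual mask files remain the conservative option.

## Quantification choices

* **Ratio of sums.** `quantify_ratio()` reports
  `Σ(ab − b)⁺ / Σ(DAPI − b)⁺` over the mask. Whether the original
  workflow used ratio-of-sums or mean-of-pixel-ratios is not documented;
  ratio-of-sums is the default because it is robust to mask-area
  variation and to near-zero DAPI pixels.
* **Background.** Default `b` is the per-channel median of off-mask
  pixels; `background_mode = "none"` reproduces a workflow in which
  off-chromosome signal is simply excluded by the mask and nothing is
  subtracted. Whether the original tool subtracted background is
  likewise undocumented; both modes are first-class.
* **Segmentation.** Gaussian smoothing (sigma 1 px — comparable to the
  band profile, small against the 7 px arm width, chosen so the Otsu
  boundary tracks the true arm edge closely), global Otsu threshold,
  removal of components under 50 px, hole filling. On default-noise
  simulations the masks reach mean IoU ≈ 0.9 against ground truth, and
  IoU degrades monotonically with noise. A user-supplied mask file
  bypasses segmentation entirely, reproducing the original manual-mask
  contract.
* **Replication unit.** The default unit is one image; when several
  spreads are imaged per slide (biological replicate),
  `aggregate_by_slide()` (CLI: `compare --by-slide`) collapses to
  per-slide means first. The source workflow is ambiguous on this point,
  so both units are supported.
* **Group comparison.** Pooled-variance Student's t-test, two-sided, per
  the source legend's wording; Welch via `var_equal = FALSE`. Degenerate
  zero-variance groups with equal means return t = 0, p = 1 rather than
  an error so batch simulations keep running.
* **Colocalization.** Channels are binarized inside the mask by
  per-channel Otsu over masked values; overlap is the fraction of one
  channel's positive pixels that are positive in the other, in both
  directions. A channel with no positive pixels yields overlap 0 with a
  warning rather than an error.

## Problem sizes used by the test suite

The suite simulates at the study's own scales where that is what is being
checked — 30 vs 67 wings for null calibration (1,000 replicates), 11 + 10
spreads for the knockdown-recovery checks at multipliers 0.64 and 0.43,
20 spreads for segmentation quality — and at small n (combined ≤ 14)
where exact enumeration is the oracle. The full suite runs in well under
a minute on one core.

## Known limitations

* The rank test assumes independent wings; wings from the same cross
  vial are treated as independent, as in the source design (one right
  wing per male fly).
* The normal approximation is anticonservative for very small groups;
  use `method = "exact_permutation"` below ~10 wings per group.
* Automated segmentation is tuned for spread-like images with dark
  background; dense nuclei or debris fields may need a manual mask.
* The simulators share the package's numerical conventions (float
  intensities in [0, 1]); 8/16-bit integer inputs are rescaled on read by
  the TIFF/PNG readers.
```{r session}
sessionInfo()
```
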