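---
title: "Grading sausage quality from NIR hyperspectral cubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading sausage quality from NIR hyperspectral cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsgrade)
```

## The problem

Cantonese-style sausage is sold in three quality grades whose main physical
difference is the proportion of lean to fat meat: the top grade is leanest,
the second grade fattest. Because the grades command very different prices,
a fast, non-destructive grading instrument is commercially interesting.
Near-infrared hyperspectral imaging (874–1734 nm, 256 bands) sees the
relevant chemistry directly — protein N–H overtones near 995 and
1056–1099 nm, fat C–H overtones at 1160 and 1210 nm, amide combination
bands at 1254–1348 nm, and water near 1400–1450 nm — so the mean
reflectance spectrum of a sausage carries a grade signature.

`hsgrade` implements the complete workflow: raw-cube calibration, region-of-
interest (ROI) spectrum extraction with wavelet denoising, chemometric
sample-set splitting, two wavelength-selection procedures, and grid-tuned
SVM and random-forest graders. Because no public image archive of graded
sausages exists, the package also contains a synthetic cube generator with
known ground truth; every statistical claim the test-suite makes is made
against that generator.

## From photons to a spectrum table

**Calibration.** Raw digital numbers are converted to relative reflectance
against a white Teflon frame and a shuttered dark frame,

$$R = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}},$$

applied per pixel (a column-averaged mode exists for line-scan references).
The transform is invariant under a common affine rescaling of all three
frames, which the tests exercise directly. Values outside $[0,1]$
(specular pixels) are kept by default — ROI averaging is robust to them and
clipping destroys information; a `clip` option exists.

**Segmentation.** The sample region is found by Otsu-thresholding the band
nearest 1100 nm, where tissue is bright against the dark conveyor, and
keeping the largest connected component (EBImage). On synthetic frames
with the default contrast the recovered mask matches the ground-truth
geometry with IoU ≥ 0.95.

**Denoising and averaging.** Pixel spectra are individually denoised with a
Daubechies-6 wavelet decomposition to level 3, soft universal thresholding
($\hat\sigma\sqrt{2\ln n}$, $\hat\sigma$ from the MAD of the finest detail
coefficients), symmetric boundary extension, then averaged over the ROI.
Decomposing alone is not denoising, so a thresholding rule had to be fixed;
the universal soft threshold is the standard default and the tests verify
noise reduction on Monte-Carlo sinusoids and near-idempotence on repeated
application. Denoise-then-average order matters (the two do not commute)
and denoising the pixel-wise spectra is the documented convention here.
Only the 200 bands between 975.01 and 1645.82 nm are retained for
modelling; the ends of the instrument range are noise-dominated.

## Chemometrics

**Split.** Calibration/prediction sets come from the Kennard–Stone
algorithm applied independently within each grade (otherwise one grade can
dominate the calibration set): seed with the two most distant samples, then
repeatedly add the sample maximizing its minimum distance to the chosen
set. At the conventional calibration fraction 0.74 this gives 37/13 per
grade for 50 samples and 111/39 for 150. The implementation is checked
against a brute-force greedy oracle on small instances.

**Exploration.** `pca_scores()` provides mean-centered PCA scores (sign
convention: largest-magnitude loading positive). Mean-centering without
autoscaling is the usual choice for reflectance spectra, where the natural
unit is common to all bands.

**Second-derivative selection.** Savitzky–Golay second derivatives
(window 11, polynomial order 3, exact on polynomials, boundary handled by
the filter's edge rows) remove baseline and emphasize absorption peaks.
Candidate bands are local extrema of the pooled mean derivative; they are
ranked by the between-grade range of the grade-mean derivatives at the
band — a concrete quantification of "peaks with large differences" — and
the top *k* (default 14) are kept subject to a five-band minimum
separation.

**RF recursive elimination.** Starting from 200 bands, 100 forests are
trained per round and the 20 bands of lowest mean impurity importance are
dropped, until 20 remain (exactly nine rounds). Survivors are ranked by
their final-round importance; forests on the top-*k* bands for
$k = 1\ldots20$ give an out-of-bag error curve, and the smallest *k*
minimizing it defines the subset. OOB error counts a sample as an error
when no tree left it out of bag. The procedure recovers three planted
informative bands (to ±2 bands) in ≥ 90% of seeded runs.

**Models.** The SVM grader is an RBF machine tuned over
$C, \gamma \in \{2^e : e = -8, -7.2, \ldots, 8\}$ — the step of 0.8 in the
exponent is the coarsest dyadic grid containing all the conventionally
reported optima (256, 3.0314, 9.1896, 48.5029, 84.4485, 147.0334) — by
5-fold stratified cross-validation, with features standardized to
calibration mean/SD (an RBF kernel on raw reflectance scales is
degenerate). The RF grader is tuned over trees ∈ {50,…,500 step 50} ×
features-per-split ∈ {10,…,100 step 10, clamped to the band count and
deduplicated} by mean OOB error over seeded repetitions. All ties break
deterministically: smaller C then smaller γ; fewer trees then fewer
features; smaller *k*; lower band index. "Features per node" is read as
the per-split candidate count (mtry); feature counts exceeding the number
of bands (as arises for 14–15-band reduced models) are clamped.

Accuracy is reported as $100\cdot\mathrm{trace}/\mathrm{total}$ of the
3×3 confusion matrix, rounded half-up to two decimals — note base R's
`round()` rounds half to even, hence `round_half_up()`.

## The synthetic study

`synthetic_config()` defaults describe the emulated study: 50 intact
sausages per grade, three 1 cm slices cut from each (150 slices per
grade), grades coded 1/2/3 = top/first/second.

Each pixel is a linear mixture of four closed-form endmembers (flat
baseline minus Gaussian absorption bands): lean meat, fat, a starch/soy
binder (fixed 12% volume fraction) and the dark background. Absorption
centers sit at the positions the grading literature assigns (995, 1070,
1160, 1210, 1300, 1395, 1450, 1725 nm); lean and fat each carry a weak
echo of the other's bands, as real tissue does. The per-sample lean
fraction of the meat portion is Beta-distributed around the grade mean
(defaults 0.75/0.60/0.45 — only the ordering is physically mandated; the
values are package choices) with concentration κ = 300; pixels jitter
around the sample fraction (κ = 100) to mimic marbling. The sensor model
is `raw = dark + R·(white − dark) + N(0, 6 DN)` with a lamp spectrum and a
±3% fixed pixel pattern in the white frame; intact samples are elongated
ellipses, slices are discs, on 40 × 26 px frames (the study's frame size
is not public; small frames keep simulation cheap without changing any
statistic of the ROI mean).

Two per-sample nuisance effects extend the pure mixture model: a
multiplicative scatter gain (SD 0.015) and a smooth random baseline
undulation (six Gaussian bumps of 150 nm width, coefficient SD 0.007).
These are the standard nuisance structure of diffuse-reflectance NIR
measurements, and they are what lets the generator reproduce two
observations that a fraction-only model cannot show simultaneously:
per-band grade envelopes that overlap (the grade signal at any single band
is buried in between-sample spread) while multivariate graders still
separate the grades almost perfectly. Sliced samples multiply all
per-sample variances by the slice-variance multiplier (default 4) —
a cut surface exposes a less-averaged mixture — which makes sliced spectra
more dispersed at every band and sliced graders systematically worse,
the qualitative signature of the real study.

What the generator does **not** emulate: casing texture, line-scan
geometric artifacts, specular highlights, inter-batch recipe drift.
Passing tests therefore demonstrate the correctness and statistical
behavior of the workflow, not instrument-level performance on real
sausages.

## Numerical and design choices

* Wavelength axis: built so that exactly 200 uniformly spaced bands fall
  in [975.01, 1645.82] nm with the endpoints as retained bands; leftover
  bands pad symmetrically (extra band above when odd).
* Band subsetting uses a closed interval; the retained endpoints are
  reported wavelengths.
* ENVI I/O: BIL and BSQ interleaves, little-endian, uint16 raw /
  float32 reflectance (float64 optional for lossless round trips);
  wavelengths serialized at 17 significant digits so the axis survives a
  round trip exactly. BIP and compressed variants are out of scope.
* Degenerate inputs: identical spectra in Kennard–Stone fall back to
  index order with a warning; white = dark pixels abort calibration with
  their positions; empty masks, missing grades, non-dividing elimination
  schedules and unseen class labels all raise early, named errors.
* Determinism: one master seed; every forest, fold assignment and
  simulation stream derives its own 32-bit seed from it. Forests run on a
  single thread; identical configurations give byte-identical report CSVs.

## Problem sizes used by the checks

The test-suite's end-to-end check and `scripts/acceptance.R` run the full
default-scale study (600 cubes, 200 bands) through the complete pipeline.
Two computations are deliberately sized down, as package choices: the RF
hyperparameter grid uses 3 seeded repetitions per combination instead of
10 (the OOB mean over 3 × 50…500 trees is already stable to well under the
accuracy resolution), and structural tests of the elimination schedule use
small `models_per_round`, which cannot change the schedule. Everything
else — grids, split fraction, selection schedule, 100 forests per
elimination round — runs at its default.

## Limitations

* The grade signal is essentially one latent dimension (lean fraction), so
  synthetic accuracies saturate near 100% for intact samples; real spectra
  carry additional recipe and batch variation.
* The second-derivative "large difference" ranking and the peak/valley
  designation (five-band separation) are concrete choices for criteria the
  literature leaves qualitative.
* Impurity-based importance is the RF selector's default for speed and
  determinism; permutation importance is available through
  `selection_config(importance = "permutation")` at substantially higher
  cost for the 100-forest rounds.
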