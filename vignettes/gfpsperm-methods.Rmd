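---
title: "Quantifying GFP-sperm occupancy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GFP-sperm occupancy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfpsperm)
```

## The measurement problem

Sperm whose heads express GFP can be visualized *in vivo* through the
translucent walls of an insect female reproductive tract. Two fluorescence
channels are acquired per sample: a green channel (520 nm collection) that
contains both true sperm-head fluorescence and a contaminant, and a red
channel (624 nm collection) that contains only the contaminant —
autofluorescence from chitinous structures such as the ring at the base of
the spermathecal duct and the outer walls of the spermathecal tubules.
Because chitin fluoresces in both channels with an approximately constant
intensity ratio, the red channel can be used to subtract the contaminant
from the green channel, leaving primarily sperm-derived signal.

Two summary metrics are then taken per region of interest (ROI):

* **percentage cover** — the fraction of ROI pixels above a binarization
  threshold, times 100; a proxy for how widely sperm have spread;
* **mean pixel intensity** — the average corrected fluorescence over all
  ROI pixels; a proxy for sperm density.

Fluorescence is a proxy for abundance, not a count; the chain makes no
attempt at single-cell segmentation.

## The quantification chain

`quantify_sample()` runs the stages in a fixed order:

1. **Rolling-ball background subtraction** (`subtract_background()`,
   radius 25 px). The background is estimated as the grayscale
   morphological opening of the channel with a non-flat spherical
   structuring element — the classical rolling-ball definition — and
   subtracted. The sphere has height $\sqrt{r^2 - d^2}$ at lateral
   distance $d$, with one intensity unit per pixel of radius; on 14-bit
   data this is nearly flat, which is what makes it a *background*
   estimator: any feature narrower than the ball (puncta, thin chitinous
   walls) survives, anything broader is removed. ImageJ-style
   downsampling heuristics are deliberately not replicated; the
   implementation is asserted against an independent brute-force opening
   oracle instead. Outside the image the structuring element is ignored
   (not padded), which keeps the opening anti-extensive up to the border;
   residual border deviation on steep gradients is bounded by the input
   and clipped at 0.
2. **Correction-factor estimation** (`compute_correction_factor()`). A
   reference ROI is drawn inside a chitinous structure showing strong red
   but no sperm-derived green signal. The factor is the ratio of the mean
   background-subtracted green intensity (Int_GFP) to the mean red
   intensity (Int_Auto) in that ROI. A red mean below `eps` (default
   1e-6) marks the ROI unusable and errors.
3. **Crosstalk subtraction** (`correct_autofluorescence()`): the red
   channel scaled by the factor is subtracted pixel-wise from the green
   channel, negatives clipped to 0 (fluorescence cannot be negative).
4. **Intermodes thresholding** (`intermodes_threshold()`): a 256-bin
   histogram of the ROI's corrected intensities (14-bit range binned
   linearly, mirroring how ImageJ thresholds scaled data) is smoothed
   with a 3-point moving mean until exactly two local maxima remain; the
   threshold is the intensity midpoint of the two modes. The iteration
   cap is 10,000. Histograms that never become bimodal — blank tracts —
   raise a typed error; `occupancy_metrics()` catches it and falls back
   to "no fluorescent pixels" (cover 0) with an explicit flag.
5. **Occupancy metrics** (`occupancy_metrics()`): mean and median are
   computed over *all* ROI pixels of the corrected image (the source
   protocol does not state whether intensity was measured before or after
   thresholding; all-pixel means are the interpretation consistent with
   measuring "within the boundary of the ROI"). Cover counts pixels
   strictly above the threshold. Presence — "observable sperm" — is
   operationalized as at least one 8-connected component of at least 4
   above-threshold pixels (configurable via `quant_config()`).

ROIs are closed polygons in 0-based pixel coordinates (x right, y down).
Rasterization uses the even-odd rule on pixel centres, so an axis-aligned
rectangle from (0,0) to (10,10) covers exactly 100 pixels; this pins area
counts down to reproducible integers. Vertices are stored at micro-pixel
(1e-6 px) precision so ROI files round-trip exactly. Medians over an even
pixel count are the mean of the two central values.

Total-tract and spermathecal images are distinct acquisition contexts
(different objectives and exposure times in the source protocol);
intensities are therefore never compared across sites, and every model in
the analysis stage is fitted per site.

## The synthetic scene generator

`simulate_tract_image()` renders a ground-truthed two-channel micrograph:

$$G = I \times (P + k \cdot C) + \varepsilon, \qquad
  R = I \times C + \varepsilon,$$

where $I$ is a smooth quadratic illumination surface, $P$ the additive
field of isotropic 2-D Gaussian sperm-head puncta, $C$ the chitin
amplitude field (thin polygonal bands), $k$ the crosstalk ratio (default
0.3) and $\varepsilon$ Poisson shot noise (gain 2) plus Gaussian read
noise (s.d. 10). The ground-truth record carries punctum coordinates and
amplitudes, the injected $k$, the illumination surface, and a true sperm
mask defined as the union of per-punctum footprints — pixels above 10% of
each punctum's peak, i.e. within $\sigma\sqrt{2\ln 10}$ of its centre.

Scene magnitudes are package choices, not literature values: the source
data report only an observed intensity range (≈ 6 to ≈ 11,000 on the
14-bit scale), so defaults were picked once to land mid-range —
punctum amplitudes 1000–1400, chitin bands at 5000–6000, σ = 0.9 px —
and are documented here rather than treated as derived quantities.

Two properties make the scene a usable oracle:

* **Crosstalk identifiability.** Within chitin, $G = k R$ holds exactly
  before noise (both channels share the illumination surface), so a
  punctum-free chitin ROI identifies $k$ exactly in noise-free mode and
  to within a few percent under the default noise.
* **Confluent clouds.** Puncta scatter uniformly in discs at a density
  (0.87 px⁻²) high enough that footprints are confluent; the true mask is
  then approximately the disc, and occupancy scales with disc area rather
  than punctum count. The intermodes threshold lands near half the
  interior fluorescence level, so the estimated cover differs from the
  footprint truth mainly by the cloud's edge ring — roughly
  $2\pi R \sigma\sqrt{2\ln 10}$ pixels. With the default geometry this
  keeps tract-cover estimates within ~3 percentage points of truth. The
  same ring is proportionally much larger for the small spermathecal ROI,
  whose cover estimates are therefore biased low against the footprint
  truth; in the real protocol the spermatheca is imaged at twice the
  magnification for exactly this reason, a refinement the single-frame
  generator does not emulate. Sparse scenes (a few isolated puncta)
  produce monotone histograms, the blank-tract fallback, and cover 0 —
  so the estimator should be read as "dense-fluorescence area", which is
  the regime the real assay operates in.

What the generator does *not* emulate: optical blur of the chitin
structures, tissue-level dim fluorescence, focus drift, saturated pixels,
or sperm motility. Passing tests therefore demonstrate the correctness of
the chain's arithmetic and its behaviour in the modelled regime, not
robustness to every artefact of real micrographs.

## The simulated experiment

`simulate_experiment()` draws the factorial study: 2 (male thermal
treatment: control 30 °C vs heat 41 °C) × 2 (female status: virgin vs
previously mated) × 2 (time: 30 min vs 24 h), with default cell sizes
(23, 25, 24, 25, 22, 24, 23, 24) — 190 females, one record per female per
site. Responses:

* **Cover** is beta-binomial with denominator 100 around the cell's
  expected proportion. The analysis stage fits quasi-binomial models, for
  which the beta-binomial is the standard generative counterpart; with a
  constant denominator of 100, an intraclass correlation ρ gives a
  constant variance inflation φ = 1 + 99ρ, exactly the quasi-binomial
  variance assumption. Default ρ = 0.05 (φ ≈ 6), i.e. strongly
  overdispersed proportions.
* **Intensity** is Gaussian truncated at 0. The default noise s.d.
  (250/350 intensity units per site) keeps the truncation mass negligible
  in every cell, so cell-mean ratios equal the injected multipliers.
* Factor effects act **multiplicatively on the response scale** — a
  thermal multiplier of 0.68 on cover means heat-treated males' sperm
  cover 32% less area. The default effect sizes encode the pattern the
  analysis stage is designed to detect: thermal effects at both sites, a
  temporal decline confined to the total tract, and a competitor
  (mating-status) effect confined to the spermatheca. Median intensity
  and presence are derived covariates so the correlation machinery has
  realistic inputs.

`simulate_paternity()` draws the sperm-competition assay: brood sizes
Poisson (mean 30), focal-male offspring counts beta-binomial with a
control-arm paternity share of 0.55, a heat-arm log-odds shift of −1.5,
and ρ = 0.35 — paternity shares in such assays are strongly heterogeneous
between females, which is why the quasi-binomial family is needed at all.

`run_full_synthetic()` chains everything: each female's target draws are
mapped to imaging parameters (cloud area ∝ target cover at fixed density,
punctum amplitude ∝ target intensity), one micrograph is rendered and
quantified per female, and the measured records are analysed. Because the
image chain intervenes, recovered effects on the image path are
attenuated relative to the injected multipliers (the cover → cloud-area →
measured-cover map is not affine); the record-level path is the one used
for calibration and recovery checks.

All randomness flows through one named generator (Mersenne-Twister with
inversion sampling) seeded explicitly per operation; child streams are
derived by seeding and drawing sub-seeds, and every run's manifest records
the seed and an MD5 of the configuration, which suffice to reproduce it
bit for bit.

## The inference stage

Each response × site combination is analysed separately, mirroring the
reporting structure of storage experiments of this kind:

* cover: logit-link **quasi-binomial** GLM on
  `cbind(percent, 100 − percent)`; non-integer "counts" are permitted —
  quasi-likelihood does not require integers;
* intensity: identity-link **Gaussian** GLM.

Fitting is IRLS (tolerance 1e-8, ≤ 100 iterations) via `stats::glm`;
non-convergence, aliasing and (quasi-)separation are rejected with named
errors. Overdispersion is assessed as the Pearson statistic over residual
degrees of freedom (`pearson_dispersion()`).

The maximal model contains the three design factors and all two-way
interactions; three-way interactions are never entered. `reduce_model()`
drops the least-significant interaction with p ≥ 0.05, refits, and
repeats until all remaining interactions are significant. Main effects
are part of the design and are never dropped regardless of p-value.

`drop1_llrt()` compares nested fits: for continuous responses
$F = (\Delta D / \Delta\mathrm{df}) / \hat\varphi$ with the dispersion
taken from the larger model (for a single-factor Gaussian model this is
exactly the classical one-way ANOVA F); for proportions the scaled
deviance $\Delta D / \hat\varphi$ is referred to χ². When a retained
interaction contains the factor under test, the main effect is tested
type-II style — both compared models exclude the interactions containing
it — because dropping a main effect *under* its interaction does not
change the model's column space in R's treatment coding.

Post-hoc contrasts (`posthoc_contrasts()`) report the Wald statistic of
each non-reference level (z for quasi-binomial, t for Gaussian) and a
percent change computed from model-predicted response-scale means with
the non-focal factors balanced equally across their levels; observed
group means ± s.e. ride along. Both model-adjusted and raw observed means
are reported because verbal effect sizes ("occupied X% less area") can be
computed either way. Explained deviance is
$1 - D_{res}/D_{null}$. **No multiple-testing correction is applied**
anywhere; every p-value is reported at face value, matching the
single-experiment reporting convention this package mirrors.

Reference levels are control, virgin, 30 min, so contrasts read
"treatment relative to control". Residual degrees of freedom are always
$n - p$; for 190 observations, three two-level factors and an intercept
that is 186.

AIC is reported only where it is defined: quasi-likelihood families have
no likelihood, so model comparison for the proportion responses rests on
the LLRTs alone.

## Problem sizes and numerical choices

The test-suite simulations use the study's default design (190 females)
for calibration: 2,000 null replicates for the type-I error of per-term
LLRTs, 500 replicates for Wald-interval coverage and effect recovery, and
100–200 seeded scenes for the image-chain properties; the default
128 × 128 scene keeps one full end-to-end run (190 rendered, quantified
and analysed micrographs) around a minute on one core. Degenerate inputs
are handled by typed errors (empty ROI, dark reference, unimodal
histogram, saturated model, zero-variance correlation) so batch runs can
skip and log individual samples; a full run aborts only if more than 10%
of samples fail.

## Known limitations

* The footprint-based cover truth and the threshold-based cover estimate
  agree only in the dense-fluorescence regime (see above); spermathecal
  cover from the shared-magnification synthetic frame is biased low.
* The rolling-ball border handling deviates from the interior behaviour
  within one ball radius of the image edge.
* The scaled-deviance χ² test with an estimated dispersion is slightly
  liberal at these sample sizes (the calibration suite bounds the
  empirical type-I error rather than assuming exact nominal level).
* The Dryad-deposited experimental dataset is not bundled or downloaded;
  `read_records_csv()` documents the schema for users who obtain it.
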