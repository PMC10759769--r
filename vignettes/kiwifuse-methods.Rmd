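---
title: "Methods: simulated fusion of vision and aroma sensing for kiwifruit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated fusion of vision and aroma sensing for kiwifruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Red-fleshed kiwifruit grown in different areas of Guilan province (Talesh,
Langarud, Rasht) differ systematically in chemistry — soluble solids,
acidity, vitamin C, phenolics, anthocyanins, antioxidant capacity — and in
the appearance of the cross-section, most visibly in the red locule ring.
Two instrument families measure correlates of these differences without wet
chemistry: a computer vision system (colour and morphology of whole fruit
and equatorial middle cuts) and an electronic nose (a 13-channel array of
metal-oxide gas sensors sampling the fruit's volatile headspace).
`kiwifuse` implements the full analysis chain — tissue segmentation, feature
extraction, feature-level fusion, PCA reduction, and grid-searched support
vector modelling — together with a synthetic-data generator that emulates
the statistical structure such a study assumes, so every stage is testable
end to end without any instrument data.

# The synthetic generator

## Physicochemical records

Each region has a profile of 13 attribute means (firmness, SSC, TA, BAR,
pH, vitamin C, TP, TAC, DPPH, FRAP, sucrose, glucose, fructose). At
`separation = 1` these equal the regional means a field study of ripened
'Khoni' fruit would report (e.g. Langarud SSC 20.96 °Brix, Rasht firmness
1.20 kg/cm²); `separation` interpolates linearly toward the grand mean, so
0 removes all regional structure. Records are drawn per attribute from a
normal law with sd `mean × cv × noise_scale` (default CV 0.05 — published
tables of this kind print letter groupings rather than dispersions, and a
5% within-orchard CV is typical for fruit quality panels), floored at 10%
of the mean to preserve positivity. The Brix–acid ratio is never sampled:
it is recomputed as SSC/TA after sampling, so `bar == ssc/ta` holds for
every record even though the rounded tabulated BAR means differ slightly
from the quotient of the tabulated SSC and TA means.

## Images

A scene is two concentric-ellipse renderings on a uniform background:
whole fruit (skin-coloured ellipse) and middle cut (outer pericarp
annulus, red locule ring, pale core). Defaults at the 1600 px working
scale: fruit semi-axes (600, 480) px, locule bound at 0.62 of the fruit
axes, core semi-axes (170, 136) px, per-channel Gaussian noise sd 3
(scaled by `noise_scale`), and ±4% uniform shape jitter. Base colours are
chosen so the per-tissue ExG (2G − R − B) levels — outer ≈ +170, core
≈ +15, locule ≈ −110 — are separated by far more than four times the ExG
noise sd (√6 × 3 ≈ 7.3), which guarantees threshold separability at
default noise. The locule ring carries radial luminance streaks added
equally to all three channels, texture that deliberately leaves ExG
untouched. Region identity enters through small colour offsets, strongest
in the locule (the tissue where growing conditions express themselves
most) and weaker in the skin, both scaled by `separation`.

Two rendering choices deserve a note. First, the background is an
off-white with a slight cool tint (246, 248, 253) rather than exact
neutral white: a perfectly neutral pixel has undefined hue, so under noise
its hue is uniform random and the hue-threshold section segmentation the
pipeline specifies could not work; a faint tint — visually
indistinguishable from white card under chamber lighting — keeps the
background hue stable. Second, the locule base colour (180, 55, 40) sits
at hue ≈ 0.02, safely off the 0/1 hue wrap, so arithmetic hue means stay
meaningful; the segmentation still rotates hue by 0.5 before thresholding
so near-wrap reds form one mode.

## E-nose curves

The acquisition protocol is 220 s at 1 Hz: 120 s clean-air baseline, 40 s
headspace injection, 60 s recovery. The 1 Hz rate is a package convention
(acquisition hardware of this class samples between 1 and 10 Hz); it makes
the 121–140 s feature window exactly 20 samples. For sensor *s* the
noiseless curve is flat at `V0_s` through the baseline, rises as
`V0_s (1 + A_s (1 − e^{−(t−120)/τ_s}))` during injection, and relaxes
toward `V0_s` with time constant `2τ_s` in recovery. Amplitude couples
chemistry to aroma: `A_s = gain_s (1 + κ z)`, with `z` the standardised
SSC of the fruit (grand mean and between-region spread of the regional SSC
means as centre and scale) and `κ = 0.3`. SSC is the single latent
coupling: it is the attribute a volatile-driven sensor plausibly tracks
(sugar-driven esters dominate ripe kiwifruit headspace), and one
documented latent keeps the regression-recovery question well-posed.
Sensor gains differ by region — Langarud fruit, the sweetest and most
aromatic, carry the largest multiplier on every channel — so both the
overall amplitude and its pattern are informative. Within-sample noise
comprises a 5% multiplicative amplitude disturbance, additive voltage
noise (sd 0.002) and a small random baseline drift, all scaled by
`noise_scale`.

## What the generator does and does not emulate

It reproduces the *statistical* structure the analysis assumes:
region-dependent means, a latent chemistry–aroma coupling, geometric and
chromatic tissue contrast, acquisition timing. It does not attempt
photorealism, sensor drift chemistry, humidity/temperature effects,
multi-fruit scenes, or illumination gradients. Consequently, passing
tests demonstrate that the pipeline recovers known structure under its own
assumptions — not that it would reach the same accuracies on real fruit,
where tissue boundaries are irregular and the chemistry–aroma relation is
far noisier. In particular, synthetic image features carry no
within-region chemistry signal at all (colour varies by region only), so
regression on visual or fused features can only exploit between-region
structure, whereas the e-nose channel carries the latent SSC signal
directly; see "Regression recovery" below.

# The measurement pipeline

## Segmentation

Whole fruit: ITU-R 601 grayscale → Otsu threshold → the class not holding
the image corners is the fruit → morphological opening (disc, radius 5 px
at the 1600 px scale, scaled proportionally at other sizes) → largest
connected component → hole filling. Middle cut: Otsu on the
half-rotated hue channel (the fruit class is the one with higher mean
saturation), the same cleanup, then a two-stage ExG split inside the
section: one Otsu isolates the strongly green outer pericarp; a second
Otsu on the remainder separates the near-zero-ExG core from the strongly
negative locule, and the locule is obtained by subtraction, which makes
the partition `outer ∪ core ∪ locule = section` exact by construction.
The two remainder subclasses are accepted as distinct tissues only when
their ExG means differ by more than three pooled standard deviations;
otherwise the remainder is a single tissue (the core) and segmentation
fails naming the locule — the behaviour wanted for a degenerate cross
section without a locule ring.

## Features

46 visual features in fixed order: whole-fruit colour means in RGB
(0–255), HSV (0–1) and CIELAB (sRGB → XYZ under D65 → Lab) plus area,
roundness and aspect ratio; section morphology; outer, locule and core
colour means; the locule area rate; core morphology. Roundness is
`4πA/P²` with the perimeter measured on the 8-connected outer contour
polygon smoothed by a 7-point circular moving average. The smoothing
removes the digitisation staircase, the dominant bias of chain-length
perimeters: an ideal digital disk then scores ≈ 1.00 while a filled
square keeps ≈ π/4, which no single classical weighting (Freeman chain,
corner-corrected chain, pixel-count) achieves on both shapes. Aspect
ratio is the axis ratio of the moment-equivalent ellipse.

13 e-nose features: each curve is normalised to fractional change from
baseline, `Y(t) = (X(t) − X(0))/X(0)`, with `X(0)` estimated as the mean
raw response over 110–120 s — the last stretch of the baseline phase —
rather than a single literal first reading, which would be needlessly
noise-sensitive; the window is configurable. The maximum sensor response
(MSR) is the maximum of `Y` over 121–140 s, both endpoints included. The
normalisation is exactly invariant to any positive gain on the raw curve,
and on noiseless curves the MSR equals the closed form
`A_s (1 − e^{−20/τ_s})`.

## Fusion and modelling

Feature-level fusion concatenates the 46 visual features and 13 MSR values
into one 59-vector before any reduction. A single PCA is fitted on
calibration data only, on z-scored features (correlation-based: pixel
areas and normalised sensor responses differ by orders of magnitude, and
an unstandardised decomposition would be dominated by areas); constant
features are dropped with a warning; the stored centre/scale/rotation are
reused verbatim for test data, so no test information leaks into the
transform. Four components are retained by default for every feature set
(a configurable choice; two suffice to visualise the e-nose separation,
but the modelling default is uniform).

Classification and regression use support vector machines with an
inhomogeneous degree-2 polynomial kernel (`(γ u·v + 1)²`; the +1 offset
admits the linear terms a homogeneous quadratic lacks), one-vs-one voting
for the three classes, and a 5 × 5 grid of cost and γ over
{0.01, 0.1, 1, 10, 100}. Model selection minimises the RMSE of pooled
out-of-fold predictions under ten-fold cross-validation — stratified folds
for classification, plain random folds for regression, both seeded.
Classification RMSE is computed on the integer region codes (Talesh 1,
Langarud 2, Rasht 3), a documented convention that makes the selection
criterion uniform across tasks. Ties take the first pair in row-major
grid order (cost outer, γ inner).

Two numerical safeguards matter here. Inputs (and regression targets) are
standardised inside each SVM fit; without this, extreme grid corners drive
the SMO solver into multi-minute stalls. Even standardised, a few extreme
pairs hit the solver's internal iteration cap and return poor fits; the
grid loop therefore abandons a candidate's remaining folds as soon as its
pooled squared error already lower-bounds its final CV RMSE above the best
completed candidate's — a purely algebraic shortcut that provably selects
the same pair as exhaustive evaluation, tie-break included.

## Evaluation

Calibration metrics come from refitting the selected pair on all
calibration data; validation metrics from the pooled ten-fold
cross-validation predictions of that pair; test metrics from the held-out
third (stratified per class, test share rounded up). Accuracy is
100 × correct/total; regression reports RMSE and R² = 100 × (1 −
SSres/SStot), which is negative for models worse than the mean.

# Choices made where the design was open

* **Opening, not closing.** The morphological cleanup is described in the
  source material as "opening (dilation followed by erosion)", which as
  parenthesised is closing; the operation is *named* opening and used for
  noise removal, so standard opening (erosion then dilation) is
  implemented.
* **ExG split in two stages.** Whether outer and core came from one
  two-level threshold or two successive Otsu splits is not specified; the
  two-stage reading is implemented because it needs only a binary Otsu and
  yields the core/locule bimodality check for free.
* **Background tint and locule hue** — see the generator section above.
* **Sampling rate 1 Hz and the averaged baseline window** — see the e-nose
  sections above.
* **PCs for single-modality models.** Score plots of e-nose data are often
  shown in two components, but all models here default to four
  (`n_components` is configurable).
* **Default regression targets** are the ten modelled quality indices
  (firmness, SSC, TA, BAR, pH, vitamin C, TP, TAC, DPPH, FRAP); the free
  sugars are generated but not modelled by default.

# Problem sizes used by the tests

The package's own test suite runs the generator at reduced rendering
resolution where full scale adds nothing: unit fixtures render at
160–400 px; the segmentation-fidelity check uses twenty 400 px scenes; the
classification-ceiling check runs the complete pipeline at the native
1600 px on 45 fruit (15 per region, separation 1, noise 0.3); regression
recovery uses 45 fruit at noise 0.5; fusion dominance averages ten seeded
replicates of 36 fruit at moderate noise (`noise_scale = 1`). Scene
geometry scales linearly with image size, so resolution changes test
runtime, not structure.

# Regression recovery and what fusion buys

With the default four components, the e-nose pipeline recovers SSC with
validation R² well above 95% up to `noise_scale = 0.5`: the MSR pattern is
linear in the latent `z` and PCA preserves that direction. Fused features
recover slightly less (≈ 90–94%) because the 46 visual features contribute
variance but no within-region chemistry, diluting the latent direction
across four components — an honest property of this generator, not of
fusion in general; with real fruit, colour does track ripeness chemistry.
Fusion pays off where both channels carry class signal: region
classification from fused features reaches 100% on separable data and, at
moderate noise, its mean held-out accuracy over ten seeds is at least that
of either single modality (the e-nose alone degrades fastest, because its
region pattern is nearly rank-one and the latent SSC variation blurs it).

# Known limitations

* Tissue boundaries are perfect ellipses; segmentation IoU on real cuts
  would be lower, and the locule subtraction inherits any outer/core error.
* One latent factor links chemistry to aroma; real covariance structures
  are richer, so the regression-recovery ceiling here is optimistic.
* Classification RMSE on integer codes treats the regions as equally
  spaced, which is a reporting convention, not a metric claim.
* The SMO iteration cap means extreme grid corners return approximate
  fits; they are never selected, but their recorded CV RMSE (or its lower
  bound, for abandoned candidates) should not be interpreted as a
  converged value.
* Hue means are arithmetic, not circular; tissue base colours are chosen
  away from the hue wrap, but strongly red-shifted custom palettes could
  bias the hue feature.
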