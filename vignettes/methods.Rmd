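---
title: "Estimating fish weight from single-camera underwater images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fish weight from single-camera underwater images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaweight)
```

## The problem

Weight is the quantity a fish farm manages: it drives feeding, grading,
and the harvest decision. Weighing Tilapia directly means netting them,
which injures fish and costs labour, so the goal here is a *non-intrusive*
estimate from a single fixed underwater camera — no stereo rig, no
controlled studio, and water kept deliberately turbid by biofloc
microorganisms. `aquaweight` implements the full estimation chain plus a
calibrated synthetic data generator that stands in for the original farm
recordings, which are not publicly distributable.

## The model

### Geometry

A pinhole camera maps true size to apparent size as

$$\mathrm{px} = \mathrm{cm} \times \frac{f}{d},$$

with $f$ the focal length in pixels and $d$ the camera-to-fish distance
("depth", 5–60 cm here). Apparent size therefore confounds body size and
depth; the cascade resolves the confound statistically, using the fish's
age as the anchor: at a known age the cohort's size distribution is
narrow, so an unusually large apparent size mostly means a close fish.

### The regression cascade

Three stages are trained on annotated sightings and chained at
prediction time:

1. **Depth**: $\hat d = f(\text{age}, \ell_{px}, w_{px})$ — support
   vector regression with an RBF kernel
   $K(x_1, x_2) = \exp(-\lVert x_1 - x_2\rVert^2 / 2\sigma^2)$.
2. **Pixel to cm**: $(\hat \ell_{cm}, \hat w_{cm}) =
   f(\text{age}, \ell_{px}, w_{px}, d)$ — two independently trained
   linear regressions, one per output (the multi-output handling is a
   design choice; nothing in the chain requires joint fitting).
3. **Weight**: $\hat W = f(\text{age}, \ell_{px}, w_{px}, d,
   \ell_{cm}, w_{cm})$ — linear regression.

Each stage trains on *annotated* inputs (the depth label a human read
off tank markers, the studio-measured centimetre dimensions); at
inference each stage's estimate feeds the next. Training on annotations
rather than on upstream predictions keeps the stages independently
interpretable and lets the nine-way family comparison
(`cascade_case_grid()`) reuse fitted stages; the cost is a train/test
input mismatch whose effect is visible in (and measured by)
`evaluate_cascade()`, which always chains.

Families are selectable per stage (LR, RFR, SVR). The defaults —
SVR / LR / LR, the "SLL" configuration — mirror the selection made on
the real data, where SVR won the depth stage and linear models won the
other two. SVR hyperparameters are chosen by exhaustive grid search on a
validation split (cost in {0.1, 1, 10, 100}, kernel coefficient in
{0.001, 0.01, 0.1, 1}, tube width in {0.01, 0.1, 1}); ties go to the
first combination in grid order, so selection is deterministic. Random
forests are depth-limited to 2 levels (mapped to 4 terminal nodes;
`min_samples_split` is folded into the leaf-size control because the
underlying forest implementation exposes only `nodesize`). Features are
standardized internally for SVR only; LR and RFR are scale-equivariant
or scale-free.

### Data splitting

`split_dataset()` shuffles by seed and applies two-level rounding with
ties to even: `|test| = n − round(0.7 n)`, then `|val| = m −
round(inner·m)`. With the 2777-row annotation table and inner fraction
0.8 this yields 1555/389/833, and with 4287 images and inner 0.7,
2101/900/1286 — matching the published split tables exactly, which is
how the rule (and the inner fractions) were pinned down.

### Evaluation

`metrics_report()` bundles MAE, $R^2 = 1 - SS_{res}/SS_{tot}$ (negative
when a model is worse out-of-sample than the mean predictor), the signed
error mean and sample SD (predicted − actual, $n-1$ denominator; the
sign convention makes "model under-predicts" a negative mean), and the
**MAE ratio** = MAE / $R^2$. The ratio is not defined at $R^2 = 0$ and
goes negative with negative $R^2$; it reproduces every published
model-comparison cell from its row's MAE and $R^2$ to ±0.01, which is
the basis for implementing it as a plain quotient.

### Area-based baselines

Seven classical allometric estimators map body area
$A = \ell_{cm} \times w_{cm} \times c$ to weight: two power laws, an
exponential, a linear, a logarithmic, and a quadratic form, with
published coefficients as defaults. `fit_comparator()` refits any family
by OLS in the appropriate (log-)space — exact on noiseless data from its
own family, deterministic, and simple; this deliberately differs from
nonlinear least squares on noisy data. The area coefficient $c$ is never
published; it defaults to 1 and is exposed as a parameter, on the
assumption that fitted constants absorb it.

## The synthetic generator

The generator emulates the study conditions rather than any particular
image:

* **Cohort**: ages 20–28 weeks (recorded biweekly); weight is normal,
  truncated at zero, with mean and SD interpolated linearly in age
  between the two published weighings (166.45 ± 26.38 g at week 20,
  482.24 ± 91.64 g at week 28). Linear interpolation is the least
  structured choice consistent with two anchor points.
* **Allometry**: $W = aL^3$ with $a = 166.45/20^3 \approx 0.0208$, so
  mean lengths run ≈20–28.5 cm (inside the measured 20–30 cm range) and
  widths, at a fixed 0.38 ratio, ≈7.6–10.8 cm (inside 7–12 cm).
* **Camera**: 1920 × 1080 frames, focal 1000 px (a 25-cm fish at 50 cm
  spans 500 px), depth uniform on [5, 60] cm redrawn when a fish would
  overflow the frame, labels quantized to the nearest 10-cm marker
  (markers only exist at multiples of the spacing inside the range, so
  a 5-cm sighting is labelled 10). The published account gives the depth
  range as 5–60 cm in one place and observed labels 5–50 cm in another;
  both bounds are plain parameters here rather than a resolution of that
  conflict.
* **Noise defaults**: pixel measurement SD 2 px; individual weight
  variation through the interpolated SD; depth label quantization.
* **Scenes**: fish drawn as filled ellipses at seeded positions over a
  dark noisy background; turbidity $t \in [0,1]$ applies Gaussian blur
  (σ = 3t px), a green cast (+40t), and contrast compression toward the
  mean (60% · t) — pixels only, never annotations.

What the generator does **not** emulate: fish texture and fins,
occlusion by other fish bodies (overlap is geometric only), lighting
gradients, motion blur, and any correlation between turbidity and
detectability of specific fish. Passing tests therefore demonstrate that
the estimation chain is implemented correctly and behaves as designed
under controlled conditions — not that a particular detector would reach
the published AP on real footage (training detection networks is out of
scope; the detector seat is a protocol with an oracle and a classical
threshold backend).

## Numerical choices

* Image operators clip to [0, 255] and round half away from zero;
  borders are replicate-padded; the colour matrix clips negative
  intermediates to zero before the $1/\gamma$ power. None of the
  enhancement constants (kernel, CCM entries, γ, α, β) are published;
  defaults are an identity CCM with γ = 2.2, the standard 3×3 sharpen
  kernel, α = 1.3, β = 10, chosen to visibly counteract the synthetic
  turbidity model, and all overridable. The four-step description of
  enhancement (sharpen, colour filter, colour balance, exposure) is
  implemented as three operators, with the CCM covering both colour
  steps.
* AP uses 101-point interpolation and greedy score-descending matching
  (highest-IoU unmatched ground truth at or above the threshold), the
  COCO convention, so small-case values are exactly reproducible. The
  empty-vs-empty case is defined as 1 by convention.
* The mask loss is the standard two-term binary cross-entropy averaged
  over pixels (the one-term form sometimes printed for it is not a BCE).
* Rank-deficient linear designs fall back to the minimum-norm SVD
  solution with a warning. This matters routinely here: the generator's
  width is exactly 0.38 × length, so the weight stage's centimetre
  features are collinear by construction.
* Degenerate inputs: zero-fish scenes render background only; an
  observation whose projection overflows the frame raises a classed
  error (`aquaweight_projection_overflow`) rather than disappearing;
  empty detection sets flow through the pipeline as warnings, not
  errors.

## Problem sizes in the test-suite experiments

The scaled-down performance analogue trains on a 2777-row synthetic
table (the published table size) with default noise and checks depth
R² ≥ 0.8 and weight R² ≥ 0.6 on the test split; measured values are
≈0.92 and ≈0.74. Recovery and pipeline tests use a 320 × 180 camera
(focal 200 px) so scenes render quickly; geometry is scale-free, so
nothing depends on the frame being full HD.

The end-to-end recovery test (scenes → oracle detector → cascade →
within 10% of true weight per fish) runs in the *noiseless* setting:
pixel noise 0, unquantized depth labels, and individual weight variation
reduced to a tenth of the calibrated SDs. The reduction is not cosmetic:
with full individual variation, per-fish weight is unidentifiable from
(age, $\ell_{px}$, $w_{px}$) even in principle — depth and body size
enter only through one projection, and width/length is constant, so the
best possible estimator collapses to the age-conditional mean and
per-fish errors reach ~35%. With variation exactly zero the test would
be vacuous (weight becomes a function of age alone). A tenth keeps the
projection chain load-bearing while making per-fish recovery
well-posed; measured errors are ≤ ~3% against the 10% bound.

## Known limitations

* Per-fish weight accuracy under realistic individual variation is
  bounded by the depth–size confound; the cascade is at its best as a
  cohort-level monitor (the population-level MAE/R² view), exactly the
  use case it was designed for.
* Cross-frame identity is out of scope: the same fish detected in two
  frames yields two rows. The 0.8 score filter applies per frame.
* The threshold detector is a baseline for synthetic scenes, not a
  substitute for a trained network on real turbid footage.
* Ages are supplied by the operator at prediction time; the system does
  not infer age.
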