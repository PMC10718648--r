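---
title: "Methods: band registration, enhancement, and detection scoring in lodgekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band registration, enhancement, and detection scoring in lodgekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodgekit)
```

## The problem

Wheat lodging — stems permanently displaced from vertical — is scored in
breeding trials on a 1–9 scale, from fully upright (class 1) to more than
75% of plants flat on the ground (class 9). UAV multi-spectral cameras
make this scoring automatable, but each spectral band is captured by a
physically separate sensor: blue, green, red, red-edge and near-infrared
images (1456×1088) and a broadband panchromatic image (2464×2056) of the
same scene are mutually misaligned by a few pixels and a fraction of a
degree, and the offset varies with flying height. Before any composite or
vegetation index can be computed, the bands must be registered onto a
common grid.

`lodgekit` implements that preprocessing chain — rigid band registration,
two radiometric enhancement presets, band composition and four vegetation
indices — together with the full object-detection evaluation suite used
to score a lodging-severity detector, and a synthetic scene generator so
the whole chain is testable without field data.

## Rigid registration by weighted mutual information

Each non-reference band is aligned to the green band (band 2), whose
central position in the spectrum makes it a good compromise reference.
The transform is rigid — rotation `theta` about the image center plus a
translation `(tx, ty)` — and resampling uses inverse-mapped bilinear
interpolation. Output pixels whose source falls outside the moving image
are excluded from the metric through a validity mask rather than filled:
a constant fill value would inject spurious joint-histogram mass and bias
the similarity metric.

The similarity metric is mutual information,

$$ s = \sum_{i,j} p_{ij} \log_2 \frac{p_{ij}}{p_i p_j}, $$

computed from a joint histogram of the two images' intensities with 64
equal-width bins per axis over [0, 1] (a bin count with no physical
meaning; 64 gives roughly 25 samples per occupied cell at the working
resolution and behaved equivalently to 32 or 128 in smoke experiments).
A Gaussian spatial weight

$$ w(x, y) = \exp\!\left(-\frac{(x - x_c)^2 + (y - y_c)^2}{2\sigma^2}\right) $$

enters the accumulation: each pixel contributes `w(x, y)` instead of 1 to
its joint cell, focusing the metric on the image center. The package
treats the weighted histogram as *the* histogram and computes MI once on
it — the only reading under which a per-pixel weighting and a global
histogram quantity are simultaneously computable. `weighted = FALSE`
gives plain MI. `sigma` defaults to `min(H, W) / 4` pixels, wide enough
that the corners still contribute a fifth of the central weight.
Logarithms are base 2 (bits); the argmax is base-invariant.

### The (1+1)-evolution strategy

The optimizer is a (1+1)-evolution strategy over `(theta, tx, ty)`:
propose `parent + radius · scales · N(0, 1)`, accept only strict
improvements, grow the radius by a factor of 1.002 on acceptance and
shrink it by the same factor on rejection, stop when the radius falls
below 1.5e-6 or after 500 iterations. The four search constants
(growth factor 1.002, 500 iterations, initial radius 2e-4, stopping
radius 1.5e-6) are fixed calibrated values. Note a structural property of
these constants: from 2e-4, five hundred divisions by 1.002 cannot reach
1.5e-6, so termination is in practice by iteration count, and the
`converged` flag mostly records that the radius never collapsed — the
recovered transform is accurate regardless (the truth-recovery suite
passes with `converged = FALSE` everywhere).

The radius lives in a normalized parameter space. Step scales are
`(1 rad, diag px, diag px)` with `diag` the image diagonal, so one unit
of radius corresponds to comparable angular and translational
perturbations.

### Capture range: pyramid plus exhaustive initialization

A 3-level coarse-to-fine pyramid (factor 2 per level, 2×2 block-mean
reduction) refines the transform from quarter to full resolution,
doubling translations between levels. The pyramid alone, however, cannot
supply the capture range the tiny initial radius lacks: the ES step
*and* the residual offset both scale with resolution, so their ratio is
level-invariant, and rotation does not shrink with the pyramid at all.
`lodgekit` therefore seeds the search deterministically:

* at the coarsest level, an exhaustive MI scan over integer coarse-grid
  shifts (±`init_search_px`, default 12 full-resolution pixels) crossed
  with whole-degree rotations (±`init_search_deg`, default 3°);
* at each finer level, a local ±0.5° angle scan in 0.125° steps around
  the current estimate.

Both scans evaluate the same objective as the ES and add a few hundred
cheap coarse-level evaluations. With them, the stochastic search only
ever needs to polish a sub-pixel, sub-half-degree residual, which the
printed radius handles well; truth-recovery on synthetic captures
(|t| ≤ 10 px, |θ| ≤ 2°, 364×272) succeeds for ≥ 90% of band
registrations at the 0.5 px / 0.2° tolerance (see
`tests/testthat/test-acceptance.R`).

The panchromatic band is first bilinearly resized to the reference shape
and then registered like any other band; its transform is therefore
expressed at reference resolution.

## Enhancement presets

**Haze & gamma adjustment.** Per channel `c` with intensities `I` in
[0, 1]:

* dark level `a_c = 0.25 · percentile(I, 1)` (linear-interpolation
  percentile);
* haze term `t_c = 1[I > a_c](1 + α_c (I − a_c)) − β_c` with α = 0.2,
  β = 0.7;
* brightness `b_c = mean((I − a_c) · t_c^{γ_c})` with γ = 0.6;
* output `b_c · t_c^{γ_c}`.

The formula as printed leaves three things undefined, resolved here as
package choices, each toggleable through `haze_gamma_params()`: the
indicator is read multiplicatively; `t_c` is clipped below at 1e-6 before
the fractional power (with β = 0.7 negative `t_c` is the common case, and
fractional powers of negatives are undefined); and the output channel is
rescaled so its maximum maps to 1, then clipped to [0, 1], because
`b_c · t^γ` has no natural bound (the clip also guards the pathological
case of a channel dark enough that `b_c < 0`). Under these choices the
map is monotone within a channel, which the tests check directly against
a per-pixel transcription oracle.

**Contrast-limit stretching** is the affine map
`(I − I_min,c) / (I_max,c − I_min,c) · 255` with the limits computed
independently per channel as that channel's extrema; the minimum maps
exactly to 0 and the maximum to 255, and re-stretching a stretched
channel is the identity. Constant channels are rejected
(`"degenerate contrast range"`) rather than silently mapped.

## Composition and vegetation indices

Composition is pure channel stacking of aligned bands: `(3, 2, 1)` gives
the true-color composite, `(4, 2, 1)` substitutes the red-edge band for
the red display channel. Four reflectance-ratio indices are evaluated
per pixel (B, G, R, NIR = bands 1, 2, 3, 5):

| Index | Formula |
|-------|---------|
| NDVI  | (NIR − R) / (NIR + R) |
| VARI  | (G − R) / (G + R − B) |
| GARI  | (NIR − (G − (B − R))) / (NIR + (G − (B − R))) |
| SABI  | (NIR − R) / (B + G) |

Some transcriptions of GARI print the denominator as
`NIR − (G + (B − R))`; the package defaults to the standard form above
and exposes the printed variant behind `as_printed = TRUE` rather than
guessing intent. Pixels whose denominator magnitude falls below
`safe_epsilon` (default 1e-9; VARI's `G + R − B` genuinely vanishes on
real data) are masked invalid instead of producing infinities.

## Detection evaluation conventions

Boxes are 0-based, half-open pixel rectangles, so areas are exact
products of side lengths; severity classes are 1–9 in memory and 0–8 in
the on-disk annotation format, shifted only at the I/O boundary. The
conventions, all chosen to make every result bit-reproducible:

* **Matching** is greedy: detections in descending confidence (ties by
  input order) claim the unmatched ground truth with highest
  IoU ≥ threshold (IoU ties to the lower ground-truth index).
* **AP** integrates the precision envelope (precision made monotonically
  non-increasing in recall) over all recall change-points — the
  all-point interpolation used by the modern single-stage detector
  family. mAP averages over classes with at least one ground-truth box;
  absent classes are excluded rather than counted as zero.
* **mAP@0.5:0.95** averages mAP over the ten IoU thresholds 0.50, 0.55,
  …, 0.95.
* **NMS** is greedy and class-aware by default (IoU threshold 0.45).
* The **confusion matrix** uses class-agnostic matching (so cross-class
  confusions are visible) with a background row/column for unmatched
  boxes, emitted as raw counts with a normalization option in the plot.
* True negatives are not reported: they are undefined for detection.

Every one of these operations is tested against an independent
brute-force oracle (exhaustive loops re-deriving the quantity from its
definition) on randomized small scenarios.

## The synthetic scene generator

`generate_capture()` emulates what the preprocessing stack consumes: a
grid of rectangular plots (3 m × 1.2 m plots map to 220×90 native pixels
under the defaults) on a soil background; per-plot severity class with a
lodged patch whose area fraction is 0 at class 1, linear to 0.75 at
class 8, and drawn from (0.75, 0.95] at class 9 — the scale anchors fix
only the two endpoints, so linearity in between is declared, not
inferred; band-dependent reflectance (upright canopy: low visible, high
NIR; lodged patches: brighter visible, darker NIR, emulating exposed
stems); a smooth multiplicative texture shared across bands so the MI
metric has structure away from plot edges; per-band rigid offsets
(default |t| ≤ 10 px, |θ| ≤ 2° at working resolution, the reference band
fixed to the identity); and additive Gaussian sensor noise (sd 0.01
reflectance units, a typical SNR for calibrated multispectral sensors).
The scene is evaluated *analytically* through each band's true inverse
transform, so truth recovery is limited only by noise and sampling, not
by a second interpolation.

What it does **not** emulate: radiometrically calibrated reflectance,
perspective or lens distortion, canopy 3-D structure, shadows, or
wind-blurred texture. Passing registration tests therefore demonstrate
the estimator recovers known rigid misalignments under realistic noise
and texture — not that real wheat imagery is this benign. Reflectance
profiles are fixed plausible constants; their only job is to give
registration texture and the indices the right sign structure (canopy
NDVI > soil NDVI is a construction guarantee the tests exploit).

Desk-scale default: `image_scale = 0.25` (364×272) keeps a 20-capture
registration suite under a minute; the lodged-area rasterization check
samples at native scale, where pixel quantization of a 90 px plot stays
inside its 2% bound.

## Numerical choices

* 16-bit loading divides by 65535 (not 65536), so the maximum code maps
  exactly to 1.0; band TIFF writing rounds to the nearest code and
  nudges by +0.499 code steps because libtiff truncates — a
  write/load cycle is exact to half a code step.
* 8-bit RGB export clips then rounds half-up (127.5 → 128).
* Annotation files print six decimals; a read/write round-trip is exact
  to `0.5e-6 ×` image width (≈ 0.0007 px at native width).
* Index maps are stored as 32-bit float TIFFs min-max scaled to [0, 1]
  with a JSON sidecar (offset, scale, invalid-pixel indices);
  `read_index()` restores original values to float-32 precision.
* All randomness (scene generation, detection degradation, optimizer
  proposals, dataset splits) flows from explicit integer seeds;
  identical inputs and seed give bit-identical results, and the RNG
  state of the calling session is restored afterwards.

## Problem sizes in the shipped checks

The test and acceptance runs use 20 synthetic captures at 364×272 for
registration recovery, 200 random 8×8 image pairs for histogram/MI
oracle equivalence, 200 toy detection scenarios (≤ 4 images, ≤ 12 boxes)
for metric oracle equivalence, one full simulate→preprocess→evaluate
pass for the perfect-detector check, and 500 truth boxes for the
degraded-recall binomial check — sizes chosen so the whole suite runs in
a few minutes on a laptop while keeping every statistical check
well-powered.

## Known limitations

* Only rigid transforms: affine, projective or deformable alignment and
  keypoint-based registration are out of scope.
* The detector itself is a file-drop interface: any model emitting the
  annotation format with confidences plugs in; no training or inference
  happens here. `split_dataset()` provides the seeded 70/10/20 partition
  for users who do train one.
* No orthomosaicking, georeferencing, or reflectance-panel calibration;
  inputs are treated as raw normalized intensities, since whether
  calibration preceded registration in the original workflow is
  unstated.
* The `(1+1)`-ES explores a 3-parameter space; with the printed
  constants it refines rather than searches, which is why the
  deterministic initializer above exists.
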