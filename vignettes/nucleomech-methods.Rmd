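---
title: "Quantifying nuclear mechanics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear mechanics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleomech)
```

This vignette documents the models behind each pipeline, the tunable
parameters with their units and defaults, what the synthetic-data
generators do and do not emulate, and the numerical choices made where the
underlying procedures left the design open.

## Sensitized-emission FRET

### Model

Three images are acquired per scene: donor excitation/donor emission
(`D`), donor excitation/acceptor emission (`F`), and acceptor
excitation/acceptor emission (`A`). The `F` channel mixes three sources:
energy transfer (sensitized emission), donor emission leaking through the
acceptor emission filter (fraction `x` of `D`), and acceptor fluorescence
excited directly by the donor line (fraction `y` of `A`). The per-pixel
index is

$$\mathrm{index} = \frac{F - xD - yA}{A},$$

the sensitized emission as a fraction of acceptor intensity. It is *not*
FRET efficiency — converting to efficiency would need spectral and
quantum-yield information the three-cube acquisition does not provide —
but it is monotone in energy transfer at fixed stoichiometry, which is
what the tension-sensor vs headless-control comparison requires. The
formula is degree-zero homogeneous in the three channels, so the index is
exactly invariant to global intensity scaling, and any multiplicative
field shared by the channels (illumination, exposure) cancels pixel-wise.

### Correction cascade

Each acquisition passes through, in order: background subtraction,
illumination-gradient correction, pixel-shift registration, and one pass
of a 3×3 uniform mean filter. Choices inside those steps:

* **Background** is the mean of a user-supplied cell-free rectangle. In
  the FRET cascade subtraction is *unclamped* (`clamp = FALSE`): clamping
  negatives to zero rectifies the noise in dim pixels and biases every
  subsequent least-squares slope; zero-mean residual noise is harmless.
  The clamped default remains for ordinary image cleanup, where
  non-negativity is the contract. The background rectangle should be
  generous: with an *n*-pixel region the background estimate carries a
  standard error of σ/√n per channel, which propagates directly into the
  per-cell index as an offset of order (σ/√n)/A.
* **Illumination** is modelled as a quadratic surface fitted by least
  squares and divided out. In sparse fluorescence scenes only
  signal-bearing pixels express the illumination profile, so the surface
  is fitted to above-Otsu pixels and evaluated everywhere; noise-only or
  flat images fall back to an all-pixel fit and pass through unchanged.
  Crucially, the three channels of one acquisition share a *single*
  surface (estimated from the brightest channel) and a single rescale
  factor: per-channel surfaces would wiggle independently and distort the
  very inter-channel ratios the index is built from, whereas a shared
  field cancels exactly by homogeneity.
* **Registration** estimates the inter-channel shift by the FFT
  cross-correlation peak with parabolic sub-pixel refinement (validated
  to < 0.1 px on smooth scenes). The shift is applied *symmetrically*:
  the donor moves by −s/2 and the moving channels by their shift minus
  s/2. Resampling one channel only would blur it by the bilinear
  interpolation kernel while leaving the reference sharp, biasing
  pixel-wise slopes low by several percent; the symmetric scheme gives
  every channel the same interpolation smoothing. Edge pixels that sample
  outside the frame are invalidated, not extrapolated. If no confident
  correlation peak exists (empty channel), a zero shift is applied with a
  warning.
* **"Three-point smoothing"** is implemented as a single 3×3 uniform
  mean — the minimal 2D reading of a three-point neighbourhood average.
  A 1D 3-tap filter applied per axis is nearly indistinguishable on
  smooth scenes; the 2D kernel was chosen and is recorded in provenance.

### Calibration

`x` is the slope of `F` on `D` over foreground pixels of a donor-only
sample; `y` likewise from an acceptor-only sample. Two refinements keep
the slope faithful at realistic noise:

* **Errors-in-variables correction.** Noise in the regressor channel
  attenuates the ordinary least-squares slope by
  $s_x^2/(s_x^2 + \sigma_n^2)$. The noise variance is estimated robustly
  (squared MAD) from sub-floor pixels of the same processed channel and
  divided back out. With clean calibration images the correction factor
  is 1 and the noiseless contract (exact slope) is untouched.
* **Binned r².** The reported fit diagnostic is computed on a
  20-quantile-bin mean profile rather than the raw pixel scatter, because
  pixel noise deflates scatter r² even when the relation is perfectly
  linear. A binned r² below 0.5 rejects the sample as unsuitable.

The per-pixel index is undefined (NA, never zero) where the acceptor is
at or below a floor of 3× the background SD, because the ratio is
unstable there. Per-cell means are taken over defined pixels inside each
mask; masks may be supplied or derived automatically as a 0.5–1.5 µm
perinuclear ring around segmented nuclei (manual masks take precedence;
overlapping automatic rings resolve to the higher label). Cells with
fewer than 50 defined pixels are dropped with a warning.

At the reference conditions (SNR 20, 10⁴–10⁴·2 foreground pixels) the
end-to-end pipeline recovers calibration slopes within 0.01 and the mean
cell index within 0.01 of truth; at SNR 10 a residual attenuation of
order 0.01 on the index remains — a known limitation of pixel-wise slope
calibration at low SNR.

## 3D volumetry and 2D shape

### Segmentation

Confocal stacks are anisotropic (default 0.25 µm z-steps, 0.1 µm
in-plane), so all geometry is computed in physical micrometres. The
pipeline: Gaussian smoothing (σ = `surface_smoothing`, default 0.2 µm —
well below nuclear scale; the axis kernels are scaled per voxel
dimension), global Otsu threshold (a deterministic, parameter-free proxy
for an automated average threshold), per-slice hole filling, 6-connected
component labelling, then splitting of touching nuclei by a seeded
watershed on the anisotropic Euclidean distance transform (Felzenszwalb's
exact algorithm with per-axis spacing; the field border counts as
background). Seeds are distance-transform maxima kept greedily at
pairwise separation ≥ `seed_point_diameter` (default 6 µm, roughly a
small nucleus), ties broken by larger distance then scan order — output
is fully deterministic. The watershed is a priority flood (highest
distance first, then smallest index), which assigns every foreground
voxel to exactly one seed, so splitting conserves foreground volume
exactly.

### QC flags

Objects touching the xy field border are flagged `border_touching`
(z truncation is pervasive in confocal stacks and only raises a warning).
Merge resolution is diagnosed from the distance field: within each
pre-split component, maxima are grouped into "cores", where two maxima
belong to the same core if they are within 1 µm or if the distance field
along the segment joining them shows no appreciable dip (less than
max(0.5 µm, 8%) below the smaller maximum). An elongated nucleus carries
a ridge of near-equal maxima and stays one core; genuinely merged nuclei
are separated by a saddle. If a component shows more cores than the seed
separation allowed seeds — or min-volume filtering removed part of a
split — its objects are flagged `unresolved_merge`. Flagged objects stay
in the label map but are excluded from population statistics, mirroring
the practice of discarding nuclei that cannot be segmented confidently.
The flag is conservative by design: a nearly concentric pair whose union
is indistinguishable from a single ellipsoid cannot be detected from the
image alone.

Volume is voxel count × voxel volume. On analytic spheres at the
reference sampling the relative error is below 5% from r = 2 µm and
falls monotonically with radius.

### Circularity

Circularity is $4\pi \cdot \mathrm{area}/\mathrm{perimeter}^2$: 1 for a
disc, π/4 ≈ 0.785 for a square. Perimeter estimation decides everything
here, and common estimators fail one canonical shape or another:
pixel-edge counting inflates a disc's perimeter by ~27% (circularity
0.62), and the 4-direction Crofton estimator, unbiased for smooth convex
shapes, underestimates a square's perimeter (circularity 0.88). The
package instead measures the length of the marching-squares boundary
polygon (base R `contourLines` at level 0.5) smoothed by a circular
moving average over ~1% of its vertices. The smoothing removes the
staircase length excess for smooth shapes while barely touching
polygonal outlines: measured circularities are 0.993 for a 50 px disc,
0.801 for a square and 0.839 for a 2:1 ellipse (analytic 0.841), all
within 0.02 of the analytic values, scale-invariant within 0.02 under
2× upsampling, and correctly ordered (disc > square > 3:1 ellipse).
Components below 9 px are rejected — no window makes the estimate
reliable there. Values are reported unclipped.

Group comparisons use a two-tailed unpaired Student's t-test (equal
variances), the conventional reading of "unpaired t-test" in this
literature; at the effect sizes involved the Welch variant gives the same
conclusions.

## FRAP double normalization

`I_t = (ROI1 − ROI3)/(ROI2 − ROI3)` removes background and — because the
unbleached reference nucleus fades at the same per-frame rate as the
bleached one — cancels acquisition photobleaching exactly (verified to
1e−6 on generated traces with 2%/frame fading). The second stage
`I = (I_t − I_4)/(I_ave − I_4)` anchors the curve: `I` is exactly 0 at
the first post-bleach frame and its pre-bleach mean is exactly 1.
Pre-bleach frames are reported through the same transform rather than
pinned to 1, precisely so those anchors are testable. `I_ave` averages
the `n_prebleach` frames (default 3). A series where `I_ave ≤ I_4`
(no detectable bleach) is rejected.

Summary statistics come from a single-exponential fit
$I(t') = m(1 - e^{-t'/\tau})$ over post-bleach frames, with $t'$ zeroed
at the first post-bleach timestamp (frames during the bleach interval do
not exist; timestamps are always read from the data, never assumed).
The single exponential is the simplest model for one bleached
compartment with one mobile pool; it is a comparison statistic, not a
reaction–diffusion model, and no diffusion coefficient is derived from
it. Fits use Levenberg–Marquardt (`minpack.lm`) with plateau/half-rise
starting values; a plateau below 0.01 short-circuits to an immobile
result (m = 0) rather than fitting an undefined τ; mobile fractions
above 1 are flagged and above 1.2 rejected.

## Gel densitometry

The normalized lane `I = (Iₙ − I_b)/I_total`, `I_total = Σ(Iₙ − I_b)`, is
a unit-mass distribution over migration position, invariant to exposure.
Choices: the background `I_b` is the per-row mean of two flanking
inter-lane strips (a rolling-ball or constant background is available);
negative net values are clipped to zero before summation with the
clipped fraction reported. Clipping leaves a small positive noise
pedestal in signal-free stretches, so *band* quantification
(`band_weights()`) integrates each detected band between its flanking
valleys above a linear baseline — standard peak-area-above-baseline
densitometry — which removes the pedestal and recovers a 70/30 mixture
within 3% at the default gel SNR.

Ladder bands are detected as local maxima with prominence ≥ 5% of the
profile maximum (deterministic, ties by position); the migration → size
map is piecewise-linear interpolation of log₁₀(size) vs position — an
empirical mobility model, not a physical one — and is defined only
within the ladder span (no extrapolation; out-of-span queries are NA and
a warning fires when > 20% of lane mass lies outside). Re-binning onto a
log-size grid transports mass, so totals are conserved exactly; the
reported density divides by bin width in log₁₀ units, the
Jacobian-corrected quantity to plot. The accessibility score is the mass
fraction below 500 bp (smaller fragments at matched dose = more
accessible chromatin); the threshold is a reporting choice, and the
score difference's *sign* is stable across noise seeds for well-separated
digestion states.

## Synthetic ground truth

The generators are pure functions of (parameters, seed) — identical
inputs give identical outputs, and the caller's RNG stream is restored.

* **Nuclei stacks**: volumes are lognormal, moment-matched to the
  requested mean/SD (positivity with only two published moments);
  shapes are randomly oriented prolate ellipsoids with aspect ratio
  uniform on [1, 1.6]; placement is rejection sampling with a controlled
  fraction (default 5%) of deliberately touching pairs. The PSF is an
  anisotropic Gaussian (default σ 0.2 µm lateral, 2× axial) — an
  approximation adequate for volumetry-error testing, not a physical
  optics model. Noise is Poisson-Gaussian at the stated SNR (default
  10). A single field cannot physically hold 60 nuclei at 0.1 µm
  sampling, so `recover_volumes()` splits a population across several
  auto-sized stacks (default 10 nuclei per stack, ~400–600 px fields) —
  problem sizes chosen so a six-group recovery study runs in minutes on
  one CPU. Real nuclei are irregular, not ellipsoidal; passing recovery
  tests therefore demonstrates correctness of the measurement chain, not
  robustness to arbitrary nuclear shapes.
* **FRET scenes**: perinuclear rings with per-cell donor/acceptor
  amplitude variation; `F = xD + yA + se·A` inside rings; gradient and
  inter-channel shift applied after composition; matching donor-only and
  acceptor-only calibration scenes; a guaranteed cell-free edge strip is
  exported as the background region.
* **FRAP traces**: the bleached-ROI model
  `base·decay(t)·[1 − depth·(1 − m(1 − e^{−t'/τ}))]` with the reference
  ROI sharing `decay(t)`, so the double normalization recovers
  `m(1 − e^{−t'/τ})` for any bleach depth and acquisition fading — the
  cancellation is by construction, which is exactly what makes it a
  sharp test. Default schedule: 3 pre-bleach frames, a 20 s bleach gap,
  then 10 frames at 0.78 s and 30 at 2 s.
* **Gels**: band centres follow a fixed log-linear mobility law over
  [50, 20000] bp, Gaussian band spread (default 5 px), intensity
  proportional to mixture weight, plus offset and Gaussian noise
  (default peak SNR 30).

## Known limitations

* The FRET index is a relative, stoichiometry-dependent quantity;
  cross-sample comparisons assume similar sensor expression.
* Calibration slopes retain O(0.01) attenuation at SNR ≤ 10 despite the
  errors-in-variables correction, because the noise-variance estimate is
  itself noisy.
* The merge flag cannot detect near-concentric fusions, and the border
  flag only covers xy clipping; population means can shift slightly when
  exclusions correlate with size.
* The mobility law, PSF and ellipsoidal nuclei are deliberately simple
  stand-ins; none of the pipelines has been tuned to vendor-specific
  artefacts (no LIF/ND2/CZI support, no deconvolution).
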