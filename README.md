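# nucleomech

Quantification pipelines for studying how actomyosin activity mechanically
compresses the nucleus and condenses chromatin. When cytoplasmic F-actin
engages the nuclear envelope through the LINC complex, the nucleus shrinks,
chromatin becomes less accessible, and histone dynamics slow down. Each of
these phenotypes has a quantitative microscopy or gel readout, and this
package implements all four as tested, reusable R pipelines:

1. **Sensitized-emission FRET** at the nuclear envelope (Nesprin tension
   sensor vs headless control). Per pixel,

   `FRET index = (F − x·D − y·A) / A`

   where `D`, `F`, `A` are the donor, FRET and acceptor channels after a
   correction cascade (background subtraction, illumination-gradient
   correction, inter-channel pixel-shift registration, 3×3 smoothing),
   `x` is the donor leakage and `y` the acceptor cross-excitation, each
   calibrated as the pixel-wise regression slope of the FRET channel on
   the donor (donor-only sample) or acceptor (acceptor-only sample)
   channel. The index is sensitized emission normalized by acceptor
   intensity, not FRET efficiency.

2. **3D nuclear volumetry and 2D circularity** from DAPI confocal z-stacks
   with anisotropic voxels (0.25 µm z-steps vs 0.1 µm in plane). Stacks
   are thresholded globally (Otsu), touching nuclei are split by a seeded
   watershed on the Euclidean distance transform computed in physical
   micrometres, unsplittable or border-clipped objects are flagged and
   excluded, and volume is voxel count × voxel volume. Circularity is
   `4π·area/perimeter²` with the perimeter taken from a smoothed
   marching-squares boundary polygon.

3. **FRAP double normalization** for histone H1⁰ mobility. Per frame,
   `I_t = (ROI1 − ROI3)/(ROI2 − ROI3)` corrects the bleached-spot trace
   for background and acquisition photobleaching via an unbleached
   reference nucleus, then `I = (I_t − I_4)/(I_ave − I_4)` rescales by the
   pre-bleach average `I_ave` and first post-bleach value `I_4`, so `I` is
   exactly 0 at the bleach and averages exactly 1 before it. A
   single-exponential fit `I(t) = m·(1 − e^(−t/τ))` summarizes each curve
   as a mobile fraction and half-time `τ·ln 2`.

4. **DNase I gel densitometry** as a chromatin-accessibility readout.
   Lane profiles are normalized as `I = (Iₙ − I_b)/I_total` with
   `I_total = Σ(Iₙ − I_b)`, migration is calibrated to fragment size with
   a ladder (piecewise-linear in log size), and lanes are compared by the
   mass fraction of small fragments: at a matched DNase dose, more
   accessible chromatin yields smaller fragments.

Because the raw microscopy and gel data behind these procedures are not
publicly deposited, the package ships a first-class synthetic-data module
(`make_nuclei_scene()`, `make_fret_scene()`, `make_frap_traces()`,
`make_gel()`) that generates every input with known ground truth, and the
test suite validates each pipeline by parameter recovery.

## Worked example

```r
library(nucleomech)

# FRAP: simulate a bleach-recovery experiment and fit it
g   <- make_frap_traces(m = 0.8, tau_s = 10, bleach_depth = 0.6,
                        noise_sd = 0.02, seed = 42)
fit <- recovery_stats(normalize_frap(g$series))
fit
#> <frap_fit> single-exponential recovery
#>   mobile fraction m : 0.7567
#>   half-time t1/2    : 6.960 s (tau = 10.041 s)
```

At 2% measurement noise a single trace recovers the true mobile fraction
(0.8) and half-time (10·ln 2 ≈ 6.93 s) to within a few percent.

```r
# nuclear volumes: synthetic nuclei at the small-nucleus condition
res <- recover_volumes(n = 12, volume_mean = 207, volume_sd = 58,
                       nuclei_per_scene = 6, seed = 31)
round(c(mean_estimate = res$mean_estimate,
        mean_truth = mean(res$truth_matched)), 1)
#> mean_estimate    mean_truth
#>         207.7         206.2
```

The segmented volumes track the generated ground truth to well under 5%.

```r
# FRET: calibrate bleed-through, then recover sensitized emission
sc  <- make_fret_scene(24, true_se_fraction = 0.15, x = 0.25, y = 0.10,
                       snr = 20, seed = 301)
bg  <- background_spec("region", region = sc$truth$background_region)
cal <- combine_calibration(
  fit_bleedthrough(prepare_fret(sc$donor_only, background = bg)),
  fit_crossexcitation(prepare_fret(sc$acceptor_only, background = bg)))
cal
#> <bleedthrough_calibration>
#>   donor leakage x       : 0.2497
#>   cross-excitation y    : 0.1016
#>   pixels used           : 21961 (r2 = 0.999)

pc <- mean_fret_per_cell(
  fret_index_map(prepare_fret(sc$sensor, background = bg), cal), sc$masks)
mean(pc$mean_index)
#> [1] 0.1473
```

The calibrated slopes land on the true `x = 0.25`, `y = 0.10`, and the
mean per-cell index recovers the true sensitized-emission fraction 0.15.

A thin command-line wrapper is provided in `inst/cli/nucleomech.R`
(`volume`, `frap`, `gel`, `sim` subcommands) for running the pipelines on
TIFF/CSV inputs from a shell.

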