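# lsraman

Processing pipeline for **hyperspectral line-scanning light-sheet Raman
microscopy** — the single-objective oblique-plane geometry in which a 660 nm
beam illuminates one tilted line in the sample and a grating disperses the
scattered light so that each camera frame records space along the line on
one axis (x′) and the Raman spectrum of every point on the other (y). The
package is for microscopists and image analysts working with such
instruments who need to turn raw frame stacks into calibrated spectra,
biochemical band maps, classified microplastic images, and phase-resolved
videos of periodic motion — and for method developers who want every stage
testable at desk scale against a simulator with known ground truth.

## What it implements

* **Spectral-axis calibration** — the affine pixel-to-wavelength model
  λ(x′, y, g) = λ_ref + D·(y − y_ref − p·(x′ − x_ref)) + G·(g − g_ref),
  with exactly two free parameters (the tilt-shift prefactor p and the
  grating-tilt offset in λ_ref): coarse calibration against the longpass
  filter edge, fine calibration by matching PS/PMMA Raman peaks, and
  recalibration of a drifted axis against a standard spectrum using the
  collagen (~1670 cm⁻¹) and water (~3240 cm⁻¹) anchors. Standard
  conversions Δν̃ = 10⁷(1/λ_exc − 1/λ) and bandwidth Δν̃ = 10⁷·Δλ/λ².
* **Preprocessing** — background subtraction, camera-tilt rotation,
  cropping, 10-pixel x′ binning, illumination-gradient compensation along
  the beam, and 38° oblique-plane deskew into orthogonal volumes.
* **Spectral analysis** — per-column spectrum extraction onto a uniform
  20 cm⁻¹ grid, Richardson–Lucy deconvolution of the 18 µm beam profile,
  asymmetric-least-squares autofluorescence subtraction, band-intensity
  maps (e.g. carotenoids 1160 ± 40, collagen 1640 ± 40, lipids
  2880 ± 40 cm⁻¹), false-colour composition, and ROI time series.
* **Microplastic classification** — rule-based training-spectrum selection
  (≥3/4/3 fingerprint peaks and ≥2/1/1 CH-stretch peaks for PS/PMMA/PA6), a
  one-convolution-layer CNN (64 filters, kernel 3) over five classes on
  141-bin features (detrend → centre → max-normalise → crop 560–3360 cm⁻¹),
  and score-weighted RGB rendering (PS red, PMMA green, PA6 blue,
  agarose/dish gray).
* **Retrospective cardiac gating** — kymographs from the middle 800 frames
  of each 35 s y-step dwell, temporal-SD column filtering (> 80% of mean),
  normalised cross-correlation of 11-frame reference-video patches at
  near-zero horizontal lag, averaging of the top-40 matching frames per
  (phase, y) cell (noise ↓ ≈ √40 ≈ 6), and assembly into a phase-resolved
  hyperspectral cycle.
* **Synthetic instrument** — compound spectral library, camera forward
  model (dispersion mapping, beam blur, camera tilt, Poisson + read noise,
  background), microplastic scenes, and a two-chamber beating-heart phantom
  (~14-frame period at 28.6 fps) scanned line-by-line with an
  unsynchronised stage — all with exported ground truth.

## Worked example

Simulate a beating-heart acquisition, reconstruct the cycle, and map the
water band:

```r
library(lsraman)

scene <- phantom_scene(n_y = 8, nx = 24)           # ~14-frame beat period
acq   <- simulate_heart_acquisition(scene, seconds_per_step = 35,
                                    n_y_px = 128, seed = 1)
n_frames(acq$steps[[1]])
#> [1] 1000

rec <- reconstruct_cycle(acq, phases = 1:17)       # one full cycle + wrap
rec$kymographs[[4]]
#> <kymograph 800 frames x 24 columns (15 retained), range -40..3400 cm^-1>

water <- band_intensity_map(as_tibble(rec$cycle),
                            band_def("water", window = c(3100, 3300)))
dplyr::filter(water, phase == 1) |> head(3)
#> # A tibble: 3 x 5
#>   phase     y x_prime band  intensity
#>   <int> <int>   <dbl> <chr>     <dbl>
#> 1     1     1       0 water      15.6
#> 2     1     1       1 water      20.0
#> 3     1     1       2 water      20.2
```

The kymograph line shows that 15 of 24 columns carry significant temporal
variation (the moving chambers); the water-band map values are per-frame
mean counts in the 3100–3300 cm⁻¹ window, highest inside the water-filled
chambers and oscillating with the reconstructed phase. Plot helpers
(`autoplot()` on kymographs/classifiers, `plot_band_map()`,
`plot_false_color()`, `plot_spectra()`) give ggplot views of each result.

Classify microplastics on synthetic spectra:

```r
lib <- simulate_training_library(n_per_class = 300, seed = 1)
cnn <- train_classifier(lib, classifier_config(epochs = 60, seed = 1))
glance(cnn)
#> # A tibble: 1 x 5
#>   accuracy n_train n_test epochs final_loss
#>      <dbl>   <int>  <int>  <dbl>      <dbl>
#> 1        1    1200    300     60   0.000139
```

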