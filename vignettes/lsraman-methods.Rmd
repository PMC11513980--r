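---
title: "Methods: processing hyperspectral line-scanning light-sheet Raman data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: processing hyperspectral line-scanning light-sheet Raman data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsraman)
```

## The instrument model

`lsraman` processes data from a single-objective oblique-plane light-sheet
microscope operated as a line-scanning Raman imaging spectrometer. A weakly
focused 660 nm beam illuminates a line in the sample, tilted at 38° to the
coverslip; a grating (300 lp/mm, m = −1 order) disperses the light scattered
from that line so that the camera records space along the line on one axis
(x′) and, mixed on the other axis (y), the optical spectrum of every point.
One frame therefore holds up to one Raman spectrum per column. Scanning the
sample in y and stacking lines yields hyperspectral maps; inserting a plain
filter cube instead of the grating gives a conventional 2D imaging mode used
for reference videos.

Working in wavenumbers, a wavelength $\lambda$ (nm) maps to a Raman shift
$\Delta\tilde\nu = 10^7(1/\lambda_{exc} - 1/\lambda)$ cm⁻¹. Because this
mapping is nonlinear, a fixed spectral bandwidth in nm shrinks in cm⁻¹
towards longer Stokes wavelengths: the same 6 nm resolution is ≈110 cm⁻¹ at
1600 cm⁻¹ but ≈88 cm⁻¹ at 3000 cm⁻¹ (`fwhm_nm_to_cm1()`). The beam width —
10 µm FWHM at the field centre, up to 20 µm at the edges — sets both the
vertical spatial resolution and the spectral resolution, which is why
deconvolving the beam profile (below) sharpens spectra.

## Spectral-axis calibration

The pixel-to-wavelength map is affine in all three of its inputs:

$$\lambda(x', y, g) = \lambda_{ref} + D\,\big(y - y_{ref} - p\,(x' - x_{ref})\big) + G\,(g - g_{ref})$$

with dispersion $D$ (nm per y pixel; positive by convention — larger y index
means longer wavelength in the m = −1 order), galvo gain $G$, and a
tilt-shift prefactor $p$ that captures the vertical image shift proportional
to x′ caused by the grating tilt. Only two quantities are genuinely unknown
after the grating constant is fixed: $p$, and the grating-tilt-dependent
offset which we fold into $\lambda_{ref}$. The calibration procedures
therefore fit exactly those two, treating $D$ as derivable-or-configurable.

* **Coarse** (`coarse_calibrate()`): a broadband emitter imaged through the
  detection longpass filter shows a dark-to-bright step along y. Each
  column's edge is located at the first crossing of 50% of the column's
  plateau level (the procedure is specified only as matching the transmission edge; 50% with linear sub-pixel interpolation is the
  conventional choice), corrected for the x′ tilt shift, averaged, and
  pinned to the 664 nm cutoff.
* **Fine** (`fine_calibrate()`): frames of isolated PS and PMMA particles
  are reduced to per-column peak positions (boxcar smoothing of width 3
  samples, local maxima, parabolic sub-pixel refinement); detected peaks are
  matched to reference shifts through the starting model, and because the
  model is affine, refitting $(p, \delta\lambda_{ref})$ is an ordinary
  linear least-squares problem in pixel space. At least three matched peaks
  spanning at least two distinct x′ columns are required, otherwise the fit
  is declared under-determined.
* **Recalibration** (`recalibrate_from_standard()`): reinserting the grating
  cube perturbs the axis slightly; rather than repeating the full
  procedure, the collagen (≈1670 cm⁻¹) and water (≈3240 cm⁻¹) peaks of a
  fresh muscle spectrum are aligned to a stored standard spectrum by an
  affine axis update. Anchor windows are 1670 ± 60 and 3240 ± 120 cm⁻¹ —
  wide enough to tolerate several-pixel drifts, narrow enough not to capture
  neighbouring bands.

Coordinates are 0-based pixel centres throughout; shift grids are uniform
with a 20 cm⁻¹ default step, the resolution at which measured images were
converted to spectra.

## The synthetic instrument

Real acquisitions from this instrument are large and live in external
archives, so the package carries a full forward model
(`render_hyperspectral_frame()`) that generates every input the pipeline
needs with known ground truth. Compound spectra are sums of Gaussian peaks
on a smooth autofluorescence bump (`compound_library()`); Gaussians rather
than Voigt profiles are entirely adequate at an 88–200 cm⁻¹ instrumental
resolution. The camera model places each column's ideal spectrum on the y
axis through the inverse calibration map, convolves along y with the beam
profile, scales by exposure, rotates by a small camera tilt (0.5° by
default — the real tilt magnitude is not documented, so we inject a
sub-degree value to exercise the compensation step), adds a background
frame, and applies Poisson shot noise plus Gaussian read noise. Beam blur is
applied along y only: the 650 nm x′ resolution is far below any simulated
pixel pitch. When an emitter is narrower than the beam, the effective line
width is the product of the two Gaussian profiles, so point-like particles
show sharper apparent spectra than extended material — a real and somewhat
counterintuitive property of this geometry.

The beating-heart phantom (`phantom_scene()`) is a two-chamber "heart":
ventricle- and atrium-like disks whose radii pulse with a ~14-frame period
at 28.6 fps, the atrium leading by a quarter cycle, with water inside the
chambers, a lipid/protein/collagen wall, and a protein/agarose background.
Two choices matter. First, the radius waveform is asymmetric (fast
contraction, slower refill, $\propto \sin\theta + 0.5\sin 2\theta$): a pure
sinusoid passes through every radius twice per cycle, making phases pairwise
ambiguous in a way real sequentially-contracting hearts are not. Second,
compartment edges are sigmoidal (softness 0.6 px), so sub-pixel radius
changes still produce smooth intensity changes on the coarse phantom grid.
`simulate_heart_acquisition()` then emulates the acquisition protocol: the
stage dwells 35 s per 5 µm y step while frames stream at 35 ms exposure
(≈1000 frames per step), the camera and stage are deliberately
unsynchronised (a random 0–60 frame offset per step acquires at the stale y
position), and a 100-frame conventional reference video is rendered at the
same frame rate.

What the generator does **not** emulate: sample scattering and depth-dependent
aberrations, photobleaching (off by default), fluorescence saturation,
cosmic rays, stage drift within a dwell, and beam-width growth towards the
field edges (the render uses the centre width). Tests passing on the phantom
therefore demonstrate the correctness of the algorithms under the stated
noise model, not robustness to every pathology of real tissue data.

## Preprocessing

Fixed order: background subtraction (clamped at zero — Raman intensities are
nonnegative; a signed variant exists for diagnostics), bilinear rotation
about the frame centre to undo the camera tilt, cropping, then optional
column binning (default 10, matching the published maps) and illumination-
gradient compensation. The gradient along the propagation direction x′ is
compensated by `exp(strength · c/(C−1))` by default — attenuation through a
sample is Beer–Lambert-like, and `fit_gradient_strength()` recovers the
constant from the log column means of a homogeneous region; a linear mode is
available. `deskew_volume()` converts an oblique plane stack to an
orthogonal volume by shearing plane $i$ by $i\,s\cos\alpha/p$ pixels and
assigning depth spacing $s\sin\alpha$ (scan step $s$, pixel size $p$,
tilt $\alpha$ = 38°); linear redistribution of intensity keeps total flux
conserved to well under 1%.

## From frames to biochemical maps

`extract_spectra()` resamples each calibrated column onto the uniform shift
grid by linear interpolation (bins outside coverage are zero-filled and
flagged). `deconvolve_beam()` removes the beam profile with Richardson–Lucy
iterations — the classical nonnegativity-preserving deconvolution for
Poisson data — using an 18 µm FWHM Gaussian kernel converted to cm⁻¹ via the
dispersion. Ten iterations with an early stop at relative change $<10^{-4}$
is the default; RL is stopped early deliberately, since late iterations
amplify noise before they sharpen further. The convolution is
edge-renormalised so flux is conserved within 1%.

Autofluorescence is estimated per spectrum by asymmetric least squares
(Eilers-style: smoothness penalty $\lambda$ on second differences, asymmetry
$p$ down-weighting points above the baseline) and subtracted;
`intensity + baseline` always reconstructs the input exactly. The reference
procedure for this subtraction is not publicly specified in detail, so the
estimator is isolated behind `subtract_fluorescence(method = )` and can be
swapped (a reweighted polynomial fit ships as the alternative). Defaults
$\lambda = 10^3$, $p = 0.01$ were fixed by requiring, on constructed
decompositions at the 20 cm⁻¹ grid, that a peak-free smooth curve is
absorbed into the baseline (residual RMS < 2%) while 90–120 cm⁻¹ peaks
retain their area within 10%; $\lambda$ scales with the fourth power of bin
density if the grid changes.

Band maps average the (optionally baseline-subtracted) intensity over
closed windows — the published "peak ± 40 cm⁻¹" windows for carotenoids
(1160), collagen (1640) and lipids (2880), and the explicit heart-video
channels: lipids/proteins 2800–2900, water 3100–3300, autofluorescence
1100–1200 cm⁻¹. Following the published channel definitions, the
autofluorescence channel is computed *without* baseline subtraction and the
two Raman channels *with* it. False-colour composition normalises each
channel to its maximum over the full series, so temporal changes remain
comparable between frames; ROI traces are normalised per band to peak 1.

## Microplastic classification

Training spectra for PS/PMMA/PA6 are selected by peak counting: smooth with
a 5-bin moving average, find local maxima above a prominence floor of 3× the
robust noise SD (the reference protocol names smoothing and peak finding but
no threshold; 3σ is the standard choice), and accept a spectrum iff it shows
at least 3/4/3 peaks in the 700–1850 cm⁻¹ fingerprint regime and at least
2/1/1 peaks in the 2700–3200 cm⁻¹ stretch regime for PS/PMMA/PA6
respectively. Acceptance is monotone in peaks by construction.

Features are built exactly in the published order: remove the linear trend,
subtract the mean, normalise to the maximum, and only then crop to
560–3360 cm⁻¹, which on the 20 cm⁻¹ grid gives 141 bins. The classifier is
a one-convolution-layer CNN — 64 filters of kernel size 3 — implemented
directly in vectorised R (no deep-learning backend is required for a network
this small). The layer glue is unspecified beyond the conv layer, so we
follow the common template for 1D Raman CNNs: ReLU, max pooling of width 2,
flatten, dense softmax over the five classes (PS, PMMA, PA6, agarose, dish),
Adam at $10^{-3}$, batch 64, cross-entropy loss, 80/20 split. One glue
choice deserves its rationale: *global* max pooling was rejected because it
discards peak-position information entirely — a kernel-3 filter sees only
local line shape, and polymers are distinguished mainly by where their peaks
sit, not by local shape; width-2 pooling keeps position at ~40 cm⁻¹
granularity. The split is stratified by class (the reference protocol says
only "randomly shuffled"; stratification prevents degenerate splits at small
n and is the conservative reading). Score-weighted rendering maps the five
softmax scores onto RGB with PS→red, PMMA→green, PA6→blue and the
agarose+dish score divided by 3 added to all three channels, so background
renders gray, all weighted by total scattering intensity.

## Retrospective cardiac gating

For each stage y position, only the middle 800 of the ~1000 frames are
trusted (the unsynchronised stage may still be moving at the ends); each
frame is summed over −40 to 3400 cm⁻¹ to one spatial row, and the rows stack
into a kymograph. Columns whose temporal SD does not strictly exceed 80% of
the mean SD carry no motion information and are dropped. For every cardiac
time point, an 11-frame window of the reference video — read as centred on
the time point (5 before + the frame + 5 after), because the description
calls the window "slightly shorter than a full cycle" and a 22-frame reading
would exceed the ~14-frame cycle — supplies the y row of interest, forming a
patch that is cross-correlated against the kymograph. Correlation is
normalised (zero mean, unit variance) so scores are comparable across
phases; genuine matches must sit within ±2 columns of zero horizontal lag.
The 40 highest-scoring local maxima along the time lag identify frames at
the same beat phase; ties break by score, then by smaller |lag|. Those
frames are combined by *mean* rather than sum — a deliberate constant-factor
deviation so output stays in per-frame count units (recorded in
provenance) — reducing shot and read noise by ≈√40 ≈ 6. Averaged rows over
all (phase, y) cells assemble into a phase-resolved hyperspectral cycle
ready for the band-map machinery above; missing cells are zero-filled and
masked.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale versions of the study
conditions, chosen as the package's own reference sizes: the phantom
acquisition covers 8 y steps × 24 columns × 128 spectral rows with the full
1000 frames per step and a 100-frame reference video; the classifier's
reference run uses 1000 spectra per class for 200 epochs (the network
converges well before that, consistent with the published convergence after
200 epochs). Calibration recovery is validated over 20 random ground-truth
models. Degenerate inputs fail loudly rather than silently: constant images
have no transmission edge, single-column peak sets cannot fix the tilt
prefactor, all-zero spectra have no defined normalisation, and a
variation-free kymograph is a degenerate-signal error.

## Limitations

The simulator's noise is pixel-independent; correlated read patterns and
structured backgrounds are only representable through the fixed background
frame. The reconstruction assumes the motion is strictly periodic over each
35 s dwell — slow rhythm drift between steps is tolerated (each step is
correlated against the video independently) but drift *within* a step
blurs the synchronised average. Fluorescence subtraction quality is
estimator-dependent near the grid edges, and the CNN's accuracy figures are
for synthetic libraries whose class spread is controlled by the generator's
jitter parameters, not for any particular real instrument.
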