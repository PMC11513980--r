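# broad-peaked compound so camera-pixel sampling resolves every feature
broad_lib <- function() {
  list(test = compound_def("test", tibble::tibble(
    center = c(800, 1450, 2900), fwhm = c(150, 150, 180),
    amplitude = c(1, 0.7, 0.9)), baseline_amplitude = 0.2))
}

dense_model <- function() {
  calibration_model(lambda_ref = 656, dispersion = 0.85,
                    tilt_shift_prefactor = 0.02)
}

test_that("extract_spectra inverts the forward model on noiseless frames", {
  model <- dense_model()
  cfg <- instrument_config(beam_fwhm_center = 0.001, beam_fwhm_edge = 0.002)
  conc <- matrix(1, 1, 16, dimnames = list("test", NULL))
  fr <- render_hyperspectral_frame(conc, model, cfg, noise = NULL,
                                   library = broad_lib(), n_y = 256)
  grid <- seq(0, 3400, by = 20)
  sp <- extract_spectra(fr, model, grid)
  one <- dplyr::filter(sp, x_prime == 5)
  ref <- compound_intensity(broad_lib()$test, one$shift_cm1) *
    2000 * cfg$frame_exposure
  expect_lt(max(abs(one$intensity - ref)) / max(ref), 0.02)

  # zero frame -> zero spectra
  z <- extract_spectra(matrix(0, 64, 4), test_model(), seq(0, 2000, 20))
  expect_true(all(z$intensity == 0))

  # same material at different x': identical spectra after x'-shift correction
  a <- dplyr::filter(sp, x_prime == 1)$intensity
  b <- dplyr::filter(sp, x_prime == 14)$intensity
  expect_gt(cor(a, b), 0.999)

  # grid beyond coverage warns and masks
  expect_warning(out <- extract_spectra(fr, model, seq(-500, 3400, 20)),
                 "coverage")
  expect_true(any(!out$covered))
  expect_true(all(out$intensity[!out$covered] == 0))
})

test_that("Richardson-Lucy narrows blurred peaks, conserves flux, keeps positivity", {
  grid <- seq(0, 3400, by = 20)
  true_fwhm <- 90
  peak <- exp(-4 * log(2) * (grid - 1600)^2 / true_fwhm^2)
  kernel_fwhm <- 120
  sigma <- kernel_fwhm / (2 * sqrt(2 * log(2)))
  blurred_fwhm <- sqrt(true_fwhm^2 + kernel_fwhm^2)
  blurred <- exp(-4 * log(2) * (grid - 1600)^2 / blurred_fwhm^2) *
    true_fwhm / blurred_fwhm
  sp <- tibble::tibble(shift_cm1 = grid, intensity = blurred)

  dec <- deconvolve_beam(sp, kernel_fwhm_cm1 = kernel_fwhm, iterations = 30)
  w_in <- measure_fwhm(grid, blurred)
  w_out <- measure_fwhm(grid, dec$intensity)
  expect_lt(w_out, w_in)
  expect_lt(w_out, 1.2 * true_fwhm)
  expect_true(all(dec$intensity >= 0))
  expect_equal(sum(dec$intensity), sum(blurred), tolerance = 0.01)

  # delta kernel -> identity
  ident <- deconvolve_beam(sp, kernel_fwhm_cm1 = 1e-9)
  expect_equal(ident$intensity, blurred)

  # nonnegativity on random nonnegative input
  set.seed(2)
  rnd <- pmax(rnorm(length(grid), 1, 0.5), 0)
  out <- deconvolve_beam(rnd, kernel_fwhm_cm1 = 100, step_cm1 = 20)
  expect_true(all(out >= 0))
  expect_error(deconvolve_beam(sp, kernel_fwhm_cm1 = -3), "nonnegative")
})

test_that("the 18 um beam maps to the printed cm^-1 resolution scale", {
  cfg <- instrument_config()            # 6 um/px -> 3 px -> 5.1 nm at D=1.7
  model <- test_model()
  w <- beam_fwhm_cm1(cfg, model, at_shift = 3000)
  # 6-11 nm corresponds to 88-160 cm^-1 at 3000 cm^-1: our 18 um sits near
  # the lower edge of that envelope
  expect_gt(w, 60); expect_lt(w, 160)
})

test_that("fluorescence subtraction is exact and recovers known decompositions", {
  grid <- seq(0, 3400, by = 20)
  # smooth, peak-free input: baseline captures nearly everything
  smooth <- 100 * exp(-((grid - 1500) / 1800)^2)
  dec <- subtract_fluorescence(tibble::tibble(shift_cm1 = grid,
                                              intensity = smooth))
  expect_equal(dec$intensity + dec$baseline, smooth, tolerance = 1e-12)
  expect_lt(sqrt(mean(dec$intensity^2)), 0.02 * max(smooth))

  # zero input
  z <- subtract_fluorescence(tibble::tibble(shift_cm1 = grid, intensity = grid * 0))
  expect_true(all(z$intensity == 0) && all(z$baseline == 0))

  # known peaks on a known polynomial baseline: peak areas within 10%
  base <- 50 + 0.01 * grid - 2e-6 * grid^2
  peaks <- 40 * exp(-4 * log(2) * (grid - 1160)^2 / 90^2) +
    60 * exp(-4 * log(2) * (grid - 2900)^2 / 120^2)
  dec2 <- subtract_fluorescence(tibble::tibble(shift_cm1 = grid,
                                               intensity = base + peaks))
  for (win in list(c(1000, 1320), c(2700, 3100))) {
    sel <- grid >= win[1] & grid <= win[2]
    expect_equal(sum(dec2$intensity[sel]), sum(peaks[sel]), tolerance = 0.1)
  }
  # both estimators decompose exactly
  dec3 <- subtract_fluorescence(tibble::tibble(shift_cm1 = grid,
                                               intensity = base + peaks),
                                method = "poly")
  expect_equal(dec3$intensity + dec3$baseline, base + peaks, tolerance = 1e-9)
})

test_that("band maps average closed windows and stay linear", {
  grid <- seq(0, 3400, by = 20)
  px <- tidyr::expand_grid(x_prime = 0:3, shift_cm1 = grid)

  const <- dplyr::mutate(px, intensity = 7)
  m <- band_intensity_map(const, band_def("flat", 1160))
  expect_true(all(m$intensity == 7))

  # unit peak in one bin of an 80 cm^-1 window (5 bins at 20 cm^-1) -> 0.2
  spike <- dplyr::mutate(px, intensity = as.numeric(shift_cm1 == 1160))
  m2 <- band_intensity_map(spike, band_def("spike", 1160, half_width = 40))
  expect_equal(unique(m2$intensity), 1 / 5)

  # peak outside the window -> 0
  m3 <- band_intensity_map(spike, band_def("far", 2880))
  expect_true(all(m3$intensity == 0))

  # linearity: map(a S1 + b S2) = a map(S1) + b map(S2)
  s1 <- dplyr::mutate(px, intensity = sin(shift_cm1 / 300)^2)
  s2 <- dplyr::mutate(px, intensity = cos(shift_cm1 / 500)^2)
  lhs <- band_intensity_map(dplyr::mutate(s1, intensity = 2 * intensity +
                                            3 * s2$intensity),
                            band_def("b", 1640))
  rhs <- 2 * band_intensity_map(s1, band_def("b", 1640))$intensity +
    3 * band_intensity_map(s2, band_def("b", 1640))$intensity
  expect_equal(lhs$intensity, rhs)
  expect_error(band_intensity_map(const, band_def("empty", window = c(5001, 5009))),
               "no grid bins")
})

test_that("false-colour composition normalises per channel over the series", {
  base <- tidyr::expand_grid(t = 1:2, y = 1:2, x_prime = 0:2)
  r <- dplyr::mutate(base, band = "r", intensity = 4)
  g <- dplyr::mutate(base, band = "g", intensity = ifelse(t == 2, 2, 1))
  b <- dplyr::mutate(base, band = "b", intensity = 0)
  expect_warning(rgbimg <- compose_false_color(r, g, b), "all-zero")
  expect_true(all(rgbimg$r == 1))
  # channel value doubles between frames under series-max normalisation
  expect_equal(unique(rgbimg$g[rgbimg$t == 1]), 0.5)
  expect_equal(unique(rgbimg$g[rgbimg$t == 2]), 1)
  expect_true(all(rgbimg$b == 0))

  # identical maps in all channels -> gray
  gray <- compose_false_color(r, dplyr::mutate(r, band = "g"),
                              dplyr::mutate(r, band = "b"))
  expect_true(all(gray$r == gray$g & gray$g == gray$b))
})

test_that("ROI time series normalise per band and preserve monotone growth", {
  maps <- tidyr::expand_grid(t = 1:5, y = 1:4, x_prime = 0:4) |>
    dplyr::mutate(band = "carotenoids", intensity = t * (y <= 2))
  out <- roi_time_series(maps, list(x_lo = 0, x_hi = 4, y_lo = 1, y_hi = 2))
  expect_equal(out$intensity, (1:5) / 5)
  expect_true(all(diff(out$intensity) > 0))

  static <- dplyr::mutate(maps, intensity = 3)
  expect_true(all(roi_time_series(static, list(x_lo = 0, x_hi = 4, y_lo = 1,
                                               y_hi = 2))$intensity == 1))
  # one-pixel ROI equals that pixel's trajectory
  one <- roi_time_series(maps, list(x_lo = 2, x_hi = 2, y_lo = 1, y_hi = 1))
  expect_equal(one$intensity, (1:5) / 5)
  expect_error(roi_time_series(maps, list(x_lo = 90, x_hi = 99, y_lo = 1,
                                          y_hi = 1)), "empty ROI")
})

test_that("band-map linearity holds end-to-end through the simulator", {
  model <- dense_model()
  cfg <- instrument_config(beam_fwhm_center = 10, beam_fwhm_edge = 20)
  mk <- function(level) {
    conc <- matrix(level, 1, 6, dimnames = list("carotenoids", NULL))
    fr <- render_hyperspectral_frame(conc, model, cfg, noise = NULL,
                                     n_y = 256)
    extract_spectra(fr, model, seq(600, 3400, 20))
  }
  band <- band_def("carotenoids", 1160, subtract_baseline = TRUE)
  m1 <- band_intensity_map(mk(1), band)
  m2 <- band_intensity_map(mk(2), band)
  expect_equal(m2$intensity / m1$intensity, rep(2, nrow(m1)), tolerance = 0.05)
})
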