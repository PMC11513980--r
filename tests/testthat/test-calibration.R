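test_that("pixel_to_wavelength is exactly affine and honours the reference point", {
  m <- calibration_model(lambda_ref = 655, dispersion = 1.7, galvo_gain = 0.5,
                         tilt_shift_prefactor = 0.03, y_ref = 10, x_ref = 4,
                         galvo_ref = 2)
  expect_equal(pixel_to_wavelength(m, 4, 10, 2), 655)
  # brute-force evaluation of the affine form on a probe grid
  probe <- expand.grid(x = c(0, 7, 19, 31), y = c(0, 63, 127), g = c(2))
  expect_equal(pixel_to_wavelength(m, probe$x, probe$y, probe$g),
               affine_oracle(m, probe$x, probe$y, probe$g))
  # finite differences constant in every coordinate
  dy <- pixel_to_wavelength(m, 3, 21, 2) - pixel_to_wavelength(m, 3, 20, 2)
  dy2 <- pixel_to_wavelength(m, 9, 101, 2) - pixel_to_wavelength(m, 9, 100, 2)
  expect_equal(dy, dy2)
  dx <- pixel_to_wavelength(m, 6, 50, 2) - pixel_to_wavelength(m, 5, 50, 2)
  expect_equal(dx, -m$dispersion * m$tilt_shift_prefactor)
  dg <- pixel_to_wavelength(m, 6, 50, 3) - pixel_to_wavelength(m, 6, 50, 2)
  expect_equal(dg, m$galvo_gain)
  # untilted grating: wavelength independent of x'
  m0 <- calibration_model(tilt_shift_prefactor = 0)
  expect_equal(pixel_to_wavelength(m0, 0, 40), pixel_to_wavelength(m0, 99, 40))
  # wavelength_to_y inverts pixel_to_wavelength
  expect_equal(wavelength_to_y(m, pixel_to_wavelength(m, 11, 77, 2), 11, 2), 77)
})

test_that("coarse calibration recovers lambda_ref from a transmission edge", {
  truth <- calibration_model(lambda_ref = 656.8, dispersion = 1.7,
                             tilt_shift_prefactor = 0.02)
  sim <- simulate_calibration_standards(truth, seed = 11)
  start <- truth
  start$lambda_ref <- 650   # wrong by several nm
  fit <- coarse_calibrate(sim$edge_frame, 664, start)
  expect_lt(abs(fit$lambda_ref - truth$lambda_ref), abs(truth$dispersion))
  # edge exactly at the reference row maps lambda_ref to the cutoff
  ny <- 64; nx <- 8
  edge <- matrix(0, ny, nx)
  edge[(ny / 2 + 1):ny, ] <- 100   # half-max crossing at y_ref = ny/2 - 0.5
  m0 <- calibration_model(lambda_ref = 600, dispersion = 2,
                          y_ref = ny / 2 - 0.5)
  fit2 <- coarse_calibrate(edge, 664, m0)
  expect_equal(fit2$lambda_ref, 664, tolerance = 1e-6)
  # constant image has no edge
  expect_error(coarse_calibrate(matrix(5, 32, 4), 664, m0), "edge")
})

test_that("fine calibration recovers both free parameters from simulated standards", {
  truth <- calibration_model(lambda_ref = 657.3, dispersion = 1.7,
                             tilt_shift_prefactor = 0.035)
  sim <- simulate_calibration_standards(truth, seed = 3)
  start <- truth
  start$lambda_ref <- truth$lambda_ref + 1.5   # ~1 pixel of offset
  start$tilt_shift_prefactor <- 0
  fit <- fine_calibrate(sim$frames, sim$compounds, sim$reference_peaks, start)
  # peak shifts through the fitted model agree with the references
  expect_lt(attr(fit, "residual_rms_cm1"), 10)
  expect_lt(abs(fit$tilt_shift_prefactor - truth$tilt_shift_prefactor),
            0.05 * truth$tilt_shift_prefactor + 5e-3)
  # fixed point: an already-optimal model is returned unchanged (within tol)
  fit2 <- fine_calibrate(sim$frames, sim$compounds, sim$reference_peaks, fit)
  expect_equal(fit2$lambda_ref, fit$lambda_ref, tolerance = 0.2)
  expect_equal(fit2$tilt_shift_prefactor, fit$tilt_shift_prefactor,
               tolerance = 0.01)
})

test_that("fine calibration parameter recovery holds over random ground truths", {
  set.seed(42)
  errs <- replicate(20, {
    truth <- calibration_model(lambda_ref = 655 + runif(1, -2, 2),
                               dispersion = 1.7,
                               tilt_shift_prefactor = runif(1, 0.015, 0.05))
    sim <- simulate_calibration_standards(truth,
                                          seed = sample.int(1e6, 1))
    start <- truth
    start$lambda_ref <- truth$lambda_ref + runif(1, -2, 2)
    start$tilt_shift_prefactor <- 0
    fit <- fine_calibrate(sim$frames, sim$compounds, sim$reference_peaks, start)
    abs(fit$tilt_shift_prefactor - truth$tilt_shift_prefactor) /
      truth$tilt_shift_prefactor
  })
  expect_lt(median(errs), 0.05)
})

test_that("degenerate fine-calibration inputs raise under-determined errors", {
  truth <- calibration_model(lambda_ref = 656, dispersion = 1.7,
                             tilt_shift_prefactor = 0.02)
  sim <- simulate_calibration_standards(truth, emitter_columns = 12, seed = 5)
  # peaks at a single x' cannot fix the tilt prefactor
  expect_error(
    fine_calibrate(sim$frames, sim$compounds, sim$reference_peaks, truth),
    "single x'")
  # fewer than 3 matched peaks
  one_ref <- sim$reference_peaks[1, ]
  sim2 <- simulate_calibration_standards(truth, emitter_columns = c(6, 30),
                                         seed = 5)
  expect_error(
    fine_calibrate(sim2$frames[1], "PS", one_ref, truth,
                   match_tol_cm1 = 15),
    "under-determined")
})

test_that("recalibration against a standard recovers constructed axis errors", {
  grid <- seq(800, 3500, by = 20)
  base <- compound_intensity(compound_library()$collagen, grid) +
    compound_intensity(compound_library()$water, grid)
  std <- tibble::tibble(shift_cm1 = grid, intensity = base)

  # identity
  upd0 <- recalibrate_from_standard(std, std)
  expect_equal(upd0$scale, 1, tolerance = 1e-6)
  expect_equal(upd0$shift, 0, tolerance = 1e-3)

  # axis shifted +30 cm^-1 -> recovered shift -30
  shifted <- std; shifted$shift_cm1 <- shifted$shift_cm1 + 30
  upd <- recalibrate_from_standard(shifted, std)
  expect_equal(upd$scale, 1, tolerance = 1e-6)
  expect_equal(upd$shift, -30, tolerance = 0.5)
  fixed <- apply_axis_update(shifted, upd)
  expect_equal(fixed$shift_cm1, std$shift_cm1, tolerance = 0.5)

  # axis scaled 1.02x about 0 -> recovered scale 1/1.02
  scaled <- std; scaled$shift_cm1 <- scaled$shift_cm1 * 1.02
  upd2 <- recalibrate_from_standard(scaled, std)
  expect_equal(upd2$scale, 1 / 1.02, tolerance = 1e-3)

  # missing peak in an anchor band
  flat <- std; flat$intensity[std$shift_cm1 > 3000] <- 0
  expect_error(recalibrate_from_standard(flat, std), "water")
})

test_that("calibration models round-trip through YAML with provenance", {
  m <- calibration_model(lambda_ref = 656.123, dispersion = 1.7,
                         galvo_gain = 0.5, tilt_shift_prefactor = 0.0213,
                         y_ref = 3, x_ref = 1, galvo_ref = 0)
  path <- tempfile(fileext = ".yaml")
  write_calibration(m, path, provenance = list(source = "unit test"))
  back <- read_calibration(path)
  expect_equal(unclass(back)[names(unclass(m))], unclass(m),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(back, "provenance")$source, "unit test")
  # schema validation
  yaml::write_yaml(list(lambda_ref = 1), path)
  expect_error(read_calibration(path), "dispersion")
  # tidy() exposes all parameters
  td <- tidy(m)
  expect_equal(td$estimate[td$term == "tilt_shift_prefactor"], 0.0213)
})
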