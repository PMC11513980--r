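# Shared fixtures, built in code at test time.

# calibration model matching the simulator defaults
test_model <- function() default_sim_model()

test_cfg <- function() instrument_config()

# independent (brute-force) evaluation of the affine pixel -> wavelength map
affine_oracle <- function(m, x, y, g) {
  m$lambda_ref + m$dispersion * (y - m$y_ref - m$tilt_shift_prefactor * (x - m$x_ref)) +
    m$galvo_gain * (g - m$galvo_ref)
}

# uniform shift grid covering the simulated camera
test_grid <- function(step = 20) seq(0, 3400, by = step)

# single-compound uniform scene line
uniform_line <- function(compound, nx = 16, level = 1) {
  matrix(level, 1, nx, dimnames = list(compound, NULL))
}

# small noiseless frame of an extended uniform emitter
noiseless_frame <- function(compound = "PS", nx = 16, model = test_model(),
                            cfg = test_cfg(), tilt = 0, ...) {
  render_hyperspectral_frame(uniform_line(compound, nx), model, cfg,
                             noise = NULL, camera_tilt_deg = tilt, ...)
}

# memoised default beating-phantom acquisition + reconstruction, shared by
# the cardiosync property tests and the acceptance checks
.heart_cache <- new.env(parent = emptyenv())
default_heart_run <- function() {
  if (is.null(.heart_cache$run)) {
    scene <- phantom_scene(n_y = 8, nx = 24)
    acq <- simulate_heart_acquisition(scene, seconds_per_step = 35,
                                      n_y_px = 128, seed = 1)
    rec <- reconstruct_cycle(acq, phases = 1:17)
    .heart_cache$run <- list(scene = scene, acq = acq, rec = rec)
  }
  .heart_cache$run
}

# circular distance between two phases (frames)
phase_dist <- function(a, b, period) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# per-selection phase-assignment errors for a reconstruction run
heart_phase_errors <- function(run) {
  pt <- run$rec$phase_table
  truth <- run$acq$phase_table
  vphase <- run$acq$video$true_phase
  per <- run$scene$beat_period
  mapply(function(ph, st, fi) {
    tp <- vphase[ph]
    fr <- truth$true_phase[truth$step == st & truth$frame == fi]
    phase_dist(fr, tp, per)
  }, pt$phase, pt$step, pt$frame_index)
}

# Gaussian peak FWHM measured by interpolated half-maximum crossings
measure_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  left <- max(which(y[1:i] <= half))
  right <- i - 1 + min(which(y[i:length(y)] <= half))
  xl <- approx(y[c(left, left + 1)], x[c(left, left + 1)], xout = half)$y
  xr <- approx(y[c(right - 1, right)], x[c(right - 1, right)], xout = half)$y
  xr - xl
}

sidecar_path_test <- function(path) paste0(path, ".yaml")
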