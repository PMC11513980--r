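test_that("spectral integration keeps the middle 800 frames and sums in range", {
  # zero frames -> zero kymograph
  z <- frame_series(array(0, c(10, 32, 6)), exposure = 0.035)
  model <- calibration_model(lambda_ref = 656, dispersion = 1.7)
  expect_warning(kz <- spectral_integrate(z, model), "using all")
  expect_true(all(kz$values == 0))
  expect_equal(dim(kz$values), c(10, 6))

  # 1000 frames -> rows 101..900 retained
  arr <- array(0, c(1000, 8, 3))
  arr[, 1, ] <- rep(1:1000, 3)   # row 1 is in spectral range for this model
  fs <- frame_series(arr, exposure = 0.035)
  kym <- spectral_integrate(fs, model, range = c(-40, 3400))
  expect_equal(nrow(kym$values), 800)
  expect_equal(kym$frame_indices, 101:900)

  # static scene: rows equal up to noise
  sc <- phantom_scene(n_y = 3, nx = 12, pulse_fraction = 0)
  acq <- simulate_heart_acquisition(sc, n_y_steps = 1, seconds_per_step = 3.5,
                                    n_y_px = 128, video_frames = 5,
                                    desync_max_frames = 0, seed = 4,
                                    brightness = 4e5)
  ks <- suppressWarnings(spectral_integrate(acq$steps[[1]], acq$model))
  cors <- cor(t(ks$values))
  expect_gt(min(cors), 0.99)
})

test_that("column filtering matches a brute-force SD oracle", {
  mk <- function(values) {
    structure(list(values = values, frame_indices = seq_len(nrow(values)),
                   mask = rep(TRUE, ncol(values)), range = c(-40, 3400)),
              class = "kymograph")
  }
  # toy: SDs {1, 1, 4}; mean 2, threshold 1.6 -> only column 3 retained
  set.seed(1)
  base <- rnorm(50)
  base <- (base - mean(base)) / sd(base)
  toy <- cbind(base * 1, base * 1, base * 4)
  kf <- filter_columns(mk(toy), 0.8)
  expect_equal(kf$mask, c(FALSE, FALSE, TRUE))

  # brute-force oracle on random matrices, strict inequality
  for (i in 1:5) {
    vals <- matrix(rnorm(40 * 7, sd = rep(runif(7, 0.1, 3), each = 40)), 40, 7)
    expected <- apply(vals, 2, sd) > 0.8 * mean(apply(vals, 2, sd))
    expect_equal(filter_columns(mk(vals), 0.8)$mask, expected)
  }

  # constant matrix: all SDs zero, nothing strictly exceeds the threshold
  expect_error(filter_columns(mk(matrix(5, 10, 4))), "degenerate")

  # beating phantom: retained columns track the moving region
  run <- default_heart_run()
  kym <- run$rec$kymographs[[4]]
  # ground-truth motion mask: columns whose noiseless integrated line
  # intensity varies by more than 10% of the strongest column's swing
  lib <- compound_library()
  grid <- seq(-40, 3400, 20)
  weights <- vapply(names(phantom_maps(run$scene, 0)), function(cn)
    sum(compound_intensity(lib[[cn]], grid)), numeric(1))
  lines <- sapply(0:13, function(t) {
    maps <- phantom_maps(run$scene, t)
    Reduce(`+`, Map(function(m, w) m * w, maps, weights))[4, ]
  })
  rng <- apply(lines, 1, function(v) diff(range(v)))
  moving <- rng > 0.1 * max(rng)
  jaccard <- sum(kym$mask & moving) / sum(kym$mask | moving)
  expect_gte(jaccard, 0.8)
})

test_that("reference patches honour the window, wrap and geometry", {
  vid <- list(frames = array(rnorm(30 * 4 * 12), c(30, 4, 12)))
  p <- reference_patch(vid, 2, 15, window = 11)
  expect_equal(dim(p), c(11, 12))
  expect_false(attr(p, "wrapped"))
  expect_equal(attr(p, "frame_ids"), 10:20)
  expect_equal(p[1, ], vid$frames[10, 2, ])
  # window of 1 -> a single row
  p1 <- reference_patch(vid, 3, 7, window = 1)
  expect_equal(as.numeric(p1), vid$frames[7, 3, ])
  # out-of-bounds windows wrap cyclically and flag it
  pw <- reference_patch(vid, 1, 2, window = 11)
  expect_true(attr(pw, "wrapped"))
  expect_equal(attr(pw, "frame_ids"), c(27:30, 1:7))
  # default window is slightly shorter than the ~14-frame cycle
  expect_lt(11, 14)
  # patches one period apart are identical with noise off
  sc <- phantom_scene(n_y = 4, nx = 12, beat_period = 14)
  acq <- simulate_heart_acquisition(sc, n_y_steps = 1, seconds_per_step = 0.35,
                                    n_y_px = 64, video_frames = 40,
                                    video_noise_sd = 0, seed = 6)
  va <- reference_patch(acq$video, 2, 10, window = 11)
  vb <- reference_patch(acq$video, 2, 24, window = 11)
  expect_equal(unclass(va), unclass(vb), ignore_attr = TRUE, tolerance = 1e-9)
  # resize maps the video onto the scan grid
  rv <- resize_video(vid, 8, 24)
  expect_equal(dim(rv$frames), c(30, 8, 24))
})

test_that("phase correlation finds autocorrelation peaks and its own provenance", {
  run <- default_heart_run()
  kym <- run$rec$kymographs[[4]]
  # a patch cut from the kymograph itself is found at its own row
  r0 <- 300
  patch <- kym$values[r0:(r0 + 10), ]
  match <- phase_correlate(patch, kym, n_select = 5)
  expect_equal(match$row[1], r0 + 5)
  expect_equal(match$h_lag[1], 0)
  expect_equal(match$frame_index[1], kym$frame_indices[r0 + 5])
  expect_equal(match$score[1], 1, tolerance = 1e-9)
  # determinism: identical inputs give identical tables
  expect_identical(phase_correlate(patch, kym, n_select = 5),
                   phase_correlate(patch, kym, n_select = 5))
  # selections never leave the current y step's retained window
  expect_true(all(match$frame_index %in% kym$frame_indices))
})

test_that("phase assignment on the default phantom is accurate and uniform under noise", {
  run <- default_heart_run()
  err <- heart_phase_errors(run)
  expect_lte(median(err), 1)
  expect_gte(mean(err <= 1), 0.9)

  # pure-noise kymograph: selected phases are uniform over the period
  set.seed(33)
  noise_kym <- structure(list(values = matrix(rnorm(800 * 20), 800, 20),
                              frame_indices = 101:900,
                              mask = rep(TRUE, 20), range = c(-40, 3400)),
                         class = "kymograph")
  patch <- matrix(rnorm(11 * 20), 11, 20)
  m <- phase_correlate(patch, noise_kym, n_select = 40)
  phases <- m$frame_index %% 14
  counts <- tabulate(phases + 1, nbins = 14)
  p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("phase assignment degrades gracefully as read noise grows", {
  sc <- phantom_scene(n_y = 4, nx = 16)
  meds <- sapply(c(1, 3, 10), function(mult) {
    acq <- simulate_heart_acquisition(
      sc, n_y_steps = 2, seconds_per_step = 35, n_y_px = 128, seed = 21,
      noise = noise_model(read_noise_sd = 2 * mult, background = 1))
    errs <- unlist(lapply(1:2, function(j) {
      kym <- filter_columns(spectral_integrate(acq$steps[[j]], acq$model))
      vid <- resize_video(acq$video, 2, 16)
      sapply(1:14, function(tp) {
        m <- phase_correlate(reference_patch(vid, j, tp), kym, n_select = 40)
        truth <- acq$phase_table
        fr <- truth$true_phase[truth$step == j][m$frame_index]
        median(phase_dist(fr, acq$video$true_phase[tp], sc$beat_period))
      })
    }))
    median(errs)
  })
  expect_lte(meds[1], 1)
  # monotone non-worsening never guaranteed sample-by-sample; compare ends
  expect_lte(meds[1], meds[3] + 1e-9)
})

test_that("synchronized averaging reduces noise like sqrt(N)", {
  set.seed(12)
  ny <- 24; nx <- 10
  signal <- matrix(runif(ny * nx, 10, 50), ny, nx)
  arr <- array(0, c(40, ny, nx))
  for (i in 1:40) arr[i, , ] <- signal + rnorm(ny * nx, 0, 3)
  fs <- frame_series(arr, exposure = 0.035)
  # one index -> that frame
  one <- synchronized_average(fs, 7)
  expect_equal(unclass(one), arr[7, , ], ignore_attr = TRUE)
  # 40 frames -> SD down by ~sqrt(40) ~ 6.3
  avg <- synchronized_average(fs, 1:40)
  ratio <- sd(arr[1, , ] - signal) / sd(unclass(avg) - signal)
  expect_gt(ratio, 5.7); expect_lt(ratio, 7.0)
  # noise law scales as N^(-1/2) over N in {4, 16, 40} within 15%
  sds <- sapply(c(4, 16, 40), function(n)
    sd(unclass(synchronized_average(fs, 1:n)) - signal))
  expect_equal(sds[1] / sds[2], sqrt(16 / 4), tolerance = 0.15)
  expect_equal(sds[2] / sds[3], sqrt(40 / 16), tolerance = 0.15)
  # identical noiseless frames average to themselves
  arr0 <- array(rep(signal, each = 5), c(5, ny, nx))
  for (i in 1:5) arr0[i, , ] <- signal
  expect_equal(unclass(synchronized_average(frame_series(arr0, 0.035), 1:5)),
               signal, ignore_attr = TRUE)
  expect_error(synchronized_average(fs, integer()), "empty")
})

test_that("assembled cycles reproduce the phantom and wrap with the period", {
  # single y, single phase -> one-row image
  fr <- hyper_frame(matrix(1, 64, 6), exposure = 0.035)
  model <- calibration_model(lambda_ref = 656, dispersion = 1.7)
  cyc1 <- assemble_cycle(list(list(fr)), phases = 1, stage_y = 0, model,
                         grid = seq(0, 1500, 20))
  expect_equal(dim(cyc1), c(1, 1, 6, 76))
  # missing cells are zero-filled and masked
  cyc2 <- assemble_cycle(list(list(fr, NULL)), phases = 1, stage_y = c(0, 5),
                         model, grid = seq(0, 1500, 20))
  expect_true(attr(cyc2, "missing")[1, 2])
  expect_true(all(cyc2[1, 2, , ] == 0))

  # end-to-end: reconstructed band maps correlate with the phantom truth
  run <- default_heart_run()
  vphase <- run$acq$video$true_phase
  cyc <- as_tibble(run$rec$cycle)
  for (band in list(c(3100, 3300, "water"), c(2800, 2900, "lipids"))) {
    bmap <- band_intensity_map(cyc, band_def("b", window = as.numeric(band[1:2])))
    rs <- sapply(1:17, function(p) {
      m <- dplyr::filter(bmap, phase == p)
      tmap <- phantom_maps(run$scene, vphase[p] - run$scene$beat_phase0)[[band[3]]]
      est <- matrix(0, run$scene$n_y, run$scene$nx)
      est[cbind(m$y, m$x_prime + 1)] <- m$intensity
      cor(as.numeric(est), as.numeric(tmap))
    })
    expect_gte(mean(rs), 0.8)
  }
  # phases one full period apart reconstruct the same image
  c1 <- run$rec$cycle[1, , , ]; c15 <- run$rec$cycle[15, , , ]
  expect_gt(cor(as.numeric(c1), as.numeric(c15)), 0.99)
})
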