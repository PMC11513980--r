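#' Camera noise model
#'
#' Shot noise is Poisson on the expected counts; read noise is additive
#' Gaussian; a fixed background frame (coverslip + fold-mirror signature)
#' adds to every exposure. Identical seeds give identical output.
#'
#' @param read_noise_sd Read noise standard deviation, counts.
#' @param background Scalar or matrix of background counts added to every
#'   frame.
#' @param shot_noise Logical, apply Poisson resampling of expected counts.
#' @param seed Optional integer; when set, the generator reseeds the RNG
#'   before rendering.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_noise_sd = 2, background = 0, shot_noise = TRUE,
                        seed = NULL) {
  stopifnot(read_noise_sd >= 0)
  structure(list(read_noise_sd = read_noise_sd, background = background,
                 shot_noise = shot_noise, seed = seed),
            class = "noise_model")
}

apply_noise <- function(expected, noise) {
  if (is.null(noise)) return(expected)
  bg <- noise$background
  if (length(bg) == 1) bg <- matrix(bg, nrow(expected), ncol(expected))
  lam <- pmax(expected + bg, 0)
  out <- if (isTRUE(noise$shot_noise)) {
    matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
  } else lam
  if (noise$read_noise_sd > 0)
    out <- out + matrix(rnorm(length(out), 0, noise$read_noise_sd),
                        nrow(out), ncol(out))
  out
}

gaussian_kernel <- function(fwhm_px, truncate = 3) {
  if (!is.finite(fwhm_px) || fwhm_px <= 0) return(1)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  half <- max(1, ceiling(truncate * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k / sum(k)
}

# 1D convolution, "same" length, edge-renormalised so a constant maps to
# itself and total flux is conserved to the edge-truncation level
conv_same <- function(x, k) {
  if (length(k) == 1) return(x * k / sum(k))
  n <- length(x); m <- length(k); half <- (m - 1) / 2
  xp <- c(rep(0, half), x, rep(0, half))
  raw <- vapply(seq_len(n), function(i) sum(xp[i:(i + m - 1)] * rev(k)), numeric(1))
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  wt <- vapply(seq_len(n), function(i) sum(ones[i:(i + m - 1)] * rev(k)), numeric(1))
  raw / wt
}

blur_columns <- function(mat, fwhm_px) {
  if (!is.finite(fwhm_px) || fwhm_px <= 0) return(mat)
  k <- gaussian_kernel(fwhm_px)
  if (length(k) == 1) return(mat)
  apply(mat, 2, conv_same, k = k)
}

#' Render one hyperspectral camera frame from a scene line
#'
#' Forward model of the line-scanning spectrometer: for every column x' the
#' ideal spectrum of the material on the illuminated line is placed along the
#' camera y axis through the inverse of the calibration mapping (including
#' the x'-proportional tilt shift), convolved along y with the Gaussian beam
#' profile (the beam width, not the grating, limits spectral resolution),
#' scaled by exposure, rotated by the small camera-tilt angle, and then
#' degraded with background + Poisson shot noise + Gaussian read noise.
#'
#' When an emitter is spatially narrower than the beam, its effective line
#' width is the product of the two Gaussian profiles, so the apparent
#' spectral resolution improves to the particle's image width.
#'
#' @param concentrations Matrix of compound concentrations on the line: rows
#'   named by compound (matching `library`), one column per x' pixel.
#' @param model A [calibration_model()].
#' @param cfg An [instrument_config()].
#' @param noise A [noise_model()] or `NULL` for a noiseless render.
#' @param n_y Number of camera rows.
#' @param galvo_y,stage_y,timestamp Acquisition metadata.
#' @param brightness Counts per unit concentration-intensity per second.
#' @param emitter_fwhm_um Per-column spatial extent of the emitter along the
#'   beam (um); `Inf` (default) means extended material filling the beam.
#' @param camera_tilt_deg Small camera rotation injected by the simulator
#'   (default 0 here; acquisition simulators pass their configured tilt).
#' @param library Compound library (default [compound_library()]).
#' @return A [hyper_frame()].
#' @export
render_hyperspectral_frame <- function(concentrations, model, cfg,
                                       noise = noise_model(),
                                       n_y = 128, galvo_y = model$galvo_ref,
                                       stage_y = NA_real_,
                                       timestamp = NA_real_,
                                       brightness = 2000,
                                       emitter_fwhm_um = Inf,
                                       camera_tilt_deg = 0,
                                       library = compound_library()) {
  stopifnot(is.matrix(concentrations), !is.null(rownames(concentrations)))
  unknown <- setdiff(rownames(concentrations), names(library))
  if (length(unknown))
    stop("unknown compound(s) in scene line: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  nx <- ncol(concentrations)
  emitter_fwhm_um <- rep_len(emitter_fwhm_um, nx)
  if (!is.null(noise) && !is.null(noise$seed)) set.seed(noise$seed)

  ys <- 0:(n_y - 1)
  xs <- 0:(nx - 1)
  shift_mat <- matrix(0, n_y, nx)
  for (j in seq_len(nx)) {
    shift_mat[, j] <- pixel_to_shift(model, xs[j], ys, galvo_y,
                                     cfg$excitation_wavelength)
  }
  ideal <- matrix(0, n_y, nx)
  for (cname in rownames(concentrations)) {
    conc <- concentrations[cname, ]
    if (all(conc == 0)) next
    base <- compound_intensity(library[[cname]], shift_mat)
    ideal <- ideal + sweep(base, 2, conc, `*`)
  }

  # beam blur along y; object narrower than the beam narrows the line image
  w_beam <- cfg$beam_fwhm_center / cfg$pixel_pitch_um
  w_obj <- emitter_fwhm_um / cfg$pixel_pitch_um
  w_eff <- 1 / sqrt(1 / w_beam^2 + 1 / w_obj^2)
  if (length(unique(round(w_eff, 6))) == 1) {
    ideal <- blur_columns(ideal, w_eff[1])
  } else {
    for (j in seq_len(nx)) ideal[, j] <- conv_same(ideal[, j],
                                                   gaussian_kernel(w_eff[j]))
  }

  expected <- ideal * brightness * cfg$frame_exposure
  if (camera_tilt_deg != 0)
    expected <- rotate_bilinear(expected, camera_tilt_deg)
  out <- apply_noise(expected, noise)
  hyper_frame(out, exposure = cfg$frame_exposure, galvo_y = galvo_y,
              stage_y = stage_y, timestamp = timestamp)
}

#' Periodically beating 2D phantom scene
#'
#' A smooth-edged two-chamber "heart": a ventricle-like and an atrium-like
#' disk whose radii pulse with the beat period, the atrium leading the
#' ventricle by a quarter cycle (the chambers fill and contract
#' sequentially), filled with water (with residual protein), surrounded by
#' a lipid/protein/collagen wall, embedded in a protein-and-agarose tissue
#' background. The radius waveform is deliberately asymmetric (fast
#' contraction, slower filling) so that every phase of the cycle has a
#' distinct spatial pattern; compartment edges are sigmoidal so sub-pixel
#' radius changes vary pixel intensities smoothly. Defaults follow the
#' zebrafish heart acquisitions: ~14-frame beat period at 28.6 fps.
#'
#' @param n_y,nx Scene grid size: rows are scanned y positions, columns x'.
#' @param beat_period Beat period in frames.
#' @param beat_phase0 Phase offset at frame 0, frames.
#' @param frame_rate Frames per second.
#' @param center Chamber centre `c(row, col)`, 1-based (default field
#'   centre).
#' @param radius Mean chamber radius, pixels.
#' @param pulse_fraction Fractional radius oscillation amplitude.
#' @param wall_width Wall thickness, pixels.
#' @param edge_softness Sigmoid edge width, pixels.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(n_y = 8, nx = 24, beat_period = 14,
                          beat_phase0 = 0, frame_rate = 28.6,
                          center = NULL, radius = NULL,
                          pulse_fraction = 0.35, wall_width = 2,
                          edge_softness = 0.6) {
  if (is.null(center)) center <- c((n_y + 1) / 2, (nx + 1) / 2)
  if (is.null(radius)) radius <- 0.3 * min(n_y, nx)
  stopifnot(beat_period > 0, radius > 0, pulse_fraction >= 0)
  structure(list(n_y = n_y, nx = nx, beat_period = beat_period,
                 beat_phase0 = beat_phase0, frame_rate = frame_rate,
                 center = center, radius = radius,
                 pulse_fraction = pulse_fraction, wall_width = wall_width,
                 edge_softness = edge_softness),
            class = "phantom_scene")
}

#' True beat phase of a frame index
#' @param scene A [phantom_scene()].
#' @param t Frame index (0-based), possibly fractional.
#' @return Phase in frames, in `[0, beat_period)`.
#' @export
phantom_phase <- function(scene, t) (t + scene$beat_phase0) %% scene$beat_period

#' Ground-truth compound concentration maps of the phantom at a frame time
#'
#' @param scene A [phantom_scene()].
#' @param t Frame index (0-based, fractional allowed).
#' @return Named list of `n_y x nx` concentration matrices (`water`,
#'   `protein`, `lipids`, `collagen`, `agarose`).
#' @export
phantom_maps <- function(scene, t) {
  phase <- phantom_phase(scene, t)
  theta <- 2 * pi * phase / scene$beat_period
  # asymmetric pulse: fast contraction, slower refill
  pulse <- function(th) (sin(th) + 0.5 * sin(2 * th)) / 1.5
  r_v <- scene$radius * (1 + scene$pulse_fraction * pulse(theta))
  r_a <- 0.7 * scene$radius *
    (1 + scene$pulse_fraction * pulse(theta + pi / 2))
  rows <- matrix(seq_len(scene$n_y), scene$n_y, scene$nx)
  cols <- matrix(seq_len(scene$nx), scene$n_y, scene$nx, byrow = TRUE)
  sep <- max(1.1 * scene$radius, 2)
  d_v <- sqrt((rows - scene$center[1])^2 + (cols - (scene$center[2] - sep / 2))^2)
  d_a <- sqrt((rows - scene$center[1])^2 + (cols - (scene$center[2] + sep))^2)
  sig <- function(x) 1 / (1 + exp(x / scene$edge_softness))
  inside <- pmin(sig(d_v - r_v) + sig(d_a - r_a), 1)
  wall <- pmin(sig(d_v - (r_v + scene$wall_width)) +
                 sig(d_a - (r_a + scene$wall_width)), 1) - inside
  outside <- 1 - inside - wall
  list(water = 1.0 * inside + 0.25 * outside,
       protein = 0.15 * inside + 0.8 * wall + 0.45 * outside,
       lipids = 0.9 * wall + 0.1 * outside,
       collagen = 0.5 * wall + 0.3 * outside,
       agarose = 0.2 * outside)
}

scene_line_concentrations <- function(maps, row) {
  do.call(rbind, lapply(maps, function(m) m[row, ]))
}

phantom_total_intensity <- function(maps, library = compound_library(),
                                    grid = seq(-40, 3500, by = 20)) {
  weights <- vapply(names(maps), function(cn)
    sum(compound_intensity(library[[cn]], grid)), numeric(1))
  Reduce(`+`, Map(function(m, w) m * w, maps, weights))
}

#' Simulate a full heart line-scan acquisition plus reference video
#'
#' Emulates the experiment: the stage dwells `seconds_per_step` at each y
#' position (5 um steps) while hyperspectral frames are taken continuously
#' (~1000 frames per step at 35 ms exposure); the camera and stage are not
#' synchronised, so a random number of frames at the start of each step are
#' still acquired at the previous y position. A 100-frame conventional
#' (spectrally integrated, full-field) reference video at the same frame
#' rate is produced alongside, together with the ground-truth phase of every
#' frame.
#'
#' @param scene A [phantom_scene()].
#' @param n_y_steps Number of stage y steps (rows of the scene scanned).
#' @param step_um Stage step, um.
#' @param seconds_per_step Stage dwell per step, seconds.
#' @param cfg An [instrument_config()] (its `frame_exposure` sets the rate).
#' @param model A [calibration_model()].
#' @param noise A [noise_model()].
#' @param n_y_px Camera rows per hyperspectral frame.
#' @param video_frames Length of the reference video.
#' @param video_noise_sd Additive Gaussian noise SD on the video, as a
#'   fraction of its dynamic range.
#' @param desync_max_frames Upper bound on the per-step start offset, frames.
#' @param camera_tilt_deg Camera tilt injected into every hyperspectral
#'   frame (compensated later by preprocessing).
#' @param brightness Counts per unit intensity per second.
#' @param seed Integer seed; the whole acquisition is reproducible from it.
#' @return An object of class `heart_acquisition`: list with `steps` (list of
#'   [frame_series()], one per y step), `video` (list: `frames` array
#'   `[t, y, x]`, `frame_rate`, `true_phase`), `phase_table` (tibble:
#'   `step`, `frame`, `global_frame`, `true_phase`, `stage_row`), `scene`,
#'   `model`, `cfg`, and `stage_y` (um per step).
#' @export
simulate_heart_acquisition <- function(scene,
                                       n_y_steps = scene$n_y,
                                       step_um = 5,
                                       seconds_per_step = 35,
                                       cfg = instrument_config(),
                                       model = default_sim_model(),
                                       noise = noise_model(read_noise_sd = 2,
                                                           background = 1),
                                       n_y_px = 128,
                                       video_frames = 100,
                                       video_noise_sd = 0.01,
                                       desync_max_frames = 60,
                                       camera_tilt_deg = 0.5,
                                       brightness = 2000,
                                       seed = 1) {
  stopifnot(n_y_steps <= scene$n_y)
  set.seed(seed)
  nf <- frames_per_step(seconds_per_step, cfg$frame_exposure)
  period <- scene$beat_period

  # noiseless base frames depend only on (beat phase mod period, scene row)
  base_cache <- new.env(parent = emptyenv())
  base_frame <- function(phase_i, row) {
    key <- paste(phase_i, row)
    if (!is.null(base_cache[[key]])) return(base_cache[[key]])
    maps <- phantom_maps(scene, phase_i - scene$beat_phase0)  # t s.t. phase(t)=phase_i
    conc <- scene_line_concentrations(maps, row)
    fr <- render_hyperspectral_frame(conc, model, cfg, noise = NULL,
                                     n_y = n_y_px,
                                     brightness = brightness,
                                     camera_tilt_deg = camera_tilt_deg)
    base_cache[[key]] <- unclass(fr)
    base_cache[[key]]
  }

  steps <- vector("list", n_y_steps)
  ptab <- vector("list", n_y_steps)
  global <- 0L
  integer_period <- abs(period - round(period)) < 1e-9
  for (j in seq_len(n_y_steps)) {
    offset <- if (desync_max_frames > 0) sample.int(desync_max_frames + 1, 1) - 1L else 0L
    frames <- array(0, c(nf, n_y_px, scene$nx))
    rows_used <- integer(nf)
    phases <- numeric(nf)
    for (i in seq_len(nf)) {
      t <- global + i - 1L
      phase <- phantom_phase(scene, t)
      row <- if (i <= offset) max(1L, j - 1L) else j
      phase_key <- if (integer_period) round(phase) %% round(period) else phase
      expected <- base_frame(phase_key, row)
      frames[i, , ] <- apply_noise(expected, noise)
      rows_used[i] <- row
      phases[i] <- phase
    }
    steps[[j]] <- frame_series(frames, exposure = cfg$frame_exposure,
                               galvo_y = model$galvo_ref,
                               stage_y = (rows_used - 1) * step_um,
                               timestamps = (global + seq_len(nf) - 1) *
                                 cfg$frame_exposure)
    ptab[[j]] <- tibble::tibble(step = j, frame = seq_len(nf),
                                global_frame = global + seq_len(nf) - 1L,
                                true_phase = phases, stage_row = rows_used)
    global <- global + nf
  }

  # conventional reference video of the full field at the same frame rate
  video_phase0 <- runif(1, 0, period)
  vid <- array(0, c(video_frames, scene$n_y, scene$nx))
  vphase <- numeric(video_frames)
  for (v in seq_len(video_frames)) {
    t <- v - 1 + video_phase0
    vphase[v] <- phantom_phase(scene, t)
    img <- phantom_total_intensity(phantom_maps(scene, t))
    vid[v, , ] <- img
  }
  if (video_noise_sd > 0) {
    vid <- vid + array(rnorm(length(vid), 0, video_noise_sd * diff(range(vid))),
                       dim(vid))
  }

  structure(list(
    steps = steps,
    video = list(frames = vid, frame_rate = 1 / cfg$frame_exposure,
                 true_phase = vphase),
    phase_table = dplyr::bind_rows(ptab),
    scene = scene, model = model, cfg = cfg,
    stage_y = (seq_len(n_y_steps) - 1) * step_um,
    camera_tilt_deg = camera_tilt_deg,
    seed = seed
  ), class = "heart_acquisition")
}

#' Default calibration model used by the simulator
#'
#' Covers roughly -90 to 3480 cm^-1 over 128 rows at 1.7 nm per pixel with a
#' small tilt-shift prefactor, matching a 300 lp/mm grating layout at 660 nm
#' excitation.
#'
#' @export
default_sim_model <- function() {
  calibration_model(lambda_ref = 656, dispersion = 1.7, galvo_gain = 0.5,
                    tilt_shift_prefactor = 0.02, y_ref = 0, x_ref = 0,
                    galvo_ref = 0)
}

#' Simulate a static microplastics scene with ground-truth labels
#'
#' Non-overlapping disks of PS / PMMA / PA6 (premixed roughly 1:1:1 in the
#' experiments) embedded in an agarose pad on a dish. Returns per-compound
#' concentration maps plus the ground-truth label map.
#'
#' @param counts Named integer vector of particles per polymer class.
#' @param radius_px Range `c(lo, hi)` of particle radii, pixels.
#' @param field `c(n_y, nx)` scene size in pixels.
#' @param agarose_level,dish_level Background concentrations.
#' @param seed Integer seed.
#' @param max_tries Placement retries per particle before failing.
#' @return An object of class `plastics_scene`: list with `concentration`
#'   (named list of maps), `label_map` (character matrix), `particles`
#'   (tibble: class, row, col, radius).
#' @export
simulate_microplastics_scene <- function(counts = c(PS = 10, PMMA = 10, PA6 = 10),
                                         radius_px = c(2, 4),
                                         field = c(64, 64),
                                         agarose_level = 0.6,
                                         dish_level = 0.4,
                                         seed = 1,
                                         max_tries = 400) {
  set.seed(seed)
  n_y <- field[1]; nx <- field[2]
  rows <- matrix(seq_len(n_y), n_y, nx)
  cols <- matrix(seq_len(nx), n_y, nx, byrow = TRUE)
  maps <- list(PS = matrix(0, n_y, nx), PMMA = matrix(0, n_y, nx),
               PA6 = matrix(0, n_y, nx),
               agarose = matrix(agarose_level, n_y, nx),
               dish = matrix(dish_level, n_y, nx))
  label_map <- matrix("agarose", n_y, nx)
  placed <- list()
  parts <- list()
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r <- runif(1, radius_px[1], radius_px[2])
        cy <- runif(1, 1 + r, n_y - r)
        cx <- runif(1, 1 + r, nx - r)
        clash <- any(vapply(placed, function(p)
          sqrt((p[1] - cy)^2 + (p[2] - cx)^2) < (p[3] + r + 1), logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok)
        stop("field too crowded: could not place particle ", i, " of class ",
             cl, call. = FALSE)
      placed[[length(placed) + 1]] <- c(cy, cx, r)
      parts[[length(parts) + 1]] <- tibble::tibble(class = cl, row = cy,
                                                   col = cx, radius = r)
      disk <- (rows - cy)^2 + (cols - cx)^2 <= r^2
      maps[[cl]][disk] <- 1
      maps$agarose[disk] <- 0
      maps$dish[disk] <- 0
      label_map[disk] <- cl
    }
  }
  structure(list(concentration = maps, label_map = label_map,
                 particles = dplyr::bind_rows(parts), seed = seed),
            class = "plastics_scene")
}
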