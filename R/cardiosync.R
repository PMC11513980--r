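#' Spectrally integrate a y-step's frames into a kymograph
#'
#' Each hyperspectral frame at one stage y position is summed over the
#' spectral range (default -40 to 3400 cm^-1, using the calibration to
#' decide which pixels fall inside), giving one spatial row per frame; rows
#' stacked in time form the kymograph for that y position. Because camera
#' and stage are not synchronised, only the middle 800 of the ~1000 frames
#' per step are used (fewer than 800 frames: all are used, with a warning).
#'
#' @param series A [frame_series()] acquired at one y step.
#' @param model A [calibration_model()].
#' @param range Spectral integration range `c(lo, hi)`, cm^-1.
#' @param keep Number of central frames to retain (default 800).
#' @param excitation_nm Excitation wavelength, nm.
#' @return An object of class `kymograph`: list with `values`
#'   (time x x' matrix), `frame_indices` (1-based indices into the series),
#'   `mask` (logical per column, all TRUE here), `range`.
#' @export
spectral_integrate <- function(series, model, range = c(-40, 3400),
                               keep = 800, excitation_nm = 660) {
  stopifnot(inherits(series, "frame_series"))
  nt <- n_frames(series)
  ny <- dim(series$frames)[2]; nx <- dim(series$frames)[3]
  if (nt > keep) {
    start <- floor((nt - keep) / 2) + 1L
    idx <- start:(start + keep - 1L)
  } else {
    if (nt < keep)
      warning("only ", nt, " frames available; using all", call. = FALSE)
    idx <- seq_len(nt)
  }
  shift <- matrix(0, ny, nx)
  for (j in seq_len(nx)) {
    shift[, j] <- pixel_to_shift(model, j - 1, 0:(ny - 1), series$galvo_y,
                                 excitation_nm)
  }
  sel <- shift >= range[1] & shift <= range[2]
  # selection matrix: (y*x) -> x accumulation of in-range pixels
  M <- matrix(0, ny * nx, nx)
  for (j in seq_len(nx)) {
    rows <- which(sel[, j]) + (j - 1) * ny
    M[rows, j] <- 1
  }
  Fm <- matrix(series$frames[idx, , ], length(idx), ny * nx)
  values <- Fm %*% M
  structure(list(values = values, frame_indices = idx,
                 mask = rep(TRUE, nx), range = range),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph %d frames x %d columns (%d retained), range %g..%g cm^-1>\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              x$range[1], x$range[2]))
  invisible(x)
}

#' Drop kymograph columns without significant time variation
#'
#' Computes the temporal SD of every column and retains only columns whose
#' SD strictly exceeds `threshold_fraction` times the mean SD (the mean is
#' taken over all columns currently in the mask).
#'
#' @param kym A [kymograph()].
#' @param threshold_fraction Fraction of the mean SD (default 0.8).
#' @return The kymograph with its `mask` updated; per-column SDs attached as
#'   attribute `column_sd`.
#' @export
filter_columns <- function(kym, threshold_fraction = 0.8) {
  stopifnot(inherits(kym, "kymograph"), nrow(kym$values) >= 2)
  sds <- apply(kym$values, 2, sd)
  thr <- threshold_fraction * mean(sds[kym$mask])
  keep <- kym$mask & (sds > thr)
  if (!any(keep))
    stop("degenerate signal: no column exceeds the variation threshold",
         call. = FALSE)
  kym$mask <- keep
  attr(kym, "column_sd") <- sds
  kym
}

#' Resize a reference video to the scan geometry
#'
#' Bilinearly interpolates every video frame onto a target pixel grid so
#' that video rows/columns match the scan's y steps and x' pixels.
#'
#' @param video List with `frames` array `[t, y, x]` (plus any metadata,
#'   preserved).
#' @param n_y,nx Target grid size.
#' @return The video with resampled frames.
#' @export
resize_video <- function(video, n_y, nx) {
  d <- dim(video$frames)
  if (d[2] == n_y && d[3] == nx) return(video)
  src_r <- if (n_y == 1) rep(1, 1) else seq(1, d[2], length.out = n_y)
  src_c <- if (nx == 1) rep(1, 1) else seq(1, d[3], length.out = nx)
  r0 <- pmin(floor(src_r), d[2] - 1); fr <- src_r - r0
  c0 <- pmin(floor(src_c), d[3] - 1); fc <- src_c - c0
  out <- array(0, c(d[1], n_y, nx))
  for (t in seq_len(d[1])) {
    f <- video$frames[t, , ]
    a <- f[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
      f[r0, c0 + 1, drop = FALSE] * outer(1 - fr, fc) +
      f[r0 + 1, c0, drop = FALSE] * outer(fr, 1 - fc) +
      f[r0 + 1, c0 + 1, drop = FALSE] * outer(fr, fc)
    out[t, , ] <- a
  }
  video$frames <- out
  video
}

#' Extract a reference patch from the conventional video
#'
#' Takes the y row of interest from an 11-frame window of the reference
#' video centred on the queried time point (5 frames before, the frame, 5
#' after — slightly shorter than the ~14-frame beat cycle), forming a small
#' time-by-x' image with the same column mask as the kymograph it will be
#' correlated against. Windows that run past the video bounds wrap
#' cyclically (the motion is periodic); the result is flagged.
#'
#' @param video List with `frames` array `[t, y, x]` (already resized to the
#'   scan geometry, see [resize_video()]).
#' @param y_row Scan y-step row (1-based) to take from each video frame.
#' @param time_point Video frame index (1-based) at the window centre.
#' @param window Window length in frames (odd, default 11).
#' @return Matrix `window x nx` with attributes `wrapped` (logical) and
#'   `frame_ids` (video frames used).
#' @export
reference_patch <- function(video, y_row, time_point, window = 11) {
  stopifnot(window >= 1, window %% 2 == 1)
  nt <- dim(video$frames)[1]
  half <- (window - 1) / 2
  ids <- time_point + (-half):half
  wrapped <- any(ids < 1 | ids > nt)
  ids <- ((ids - 1) %% nt) + 1
  patch <- video$frames[ids, y_row, , drop = FALSE]
  patch <- matrix(patch, window, dim(video$frames)[3])
  attr(patch, "wrapped") <- wrapped
  attr(patch, "frame_ids") <- ids
  patch
}

# zero-mean unit-variance correlation of each sliding window row-block of K
# against patch P, columns restricted to mask
ncc_profile <- function(P, K, mask) {
  w <- nrow(P)
  nv <- nrow(K) - w + 1
  if (nv < 1) stop("kymograph shorter than the patch window", call. = FALSE)
  Pm <- P[, mask, drop = FALSE]
  # row-major flattening to match the sliding-window block layout below
  pvec <- as.numeric(t(Pm)) - mean(Pm)
  pnorm_ <- sqrt(sum(pvec^2))
  if (pnorm_ == 0) return(rep(0, nv))
  Km <- K[, mask, drop = FALSE]
  # sliding window matrix: rows = start index v, cols = stacked (w x ncol)
  blocks <- lapply(seq_len(w), function(dr) Km[dr:(dr + nv - 1), , drop = FALSE])
  W <- do.call(cbind, blocks)
  mu <- rowMeans(W)
  Wc <- W - mu
  denom <- sqrt(rowSums(Wc^2)) * pnorm_
  num <- as.numeric(Wc %*% pvec)
  ifelse(denom > 0, num / denom, 0)
}

#' Cross-correlate a reference patch against a kymograph
#'
#' Normalised (zero-mean, unit-variance) cross-correlation of the video
#' patch with the kymograph, over all vertical (time) lags and a small set
#' of horizontal lags; true matches sit at (near-)zero horizontal lag, so
#' candidate peaks keep the best score within `h_tol` columns of centre.
#' Local maxima of the vertical profile are ranked by score and the top
#' `n_select` (40 in the experiments) identify the scan frames at the same
#' beat phase as the patch.
#'
#' @param patch Matrix from [reference_patch()].
#' @param kym A [kymograph()] (after [filter_columns()]).
#' @param h_tol Horizontal lag tolerance in columns (default 2).
#' @param n_select Number of peaks to keep (default 40; fewer are returned
#'   with a warning if the profile has fewer local maxima).
#' @return An object of class `phase_match`: tibble with `frame_index`
#'   (1-based index into the original series), `row` (kymograph row of the
#'   window centre), `score`, `h_lag`, sorted by score descending; the full
#'   correlation profile is attached as attribute `profile`.
#' @export
phase_correlate <- function(patch, kym, h_tol = 2, n_select = 40) {
  stopifnot(inherits(kym, "kymograph"), ncol(patch) == ncol(kym$values))
  lags <- -h_tol:h_tol
  nv <- nrow(kym$values) - nrow(patch) + 1
  best <- rep(-Inf, nv); best_lag <- integer(nv)
  nx <- ncol(patch)
  for (h in lags) {
    # shift patch columns by h relative to the kymograph
    if (h >= 0) { pc <- 1:(nx - h); kc <- (1 + h):nx } else { pc <- (1 - h):nx; kc <- 1:(nx + h) }
    mask <- kym$mask[kc]
    if (!any(mask)) next
    prof <- ncc_profile(patch[, pc, drop = FALSE],
                        kym$values[, kc, drop = FALSE], mask)
    upd <- prof > best
    best[upd] <- prof[upd]
    best_lag[upd] <- h
  }
  # local maxima of the vertical profile, ties broken by score then |lag|
  n <- length(best)
  is_peak <- c(FALSE, best[2:(n - 1)] > best[1:(n - 2)] &
                 best[2:(n - 1)] >= best[3:n], FALSE)
  pk <- which(is_peak)
  if (!length(pk)) pk <- which.max(best)
  ord <- order(-best[pk], abs(pk - (n + 1) / 2))
  pk <- pk[ord]
  if (length(pk) < n_select)
    warning("only ", length(pk), " correlation peaks found (requested ",
            n_select, ")", call. = FALSE)
  pk <- head(pk, n_select)
  center <- (nrow(patch) - 1) / 2
  out <- tibble::tibble(
    frame_index = kym$frame_indices[pk + center],
    row = pk + center,
    score = best[pk],
    h_lag = best_lag[pk])
  structure(out, class = c("phase_match", class(out)), profile = best)
}

#' Average the frames assigned to one cardiac phase
#'
#' Pixelwise mean of the selected hyperspectral frames; averaging N frames
#' of identical signal plus independent noise reduces the residual SD by
#' about sqrt(N) (N = 40 gives a factor of ~6.3).
#'
#' @param series A [frame_series()].
#' @param indices Frame indices (1-based), e.g. `frame_index` from
#'   [phase_correlate()].
#' @return A [hyper_frame()].
#' @export
synchronized_average <- function(series, indices) {
  stopifnot(inherits(series, "frame_series"))
  if (!length(indices)) stop("empty frame index list", call. = FALSE)
  stopifnot(all(indices >= 1), all(indices <= n_frames(series)))
  sub <- series$frames[indices, , , drop = FALSE]
  avg <- apply(sub, c(2, 3), mean)
  hyper_frame(avg, exposure = series$exposure, galvo_y = series$galvo_y,
              stage_y = stats::median(series$stage_y[indices]),
              timestamp = NA_real_)
}

#' Assemble per-(phase, y) averaged frames into a hyperspectral cycle
#'
#' Stacks the averaged line frames into full-field hyperspectral frames per
#' cardiac phase: each averaged frame is converted to per-column spectra on
#' a common grid and placed at its y position, yielding a
#' phase x y x x' x shift array ready for the spectral module (baseline
#' subtraction, band maps, false colour). Missing (phase, y) cells are
#' zero-filled and masked.
#'
#' @param cell_frames Nested list: `cell_frames[[p]][[j]]` is the averaged
#'   [hyper_frame()] for phase `p` and y step `j` (or `NULL`).
#' @param phases Vector of phase labels (length = number of phase cells).
#' @param stage_y Vector of stage y positions, um (length = number of y
#'   cells).
#' @param model A [calibration_model()].
#' @param grid Uniform shift grid for the extracted spectra.
#' @param excitation_nm Excitation wavelength, nm.
#' @return An object of class `hyper_cycle`: 4D array
#'   `[phase, y, x', shift]` with attributes `phases`, `stage_y`, `shifts`,
#'   `missing` (logical phase x y matrix).
#' @export
assemble_cycle <- function(cell_frames, phases, stage_y, model,
                           grid = seq(-40, 3400, by = 20),
                           excitation_nm = 660) {
  np <- length(phases); nyy <- length(stage_y)
  stopifnot(length(cell_frames) == np)
  first <- NULL
  for (p in seq_len(np)) for (j in seq_len(nyy)) {
    if (!is.null(cell_frames[[p]][[j]])) { first <- cell_frames[[p]][[j]]; break }
  }
  if (is.null(first)) stop("no cells supplied", call. = FALSE)
  nx <- ncol(first)
  cube <- array(0, c(np, nyy, nx, length(grid)))
  missing_cell <- matrix(FALSE, np, nyy)
  for (p in seq_len(np)) {
    for (j in seq_len(nyy)) {
      fr <- cell_frames[[p]][[j]]
      if (is.null(fr)) { missing_cell[p, j] <- TRUE; next }
      sp <- suppressWarnings(extract_spectra(fr, model, grid,
                                             excitation_nm = excitation_nm))
      cube[p, j, , ] <- matrix(sp$intensity, length(grid), nx)[, , drop = FALSE] |>
        t()
    }
  }
  structure(cube, class = "hyper_cycle", phases = phases, stage_y = stage_y,
            shifts = grid, missing = missing_cell)
}

#' Long-tibble view of a hyperspectral cycle
#'
#' @param x A `hyper_cycle`.
#' @param ... Unused.
#' @return Tibble with columns `phase`, `y`, `x_prime`, `shift_cm1`,
#'   `intensity`.
#' @method as_tibble hyper_cycle
#' @export
as_tibble.hyper_cycle <- function(x, ...) {
  d <- dim(x)
  grid <- expand.grid(phase = attr(x, "phases"),
                      y = seq_len(d[2]),
                      x_prime = seq_len(d[3]) - 1,
                      shift_cm1 = attr(x, "shifts"),
                      KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(phase = grid$phase, y = grid$y, x_prime = grid$x_prime,
                 shift_cm1 = grid$shift_cm1, intensity = as.numeric(x))
}

#' Retrospectively reconstruct the beat cycle from an acquisition
#'
#' End-to-end driver tying the module together: preprocess every y step
#' (background subtraction, camera-tilt rotation), build and filter its
#' kymograph, correlate reference patches for each queried phase, average
#' the top-scoring frames, and assemble the phase-resolved hyperspectral
#' cycle.
#'
#' @param acq A `heart_acquisition` from [simulate_heart_acquisition()] (or
#'   an equivalently shaped list from file readers).
#' @param phases Video frame indices (1-based) used as cardiac time points;
#'   default the first 17 frames (slightly more than one ~14-frame cycle).
#' @param rotation_deg Camera-tilt compensation angle; defaults to minus the
#'   acquisition's injected tilt.
#' @param background Background level subtracted from every frame.
#' @param range Spectral integration range for the kymographs, cm^-1.
#' @param window Reference-patch window length (frames).
#' @param n_select Frames averaged per (phase, y) cell.
#' @param grid Shift grid of the assembled cube.
#' @param threshold_fraction Column-SD retention threshold.
#' @return List with `cycle` (a `hyper_cycle`), `phase_table` (tibble:
#'   `phase`, `step`, `frame_index`, `score`, `h_lag`), and `kymographs`.
#' @export
reconstruct_cycle <- function(acq, phases = 1:17,
                              rotation_deg = NULL,
                              background = 0,
                              range = c(-40, 3400),
                              window = 11, n_select = 40,
                              grid = seq(-40, 3400, by = 20),
                              threshold_fraction = 0.8) {
  if (is.null(rotation_deg)) rotation_deg <- -(acq$camera_tilt_deg %||% 0)
  model <- acq$model
  nsteps <- length(acq$steps)
  video <- resize_video(acq$video, nsteps, dim(acq$steps[[1]]$frames)[3])

  kyms <- vector("list", nsteps)
  prep <- vector("list", nsteps)
  for (j in seq_len(nsteps)) {
    s <- acq$steps[[j]]
    fr <- s$frames
    if (rotation_deg != 0 || any(background != 0)) {
      for (i in seq_len(dim(fr)[1])) {
        f <- fr[i, , ]
        if (any(background != 0)) f <- pmax(f - background, 0)
        if (rotation_deg != 0) f <- rotate_bilinear(f, rotation_deg)
        fr[i, , ] <- f
      }
    }
    prep[[j]] <- frame_series(fr, exposure = s$exposure, galvo_y = s$galvo_y,
                              stage_y = s$stage_y, timestamps = s$timestamps)
    kyms[[j]] <- filter_columns(
      spectral_integrate(prep[[j]], model, range = range),
      threshold_fraction = threshold_fraction)
  }

  cells <- vector("list", length(phases))
  ptab <- list()
  for (pi in seq_along(phases)) {
    cells[[pi]] <- vector("list", nsteps)
    for (j in seq_len(nsteps)) {
      patch <- reference_patch(video, j, phases[pi], window = window)
      match <- phase_correlate(patch, kyms[[j]], n_select = n_select)
      cells[[pi]][[j]] <- synchronized_average(prep[[j]], match$frame_index)
      ptab[[length(ptab) + 1]] <- tibble::tibble(
        phase = phases[pi], step = j, frame_index = match$frame_index,
        score = match$score, h_lag = match$h_lag)
    }
  }
  cycle <- assemble_cycle(cells, phases, acq$stage_y, model, grid = grid,
                          excitation_nm = acq$cfg$excitation_wavelength)
  list(cycle = cycle, phase_table = dplyr::bind_rows(ptab), kymographs = kyms)
}
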