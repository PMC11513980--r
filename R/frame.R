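#' Hyperspectral camera frame
#'
#' A single camera exposure in hyperspectral mode: rows are the mixed
#' spatial/spectral y axis, columns are the spatial x' axis along the
#' illuminated line. Stored as a numeric matrix with acquisition metadata in
#' attributes.
#'
#' @param pixels Numeric matrix (rows = y, columns = x'), nonnegative.
#' @param exposure Exposure time, seconds.
#' @param galvo_y Galvo-y setting, instrument units.
#' @param stage_y Stage y position, um.
#' @param timestamp Acquisition time, seconds.
#' @return An object of class `hyper_frame` (a matrix).
#' @export
hyper_frame <- function(pixels, exposure = NA_real_, galvo_y = 0,
                        stage_y = NA_real_, timestamp = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite", call. = FALSE)
  structure(pixels, class = c("hyper_frame", "matrix", "array"),
            exposure = exposure, galvo_y = galvo_y,
            stage_y = stage_y, timestamp = timestamp)
}

#' @export
print.hyper_frame <- function(x, ...) {
  cat(sprintf("<hyper_frame %d y-px x %d x'-px, exposure %s s, galvo %s, stage_y %s um>\n",
              nrow(x), ncol(x), format(attr(x, "exposure")),
              format(attr(x, "galvo_y")), format(attr(x, "stage_y"))))
  invisible(x)
}

#' Series of frames sharing one geometry
#'
#' A time-ordered stack of frames with per-frame stage position and
#' timestamps, stored as a 3D array `[t, y, x]` plus metadata. This is the
#' in-memory form of a line-scan acquisition at one or more stage y steps.
#'
#' @param frames 3D numeric array `[t, y, x]`.
#' @param exposure Exposure time, seconds (scalar).
#' @param galvo_y Galvo-y setting (scalar).
#' @param stage_y Numeric vector of per-frame stage y positions, um.
#' @param timestamps Numeric vector of per-frame times, seconds (monotone
#'   nondecreasing).
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, exposure, galvo_y = 0,
                         stage_y = rep(NA_real_, dim(frames)[1]),
                         timestamps = seq_len(dim(frames)[1]) * exposure) {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  nt <- dim(frames)[1]
  stopifnot(length(stage_y) == nt, length(timestamps) == nt)
  if (is.unsorted(timestamps)) stop("timestamps must be monotone", call. = FALSE)
  structure(list(frames = frames, exposure = exposure, galvo_y = galvo_y,
                 stage_y = stage_y, timestamps = timestamps),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_series %d frames of %d y-px x %d x'-px, exposure %g s>\n",
              d[1], d[2], d[3], x$exposure))
  invisible(x)
}

#' Number of frames in a series
#' @param series A `frame_series`.
#' @export
n_frames <- function(series) dim(series$frames)[1]

#' Extract one frame of a series as a `hyper_frame`
#' @param series A `frame_series`.
#' @param i Frame index (1-based).
#' @export
series_frame <- function(series, i) {
  stopifnot(i >= 1, i <= n_frames(series))
  hyper_frame(series$frames[i, , ], exposure = series$exposure,
              galvo_y = series$galvo_y, stage_y = series$stage_y[i],
              timestamp = series$timestamps[i])
}
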