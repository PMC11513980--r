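#' Detect peaks in a 1D signal
#'
#' Boxcar-smooths the trace, finds strict local maxima, estimates each peak's
#' prominence (height above the higher of the two bounding valleys), and
#' refines positions to sub-sample precision with a three-point parabola.
#' Used by the calibration routines and by the training-spectrum selection
#' rules.
#'
#' @param intensity Numeric vector.
#' @param axis Positions of the samples (default 0-based index). Must be
#'   strictly monotone.
#' @param smooth_width Boxcar width in samples (odd; 1 disables smoothing).
#' @param min_prominence Minimum prominence to keep a peak. The default
#'   (`NULL`) uses 3x the robust noise SD estimated from first differences,
#'   `mad(diff(intensity)) / sqrt(2)`.
#' @return Tibble with columns `index` (1-based sample), `position` (refined,
#'   on `axis` units), `height`, `prominence`, sorted by `height` descending.
#' @export
find_peaks <- function(intensity, axis = seq_along(intensity) - 1,
                       smooth_width = 3, min_prominence = NULL) {
  n <- length(intensity)
  stopifnot(length(axis) == n)
  if (n < 3) return(empty_peaks())
  y <- if (smooth_width > 1) boxcar(intensity, smooth_width) else intensity
  if (is.null(min_prominence)) {
    noise <- stats::mad(diff(y)) / sqrt(2)
    min_prominence <- 3 * noise
  }
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  if (!length(idx)) return(empty_peaks())
  # prominence: descend to the lowest point before a higher peak on each side
  prom <- vapply(idx, function(i) {
    h <- y[i]
    lv <- y[i]; j <- i
    while (j > 1 && y[j - 1] <= h) { j <- j - 1; lv <- min(lv, y[j]) }
    if (j > 1) lv <- min(lv, min(y[j:i])) else lv <- min(y[1:i])
    rv <- y[i]; k <- i
    while (k < n && y[k + 1] <= h) { k <- k + 1; rv <- min(rv, y[k]) }
    if (k < n) rv <- min(rv, min(y[i:k])) else rv <- min(y[i:n])
    h - max(lv, rv)
  }, numeric(1))
  keep <- prom >= min_prominence & is.finite(prom)
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(empty_peaks())
  pos <- vapply(idx, function(i) {
    # parabolic sub-sample refinement on the smoothed trace
    a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
    denom <- a - 2 * b + c
    delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (a - c) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    axis[i] + delta * (axis[min(i + 1, n)] - axis[max(i - 1, 1)]) / 2
  }, numeric(1))
  out <- tibble::tibble(index = idx, position = pos,
                        height = intensity[idx], prominence = prom)
  dplyr::arrange(out, dplyr::desc(.data$height))
}

empty_peaks <- function() {
  tibble::tibble(index = integer(), position = numeric(),
                 height = numeric(), prominence = numeric())
}

#' Boxcar (moving-average) smoothing with edge shrinkage
#'
#' @param x Numeric vector.
#' @param width Window width in samples (odd).
#' @return Smoothed vector of the same length.
#' @export
boxcar <- function(x, width = 3) {
  stopifnot(width >= 1)
  if (width == 1) return(x)
  half <- floor(width / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
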