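#' Extract per-column Raman spectra from a calibrated frame
#'
#' For each x' column, camera rows are mapped to Raman shifts through the
#' calibration model (which corrects the x'-proportional vertical tilt
#' shift) and the intensities are resampled onto a uniform shift grid by
#' linear interpolation. Grid bins outside the column's spectral coverage
#' are zero-filled and flagged `covered = FALSE` (with a warning).
#'
#' @param frame Matrix or [hyper_frame()].
#' @param model A [calibration_model()].
#' @param grid Uniform Raman-shift grid, cm^-1.
#' @param galvo_y Galvo setting of the frame (defaults to the frame
#'   attribute, else the model reference).
#' @param excitation_nm Excitation wavelength, nm.
#' @return Tibble with columns `x_prime` (0-based column), `shift_cm1`,
#'   `intensity`, `covered`.
#' @export
extract_spectra <- function(frame, model, grid = seq(0, 3400, by = 20),
                            galvo_y = NULL, excitation_nm = 660) {
  px <- unclass(frame)
  stopifnot(is.matrix(px))
  if (is.null(galvo_y)) galvo_y <- attr(frame, "galvo_y") %||% model$galvo_ref
  ny <- nrow(px); nx <- ncol(px)
  ys <- 0:(ny - 1)
  out <- vector("list", nx)
  any_partial <- FALSE
  for (j in seq_len(nx)) {
    s <- pixel_to_shift(model, j - 1, ys, galvo_y, excitation_nm)
    if (s[1] > s[ny]) { s <- rev(s); v <- rev(px[, j]) } else v <- px[, j]
    res <- approx(s, v, xout = grid, rule = 1)$y
    covered <- !is.na(res)
    if (!all(covered)) any_partial <- TRUE
    res[!covered] <- 0
    out[[j]] <- tibble::tibble(x_prime = j - 1, shift_cm1 = grid,
                               intensity = res, covered = covered)
  }
  if (any_partial)
    warning("grid extends beyond the spectral coverage of some columns; ",
            "uncovered bins zero-filled and flagged", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Richardson-Lucy deconvolution of the beam profile
#'
#' The illumination beam's spatial profile blurs the spectral (y) axis; with
#' the beam modelled as a Gaussian (18 um FWHM by default), iterative
#' Richardson-Lucy deconvolution sharpens spectra while preserving
#' nonnegativity and total flux. Iterations stop early when the relative
#' change drops below `tol`.
#'
#' @param spectrum Data frame with `shift_cm1`, `intensity` on a uniform
#'   grid, or a bare numeric vector.
#' @param kernel_fwhm_cm1 Kernel FWHM in cm^-1. If `NULL`, derived from
#'   `cfg$deconvolution_fwhm` via the calibration model's dispersion at
#'   `at_shift`.
#' @param cfg,model Used only when `kernel_fwhm_cm1` is `NULL`.
#' @param at_shift Shift (cm^-1) at which the um -> cm^-1 conversion is
#'   evaluated.
#' @param step_cm1 Grid step, required when `spectrum` is a bare vector.
#' @param iterations Maximum RL iterations (default 10).
#' @param tol Early-stop relative-change threshold (default 1e-4).
#' @return Same type as the input; the number of iterations actually run is
#'   attached as attribute `iterations`.
#' @export
deconvolve_beam <- function(spectrum, kernel_fwhm_cm1 = NULL, cfg = NULL,
                            model = NULL, at_shift = 2900, step_cm1 = NULL,
                            iterations = 10, tol = 1e-4) {
  if (is.null(kernel_fwhm_cm1)) {
    if (is.null(cfg) || is.null(model))
      stop("give kernel_fwhm_cm1 or both cfg and model", call. = FALSE)
    kernel_fwhm_cm1 <- beam_fwhm_cm1(cfg, model, at_shift)
  }
  if (kernel_fwhm_cm1 < 0) stop("kernel width must be nonnegative", call. = FALSE)
  is_df <- is.data.frame(spectrum)
  if (is_df) {
    y <- spectrum$intensity
    step_cm1 <- diff(spectrum$shift_cm1[1:2])
  } else {
    y <- spectrum
    if (is.null(step_cm1)) stop("step_cm1 required for vector input", call. = FALSE)
  }
  if (any(y < 0)) stop("input must be nonnegative for Richardson-Lucy",
                       call. = FALSE)
  k <- gaussian_kernel(kernel_fwhm_cm1 / step_cm1)
  if (length(k) == 1) {
    res <- y; iters <- 0L
  } else {
    u <- pmax(y, .Machine$double.eps)
    iters <- 0L
    for (it in seq_len(iterations)) {
      c_ <- conv_same(u, k)
      ratio <- y / pmax(c_, .Machine$double.eps)
      u_new <- u * conv_same(ratio, rev(k))
      iters <- it
      delta <- sum(abs(u_new - u)) / max(sum(abs(u)), .Machine$double.eps)
      u <- u_new
      if (delta < tol) break
    }
    res <- u
  }
  out <- if (is_df) { spectrum$intensity <- res; spectrum } else res
  attr(out, "iterations") <- iters
  out
}

#' Beam spatial FWHM expressed in cm^-1 on the spectral axis
#'
#' @param cfg An [instrument_config()].
#' @param model A [calibration_model()].
#' @param at_shift Raman shift at which to evaluate the conversion.
#' @param fwhm_um Beam FWHM in um (default `cfg$deconvolution_fwhm`).
#' @return Kernel FWHM in cm^-1.
#' @export
beam_fwhm_cm1 <- function(cfg, model, at_shift = 2900,
                          fwhm_um = cfg$deconvolution_fwhm) {
  fwhm_px <- fwhm_um / cfg$pixel_pitch_um
  delta_lambda <- fwhm_px * abs(model$dispersion)
  fwhm_nm_to_cm1(delta_lambda, at_shift, cfg$excitation_wavelength)
}

#' Estimate and subtract the autofluorescence baseline
#'
#' Broad smooth autofluorescence underlies the sharp Raman peaks; the
#' baseline is estimated from the measured spectrum and subtracted to
#' increase peak contrast. The default estimator is asymmetric least
#' squares (Eilers-style: smoothness penalty `lambda` on second differences,
#' asymmetry `p` down-weighting points above the baseline); a low-order
#' polynomial fit is available as an alternative. The decomposition is
#' exact: `intensity + baseline` columns always sum to the input.
#'
#' @param spectrum Data frame with `shift_cm1`, `intensity` on a uniform
#'   grid.
#' @param method `"als"` or `"poly"`.
#' @param lambda ALS smoothness (default 1e3, tuned to the 20 cm^-1 grid;
#'   scale with the fourth power of any change in bin density).
#' @param p ALS asymmetry (default 0.01).
#' @param degree Polynomial degree for `method = "poly"` (default 5).
#' @param iterations ALS reweighting iterations (default 10).
#' @return Tibble with columns `shift_cm1`, `intensity` (the Raman part) and
#'   `baseline`; `intensity + baseline` reconstructs the input exactly.
#' @export
subtract_fluorescence <- function(spectrum, method = c("als", "poly"),
                                  lambda = 1e3, p = 0.01, degree = 5,
                                  iterations = 10) {
  method <- match.arg(method)
  spectrum <- tibble::as_tibble(spectrum)
  y <- spectrum$intensity
  n <- length(y)
  if (n < 5) stop("spectrum too short for baseline estimation", call. = FALSE)
  if (all(y == 0)) {
    return(tibble::tibble(shift_cm1 = spectrum$shift_cm1,
                          intensity = y, baseline = y))
  }
  z <- switch(method,
    als = als_baseline(y, lambda, p, iterations),
    poly = {
      x <- seq_len(n)
      fit <- lm(y ~ poly(x, degree))
      # one asymmetric reweighting pass so peaks pull the fit up less
      for (i in 1:3) {
        w <- ifelse(y > fitted(fit), p, 1)
        fit <- lm(y ~ poly(x, degree), weights = w)
      }
      unname(fitted(fit))
    })
  if (any(!is.finite(z)))
    stop("baseline estimation diverged", call. = FALSE)
  tibble::tibble(shift_cm1 = spectrum$shift_cm1,
                 intensity = y - z, baseline = z)
}

als_baseline <- function(y, lambda = 1e3, p = 0.01, iterations = 10) {
  n <- length(y)
  D <- diff(diag(n), differences = 2)
  P <- lambda * crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(iterations)) {
    z <- solve(diag(w) + P, w * y)
    w_new <- ifelse(y > z, p, 1 - p)
    if (all(w_new == w)) break
    w <- w_new
  }
  as.numeric(z)
}

#' Band definition
#'
#' A named spectral window, either `center +/- half_width` (the conventional
#' "peak +/- 40 cm^-1" windows) or an explicit `[lo, hi]` range.
#'
#' @param name Band name.
#' @param center Band centre, cm^-1 (ignored when `window` given).
#' @param half_width Half width, cm^-1 (default 40).
#' @param window Optional explicit `c(lo, hi)`.
#' @param subtract_baseline Estimate and remove the autofluorescence
#'   baseline per spectrum before averaging.
#' @return An object of class `band_def`.
#' @export
band_def <- function(name, center = NULL, half_width = 40, window = NULL,
                     subtract_baseline = FALSE) {
  if (is.null(window)) {
    stopifnot(!is.null(center), half_width > 0)
    window <- c(center - half_width, center + half_width)
  }
  stopifnot(window[1] < window[2])
  structure(list(name = name, window = window,
                 subtract_baseline = subtract_baseline),
            class = "band_def")
}

#' Band-intensity map over a grid of spectra
#'
#' Per pixel, the mean of (optionally baseline-subtracted) intensities over
#' the band window; grid bins whose centres fall inside the closed window
#' are included. Works on any long spectra table: every column other than
#' `shift_cm1`, `intensity` (and `covered`/`baseline`) is treated as a pixel
#' coordinate, so the same function serves single frames (`x_prime`),
#' assembled scans (`y`, `x_prime`) and phase-resolved cubes
#' (`phase`, `y`, `x_prime`).
#'
#' @param spectra Long tibble with `shift_cm1`, `intensity` plus coordinate
#'   columns.
#' @param band A [band_def()].
#' @param ... Passed to [subtract_fluorescence()] when the band requests
#'   baseline subtraction.
#' @return Tibble with the coordinate columns, `band`, and `intensity` (the
#'   band mean).
#' @export
band_intensity_map <- function(spectra, band, ...) {
  stopifnot(inherits(band, "band_def"))
  spectra <- tibble::as_tibble(spectra)
  coord_cols <- setdiff(names(spectra),
                        c("shift_cm1", "intensity", "covered", "baseline", "label"))
  if (band$subtract_baseline) {
    spectra <- spectra |>
      dplyr::group_by(dplyr::across(dplyr::all_of(coord_cols))) |>
      dplyr::group_modify(function(df, key) {
        dec <- subtract_fluorescence(df[, c("shift_cm1", "intensity")], ...)
        df$intensity <- dec$intensity
        df
      }) |>
      dplyr::ungroup()
  }
  sel <- spectra$shift_cm1 >= band$window[1] & spectra$shift_cm1 <= band$window[2]
  if (!any(sel)) stop("band window ", paste(band$window, collapse = "-"),
                      " cm^-1 contains no grid bins", call. = FALSE)
  spectra[sel, ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(coord_cols))) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop") |>
    dplyr::mutate(band = band$name, .before = "intensity")
}

#' Compose three band maps into a false-colour RGB image
#'
#' Each channel is normalised independently; by default to its maximum over
#' everything supplied (e.g. a full time series, so temporal changes remain
#' comparable between frames), then clipped to [0, 1].
#'
#' @param red,green,blue Band-map tibbles from [band_intensity_map()], with
#'   identical coordinate columns.
#' @param normalize `"series_max"` (default) or `"none"`.
#' @return Tibble with the coordinate columns and `r`, `g`, `b` in [0, 1].
#' @export
compose_false_color <- function(red, green, blue,
                                normalize = c("series_max", "none")) {
  normalize <- match.arg(normalize)
  chan <- function(m, nm) {
    m <- tibble::as_tibble(m)
    m$band <- NULL
    names(m)[names(m) == "intensity"] <- nm
    m
  }
  out <- chan(red, "r") |>
    dplyr::inner_join(chan(green, "g"),
                      by = setdiff(names(chan(red, "r")), "r")) |>
    dplyr::inner_join(chan(blue, "b"),
                      by = setdiff(names(chan(red, "r")), "r"))
  for (nm in c("r", "g", "b")) {
    v <- out[[nm]]
    if (normalize == "series_max") {
      mx <- max(v)
      if (mx <= 0) {
        warning("all-zero ", nm, " channel; left at zero", call. = FALSE)
      } else v <- v / mx
    }
    out[[nm]] <- pmin(pmax(v, 0), 1)
  }
  out
}

#' Region-of-interest band time series
#'
#' Mean band intensity inside a rectangular ROI per time point, normalised
#' per band so each trace peaks at 1 across the series.
#'
#' @param band_maps Tibble of band maps over time: columns `t`, coordinate
#'   columns `y` and/or `x_prime`, `band`, `intensity` (e.g. several
#'   [band_intensity_map()] results bound together).
#' @param roi Named list or vector with `x_lo`, `x_hi`, `y_lo`, `y_hi`
#'   (inclusive; either pair may be omitted when the corresponding
#'   coordinate is absent).
#' @return Tibble `band`, `t`, `intensity` (normalised to max 1 per band).
#' @export
roi_time_series <- function(band_maps, roi) {
  m <- tibble::as_tibble(band_maps)
  stopifnot(all(c("t", "band", "intensity") %in% names(m)))
  roi <- as.list(roi)
  if ("x_prime" %in% names(m) && !is.null(roi$x_lo))
    m <- dplyr::filter(m, .data$x_prime >= roi$x_lo, .data$x_prime <= roi$x_hi)
  if ("y" %in% names(m) && !is.null(roi$y_lo))
    m <- dplyr::filter(m, .data$y >= roi$y_lo, .data$y <= roi$y_hi)
  if (!nrow(m)) stop("empty ROI", call. = FALSE)
  m |>
    dplyr::group_by(.data$band, .data$t) |>
    dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop_last") |>
    dplyr::mutate(intensity = .data$intensity / max(.data$intensity)) |>
    dplyr::ungroup()
}
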