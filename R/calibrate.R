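#' Coarse spectral calibration from a longpass transmission edge
#'
#' With a broadband emitter (e.g. a quantum-dot solution) imaged through the
#' detection longpass filter, each camera column shows a dark-to-bright step
#' along y where transmission turns on. The step is located per column as the
#' first crossing of 50% of the column's plateau level (with linear
#' sub-pixel interpolation), corrected for the x'-proportional tilt shift,
#' and averaged across columns; `lambda_ref` is then adjusted so that this
#' edge row maps to the filter cutoff wavelength.
#'
#' @param edge_frame Matrix or [hyper_frame()] of the filtered broadband
#'   image.
#' @param cutoff_nm Longpass cutoff wavelength, nm.
#' @param model0 Starting [calibration_model()]; only `lambda_ref` is
#'   adjusted.
#' @param min_contrast Minimum relative plateau contrast
#'   `(plateau - floor) / plateau` for a column to count (default 0.2).
#' @return A `calibration_model` with updated `lambda_ref`; the detected mean
#'   edge row is attached as attribute `edge_row`.
#' @export
coarse_calibrate <- function(edge_frame, cutoff_nm, model0,
                             min_contrast = 0.2) {
  stopifnot(inherits(model0, "calibration_model"))
  px <- unclass(edge_frame)
  stopifnot(is.matrix(px))
  galvo <- attr(edge_frame, "galvo_y") %||% model0$galvo_ref
  edges <- vapply(seq_len(ncol(px)), function(j) {
    v <- boxcar(px[, j], 3)
    floor_ <- min(v)
    plateau <- quantile(v, 0.9, names = FALSE)
    if (plateau <= 0 || (plateau - floor_) < min_contrast * plateau)
      return(NA_real_)
    thr <- 0.5 * plateau
    above <- which(v >= thr)
    if (!length(above) || above[1] == 1) return(if (length(above) && above[1] == 1) 0 else NA_real_)
    i <- above[1]
    # linear interpolation between samples i-1 and i (0-based pixel units)
    frac <- (thr - v[i - 1]) / (v[i] - v[i - 1])
    (i - 2) + frac
  }, numeric(1))
  xs <- seq_len(ncol(px)) - 1
  ok <- is.finite(edges)
  if (!any(ok))
    stop("no detectable transmission edge (plateau contrast below minimum)",
         call. = FALSE)
  # remove the tilt-induced x' dependence before averaging
  y_edge <- mean(edges[ok] - model0$tilt_shift_prefactor * (xs[ok] - model0$x_ref))
  lambda_at_edge <- pixel_to_wavelength(model0, model0$x_ref, y_edge, galvo)
  model <- model0
  model$lambda_ref <- model0$lambda_ref + (cutoff_nm - lambda_at_edge)
  attr(model, "edge_row") <- y_edge
  model
}

#' Fine spectral calibration by matching known Raman peaks
#'
#' Frames containing isolated emitters of known compounds (typically PS and
#' PMMA microparticles) are reduced to per-column peak positions; detected
#' peaks are matched, through the starting model, to the supplied reference
#' shifts, and the two free parameters of the calibration — the tilt-shift
#' prefactor and the grating-tilt offset folded into `lambda_ref` — are
#' refitted by least squares in pixel space (the problem is linear in both).
#'
#' @param frames List of matrices / [hyper_frame()]s, one or more per
#'   compound.
#' @param compounds Character vector, one compound name per frame.
#' @param reference_peaks Tibble/data frame with columns `compound`,
#'   `shift_cm1` giving the literature peak positions.
#' @param model0 Starting [calibration_model()].
#' @param excitation_nm Excitation wavelength, nm.
#' @param match_tol_cm1 Maximum |detected - reference| shift for a match
#'   (default 150 cm^-1, about half the instrument resolution envelope).
#' @param min_col_fraction Columns whose total signal exceeds this fraction
#'   of the strongest column are treated as containing an emitter.
#' @return A refitted `calibration_model`; the matched-peak table is attached
#'   as attribute `matches` and the per-peak residual RMS (cm^-1) as
#'   `residual_rms_cm1`.
#' @export
fine_calibrate <- function(frames, compounds, reference_peaks, model0,
                           excitation_nm = 660, match_tol_cm1 = 150,
                           min_col_fraction = 0.25) {
  stopifnot(inherits(model0, "calibration_model"),
            length(frames) == length(compounds))
  reference_peaks <- tibble::as_tibble(reference_peaks)
  stopifnot(all(c("compound", "shift_cm1") %in% names(reference_peaks)))

  rows <- list()
  for (k in seq_along(frames)) {
    px <- unclass(frames[[k]])
    galvo <- attr(frames[[k]], "galvo_y") %||% model0$galvo_ref
    refs <- reference_peaks$shift_cm1[reference_peaks$compound == compounds[k]]
    if (!length(refs)) next
    totals <- colSums(px)
    signal_cols <- which(totals >= min_col_fraction * max(totals) &
                           totals > 0)
    for (j in signal_cols) {
      pk <- find_peaks(px[, j], smooth_width = 3)
      if (!nrow(pk)) next
      pk <- head(pk, 2 * length(refs))
      det_shift <- pixel_to_shift(model0, j - 1, pk$position, galvo,
                                  excitation_nm)
      for (r in refs) {
        d <- abs(det_shift - r)
        i <- which.min(d)
        if (d[i] <= match_tol_cm1) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            compound = compounds[k], x_prime = j - 1,
            y_pix = pk$position[i], galvo_y = galvo,
            ref_shift_cm1 = r,
            lambda_nm = shift_to_wavelength(r, excitation_nm))
        }
      }
    }
  }
  if (!length(rows))
    stop("under-determined fine calibration: no detected peak matched a reference shift",
         call. = FALSE)
  matches <- dplyr::bind_rows(rows)
  if (nrow(matches) < 3)
    stop("under-determined fine calibration: fewer than 3 matched peaks",
         call. = FALSE)
  if (length(unique(matches$x_prime)) < 2)
    stop("under-determined fine calibration: peaks at a single x' cannot fix the tilt-shift prefactor",
         call. = FALSE)

  # y = y_ref + p (x - x_ref) + (lambda - lambda_ref_new - G dg) / D
  # lhs := y - y_ref - (lambda - lambda_ref0 - G dg) / D = p (x - x_ref) - dlam / D
  D <- model0$dispersion
  lhs <- matches$y_pix - model0$y_ref -
    (matches$lambda_nm - model0$lambda_ref -
       model0$galvo_gain * (matches$galvo_y - model0$galvo_ref)) / D
  xc <- matches$x_prime - model0$x_ref
  fit <- lm(lhs ~ xc)
  model <- model0
  model$tilt_shift_prefactor <- unname(coef(fit)[2])
  model$lambda_ref <- model0$lambda_ref - unname(coef(fit)[1]) * D

  fitted_shift <- pixel_to_shift(model, matches$x_prime, matches$y_pix,
                                 matches$galvo_y, excitation_nm)
  attr(model, "matches") <- matches
  attr(model, "residual_rms_cm1") <-
    sqrt(mean((fitted_shift - matches$ref_shift_cm1)^2))
  model
}

#' Recalibrate the spectral axis against a standard spectrum
#'
#' When the grating cube is reinserted its tilt changes subtly; rather than
#' repeating the full calibration, a newly measured spectrum of a stable
#' specimen (e.g. embryo muscle) is aligned to a stored standard spectrum of
#' the same specimen. The peak position inside each anchor band (defaults:
#' the ~1670 cm^-1 collagen band and the ~3240 cm^-1 water band) is located
#' in both spectra, and the affine axis correction mapping the new positions
#' onto the standard's is returned.
#'
#' @param new_spectrum,standard_spectrum Data frames with columns
#'   `shift_cm1`, `intensity`.
#' @param anchor_bands Named list of `c(lo, hi)` windows in cm^-1; default
#'   collagen 1670 +/- 60 and water 3240 +/- 120.
#' @return An object of class `axis_update`: `list(scale, shift)` such that
#'   `corrected = scale * shift_cm1 + shift` aligns the new spectrum to the
#'   standard. Anchor-peak positions are attached as attribute `anchors`.
#' @export
recalibrate_from_standard <- function(new_spectrum, standard_spectrum,
                                      anchor_bands = list(
                                        collagen = c(1610, 1730),
                                        water = c(3120, 3360))) {
  if (length(anchor_bands) < 2)
    stop("need at least two anchor bands for an affine axis update", call. = FALSE)
  locate <- function(sp, band, label) {
    sp <- tibble::as_tibble(sp)
    if (sum(sp$shift_cm1 >= band[1] & sp$shift_cm1 <= band[2]) < 3)
      stop("anchor band ", label, " not covered by the spectrum", call. = FALSE)
    # detect on the full spectrum, then keep peaks falling inside the band
    pk <- find_peaks(sp$intensity, axis = sp$shift_cm1, smooth_width = 3,
                     min_prominence = 0.02 * max(sp$intensity))
    pk <- pk[pk$position >= band[1] & pk$position <= band[2], ]
    if (!nrow(pk))
      stop("no detectable peak in anchor band ", label, call. = FALSE)
    pk$position[1]
  }
  new_pos <- vapply(names(anchor_bands), function(nm)
    locate(new_spectrum, anchor_bands[[nm]], nm), numeric(1))
  std_pos <- vapply(names(anchor_bands), function(nm)
    locate(standard_spectrum, anchor_bands[[nm]], nm), numeric(1))
  fit <- lm(std_pos ~ new_pos)
  upd <- structure(list(scale = unname(coef(fit)[2]),
                        shift = unname(coef(fit)[1])),
                   class = "axis_update")
  attr(upd, "anchors") <- tibble::tibble(
    band = names(anchor_bands), new = unname(new_pos), standard = unname(std_pos))
  upd
}

#' Apply an axis update to a spectrum
#'
#' @param spectrum Data frame with `shift_cm1`, `intensity`.
#' @param update An `axis_update` from [recalibrate_from_standard()].
#' @return The spectrum with its `shift_cm1` axis corrected.
#' @export
apply_axis_update <- function(spectrum, update) {
  stopifnot(inherits(update, "axis_update"))
  spectrum <- tibble::as_tibble(spectrum)
  spectrum$shift_cm1 <- update$scale * spectrum$shift_cm1 + update$shift
  spectrum
}

`%||%` <- function(a, b) if (is.null(a)) b else a
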