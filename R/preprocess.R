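#' Subtract a background frame
#'
#' Pixelwise subtraction of the stored background (coverslip + fold-mirror
#' signature and camera offset). Raman intensities are nonnegative, so the
#' result is clamped at zero by default; pass `clamp = FALSE` for signed
#' residuals.
#'
#' @param frame Matrix or [hyper_frame()].
#' @param background Matrix of the same shape (or scalar).
#' @param clamp Clamp negatives to zero (default TRUE).
#' @return Same type as `frame`.
#' @export
subtract_background <- function(frame, background, clamp = TRUE) {
  px <- unclass(frame)
  if (length(background) == 1) background <- matrix(background, nrow(px), ncol(px))
  if (!all(dim(px) == dim(background)))
    stop("background shape ", paste(dim(background), collapse = "x"),
         " does not match frame ", paste(dim(px), collapse = "x"), call. = FALSE)
  out <- px - background
  if (clamp) out <- pmax(out, 0)
  restore_frame(out, frame)
}

restore_frame <- function(pixels, template) {
  if (inherits(template, "hyper_frame")) {
    hyper_frame(pixels, exposure = attr(template, "exposure"),
                galvo_y = attr(template, "galvo_y"),
                stage_y = attr(template, "stage_y"),
                timestamp = attr(template, "timestamp"))
  } else pixels
}

# inverse-mapped bilinear rotation about the matrix centre; out-of-bounds 0
rotate_bilinear <- function(mat, angle_deg) {
  if (angle_deg == 0) return(mat)
  th <- angle_deg * pi / 180
  nr <- nrow(mat); nc <- ncol(mat)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc) - cy
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  # source coordinates = inverse rotation of target coordinates
  sr <- cos(th) * r + sin(th) * c + cy
  sc <- -sin(th) * r + cos(th) * c + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- mat[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * get(r0, c0) +
    (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) +
    fr * fc * get(r0 + 1, c0 + 1)
  matrix(v, nr, nc)
}

#' Rotate a frame to compensate camera tilt, then crop
#'
#' Bilinear rotation about the frame centre (small angles only; the camera
#' tilt is a fraction of a degree) followed by an optional crop. Pixels
#' mapped from outside the original frame are zero-filled and counted in the
#' `n_outside` attribute.
#'
#' @param frame Matrix or [hyper_frame()].
#' @param rotation_deg Rotation angle, degrees, |angle| < 5.
#' @param crop Optional `c(row_lo, row_hi, col_lo, col_hi)` (1-based,
#'   inclusive).
#' @return Rotated (and cropped) frame of the same type.
#' @export
rotate_and_crop <- function(frame, rotation_deg = 0, crop = NULL) {
  if (abs(rotation_deg) >= 5)
    stop("|rotation| must be < 5 degrees (camera tilt compensation only)",
         call. = FALSE)
  px <- unclass(frame)
  out <- rotate_bilinear(px, rotation_deg)
  support <- rotate_bilinear(matrix(1, nrow(px), ncol(px)), rotation_deg)
  n_outside <- sum(support < 1 - 1e-9)
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4)
    if (crop[1] < 1 || crop[3] < 1 || crop[2] > nrow(out) || crop[4] > ncol(out) ||
        crop[1] > crop[2] || crop[3] > crop[4])
      stop("crop window outside frame", call. = FALSE)
    out <- out[crop[1]:crop[2], crop[3]:crop[4], drop = FALSE]
  }
  res <- restore_frame(out, frame)
  attr(res, "n_outside") <- n_outside
  res
}

#' Bin columns (x' direction)
#'
#' Mean over non-overlapping groups of `factor` adjacent columns; a trailing
#' remainder that does not fill a group is dropped (recorded in the
#' `dropped_columns` attribute).
#'
#' @param frame Matrix or [hyper_frame()].
#' @param factor Bin width in columns (default 10).
#' @return Binned frame.
#' @export
bin_x <- function(frame, factor = 10) {
  stopifnot(factor >= 1, factor == round(factor))
  px <- unclass(frame)
  if (factor == 1) {
    res <- restore_frame(px, frame)
    attr(res, "dropped_columns") <- 0L
    return(res)
  }
  ngroups <- ncol(px) %/% factor
  dropped <- ncol(px) - ngroups * factor
  if (ngroups == 0) stop("fewer columns than one bin", call. = FALSE)
  out <- matrix(0, nrow(px), ngroups)
  for (g in seq_len(ngroups)) {
    out[, g] <- rowMeans(px[, ((g - 1) * factor + 1):(g * factor), drop = FALSE])
  }
  res <- restore_frame(out, frame)
  attr(res, "dropped_columns") <- as.integer(dropped)
  res
}

#' Compensate the illumination gradient along the beam
#'
#' The laser loses intensity as it propagates through the sample along x';
#' image brightness is rescaled with a gradient in that direction. The
#' exponential mode (Beer-Lambert-like attenuation) is the default
#' functional form; `linear` is available, and `off` is the identity.
#' Column c (0-based, of C columns) is multiplied by
#' `1 + strength * c/(C-1)` (linear) or `exp(strength * c/(C-1))`
#' (exponential).
#'
#' @param frame Matrix or [hyper_frame()].
#' @param mode One of `"off"`, `"linear"`, `"exponential"`.
#' @param strength Nonnegative gradient strength.
#' @return Frame with the compensation applied; the per-column scaling
#'   vector is attached as attribute `scaling`.
#' @export
compensate_gradient <- function(frame, mode = c("exponential", "linear", "off"),
                                strength = 0) {
  mode <- match.arg(mode)
  if (strength < 0) stop("gradient strength must be nonnegative", call. = FALSE)
  px <- unclass(frame)
  cc <- (seq_len(ncol(px)) - 1) / max(ncol(px) - 1, 1)
  g <- switch(mode,
              off = rep(1, ncol(px)),
              linear = 1 + strength * cc,
              exponential = exp(strength * cc))
  res <- restore_frame(sweep(px, 2, g, `*`), frame)
  attr(res, "scaling") <- g
  res
}

#' Fit an exponential illumination-gradient strength
#'
#' Estimates the attenuation constant k such that column means decay as
#' `exp(-k c/(C-1))`, by least squares on the log column means of a
#' homogeneous region; the fitted k is the `strength` that
#' [compensate_gradient()] needs to flatten the profile.
#'
#' @param frame Matrix of a homogeneous region.
#' @return Estimated strength (nonnegative).
#' @export
fit_gradient_strength <- function(frame) {
  m <- colMeans(unclass(frame))
  if (any(m <= 0)) stop("column means must be positive to fit a log-linear gradient",
                        call. = FALSE)
  cc <- (seq_along(m) - 1) / max(length(m) - 1, 1)
  max(0, -unname(coef(lm(log(m) ~ cc))[2]))
}

#' Deskew a stack of oblique planes into an orthogonal volume
#'
#' Each plane acquired by the oblique-plane microscope is tilted by the OPM
#' angle; successive planes (scan step `plane_step_um`) are sheared laterally
#' by `plane_step_um * cos(tilt) / pixel_um` pixels and sit
#' `plane_step_um * sin(tilt)` um deeper. The shear is applied with linear
#' interpolation into a widened output, so total intensity is conserved up
#' to interpolation error. At 90 degrees the planes are already vertical and
#' no shear is applied.
#'
#' @param stack 3D array `[plane, row, col]`; the shear displaces rows.
#' @param tilt_deg OPM tilt angle in degrees, in (0, 90].
#' @param plane_step_um Scan step between planes, um.
#' @param pixel_um In-plane pixel size along the sheared (row) axis, um.
#' @return 3D array `[plane, row, col]` with rows widened to hold the shear;
#'   attributes `depth_step_um` (= `plane_step_um * sin(tilt)`) and
#'   `shear_px_per_plane`.
#' @export
deskew_volume <- function(stack, tilt_deg = 38, plane_step_um = 5,
                          pixel_um = 1) {
  stopifnot(is.array(stack), length(dim(stack)) == 3)
  if (tilt_deg <= 0 || tilt_deg > 90)
    stop("tilt angle must be in (0, 90] degrees", call. = FALSE)
  np <- dim(stack)[1]; nr <- dim(stack)[2]; nc <- dim(stack)[3]
  shear <- plane_step_um * cos(tilt_deg * pi / 180) / pixel_um
  total_shift <- shear * (np - 1)
  nr_out <- nr + ceiling(total_shift)
  out <- array(0, c(np, nr_out, nc))
  for (p in seq_len(np)) {
    d <- shear * (p - 1)
    i0 <- floor(d); f <- d - i0
    rows <- seq_len(nr)
    out[p, rows + i0, ] <- out[p, rows + i0, ] + (1 - f) * stack[p, , ]
    if (f > 0)
      out[p, rows + i0 + 1, ] <- out[p, rows + i0 + 1, ] + f * stack[p, , ]
  }
  attr(out, "depth_step_um") <- plane_step_um * sin(tilt_deg * pi / 180)
  attr(out, "shear_px_per_plane") <- shear
  out
}
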