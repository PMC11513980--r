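#' Instrument configuration
#'
#' Bundles the optical parameters of the single-objective oblique-plane
#' line-scanning Raman microscope that the processing pipeline needs:
#' excitation wavelength, grating density, the 38 degree tilt of the oblique
#' plane, the illumination-beam width (10 um FWHM at the field centre growing
#' to 20 um at the edges), the Gaussian FWHM assumed when deconvolving the
#' beam profile, and the longpass filter cutoff used for coarse calibration.
#'
#' @param excitation_wavelength Laser wavelength, nm.
#' @param grating_density Grating line density, line pairs per mm.
#' @param tilt_angle Tilt of the oblique image plane, degrees.
#' @param beam_fwhm_center,beam_fwhm_edge Illumination beam FWHM at the field
#'   centre / edge, um.
#' @param deconvolution_fwhm Gaussian FWHM assumed for beam-profile
#'   deconvolution, um.
#' @param frame_exposure Camera exposure per frame, seconds.
#' @param longpass_cutoff Longpass filter cutoff wavelength, nm.
#' @param pixel_pitch_um Sample-referred pixel pitch along the camera y axis,
#'   um per pixel (converts beam widths to pixels).
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(excitation_wavelength = 660,
                              grating_density = 300,
                              tilt_angle = 38,
                              beam_fwhm_center = 10,
                              beam_fwhm_edge = 20,
                              deconvolution_fwhm = 18,
                              frame_exposure = 0.035,
                              longpass_cutoff = 664,
                              pixel_pitch_um = 6) {
  stopifnot(excitation_wavelength > 0,
            tilt_angle > 0, tilt_angle < 90,
            beam_fwhm_center <= beam_fwhm_edge,
            beam_fwhm_center > 0,
            longpass_cutoff >= excitation_wavelength,
            frame_exposure > 0, pixel_pitch_um > 0)
  structure(list(
    excitation_wavelength = excitation_wavelength,
    grating_density = grating_density,
    tilt_angle = tilt_angle,
    beam_fwhm_center = beam_fwhm_center,
    beam_fwhm_edge = beam_fwhm_edge,
    deconvolution_fwhm = deconvolution_fwhm,
    frame_exposure = frame_exposure,
    longpass_cutoff = longpass_cutoff,
    pixel_pitch_um = pixel_pitch_um
  ), class = "instrument_config")
}

#' Two-parameter spectral-axis calibration model
#'
#' In a hyperspectral frame the horizontal axis x' is space along the
#' illuminated line and the vertical axis y mixes wavelength with the beam
#' position: wavelength is affine in y, in the galvo-y setting, and -- because
#' the grating tilt shifts the image vertically in proportion to x' -- in x'.
#' The model is
#' \deqn{\lambda(x', y, g) = \lambda_{ref} + D (y - y_{ref} - p (x' - x_{ref}))
#'   + G (g - g_{ref})}
#' with dispersion D (nm per y pixel, positive: larger y index means longer
#' wavelength, the m = -1 diffraction order), tilt-shift prefactor p (y pixels
#' per x' pixel) and galvo gain G. The two quantities the calibration
#' procedures actually fit are p and the grating-tilt-dependent offset folded
#' into `lambda_ref`; D follows from the grating constant (or is configured).
#'
#' @param lambda_ref Wavelength (nm) at the reference pixel for the reference
#'   galvo setting.
#' @param dispersion nm per y pixel; must be nonzero.
#' @param galvo_gain nm per galvo-y unit.
#' @param tilt_shift_prefactor y pixels of vertical image shift per x' pixel.
#' @param y_ref,x_ref Reference pixel coordinates (0-based, pixel centres).
#' @param galvo_ref Reference galvo-y setting.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(lambda_ref = 660,
                              dispersion = 1.7,
                              galvo_gain = 0,
                              tilt_shift_prefactor = 0,
                              y_ref = 0, x_ref = 0, galvo_ref = 0) {
  stopifnot(is.finite(dispersion), dispersion != 0)
  structure(list(
    lambda_ref = lambda_ref,
    dispersion = dispersion,
    galvo_gain = galvo_gain,
    tilt_shift_prefactor = tilt_shift_prefactor,
    y_ref = y_ref, x_ref = x_ref, galvo_ref = galvo_ref
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Spectral-axis calibration model\n")
  cat(sprintf("  lambda_ref: %.3f nm at (x'=%g, y=%g), galvo %g\n",
              x$lambda_ref, x$x_ref, x$y_ref, x$galvo_ref))
  cat(sprintf("  dispersion: %.5f nm/px, galvo gain: %.5f nm/unit\n",
              x$dispersion, x$galvo_gain))
  cat(sprintf("  tilt-shift prefactor: %.5f y-px per x'-px\n",
              x$tilt_shift_prefactor))
  invisible(x)
}

#' Map a camera pixel to a wavelength
#'
#' Evaluates the affine calibration model at pixel coordinates (x', y) and a
#' galvo-y setting. Extrapolation beyond the calibrated frame is permitted;
#' callers that care can compare against their frame extent.
#'
#' @param model A [calibration_model()].
#' @param x_prime,y Pixel coordinates (0-based, pixel centres); vectors
#'   recycle.
#' @param galvo_y Galvo-y setting in instrument units.
#' @return Wavelength(s) in nm.
#' @export
pixel_to_wavelength <- function(model, x_prime, y, galvo_y = model$galvo_ref) {
  stopifnot(inherits(model, "calibration_model"))
  model$lambda_ref +
    model$dispersion *
      (y - model$y_ref - model$tilt_shift_prefactor * (x_prime - model$x_ref)) +
    model$galvo_gain * (galvo_y - model$galvo_ref)
}

#' Map a camera pixel to a Raman shift
#'
#' @inheritParams pixel_to_wavelength
#' @param excitation_nm Excitation wavelength in nm.
#' @return Raman shift(s) in cm^-1.
#' @export
pixel_to_shift <- function(model, x_prime, y, galvo_y = model$galvo_ref,
                           excitation_nm = 660) {
  wavelength_to_shift(pixel_to_wavelength(model, x_prime, y, galvo_y),
                      excitation_nm)
}

#' Inverse of [pixel_to_wavelength()] in y
#'
#' Returns the (fractional) y pixel at which a wavelength appears in column
#' x'.
#'
#' @inheritParams pixel_to_wavelength
#' @param lambda_nm Wavelength(s) in nm.
#' @return Fractional y pixel coordinate(s).
#' @export
wavelength_to_y <- function(model, lambda_nm, x_prime, galvo_y = model$galvo_ref) {
  stopifnot(inherits(model, "calibration_model"))
  (lambda_nm - model$lambda_ref -
     model$galvo_gain * (galvo_y - model$galvo_ref)) / model$dispersion +
    model$y_ref + model$tilt_shift_prefactor * (x_prime - model$x_ref)
}

#' Tidy a calibration model into a one-row-per-parameter tibble
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(
    term = c("lambda_ref", "dispersion", "galvo_gain", "tilt_shift_prefactor",
             "y_ref", "x_ref", "galvo_ref"),
    estimate = c(x$lambda_ref, x$dispersion, x$galvo_gain,
                 x$tilt_shift_prefactor, x$y_ref, x$x_ref, x$galvo_ref),
    unit = c("nm", "nm/px", "nm/galvo-unit", "px/px", "px", "px", "galvo-unit")
  )
}

#' Serialize / deserialize a calibration model as YAML
#'
#' The document stores every model field plus a free-form provenance block
#' (source frames, date, notes).
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @param provenance Optional named list recorded verbatim.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the model with a `provenance` attribute.
#' @export
write_calibration <- function(model, path, provenance = list()) {
  stopifnot(inherits(model, "calibration_model"))
  doc <- c(unclass(model), list(provenance = provenance))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("lambda_ref", "dispersion", "galvo_gain", "tilt_shift_prefactor",
            "y_ref", "x_ref", "galvo_ref")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("calibration file lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- do.call(calibration_model, doc[need])
  attr(m, "provenance") <- doc$provenance
  m
}
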