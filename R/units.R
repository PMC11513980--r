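#' Convert an emission wavelength to a Raman shift
#'
#' Standard wavenumber conversion for Stokes/anti-Stokes scattering,
#' \eqn{\Delta\tilde\nu = 10^7 (1/\lambda_{exc} - 1/\lambda)} with both
#' wavelengths in nm and the shift in cm\eqn{^{-1}}.
#'
#' @param lambda_nm Emission wavelength(s) in nm.
#' @param excitation_nm Excitation wavelength in nm (default 660).
#' @return Raman shift(s) in cm^-1; negative for anti-Stokes wavelengths.
#' @examples
#' wavelength_to_shift(860, 660) # ~3523 cm^-1
#' @export
wavelength_to_shift <- function(lambda_nm, excitation_nm = 660) {
  if (any(!is.finite(lambda_nm)) || any(lambda_nm <= 0))
    stop("wavelengths must be positive and finite", call. = FALSE)
  if (any(!is.finite(excitation_nm)) || any(excitation_nm <= 0))
    stop("excitation wavelength must be positive and finite", call. = FALSE)
  1e7 * (1 / excitation_nm - 1 / lambda_nm)
}

#' Convert a Raman shift to an emission wavelength
#'
#' Exact inverse of [wavelength_to_shift()].
#'
#' @param shift_cm1 Raman shift(s) in cm^-1.
#' @param excitation_nm Excitation wavelength in nm (default 660).
#' @return Wavelength(s) in nm.
#' @export
shift_to_wavelength <- function(shift_cm1, excitation_nm = 660) {
  if (any(!is.finite(excitation_nm)) || any(excitation_nm <= 0))
    stop("excitation wavelength must be positive and finite", call. = FALSE)
  pole <- 1e7 / excitation_nm
  if (any(shift_cm1 >= pole))
    stop("shift at or beyond the 1/lambda pole (", round(pole), " cm^-1)", call. = FALSE)
  1 / (1 / excitation_nm - shift_cm1 * 1e-7)
}

#' Convert a spectral FWHM from nm to cm^-1 at a given Raman shift
#'
#' A bandwidth \eqn{\Delta\lambda} at wavelength \eqn{\lambda} corresponds to
#' \eqn{\Delta\tilde\nu = 10^7 \Delta\lambda / \lambda^2}; the width in
#' wavenumbers therefore shrinks as the Stokes wavelength grows, so a fixed
#' 6 nm resolution is ~88 cm^-1 near 3000 cm^-1 but ~110 cm^-1 at 1600 cm^-1
#' (660 nm excitation).
#'
#' @param delta_lambda_nm Spectral width in nm (>= 0).
#' @param shift_cm1 Raman shift at which the width is evaluated.
#' @param excitation_nm Excitation wavelength in nm.
#' @return Width in cm^-1.
#' @export
fwhm_nm_to_cm1 <- function(delta_lambda_nm, shift_cm1, excitation_nm = 660) {
  if (any(delta_lambda_nm < 0))
    stop("spectral width must be nonnegative", call. = FALSE)
  lambda <- shift_to_wavelength(shift_cm1, excitation_nm)
  delta_lambda_nm * 1e7 / lambda^2
}

#' Peak power density of a Gaussian beam
#'
#' For a 2D Gaussian beam of total power P and full width at half maximum w,
#' the on-axis intensity is \eqn{I_0 = 4 \ln 2 \, P / (\pi w^2)}. With 248 mW
#' in a 10 um FWHM beam this gives ~2.2 mW/um^2.
#'
#' @param power_mw Total beam power in mW.
#' @param fwhm_um Beam FWHM in um.
#' @return Peak intensity in mW/um^2.
#' @export
gaussian_peak_intensity <- function(power_mw, fwhm_um) {
  if (any(power_mw < 0) || any(fwhm_um <= 0))
    stop("power must be >= 0 and FWHM > 0", call. = FALSE)
  4 * log(2) * power_mw / (pi * fwhm_um^2)
}

#' Acquisition-rate arithmetic
#'
#' @param exposure_s Camera exposure per frame in seconds.
#' @return `frames_per_second()`: frame rate in Hz. `frames_per_step()`:
#'   number of whole frames acquired while the stage dwells at one y
#'   position.
#' @export
frames_per_second <- function(exposure_s) {
  if (any(exposure_s <= 0)) stop("exposure must be positive", call. = FALSE)
  1 / exposure_s
}

#' @rdname frames_per_second
#' @param dwell_s Stage dwell time per y step in seconds.
#' @export
frames_per_step <- function(dwell_s, exposure_s) {
  if (any(dwell_s < 0)) stop("dwell time must be nonnegative", call. = FALSE)
  round(dwell_s / exposure_s)
}
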