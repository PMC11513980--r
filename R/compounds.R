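#' Define a compound's Raman spectrum model
#'
#' A compound is modelled as a sum of Gaussian peaks on a smooth, broad
#' autofluorescence baseline:
#' \deqn{I(s) = \sum_k a_k \exp(-4\ln 2\,(s - c_k)^2 / w_k^2) + b(s)}
#' with the baseline \eqn{b(s) = A \exp(-((s - c_b)/w_b)^2)} a low-order
#' smooth bump. Gaussian (rather than Voigt) peak shapes are adequate at the
#' instrument's 88-200 cm^-1 resolution.
#'
#' @param name Compound name.
#' @param peaks Data frame with columns `center` (cm^-1, within 0-3600),
#'   `fwhm` (> 0) and `amplitude` (>= 0).
#' @param baseline_amplitude Baseline height, arbitrary units.
#' @param baseline_center,baseline_width Centre and Gaussian width of the
#'   baseline bump, cm^-1.
#' @return An object of class `compound_def`.
#' @export
compound_def <- function(name, peaks, baseline_amplitude = 0,
                         baseline_center = 1300, baseline_width = 2200) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("center", "fwhm", "amplitude") %in% names(peaks)) ||
              nrow(peaks) == 0)
  if (nrow(peaks)) {
    stopifnot(all(peaks$center >= 0 & peaks$center <= 3600),
              all(peaks$fwhm > 0), all(peaks$amplitude >= 0))
  }
  stopifnot(baseline_amplitude >= 0)
  structure(list(name = name, peaks = peaks,
                 baseline_amplitude = baseline_amplitude,
                 baseline_center = baseline_center,
                 baseline_width = baseline_width),
            class = "compound_def")
}

pk <- function(center, fwhm, amplitude) {
  tibble::tibble(center = center, fwhm = fwhm, amplitude = amplitude)
}

#' Built-in compound spectral library
#'
#' Reference spectral models for the three microplastics (polystyrene PS,
#' poly(methyl methacrylate) PMMA, polyamide-6 PA6), the embedding medium
#' (agarose) and the imaging dish, and for the tissue constituents used in
#' the zebrafish experiments (collagen 960/1330/1670, carotenoids 1160/1525,
#' lipids 1450/2880, protein 2930, and the broad ~3240 cm^-1 water band).
#' Major band positions follow the polymer/tissue Raman literature; minor
#' polymer bands are included so that spectra show realistic peak counts for
#' the rule-based training-spectrum selection.
#'
#' @return Named list of [compound_def()] objects.
#' @export
compound_library <- function() {
  list(
    PS = compound_def("PS", rbind(
      pk(795, 45, 0.25), pk(1001, 35, 1.00), pk(1031, 35, 0.45),
      pk(1155, 45, 0.20), pk(1602, 45, 0.50),
      pk(2904, 70, 0.85), pk(3054, 60, 0.55)),
      baseline_amplitude = 0.06),
    PMMA = compound_def("PMMA", rbind(
      pk(602, 45, 0.30), pk(812, 45, 0.90), pk(988, 45, 0.25),
      pk(1240, 55, 0.20), pk(1450, 55, 0.55), pk(1730, 45, 0.60),
      pk(2950, 80, 1.00)),
      baseline_amplitude = 0.06),
    PA6 = compound_def("PA6", rbind(
      pk(960, 45, 0.25), pk(1065, 45, 0.30), pk(1130, 45, 0.55),
      pk(1440, 55, 0.70), pk(1635, 50, 0.35),
      pk(2900, 80, 1.00), pk(3300, 90, 0.35)),
      baseline_amplitude = 0.06),
    agarose = compound_def("agarose", rbind(
      pk(890, 55, 0.30), pk(1083, 60, 0.25), pk(1380, 70, 0.15),
      pk(2910, 110, 0.40)),
      baseline_amplitude = 0.10),
    dish = compound_def("dish", rbind(
      pk(1090, 320, 0.25), pk(2930, 260, 0.15)),
      baseline_amplitude = 0.45, baseline_center = 1500,
      baseline_width = 2600),
    collagen = compound_def("collagen", rbind(
      pk(960, 50, 0.55), pk(1330, 60, 0.50), pk(1670, 60, 0.80),
      pk(2930, 90, 0.45)),
      baseline_amplitude = 0.10),
    carotenoids = compound_def("carotenoids", rbind(
      pk(1160, 45, 0.90), pk(1525, 45, 1.00)),
      baseline_amplitude = 0.20),
    lipids = compound_def("lipids", rbind(
      pk(1300, 60, 0.30), pk(1450, 55, 0.50), pk(2852, 70, 0.90),
      pk(2880, 70, 0.80)),
      baseline_amplitude = 0.05),
    protein = compound_def("protein", rbind(
      pk(1004, 40, 0.25), pk(1450, 60, 0.35), pk(1660, 65, 0.45),
      pk(2930, 90, 1.00)),
      baseline_amplitude = 0.08),
    water = compound_def("water", rbind(
      pk(3240, 420, 1.00), pk(1640, 180, 0.12)),
      baseline_amplitude = 0.02)
  )
}

#' Evaluate a compound's model intensity at arbitrary Raman shifts
#'
#' @param def A [compound_def()].
#' @param shift_cm1 Numeric vector (or matrix) of Raman shifts.
#' @return Intensities with the same shape as `shift_cm1`.
#' @export
compound_intensity <- function(def, shift_cm1) {
  stopifnot(inherits(def, "compound_def"))
  out <- def$baseline_amplitude *
    exp(-((shift_cm1 - def$baseline_center) / def$baseline_width)^2)
  if (nrow(def$peaks)) {
    for (i in seq_len(nrow(def$peaks))) {
      out <- out + def$peaks$amplitude[i] *
        exp(-4 * log(2) * (shift_cm1 - def$peaks$center[i])^2 /
              def$peaks$fwhm[i]^2)
    }
  }
  out
}

#' Render a compound definition as a spectrum on a uniform grid
#'
#' @param def A [compound_def()].
#' @param grid Uniform Raman-shift grid in cm^-1 (default 0-3500 in 20 cm^-1
#'   steps, the instrument's working resolution).
#' @return Tibble with columns `shift_cm1`, `intensity`, `label`.
#' @export
make_spectrum <- function(def, grid = seq(0, 3500, by = 20)) {
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  steps <- diff(grid)
  if (max(steps) - min(steps) > 1e-9 * max(abs(grid)))
    stop("grid must be uniform", call. = FALSE)
  tibble::tibble(shift_cm1 = grid,
                 intensity = compound_intensity(def, grid),
                 label = def$name)
}
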