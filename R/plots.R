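#' Plot spectra
#'
#' Line plot of one or many spectra; colour by `label` or `x_prime` when
#' present.
#'
#' @param spectra Tibble with `shift_cm1`, `intensity` and optional
#'   `label`/`x_prime` columns.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra) {
  spectra <- tibble::as_tibble(spectra)
  aes <- if ("label" %in% names(spectra)) {
    ggplot2::aes(.data$shift_cm1, .data$intensity, colour = .data$label)
  } else if ("x_prime" %in% names(spectra)) {
    ggplot2::aes(.data$shift_cm1, .data$intensity,
                 group = .data$x_prime, colour = .data$x_prime)
  } else ggplot2::aes(.data$shift_cm1, .data$intensity)
  ggplot2::ggplot(spectra, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a band-intensity map
#'
#' @param map Tibble from [band_intensity_map()] with `y` (or one spatial
#'   axis) and `x_prime` coordinates.
#' @return A ggplot raster.
#' @export
plot_band_map <- function(map) {
  m <- tibble::as_tibble(map)
  stopifnot(all(c("x_prime", "intensity") %in% names(m)))
  ycol <- if ("y" %in% names(m)) "y" else "x_prime"
  ggplot2::ggplot(m, ggplot2::aes(.data$x_prime, .data[[ycol]],
                                  fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x' (px)", y = ycol,
                  fill = unique(m$band)[1] %||% "intensity") +
    ggplot2::theme_minimal()
}

#' Plot a false-colour composite
#'
#' @param rgb Tibble with coordinates and `r`, `g`, `b`.
#' @return A ggplot raster using the literal RGB values.
#' @export
plot_false_color <- function(rgb) {
  m <- tibble::as_tibble(rgb)
  xcol <- intersect(c("x_prime", "x", "col"), names(m))[1]
  ycol <- intersect(c("y", "row"), names(m))[1]
  m$fill <- grDevices::rgb(m$r, m$g, m$b)
  ggplot2::ggplot(m, ggplot2::aes(.data[[xcol]], .data[[ycol]])) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Autoplot methods
#'
#' `kymograph`: time-by-x' raster with the retained-column mask;
#' `raman_cnn`: training-loss curve; `phase_match`: correlation profile
#' with selected peaks.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kymograph <- function(object, ...) {
  df <- tibble::tibble(
    t = rep(seq_len(nrow(object$values)), ncol(object$values)),
    x_prime = rep(seq_len(ncol(object$values)) - 1, each = nrow(object$values)),
    intensity = as.numeric(object$values),
    retained = rep(object$mask, each = nrow(object$values)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_prime, .data$t,
                                   fill = .data$intensity,
                                   alpha = .data$retained)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25)) +
    ggplot2::labs(x = "x' (px)", y = "frame") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kymograph
#' @export
autoplot.raman_cnn <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "training cross-entropy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kymograph
#' @export
autoplot.phase_match <- function(object, ...) {
  prof <- attr(object, "profile")
  df <- tibble::tibble(v = seq_along(prof), score = prof)
  ggplot2::ggplot(df, ggplot2::aes(.data$v, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble::tibble(v = object$row,
                                              score = object$score),
                        colour = "red") +
    ggplot2::labs(x = "kymograph frame", y = "normalised correlation") +
    ggplot2::theme_minimal()
}
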