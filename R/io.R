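#' Write / read a frame series as multi-page TIFF plus YAML sidecar
#'
#' Frames are stored as 32-bit float TIFF pages scaled into [0, 1] by the
#' series maximum; the scale factor and all acquisition metadata (exposure,
#' galvo setting, per-frame stage positions and timestamps) live in a YAML
#' sidecar at `<path>.yaml`. Reading validates the sidecar schema and
#' monotone timestamps.
#'
#' @param series A [frame_series()].
#' @param path TIFF file path.
#' @param provenance Optional named list recorded in the sidecar.
#' @return `write_frame_series()` returns `path` invisibly;
#'   `read_frame_series()` returns a [frame_series()].
#' @export
write_frame_series <- function(series, path, provenance = list()) {
  stopifnot(inherits(series, "frame_series"))
  nt <- n_frames(series)
  mx <- max(abs(series$frames), 1e-12)
  pages <- lapply(seq_len(nt), function(i)
    pmin(pmax(series$frames[i, , ] / mx, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(scale = mx, exposure = series$exposure,
               galvo_y = series$galvo_y,
               stage_y = as.numeric(series$stage_y),
               timestamps = as.numeric(series$timestamps),
               n_frames = nt, provenance = provenance)
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' @rdname write_frame_series
#' @export
read_frame_series <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("metadata sidecar missing: ", sc, call. = FALSE)
  meta <- yaml::read_yaml(sc)
  need <- c("scale", "exposure", "galvo_y", "stage_y", "timestamps")
  absent <- setdiff(need, names(meta))
  if (length(absent))
    stop("frame-series metadata lacks field(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * meta$scale
  frame_series(arr, exposure = meta$exposure, galvo_y = meta$galvo_y,
               stage_y = unlist(meta$stage_y),
               timestamps = unlist(meta$timestamps))
}

#' Provenance block for output files
#'
#' Hash of the configuration, the seed, package version and a label;
#' embedded in CSV headers and YAML outputs so any result can be
#' regenerated from its inputs.
#'
#' @param config Named list of every parameter that shaped the output.
#' @param seed RNG seed used.
#' @param label Free-text stage label.
#' @return Named list with `config_hash`, `seed`, `version`, `label`.
#' @export
provenance_block <- function(config = list(), seed = NA_integer_,
                             label = "") {
  list(config_hash = rlang::hash(config), seed = seed,
       version = as.character(utils::packageVersion("lsraman")),
       label = label)
}

#' Write / read spectra as CSV with a provenance header
#'
#' Columns `shift_cm1`, `intensity` and optionally `label`; the provenance
#' block is stored in leading `#`-comment lines.
#'
#' @param spectra Data frame with at least `shift_cm1`, `intensity`.
#' @param path CSV path.
#' @param provenance Named list (e.g. [provenance_block()]).
#' @return The path, invisibly / the tibble.
#' @export
write_spectra_csv <- function(spectra, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(sprintf("# %s: %s", nm, format(provenance[[nm]])), con)
  write.csv(spectra, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  tibble::as_tibble(read.csv(path, comment.char = "#"))
}

#' Read a reference-peak table
#'
#' CSV with columns `compound`, `shift_cm1`.
#'
#' @param path CSV path.
#' @export
read_reference_peaks <- function(path) {
  df <- tibble::as_tibble(read.csv(path, comment.char = "#"))
  if (!all(c("compound", "shift_cm1") %in% names(df)))
    stop("reference peak table needs columns compound, shift_cm1", call. = FALSE)
  df
}

#' Write an intensity map as TIFF / an RGB composite as PNG
#'
#' @param map Matrix, or tibble with `y`/`x_prime` (or `x`) coordinates and
#'   `intensity`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  m <- map_to_matrix(map, "intensity")
  mx <- max(abs(m), 1e-12)
  tiff::writeTIFF(pmin(pmax(m / mx, 0), 1), path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_map_tiff
#' @param rgb Tibble with coordinates and `r`, `g`, `b` in [0, 1] (from
#'   [compose_false_color()] or [render_classification()]).
#' @export
write_rgb_png <- function(rgb, path) {
  r <- map_to_matrix(rgb, "r"); g <- map_to_matrix(rgb, "g")
  b <- map_to_matrix(rgb, "b")
  arr <- array(0, c(nrow(r), ncol(r), 3))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  png::writePNG(pmin(pmax(arr, 0), 1), path)
  invisible(path)
}

map_to_matrix <- function(map, value_col) {
  if (is.matrix(map)) return(map)
  m <- tibble::as_tibble(map)
  xcol <- intersect(c("x_prime", "x", "col"), names(m))[1]
  ycol <- intersect(c("y", "row"), names(m))[1]
  if (is.na(xcol) || is.na(ycol))
    stop("cannot identify coordinate columns in map", call. = FALSE)
  xs <- sort(unique(m[[xcol]])); ys <- sort(unique(m[[ycol]]))
  out <- matrix(0, length(ys), length(xs))
  out[cbind(match(m[[ycol]], ys), match(m[[xcol]], xs))] <- m[[value_col]]
  out
}

#' Write a phase table as CSV
#'
#' @param phase_table Tibble (e.g. from [reconstruct_cycle()]).
#' @param path CSV path.
#' @param provenance Named list.
#' @export
write_phase_table <- function(phase_table, path, provenance = list()) {
  write_spectra_csv(phase_table, path, provenance)
}
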