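#' Raw spectral M-scan
#'
#' One lateral position's block of repeated spectrometer readouts:
#' a `[spectrometer pixel x time]` matrix of non-negative interferogram
#' counts, the per-pixel wavelength calibration and the acquisition config.
#'
#' @param spectra Numeric matrix, spectrometer pixel by time sample.
#' @param wavelength_grid Strictly monotonic per-pixel wavelength, nm.
#' @param config An [acq_config()]. Its `n_repeats` must equal `ncol(spectra)`
#'   and `n_spectrometer_pixels` must equal `nrow(spectra)`.
#' @return An object of class `raw_mscan`.
#' @export
raw_mscan <- function(spectra, wavelength_grid, config) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelength_grid <- as.numeric(wavelength_grid)
  validate_acq_config(config)
  if (nrow(spectra) != length(wavelength_grid)) {
    stop("raw_mscan: wavelength_grid length must equal nrow(spectra)",
         call. = FALSE)
  }
  if (nrow(spectra) != config$n_spectrometer_pixels) {
    stop("raw_mscan: nrow(spectra) does not match config$n_spectrometer_pixels",
         call. = FALSE)
  }
  if (ncol(spectra) != config$n_repeats) {
    stop("raw_mscan: time dimension must have length config$n_repeats",
         call. = FALSE)
  }
  if (any(spectra < 0)) {
    stop("raw_mscan: spectra must be non-negative", call. = FALSE)
  }
  d <- diff(wavelength_grid)
  if (!(all(d > 0) || all(d < 0))) {
    stop("raw_mscan: wavelength_grid must be strictly monotonic", call. = FALSE)
  }
  structure(list(spectra = spectra, wavelength_grid = wavelength_grid,
                 config = config),
            class = "raw_mscan")
}

#' @export
print.raw_mscan <- function(x, ...) {
  cat(sprintf("raw_mscan: %d spectrometer pixels x %d time samples, %g-%g nm\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavelength_grid), max(x$wavelength_grid)))
  invisible(x)
}

#' Complex reconstructed M-scan
#'
#' Depth-resolved complex field over time for one lateral position, as
#' produced by [chirpz_to_depth()].
#'
#' @param field Complex matrix, depth pixel by time sample.
#' @param depth_grid Uniform, increasing physical depth per pixel, um.
#' @param config The [acq_config()] the data were acquired with.
#' @return An object of class `complex_mscan`.
#' @export
complex_mscan <- function(field, depth_grid, config) {
  field <- as.matrix(field)
  depth_grid <- as.numeric(depth_grid)
  validate_acq_config(config)
  if (nrow(field) != length(depth_grid)) {
    stop("complex_mscan: depth_grid length must equal nrow(field)", call. = FALSE)
  }
  d <- diff(depth_grid)
  if (length(d) && (any(d <= 0) ||
                    (max(d) - min(d)) > 1e-6 * max(abs(d)))) {
    stop("complex_mscan: depth_grid must be uniform and increasing", call. = FALSE)
  }
  structure(list(field = field, depth_grid = depth_grid, config = config),
            class = "complex_mscan")
}

#' Image volume (OCT intensity or PT-OCT amplitude)
#'
#' A `[depth x lateral x bscan]` array with its axial pixel size and a kind
#' tag. Depth index 1 is zero optical delay; depth increases downward
#' (toward the choroid in retinal data). PT-OCT volumes are in nm of optical
#' path length and must be non-negative.
#'
#' @param values 3-D numeric array, depth x lateral x B-scan. A matrix is
#'   promoted to a single-B-scan volume.
#' @param pixel_size_z Axial pixel size, um per pixel.
#' @param kind `"oct_log_intensity"` or `"ptoct_nm"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, pixel_size_z,
                         kind = c("oct_log_intensity", "ptoct_nm")) {
  kind <- match.arg(kind)
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L, is.numeric(values))
  if (!is.finite(pixel_size_z) || pixel_size_z <= 0) {
    stop("image_volume: pixel_size_z must be positive", call. = FALSE)
  }
  if (kind == "ptoct_nm" && any(values < 0, na.rm = TRUE)) {
    stop("image_volume: ptoct_nm values must be >= 0", call. = FALSE)
  }
  structure(list(values = values, pixel_size_z = as.numeric(pixel_size_z),
                 kind = kind),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("image_volume [%s]: %d depth x %d lateral x %d B-scans, %.3g um/px\n",
              x$kind, d[1], d[2], d[3], x$pixel_size_z))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Boolean raster congruent with an [image_volume()]; used to restrict
#' lesion statistics to a manually selected region.
#'
#' @param mask Logical array (or matrix, promoted to one B-scan).
#' @param label Free-text label for the region.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "roi") {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  stopifnot(length(dim(mask)) == 3L)
  mask <- array(as.logical(mask), dim(mask))
  if (anyNA(mask)) stop("roi_mask: mask may not contain NA", call. = FALSE)
  structure(list(mask = mask, label = as.character(label)[1]),
            class = "roi_mask")
}

stop_if_incongruent <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop("dimension mismatch: ", what, " have shapes ",
         paste(dim(a), collapse = "x"), " and ",
         paste(dim(b), collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}
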