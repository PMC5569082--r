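#' Export co-registered OCT / PT-OCT images as TIFF stacks
#'
#' Writes three 32-bit float TIFF stacks (one page per B-scan): the OCT
#' intensity in grayscale, the PT-OCT amplitude, and an RGB composite in
#' which the PT-OCT signal occupies the green channel over the grayscale
#' OCT, scaled to a display range recorded in the sidecar metadata. The
#' default display range is `[0, 99th percentile]` of the PT-OCT volume.
#'
#' @param oct,ptoct Congruent [image_volume()]s (`oct_log_intensity` and
#'   `ptoct_nm`).
#' @param path_prefix Output path prefix; `<prefix>_oct.tif`,
#'   `<prefix>_ptoct.tif`, `<prefix>_overlay.tif` and `<prefix>_meta.yaml`
#'   are written.
#' @param roi Optional [roi_mask()]; drawn as a thin outline in the red
#'   channel of the overlay.
#' @param display_range Length-2 PT-OCT display range in nm, or `NULL` for
#'   the default.
#' @return Invisibly, a list with the file paths and the display range used.
#' @export
export_images <- function(oct, ptoct, path_prefix, roi = NULL,
                          display_range = NULL) {
  stopifnot(inherits(oct, "image_volume"), inherits(ptoct, "image_volume"))
  stop_if_incongruent(oct$values, ptoct$values, "OCT and PT-OCT volumes")
  if (!is.null(roi)) {
    stop_if_incongruent(oct$values, roi$mask, "volume and ROI mask")
  }
  if (is.null(display_range)) {
    hi <- stats::quantile(ptoct$values, 0.99, names = FALSE)
    display_range <- c(0, if (hi > 0) hi else 1)
  }
  stopifnot(length(display_range) == 2, display_range[2] > display_range[1])

  norm01 <- function(v, rng) pmin(pmax((v - rng[1]) / (rng[2] - rng[1]), 0), 1)
  d <- dim(oct$values)
  oct_rng <- range(oct$values)
  if (diff(oct_rng) == 0) oct_rng <- oct_rng + c(0, 1)
  oct_n <- norm01(oct$values, oct_rng)
  pt_n <- norm01(ptoct$values, display_range)

  paths <- paste0(path_prefix, c("_oct.tif", "_ptoct.tif", "_overlay.tif",
                                 "_meta.yaml"))
  as_pages <- function(a) lapply(seq_len(d[3]), function(b) a[, , b])
  tiff::writeTIFF(as_pages(oct_n), paths[1], bits.per.sample = 32L)
  tiff::writeTIFF(as_pages(pt_n), paths[2], bits.per.sample = 32L)
  overlay <- lapply(seq_len(d[3]), function(b) {
    rgb <- array(0, c(d[1], d[2], 3))
    rgb[, , 1] <- oct_n[, , b]
    rgb[, , 2] <- pmin(oct_n[, , b] + pt_n[, , b], 1)
    rgb[, , 3] <- oct_n[, , b]
    if (!is.null(roi)) {
      edge <- roi$mask[, , b] &
        !(rbind(roi$mask[-1, , b], FALSE) & rbind(FALSE, roi$mask[-d[1], , b]) &
            cbind(roi$mask[, -1, b], FALSE) & cbind(FALSE, roi$mask[, -d[2], b]))
      rgb[, , 1][edge] <- 1
    }
    rgb
  })
  tiff::writeTIFF(overlay, paths[3], bits.per.sample = 32L)
  meta <- list(ptoct_display_range_nm = as.numeric(display_range),
               oct_display_range = as.numeric(oct_rng),
               pixel_size_z_um = oct$pixel_size_z,
               depth_convention = "index 1 = zero optical delay, increasing downward",
               n_bscans = d[3])
  yaml::write_yaml(meta, paths[4])
  invisible(list(oct = paths[1], ptoct = paths[2], overlay = paths[3],
                 meta = paths[4], display_range = display_range))
}

#' Re-read an exported PT-OCT TIFF in nm
#'
#' Inverts the display scaling recorded in the export's metadata sidecar.
#'
#' @param path `_ptoct.tif` path written by [export_images()].
#' @param meta_path Its `_meta.yaml` sidecar.
#' @return An [image_volume()] in nm (values clipped to the display range).
#' @export
read_ptoct_tiff <- function(path, meta_path) {
  meta <- yaml::read_yaml(meta_path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  rng <- meta$ptoct_display_range_nm
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    arr[, , i] <- pages[[i]] * (rng[2] - rng[1]) + rng[1]
  }
  image_volume(arr, meta$pixel_size_z_um, "ptoct_nm")
}
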