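#' Analysis configuration for ROI quantification
#'
#' @param area_threshold Minimum total lesion mask area (pixels, summed
#'   over B-scans) for a lesion to be included in group statistics.
#' @param background_margin Pixels added on each side of the half-maximum
#'   band before computing background statistics.
#' @param power_levels Photothermal powers of a power-series experiment, mW.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(area_threshold = 40000, background_margin = 1,
                            power_levels = c(0.4, 1, 2, 4, 8, 10)) {
  stopifnot(area_threshold > 0, background_margin >= 0)
  structure(list(area_threshold = area_threshold,
                 background_margin = background_margin,
                 power_levels = power_levels),
            class = "analysis_config")
}

#' Mean axial PT-OCT profile of a B-scan
#'
#' Mean signal per depth over the A-scans of one B-scan, excluding flagged
#' (vacated / corrupted / low-SNR) pixels.
#'
#' @param bscan Matrix `[depth x lateral]`, nm.
#' @param valid Optional logical matrix of the same shape; `FALSE` pixels
#'   are excluded from the mean.
#' @return Numeric vector, one mean per depth (NaN where no valid pixel).
#' @export
axial_profile <- function(bscan, valid = NULL) {
  stopifnot(is.matrix(bscan), ncol(bscan) >= 1)
  if (is.null(valid)) return(rowMeans(bscan))
  stop_if_incongruent(bscan, valid, "B-scan and validity mask")
  num <- rowSums(bscan * valid)
  den <- rowSums(valid)
  num / den
}

#' Peak and full width at half maximum of an axial profile
#'
#' Locates the global maximum (center of the plateau if tied) and the
#' contiguous band around it where the profile stays at or above half the
#' maximum, with linear sub-pixel interpolation of the two half-maximum
#' crossings. The band edges are truncated (with a warning) when the
#' profile never falls below half maximum on one side.
#'
#' @param profile Numeric vector (nm per depth pixel).
#' @param depth_grid Optional depth coordinate per pixel (um); defaults to
#'   pixel indices.
#' @return A `layer_metrics` list: `peak_depth`, `peak_value`, `fwhm`,
#'   `band` (length-2, same units as `depth_grid`), `peak_index`.
#' @export
find_peak_fwhm <- function(profile, depth_grid = seq_along(profile)) {
  stopifnot(length(profile) == length(depth_grid), length(profile) >= 3)
  fin <- is.finite(profile)
  if (!any(fin)) stop("find_peak_fwhm: profile has no finite values", call. = FALSE)
  pmax_val <- max(profile[fin])
  if (pmax_val <= 0) {
    stop("find_peak_fwhm: profile has no positive peak", call. = FALSE)
  }
  peaks <- which(fin & profile == pmax_val)
  ipk <- peaks[ceiling(length(peaks) / 2)]   # center of a plateau
  half <- pmax_val / 2
  n <- length(profile)

  cross <- function(side) {
    idx <- if (side == "left") ipk:1 else ipk:n
    below <- which(profile[idx] < half | !fin[idx])
    if (!length(below)) {
      warning("find_peak_fwhm: no half-maximum crossing on the ", side,
              " side; band truncated at the profile edge")
      return(depth_grid[idx[length(idx)]])
    }
    i_out <- idx[below[1]]                  # first pixel below half
    i_in <- idx[below[1] - 1]               # last pixel at/above half
    frac <- (profile[i_in] - half) / (profile[i_in] - profile[i_out])
    depth_grid[i_in] + frac * (depth_grid[i_out] - depth_grid[i_in])
  }
  lo <- cross("left")
  hi <- cross("right")
  structure(list(peak_depth = depth_grid[ipk], peak_value = pmax_val,
                 fwhm = abs(hi - lo), band = sort(c(lo, hi)),
                 peak_index = ipk),
            class = "layer_metrics")
}

#' Background statistics outside the layer band
#'
#' Mean profile value outside the half-maximum band (dilated by a margin),
#' and the peak-to-background ratio (band maximum over the background
#' mean). The ratio is `NA` (undefined) when the background mean is zero.
#'
#' @param profile Numeric vector (nm).
#' @param band Length-2 band from [find_peak_fwhm()], same coordinate
#'   system as `depth_grid`.
#' @param depth_grid Depth coordinate per pixel.
#' @param margin Margin added to both band edges (same units as
#'   `depth_grid`).
#' @return List: `mean_background` (nm), `peak_to_background`
#'   (dimensionless or `NA`), `n_background` (pixels used).
#' @export
background_stats <- function(profile, band, depth_grid = seq_along(profile),
                             margin = 1) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  fin <- is.finite(profile)
  inside <- depth_grid >= band[1] - margin & depth_grid <= band[2] + margin
  outside <- !inside & fin
  if (!any(outside)) {
    stop("background_stats: no pixels outside the band and margin", call. = FALSE)
  }
  in_band <- depth_grid >= band[1] & depth_grid <= band[2] & fin
  mb <- mean(profile[outside])
  pk <- max(profile[in_band])
  list(mean_background = mb,
       peak_to_background = if (mb > 0) pk / mb else NA_real_,
       n_background = sum(outside))
}

#' Lesion-ROI mean PT-OCT signal
#'
#' Mean PT-OCT amplitude per voxel inside a lesion mask, with the study's
#' inclusion filter: the lesion is included when its total mask area
#' (pixels summed over B-scans) strictly exceeds the configured threshold.
#'
#' @param ptoct An [image_volume()] of kind `ptoct_nm`.
#' @param roi An [roi_mask()] congruent with it.
#' @param config An [analysis_config()].
#' @param eye_id,group Labels carried into the summary.
#' @return A `lesion_summary` data.frame row: `eye_id`, `group`,
#'   `mean_signal` (nm), `roi_voxels`, `roi_area`, `included`.
#' @export
lesion_mean <- function(ptoct, roi, config = analysis_config(),
                        eye_id = "eye", group = "gnr") {
  stopifnot(inherits(ptoct, "image_volume"), inherits(roi, "roi_mask"))
  stop_if_incongruent(ptoct$values, roi$mask, "PT-OCT volume and ROI mask")
  nvox <- sum(roi$mask)
  if (nvox == 0) stop("lesion_mean: empty ROI mask", call. = FALSE)
  area <- nvox   # total mask pixel count across B-scans
  structure(data.frame(eye_id = eye_id, group = group,
                       mean_signal = sum(ptoct$values[roi$mask]) / nvox,
                       roi_voxels = nvox, roi_area = area,
                       included = area > config$area_threshold),
            class = c("lesion_summary", "data.frame"))
}

#' En-face mean projections and green-channel composite
#'
#' Mean over depth per (lateral, B-scan) position of the OCT and PT-OCT
#' volumes, plus an RGB composite with the PT-OCT projection in the green
#' channel over the normalized grayscale OCT projection.
#'
#' @param oct,ptoct Congruent [image_volume()]s.
#' @param display_range PT-OCT display range, nm (default 99th percentile).
#' @return List: `oct` and `ptoct` projections (`[lateral x bscan]`
#'   matrices) and `composite` (`[lateral x bscan x 3]`).
#' @export
enface_projection <- function(oct, ptoct, display_range = NULL) {
  stopifnot(inherits(oct, "image_volume"), inherits(ptoct, "image_volume"))
  stop_if_incongruent(oct$values, ptoct$values, "OCT and PT-OCT volumes")
  po <- apply(oct$values, c(2, 3), mean)
  pp <- apply(ptoct$values, c(2, 3), mean)
  if (is.null(display_range)) {
    hi <- stats::quantile(pp, 0.99, names = FALSE)
    display_range <- c(0, if (hi > 0) hi else 1)
  }
  rng_o <- range(po)
  if (diff(rng_o) == 0) rng_o <- rng_o + c(0, 1)
  o_n <- (po - rng_o[1]) / diff(rng_o)
  p_n <- pmin(pmax((pp - display_range[1]) / diff(display_range), 0), 1)
  comp <- array(0, c(dim(po), 3))
  comp[, , 1] <- o_n
  comp[, , 2] <- pmin(o_n + p_n, 1)
  comp[, , 3] <- o_n
  list(oct = po, ptoct = pp, composite = comp,
       display_range = display_range)
}

#' Retina-band mean signal of a PT-OCT volume
#'
#' Per-eye summary used for the pigmented-vs-albino comparison: mean
#' PT-OCT amplitude over the retinal depth band (between inner limiting
#' membrane and choroid proxies).
#'
#' @param ptoct An [image_volume()] (`ptoct_nm`).
#' @param depth_grid Depth per pixel, um.
#' @param band Length-2 depth interval, um.
#' @param valid Optional validity array congruent with the volume.
#' @return Mean signal in nm.
#' @export
retina_band_mean <- function(ptoct, depth_grid, band, valid = NULL) {
  stopifnot(inherits(ptoct, "image_volume"))
  sel <- depth_grid >= band[1] & depth_grid <= band[2]
  if (!any(sel)) stop("retina_band_mean: empty depth band", call. = FALSE)
  v <- ptoct$values[sel, , , drop = FALSE]
  if (is.null(valid)) return(mean(v))
  w <- valid[sel, , , drop = FALSE]
  if (!any(w)) stop("retina_band_mean: no valid pixels in band", call. = FALSE)
  sum(v[w]) / sum(w)
}
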