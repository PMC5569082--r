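#' Write / read a raw-data container
#'
#' Serializes a [raw_mscan()], a `raw_volume` (see [simulate_volume()]) or a
#' plain list of B-scans of M-scans to a single container file, preserving
#' arrays bit-exactly together with all acquisition metadata and, for
#' simulated data, the [phantom_truth] ground truth. The logical layout
#' mirrors the acquisition hierarchy (`bscan_i/mscan_j` with `spectra` and
#' `wavelength_grid` per position, config fields as attributes, optional
#' `truth` group); [read_raw()] validates the layout and re-runs the
#' container-level invariant checks, so a file missing a required component
#' fails with an error naming it.
#'
#' @param x Object to write.
#' @param path File path.
#' @return `write_raw` returns `path` invisibly; `read_raw` returns the
#'   stored object with its classes restored.
#' @export
write_raw <- function(x, path) {
  if (inherits(x, "raw_mscan")) {
    payload <- list(format = "ptoctr-raw", version = 1L, kind = "mscan",
                    bscans = list(list(strip_mscan(x))),
                    config = unclass(x$config), truth = NULL)
  } else if (inherits(x, "raw_volume")) {
    payload <- list(format = "ptoctr-raw", version = 1L, kind = "volume",
                    bscans = lapply(x$bscans, function(b) lapply(b, strip_mscan)),
                    reference = lapply(x$reference, function(b)
                      lapply(b, strip_mscan)),
                    config = unclass(x$config),
                    reference_config = unclass(x$reference_config),
                    truth = if (!is.null(x$truth)) unclass(x$truth) else NULL)
  } else {
    stop("write_raw: expected a raw_mscan or raw_volume", call. = FALSE)
  }
  saveRDS(payload, path, compress = FALSE)
  invisible(path)
}

strip_mscan <- function(m) {
  list(spectra = m$spectra, wavelength_grid = m$wavelength_grid)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  if (!file.exists(path)) {
    stop("read_raw: no such file: ", path, call. = FALSE)
  }
  payload <- readRDS(path)
  if (!identical(payload$format, "ptoctr-raw")) {
    stop("read_raw: not a ptoctr raw container: ", path, call. = FALSE)
  }
  if (is.null(payload$config)) {
    stop("read_raw: format error: missing 'config' attributes", call. = FALSE)
  }
  config <- validate_acq_config(structure(payload$config, class = "acq_config"))
  rebuild <- function(group, cfg, where) {
    if (is.null(group$spectra)) {
      stop("read_raw: format error: missing dataset '", where, "/spectra'",
           call. = FALSE)
    }
    if (is.null(group$wavelength_grid)) {
      stop("read_raw: format error: missing dataset '", where,
           "/wavelength_grid'", call. = FALSE)
    }
    raw_mscan(group$spectra, group$wavelength_grid, cfg)
  }
  bscans <- lapply(seq_along(payload$bscans), function(i) {
    lapply(seq_along(payload$bscans[[i]]), function(j) {
      rebuild(payload$bscans[[i]][[j]], config,
              sprintf("bscan_%d/mscan_%d", i, j))
    })
  })
  if (identical(payload$kind, "mscan")) {
    return(bscans[[1]][[1]])
  }
  ref_config <- validate_acq_config(structure(payload$reference_config,
                                              class = "acq_config"))
  reference <- lapply(seq_along(payload$reference), function(i) {
    lapply(seq_along(payload$reference[[i]]), function(j) {
      rebuild(payload$reference[[i]][[j]], ref_config,
              sprintf("reference/bscan_%d/mscan_%d", i, j))
    })
  })
  truth <- if (!is.null(payload$truth)) {
    structure(payload$truth, class = "phantom_truth")
  }
  structure(list(bscans = bscans, reference = reference, config = config,
                 reference_config = ref_config, truth = truth),
            class = "raw_volume")
}

#' Read / write a result table
#'
#' Result tables hold one row per eye (or per eye and power level) with the
#' summary signal feeding the statistics stage.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @return `read_result_table` returns a data.frame.
#' @export
write_result_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a region-of-interest mask from image or CSV rasters
#'
#' Accepts a PNG (any nonzero pixel is inside the region) or a CSV of 0/1
#' values, one file per B-scan, and stacks them into an [roi_mask()].
#'
#' @param paths Character vector of per-B-scan raster files, in B-scan
#'   order.
#' @param label Label for the mask.
#' @return An [roi_mask()].
#' @export
read_roi_mask <- function(paths, label = "roi") {
  slices <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    if (ext == "png") {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("read_roi_mask: the 'png' package is required for PNG masks",
             call. = FALSE)
      }
      img <- png::readPNG(p)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img > 0
    } else {
      as.matrix(utils::read.csv(p, header = FALSE)) > 0
    }
  })
  d <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), d), logical(1)))) {
    stop("read_roi_mask: all B-scan rasters must share one shape", call. = FALSE)
  }
  arr <- array(FALSE, c(d, length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]
  roi_mask(arr, label)
}
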