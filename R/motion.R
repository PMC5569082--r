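#' Axial shift between an A-scan and its reference by cross-correlation
#'
#' Estimates the vertical (depth) displacement maximizing the normalized
#' cross-correlation between a column and its reference, by FFT-based
#' linear (zero-padded, non-circular) correlation at integer lags, then --
#' if `upsample > 1` -- refined on a local fine grid of fractional lags
#' evaluated directly in the Fourier domain (matrix-multiply DFT around the
#' coarse peak, as in upsampled phase-correlation registration). Columns
#' are mean-centered before correlating so a flat offset carries no weight.
#'
#' @param column Numeric vector (e.g. linear OCT intensity A-scan).
#' @param reference Reference column of equal length.
#' @param upsample Refinement factor; 1 = integer-pixel.
#' @param max_shift Largest |shift| searched, pixels.
#' @return List: `offset` (pixels, positive = column content sits deeper
#'   than reference), `correlation` (normalized peak, in [-1, 1]),
#'   `corrupted` (`TRUE` for degenerate/flat columns, offset `NA`).
#' @export
estimate_shift <- function(column, reference, upsample = 1,
                           max_shift = floor(length(column) / 4)) {
  stopifnot(length(column) == length(reference))
  n <- length(column)
  a <- column - mean(column)
  b <- reference - mean(reference)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    return(list(offset = NA_real_, correlation = 0, corrupted = TRUE))
  }
  L <- stats::nextn(2 * n, 2)
  fa <- stats::fft(c(a, rep(0, L - n)))
  fb <- stats::fft(c(b, rep(0, L - n)))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / L
  # lag k (column shifted down by k relative to reference) lives at index
  # k + 1 (mod L)
  lags <- c(0:(L / 2 - 1), -(L / 2):-1)
  ok <- abs(lags) <= max_shift
  cc_ok <- cc[ok] / (na * nb)
  lag_ok <- lags[ok]
  ibest <- which.max(cc_ok)
  offset <- lag_ok[ibest]
  corr <- cc_ok[ibest]
  if (upsample > 1) {
    fine <- seq(offset - 1, offset + 1, by = 1 / upsample)
    w <- 2 * pi * lags_freq(L) # angular frequencies
    Fprod <- fa * Conj(fb)
    vals <- vapply(fine, function(s) Re(sum(Fprod * exp(1i * w * s))) / L,
                   numeric(1)) / (na * nb)
    ibest <- which.max(vals)
    offset <- fine[ibest]
    corr <- vals[ibest]
  }
  list(offset = offset, correlation = min(corr, 1), corrupted = FALSE)
}

lags_freq <- function(L) {
  c(0:(L / 2 - 1), -(L / 2):-1) / L
}

shift_column <- function(x, offset, fill = 0) {
  n <- length(x)
  if (offset == 0) return(list(values = x, vacated = rep(FALSE, n)))
  if (abs(offset - round(offset)) < 1e-9) {
    k <- as.integer(round(offset))
    out <- rep(fill, n)
    vac <- rep(TRUE, n)
    if (abs(k) < n) {
      if (k > 0) {        # move content up by k (content was k deeper)
        out[1:(n - k)] <- x[(k + 1):n]
        vac[1:(n - k)] <- FALSE
      } else {
        out[(1 - k):n] <- x[1:(n + k)]
        vac[(1 - k):n] <- FALSE
      }
    }
    return(list(values = out, vacated = vac))
  }
  src <- seq_len(n) + offset
  out <- stats::approx(seq_len(n), x, xout = src, rule = 1)$y
  vac <- is.na(out)
  out[vac] <- fill
  list(values = out, vacated = vac)
}

#' Motion-correct one OCT/PT-OCT B-scan pair against a reference
#'
#' Each OCT A-scan is registered axially to the corresponding reference
#' A-scan ([estimate_shift()]); the estimated offset is removed from both
#' the OCT and the PT-OCT column (identical offsets, as the two images are
#' acquired simultaneously). Shifts are non-circular: vacated pixels are
#' zero-filled and flagged so downstream statistics can exclude them.
#' Columns whose normalized correlation falls below `threshold` are flagged
#' corrupted and left for [interpolate_missing()].
#'
#' @param oct_bscan,ptoct_bscan Congruent matrices `[depth x lateral]`.
#' @param reference_bscan Reference OCT B-scan, same shape.
#' @param threshold Correlation below which a column is declared corrupted.
#' @param upsample Subpixel refinement factor (1 = integer offsets, the
#'   default, so the PT-OCT image is never resampled).
#' @param max_shift Passed to [estimate_shift()].
#' @return List of class `motion_corrected`: `oct`, `ptoct` (corrected
#'   matrices), `valid` (logical matrix, FALSE at vacated pixels and in
#'   corrupted columns) and `trace` (a data.frame `motion_trace`:
#'   `offset`, `correlation`, `corrupted` per A-scan).
#' @export
correct_bscan <- function(oct_bscan, ptoct_bscan, reference_bscan,
                          threshold = 0.5, upsample = 1,
                          max_shift = floor(nrow(oct_bscan) / 4)) {
  stop_if_incongruent(oct_bscan, ptoct_bscan, "OCT and PT-OCT B-scans")
  stop_if_incongruent(oct_bscan, reference_bscan, "B-scan and reference")
  n_l <- ncol(oct_bscan)
  oct_out <- oct_bscan
  pt_out <- ptoct_bscan
  valid <- matrix(TRUE, nrow(oct_bscan), n_l)
  offs <- numeric(n_l)
  corr <- numeric(n_l)
  bad <- logical(n_l)
  for (l in seq_len(n_l)) {
    es <- estimate_shift(oct_bscan[, l], reference_bscan[, l],
                         upsample = upsample, max_shift = max_shift)
    if (es$corrupted || es$correlation < threshold) {
      bad[l] <- TRUE
      offs[l] <- NA_real_
      corr[l] <- es$correlation
      valid[, l] <- FALSE
      next
    }
    offs[l] <- if (upsample > 1) es$offset else round(es$offset)
    corr[l] <- es$correlation
    so <- shift_column(oct_bscan[, l], offs[l])
    sp <- shift_column(ptoct_bscan[, l], offs[l])
    oct_out[, l] <- so$values
    pt_out[, l] <- sp$values
    valid[so$vacated, l] <- FALSE
  }
  trace <- structure(data.frame(ascan = seq_len(n_l), offset = offs,
                                correlation = corr, corrupted = bad),
                     class = c("motion_trace", "data.frame"))
  structure(list(oct = oct_out, ptoct = pt_out, valid = valid, trace = trace),
            class = "motion_corrected")
}

#' Fill corrupted A-scans by lateral linear interpolation
#'
#' Each corrupted column is replaced, per depth pixel, by linear
#' interpolation between the nearest valid columns on either side
#' (nearest-valid extension at the image edges).
#'
#' @param bscan Matrix `[depth x lateral]`.
#' @param corrupted Logical vector, one per column.
#' @return Matrix with corrupted columns filled.
#' @export
interpolate_missing <- function(bscan, corrupted) {
  stopifnot(is.matrix(bscan), length(corrupted) == ncol(bscan))
  if (!any(corrupted)) return(bscan)
  if (all(corrupted)) {
    stop("interpolate_missing: all columns corrupted; nothing to interpolate from",
         call. = FALSE)
  }
  good <- which(!corrupted)
  bad <- which(corrupted)
  out <- bscan
  for (z in seq_len(nrow(bscan))) {
    out[z, bad] <- stats::approx(good, bscan[z, good], xout = bad,
                                 rule = 2)$y
  }
  out
}

#' Motion-correct a processed volume
#'
#' Applies [correct_bscan()] B-scan by B-scan using the reference OCT
#' volume, then fills corrupted columns of both volumes with
#' [interpolate_missing()].
#'
#' @param vols A list as returned by [process_volume()] (`oct`, `ptoct`,
#'   `reference_oct`).
#' @param threshold,upsample Passed to [correct_bscan()].
#' @return List: corrected `oct` and `ptoct` [image_volume()]s, `valid`
#'   array, and `traces` (list of per-B-scan `motion_trace`s).
#' @export
correct_volume <- function(vols, threshold = 0.5, upsample = 1) {
  d <- dim(vols$oct$values)
  oct <- vols$oct$values
  pt <- vols$ptoct$values
  valid <- array(TRUE, d)
  traces <- vector("list", d[3])
  for (b in seq_len(d[3])) {
    # register on linear intensity
    mc <- correct_bscan(10^(oct[, , b] / 20), pt[, , b],
                        10^(vols$reference_oct$values[, , b] / 20),
                        threshold = threshold, upsample = upsample)
    octb <- 20 * log10(mc$oct + .Machine$double.eps)
    corrupted <- mc$trace$corrupted
    oct[, , b] <- interpolate_missing(octb, corrupted)
    pt[, , b] <- interpolate_missing(mc$ptoct, corrupted)
    valid[, , b] <- mc$valid | matrix(corrupted, d[1], d[2], byrow = TRUE)
    traces[[b]] <- mc$trace
  }
  list(oct = image_volume(oct, vols$oct$pixel_size_z, "oct_log_intensity"),
       ptoct = image_volume(pt, vols$ptoct$pixel_size_z, "ptoct_nm"),
       valid = valid, traces = traces)
}

#' Write motion traces as CSV
#'
#' @param traces List of per-B-scan `motion_trace` data frames.
#' @param path CSV path.
#' @export
write_motion_trace <- function(traces, path) {
  rows <- do.call(rbind, lapply(seq_along(traces), function(b) {
    cbind(bscan = b, as.data.frame(traces[[b]]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
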