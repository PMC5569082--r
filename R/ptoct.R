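#' Phase time series at one depth pixel
#'
#' Argument of the complex field over time at one depth. No unwrapping is
#' applied; slow drifts are handled by [temporal_derivative()]. A pixel with
#' zero magnitude at any time sample is flagged invalid (its phase is
#' undefined there) and should be excluded downstream.
#'
#' @param cm A [complex_mscan()].
#' @param pixel Depth pixel index.
#' @return List: `phase` (rad, length `n_repeats`), `valid` (logical).
#' @export
phase_series <- function(cm, pixel) {
  stopifnot(inherits(cm, "complex_mscan"),
            pixel >= 1, pixel <= nrow(cm$field))
  f <- cm$field[pixel, ]
  list(phase = Arg(f), valid = all(Mod(f) > 0))
}

#' Wrapped first temporal derivative of a phase series
#'
#' First difference with each increment re-wrapped to `(-pi, pi]`. Constant
#' offsets vanish and linear bulk drift becomes a constant, so the lock-in
#' stage sees only the oscillatory part; increments are immune to 2 pi
#' wrapping as long as the true per-sample change stays below pi.
#'
#' @param phase Phase series, rad (vector) or matrix (`[depth x time]`,
#'   differenced along time).
#' @return Differenced series, one sample shorter in time.
#' @export
temporal_derivative <- function(phase) {
  if (is.matrix(phase)) {
    stopifnot(ncol(phase) >= 2)
    return(wrap_to_pi(phase[, -1, drop = FALSE] -
                        phase[, -ncol(phase), drop = FALSE]))
  }
  stopifnot(length(phase) >= 2)
  wrap_to_pi(diff(phase))
}

# Dirichlet kernel sum W(omega) = sum_{t=0}^{N-1} exp(-1i omega t)
dirichlet_sum <- function(omega, n) {
  out <- complex(length.out = length(omega))
  small <- abs(sin(omega / 2)) < 1e-12
  out[small] <- n
  o <- omega[!small]
  out[!small] <- exp(-1i * o * (n - 1) / 2) * sin(n * o / 2) / sin(o / 2)
  out
}

#' Lock-in amplitude and noise floor at the modulation frequency
#'
#' Reads the photothermal oscillation out of a differenced phase series.
#' The single-sided magnitude spectrum (scaled `2/N`) is formed; the
#' amplitude at the drive is estimated either by an exact single-tone
#' inversion at `f0` (default: solves the two-term Dirichlet window model
#' for the tone's amplitude and phase, exact for one tone of any
#' non-integer number of cycles) or by reading the bin nearest `f0`
#' (`method = "bin"`). The result is divided by the first-difference
#' transfer function `2 sin(pi f0 / fs)` so it is the amplitude of the
#' phase oscillation itself, not of its derivative. The noise floor is the
#' median magnitude over bins excluding DC, `f0` and `2 f0` (each +/- 2
#' bins), converted identically.
#'
#' @param d Differenced phase series (vector, rad) or matrix
#'   (`[depth x time]`; each row processed).
#' @param f0 Modulation frequency, Hz.
#' @param fs Line (sampling) rate, Hz.
#' @param method `"single_tone"` (default) or `"bin"`.
#' @param exclude_halfwidth Bins excluded on each side of DC/f0/2f0 for the
#'   floor estimate.
#' @return For a vector input, a list with `phase_amplitude` (rad),
#'   `noise_floor` (rad), `freq` and `magnitude` (the single-sided spectrum
#'   of the differenced series, rad). For a matrix input, a list with
#'   vectors `phase_amplitude` and `noise_floor` (one per row).
#' @export
lockin_amplitude <- function(d, f0, fs, method = c("single_tone", "bin"),
                             exclude_halfwidth = 2) {
  method <- match.arg(method)
  vec <- !is.matrix(d)
  if (vec) d <- matrix(d, nrow = 1)
  n <- ncol(d)
  if (n < 2 * fs / f0) {
    stop("lockin_amplitude: need at least 2 modulation cycles in the record",
         call. = FALSE)
  }
  binf <- f0 / fs * n
  bin0 <- round(binf)
  if (abs(binf - bin0) > 0.45) {
    warning("lockin_amplitude: f0 falls between bins; using the nearest bin")
  }
  X <- stats::mvfft(t(d))                   # [freq x depth]
  nside <- floor(n / 2) + 1L
  mag <- (2 / n) * Mod(X[seq_len(nside), , drop = FALSE])
  transfer <- 2 * sin(pi * f0 / fs)
  if (method == "bin") {
    amp_raw <- mag[bin0 + 1L, ]
  } else {
    omega <- 2 * pi * f0 / fs
    Xf <- as.vector(d %*% exp(-1i * omega * (0:(n - 1))))
    W2 <- dirichlet_sum(2 * omega, n)
    # d_t = Re(u e^{i omega t}); solve 2 X = N u + W2 Conj(u) for u
    A11 <- n + Re(W2); A12 <- Im(W2)
    A21 <- Im(W2);     A22 <- n - Re(W2)
    det <- A11 * A22 - A12 * A21
    p <- (A22 * 2 * Re(Xf) - A12 * 2 * Im(Xf)) / det
    q <- (A11 * 2 * Im(Xf) - A21 * 2 * Re(Xf)) / det
    amp_raw <- sqrt(p^2 + q^2)
  }
  keep <- rep(TRUE, nside)
  for (b in c(0L, bin0, round(2 * f0 / fs * n))) {
    lo <- max(1L, b + 1L - exclude_halfwidth)
    hi <- min(nside, b + 1L + exclude_halfwidth)
    if (lo <= hi) keep[lo:hi] <- FALSE
  }
  floor_raw <- apply(mag[keep, , drop = FALSE], 2, stats::median)
  amp <- amp_raw / transfer
  flr <- floor_raw / transfer
  if (vec) {
    list(phase_amplitude = amp[1], noise_floor = flr[1],
         freq = (seq_len(nside) - 1) * fs / n, magnitude = mag[, 1])
  } else {
    list(phase_amplitude = amp, noise_floor = flr)
  }
}

#' Convert a phase amplitude to optical path length
#'
#' Inverts `delta_phi = 4 pi n delta_OPL / lambda0`:
#' `delta_OPL = lambda0 * delta_phi / (4 pi n)`.
#'
#' @param dphi Phase amplitude, rad (any shape).
#' @param lambda0 Center wavelength, nm.
#' @param refractive_index Sample group index.
#' @return Optical path length change, nm.
#' @export
#' @examples
#' to_opl(0.1, 860, 1.38)  # ~4.96 nm
to_opl <- function(dphi, lambda0, refractive_index) {
  if (refractive_index <= 0) {
    stop("to_opl: refractive_index must be > 0", call. = FALSE)
  }
  stopifnot(lambda0 > 0)
  lambda0 * dphi / (4 * pi * refractive_index)
}

#' PT-OCT depth profile from one raw M-scan
#'
#' Chains the full per-position pipeline: wavelength-to-wavenumber
#' resampling, dispersion compensation, Chirp-Z depth transform, per-depth
#' wrapped phase differencing, Fourier lock-in at the modulation frequency,
#' noise-floor subtraction (clipped at zero) and conversion to nm of
#' optical path length. Background removal uses
#' [remove_source_envelope()] plus spectral apodization and
#' [analytic_signal()]: together they suppress the zero-delay source term,
#' its window-truncation tails and the conjugate image without touching
#' per-sample fringe phase (a temporal-mean subtraction would cancel
#' quasi-static fringes and corrupt the phase, and would erase the
#' structural image of an unmodulated acquisition entirely). The OCT
#' intensity profile is the time-averaged magnitude of the same
#' reconstruction, log-scaled.
#'
#' @param raw A [raw_mscan()].
#' @param dispersion `NULL` (no correction), a [dispersion_model()], or
#'   `"estimate"` to optimize one from the data.
#' @param depth_window_um,n_out Passed to [chirpz_to_depth()].
#' @param method Lock-in method, see [lockin_amplitude()].
#' @param snr_db Pixels whose mean magnitude lies less than `snr_db`
#'   decibels above the empty-depth floor (10th percentile over the window)
#'   carry no trustworthy phase and are masked to zero in `opl_amplitude`
#'   (`valid = FALSE`). Set to `-Inf` to disable.
#' @param dynamic_range_db Pixels more than this many dB below the
#'   brightest pixel of the window are likewise masked.
#' @return An object of class `ptoct_profile`: `depth_grid` (um),
#'   `opl_amplitude` (floor-subtracted, nm, >= 0), `noise_floor_nm`,
#'   `phase_amplitude` (rad), `oct_db` (log-scaled mean OCT intensity),
#'   `valid` (per-pixel flag), `dispersion`, `config`.
#' @export
process_mscan <- function(raw, dispersion = NULL,
                          depth_window_um = NULL, n_out = NULL,
                          method = "single_tone", snr_db = 5,
                          dynamic_range_db = 50) {
  stopifnot(inherits(raw, "raw_mscan"))
  ks <- resample_to_wavenumber(raw)
  model <- if (is.null(dispersion)) {
    dispersion_model(0, 0)
  } else if (identical(dispersion, "estimate")) {
    estimate_dispersion(ks)
  } else {
    stopifnot(inherits(dispersion, "dispersion_model"))
    dispersion
  }
  # phase pathway: suppress the zero-delay source term (smooth envelope fit,
  # which keeps static fringes) and apodize the spectral window so that
  # neither term's truncation tails reach the imaging depths; both protect
  # the per-pixel phase from static interference bias
  ks_phase <- ks
  ks_phase$spectra <- analytic_signal(
    remove_source_envelope(ks$spectra) * tukey_window(length(ks$k_grid), 0.25))
  ks_phase <- apply_dispersion(ks_phase, model)
  cm <- chirpz_to_depth(ks_phase, depth_window_um, n_out)

  mag_mean <- rowMeans(Mod(cm$field))
  oct_db <- 20 * log10(mag_mean + .Machine$double.eps)
  # phase validity: (i) nonzero magnitude everywhere; (ii) magnitude at
  # least snr_db above the empty-depth floor (10th percentile of the
  # window); (iii) no deep destructive-interference dips over time, where
  # the phase is dominated by whichever term cancels last
  m_ph <- Mod(cm$field)
  mag_phase <- rowMeans(m_ph)
  valid <- apply(m_ph > 0, 1, all)
  floor_mag <- stats::quantile(mag_phase, 0.10, names = FALSE)
  valid <- valid & (mag_phase >= floor_mag * 10^(snr_db / 20))
  # phase is meaningless far below the dynamic range of the scene
  valid <- valid & (mag_phase >= max(mag_phase) * 10^(-dynamic_range_db / 20))
  row_min <- apply(m_ph, 1, min)
  row_med <- apply(m_ph, 1, stats::median)
  valid <- valid & (row_min >= 0.5 * row_med)

  ph <- Arg(cm$field)
  d <- temporal_derivative(ph)
  li <- lockin_amplitude(d, raw$config$mod_frequency, raw$config$line_rate,
                         method = method)
  lam0 <- raw$config$center_wavelength
  ri <- raw$config$refractive_index
  sig_nm <- to_opl(li$phase_amplitude, lam0, ri)
  flr_nm <- to_opl(li$noise_floor, lam0, ri)
  opl <- pmax(sig_nm - flr_nm, 0)
  opl[!valid] <- 0
  structure(list(depth_grid = cm$depth_grid,
                 opl_amplitude = opl,
                 noise_floor_nm = flr_nm,
                 phase_amplitude = li$phase_amplitude,
                 oct_db = oct_db,
                 valid = valid,
                 dispersion = model,
                 config = raw$config),
            class = "ptoct_profile")
}

#' @export
print.ptoct_profile <- function(x, ...) {
  i <- which.max(x$opl_amplitude)
  cat(sprintf("ptoct_profile: %d depth px (%.1f-%.1f um); peak %.3g nm at %.1f um\n",
              length(x$depth_grid), min(x$depth_grid), max(x$depth_grid),
              x$opl_amplitude[i], x$depth_grid[i]))
  invisible(x)
}

#' Process a raw volume into co-registered OCT and PT-OCT volumes
#'
#' Runs [process_mscan()] over every column of a [simulate_volume()] output
#' (or any `raw_volume`), assembling paired [image_volume()]s, and
#' reconstructs the reference volume's OCT intensity the same way.
#'
#' @param rawvol A `raw_volume`.
#' @param depth_window_um,n_out,dispersion,method Passed to
#'   [process_mscan()].
#' @return List: `oct`, `ptoct`, `reference_oct` ([image_volume()]s),
#'   `depth_grid` (um), `truth` (carried through if present).
#' @export
process_volume <- function(rawvol, depth_window_um = NULL, n_out = NULL,
                           dispersion = NULL, method = "single_tone") {
  stopifnot(inherits(rawvol, "raw_volume"))
  n_b <- length(rawvol$bscans)
  n_l <- length(rawvol$bscans[[1]])
  first <- process_mscan(rawvol$bscans[[1]][[1]], dispersion,
                         depth_window_um, n_out)
  n_z <- length(first$depth_grid)
  oct <- array(0, c(n_z, n_l, n_b))
  pt <- array(0, c(n_z, n_l, n_b))
  ref <- array(0, c(n_z, n_l, n_b))
  for (b in seq_len(n_b)) {
    for (l in seq_len(n_l)) {
      p <- if (b == 1 && l == 1) first else
        process_mscan(rawvol$bscans[[b]][[l]], dispersion,
                      depth_window_um, n_out)
      oct[, l, b] <- p$oct_db
      pt[, l, b] <- p$opl_amplitude
      rr <- rawvol$reference[[b]][[l]]
      ksr <- resample_to_wavenumber(rr)
      ksr$spectra <- analytic_signal(
        remove_source_envelope(ksr$spectra) *
          tukey_window(length(ksr$k_grid), 0.25))
      cmr <- chirpz_to_depth(apply_dispersion(ksr, p$dispersion),
                             depth_window_um, n_out)
      ref[, l, b] <- 20 * log10(rowMeans(Mod(cmr$field)) + .Machine$double.eps)
    }
  }
  dz <- diff(first$depth_grid[1:2])
  list(oct = image_volume(oct, dz, "oct_log_intensity"),
       ptoct = image_volume(pt, dz, "ptoct_nm"),
       reference_oct = image_volume(ref, dz, "oct_log_intensity"),
       depth_grid = first$depth_grid,
       truth = rawvol$truth)
}
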