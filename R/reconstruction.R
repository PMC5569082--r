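#' Resample spectra from wavelength to wavenumber
#'
#' Spectrometer pixels sample the interferogram linearly in wavelength;
#' depth reconstruction requires samples uniform in wavenumber `k = 2 pi /
#' lambda`. Each time sample is interpolated with a cubic spline onto a
#' uniform k grid spanning the input range (endpoints preserved).
#'
#' @param raw A [raw_mscan()].
#' @return A `kspace_mscan` list: `spectra` (`[k pixel x time]`), uniform
#'   increasing `k_grid` (rad/nm) and the `config`.
#' @export
resample_to_wavenumber <- function(raw) {
  stopifnot(inherits(raw, "raw_mscan"))
  k_raw <- 2 * pi / raw$wavelength_grid
  sp <- raw$spectra
  if (k_raw[1] > k_raw[length(k_raw)]) {      # make k increasing
    k_raw <- rev(k_raw)
    sp <- sp[rev(seq_len(nrow(sp))), , drop = FALSE]
  }
  n <- length(k_raw)
  k_grid <- seq(k_raw[1], k_raw[n], length.out = n)
  out <- matrix(0, n, ncol(sp))
  for (tcol in seq_len(ncol(sp))) {
    out[, tcol] <- stats::spline(k_raw, sp[, tcol], xout = k_grid,
                                 method = "fmm")$y
  }
  structure(list(spectra = out, k_grid = k_grid, config = raw$config),
            class = "kspace_mscan")
}

#' Subtract the temporal-mean background spectrum
#'
#' Removes the per-pixel mean over time from every time sample, suppressing
#' the source spectrum / DC term and fixed-pattern noise. Time-varying
#' fringe components are preserved per sample; only their static part is
#' removed.
#'
#' @param x A numeric matrix (`[pixel x time]`) or a `kspace_mscan`.
#' @return Same type as the input, background-subtracted.
#' @export
subtract_background <- function(x) {
  if (inherits(x, "kspace_mscan")) {
    x$spectra <- subtract_background(x$spectra)
    return(x)
  }
  stopifnot(is.matrix(x), ncol(x) >= 2)
  x - rowMeans(x)
}

#' Remove the smooth source envelope from spectra
#'
#' Estimates the non-fringe (source/DC) component of the spectra as a
#' low-order polynomial fit to the temporal-mean spectrum and subtracts it
#' from every time sample. Unlike [subtract_background()], fringe
#' components (oscillating much faster than the polynomial can follow)
#' survive with their phase intact, so quasi-static interference terms are
#' preserved while the strong zero-delay term is suppressed by orders of
#' magnitude. The fit is smooth across the whole window, so no spurious
#' edges are introduced into the depth transform.
#'
#' @param x Numeric matrix, `[pixel x time]`.
#' @param degree Polynomial degree of the envelope fit.
#' @return Matrix of the same shape.
#' @export
remove_source_envelope <- function(x, degree = 20) {
  stopifnot(is.matrix(x))
  s_mean <- rowMeans(x)
  u <- seq(-1, 1, length.out = nrow(x))
  env <- stats::fitted(stats::lm(s_mean ~ stats::poly(u, degree)))
  x - as.numeric(env)
}

#' Analytic signal along the wavenumber axis
#'
#' Zeroes the negative-frequency half of each column's spectrum (Hilbert
#' transform), so that the complex-conjugate fringe terms -- which map to
#' negative depths but whose window tails would otherwise leak
#' phase-reversed energy into positive depths -- are removed before the
#' depth transform.
#'
#' @param x Real matrix, `[k pixel x time]`.
#' @return Complex matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Dispersion model
#'
#' Polynomial phase `theta(k) = a2 (k - k0)^2 + a3 (k - k0)^3` applied in
#' wavenumber to compensate group-velocity dispersion mismatch between the
#' interferometer arms.
#'
#' @param a2,a3 Second/third order coefficients (nm^2, nm^3).
#' @param source `"known_truth"` or `"optimized"`.
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(a2 = 0, a3 = 0,
                             source = c("known_truth", "optimized")) {
  source <- match.arg(source)
  if (!is.finite(a2) || !is.finite(a3)) {
    stop("dispersion_model: coefficients must be finite", call. = FALSE)
  }
  structure(list(a2 = a2, a3 = a3, source = source),
            class = "dispersion_model")
}

#' Apply a dispersion model to k-space spectra
#'
#' Multiplies the (real or complex) spectra by `exp(-i theta(k))`, with
#' `theta` expanded around the grid's center wavenumber. For real spectra the
#' complex-conjugate fringe term maps to negative depths and stays outside
#' the reconstruction window.
#'
#' @param ks A `kspace_mscan` (or a matrix plus `k_grid`).
#' @param model A [dispersion_model()].
#' @param k_grid Wavenumber grid, required when `ks` is a bare matrix.
#' @return Same structure as `ks` with complex spectra.
#' @export
apply_dispersion <- function(ks, model, k_grid = NULL, k_center = NULL) {
  stopifnot(inherits(model, "dispersion_model"))
  if (inherits(ks, "kspace_mscan")) {
    ks$spectra <- apply_dispersion(ks$spectra, model, ks$k_grid,
                                   2 * pi / ks$config$center_wavelength)
    return(ks)
  }
  stopifnot(is.matrix(ks), !is.null(k_grid))
  if (is.null(k_center)) k_center <- k_grid[(length(k_grid) + 1L) %/% 2L]
  dk <- k_grid - k_center
  phase <- model$a2 * dk^2 + model$a3 * dk^3
  ks * exp(-1i * phase)
}

#' Estimate dispersion coefficients by image sharpness
#'
#' Searches for the `(a2, a3)` that maximize the peak intensity of the
#' reconstructed A-scan (grid search over `a2` followed by Nelder-Mead
#' refinement over both coefficients). Deterministic given the input. If no
#' reflector stands out of the reconstruction (peak below 5x the median
#' magnitude), a warning is issued and the identity model returned.
#'
#' @param ks A `kspace_mscan` (background subtraction applied internally for
#'   the sharpness metric).
#' @param a2_range Search interval for `a2`, nm^2.
#' @param n_grid Number of coarse grid points.
#' @return A [dispersion_model()] with `source = "optimized"`.
#' @export
estimate_dispersion <- function(ks, a2_range = c(-6e7, 6e7), n_grid = 41) {
  stopifnot(inherits(ks, "kspace_mscan"))
  # fringes ride on the source envelope; remove the smooth envelope, which
  # keeps static fringes (a temporal-mean subtraction would cancel them)
  s <- remove_source_envelope(ks$spectra[, 1, drop = FALSE])[, 1]
  n <- length(s)
  s <- s * tukey_window(n, 0.25)
  kc <- 2 * pi / ks$config$center_wavelength
  n_fine <- 4L * n                        # oversample so the peak is resolved
  metric <- function(p) {
    cs <- apply_dispersion(matrix(s, ncol = 1), dispersion_model(p[1], p[2]),
                           ks$k_grid, kc)
    f <- chirpz_to_depth_matrix(cs, ks$k_grid, ks$config, n_out = n_fine)
    max(Mod(f$field))
  }
  # degenerate input: no fringe energy stands out at any trial dispersion
  f0 <- Mod(chirpz_to_depth_matrix(matrix(s, ncol = 1) + 0i, ks$k_grid,
                                   ks$config, n_out = n_fine)$field)
  if (max(f0) < 5 * stats::median(f0) || max(f0) == 0) {
    warning("estimate_dispersion: no clear reflector found; returning identity model")
    return(dispersion_model(0, 0, source = "optimized"))
  }
  a2s <- seq(a2_range[1], a2_range[2], length.out = n_grid)
  vals <- vapply(a2s, function(a) metric(c(a, 0)), numeric(1))
  best <- a2s[which.max(vals)]
  opt <- stats::optim(c(best, 0), function(p) -metric(p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 800))
  # restart from the optimum to escape simplex collapse
  opt <- stats::optim(opt$par, function(p) -metric(p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 800))
  model <- dispersion_model(opt$par[1], opt$par[2], source = "optimized")
  # sanity: does the corrected reconstruction actually contain a reflector?
  cs <- apply_dispersion(matrix(s, ncol = 1), model, ks$k_grid, kc)
  f <- Mod(chirpz_to_depth_matrix(cs, ks$k_grid, ks$config, n_out = n_fine)$field)
  if (max(f) < 5 * stats::median(f)) {
    warning("estimate_dispersion: no clear reflector found; returning identity model")
    return(dispersion_model(0, 0, source = "optimized"))
  }
  model
}

# internal: depth transform of a (possibly complex) k-space matrix
chirpz_to_depth_matrix <- function(spectra, k_grid, config,
                                   depth_window_um = NULL, n_out = NULL) {
  n <- length(k_grid)
  dks <- diff(k_grid)
  if (any(dks <= 0) || (max(dks) - min(dks)) > 1e-8 * mean(dks)) {
    stop("chirpz_to_depth: k grid must be uniform and increasing", call. = FALSE)
  }
  dk <- mean(dks)
  ri <- config$refractive_index
  z_nyq_nm <- pi / (2 * ri * dk)            # one-sided unambiguous depth
  if (is.null(depth_window_um)) depth_window_um <- c(0, z_nyq_nm / 1000)
  if (is.null(n_out)) n_out <- max(2L, n %/% 2L)
  z0 <- depth_window_um[1] * 1000
  z1 <- depth_window_um[2] * 1000
  if (z0 < 0 || z1 <= z0 || z1 > 2 * z_nyq_nm + 1e-9) {
    stop("chirpz_to_depth: depth window must lie inside [0, ",
         round(2 * z_nyq_nm / 1000, 1), "] um (unambiguous range)",
         call. = FALSE)
  }
  dz <- (z1 - z0) / n_out                   # half-open window [z0, z1)
  zs <- z0 + (0:(n_out - 1)) * dz
  w <- exp(-2i * ri * dk * dz)
  a <- exp(2i * ri * dk * z0)
  field <- czt(spectra, n_out, w, a)
  field <- field * exp(-2i * ri * k_grid[1] * zs)   # carrier from k_min
  list(field = field, depth_grid = zs / 1000)
}

#' Chirp-Z depth transform
#'
#' Converts uniform-k spectra to a complex depth-resolved field over an
#' arbitrary (possibly zoomed) depth window, evaluating
#' `X(z) = sum_j S(k_j) exp(-2 i n k_j z)` on `n_out` uniformly spaced
#' depths. With the window equal to the full unambiguous range and `n_out`
#' equal to the input length this reproduces the FFT bin-for-bin (up to the
#' analytic carrier `exp(-2 i n k_min z)`, which the function includes).
#'
#' @param ks A `kspace_mscan` (real or complex spectra).
#' @param depth_window_um Length-2 physical depth window, um. Default:
#'   `[0, z_nyquist]`, the upper half-range that excludes the conjugate
#'   mirror image.
#' @param n_out Number of depth pixels (default: half the input length).
#' @return A [complex_mscan()].
#' @export
chirpz_to_depth <- function(ks, depth_window_um = NULL, n_out = NULL) {
  stopifnot(inherits(ks, "kspace_mscan"))
  r <- chirpz_to_depth_matrix(ks$spectra, ks$k_grid, ks$config,
                              depth_window_um, n_out)
  complex_mscan(r$field, r$depth_grid, ks$config)
}
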