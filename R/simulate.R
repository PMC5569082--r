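#' Simulate one raw spectral M-scan
#'
#' Forward model for one lateral position: each reflector `j` at depth `z_j`
#' with reflectivity `a_j` contributes a fringe
#' `a_j cos(2 k n z_j + phi_j(t) + theta(k))` under a Gaussian source
#' envelope, where the photothermal phase is
#' `phi_j(t) = (4 pi n / lambda0) * A_j * m(t)` plus common-mode bulk phase
#' noise. `A_j` is the ground-truth photothermal amplitude at the reflector
#' ([reflector_amplitudes()]), `m(t)` the unit-peak modulation waveform
#' ([modulation_waveform()]), and `theta(k)` an optional dispersion phase
#' polynomial. Spectra are sampled on a wavelength grid linear in pixel
#' index spanning `lambda0 +/- 1.5 * bandwidth`.
#'
#' @param truth A [phantom_truth] object.
#' @param config An [acq_config()].
#' @param power Photothermal laser power, mW (default `config$pt_power`).
#' @param lateral,bscan Which phantom column to render.
#' @param dispersion Numeric `c(a2, a3)` dispersion coefficients baked into
#'   the data (nm^2, nm^3).
#' @param axial_shift_um Bulk axial displacement of the whole column
#'   (breathing motion), um.
#' @param dropout If `TRUE`, render a corrupted A-scan: the structured
#'   fringes are replaced by a decorrelated random speckle column.
#' @param seed Seed for the noise draws (default derives from the phantom
#'   seed and the column index).
#' @return A [raw_mscan()].
#' @export
simulate_mscan <- function(truth, config, power = config$pt_power,
                           lateral = 1, bscan = 1,
                           dispersion = c(0, 0),
                           axial_shift_um = 0,
                           dropout = FALSE,
                           seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  validate_acq_config(config)
  if (power < 0) stop("simulate_mscan: power must be >= 0", call. = FALSE)
  if (is.null(seed)) seed <- sub_seed(truth$seed, bscan, lateral, 7L)

  n_px <- config$n_spectrometer_pixels
  n_t <- config$n_repeats
  lam0 <- config$center_wavelength
  bw <- config$bandwidth
  ri <- config$refractive_index

  lambda <- seq(lam0 - 1.5 * bw, lam0 + 1.5 * bw, length.out = n_px)
  k <- 2 * pi / lambda
  k0 <- 2 * pi / lam0
  dk_fwhm <- 2 * pi * bw / lam0^2
  G <- exp(-4 * log(2) * ((k - k0) / dk_fwhm)^2)

  refl <- reflector_amplitudes(truth, power, lateral, bscan)
  refl$depth_um <- refl$depth_um + axial_shift_um
  if (nrow(refl) == 0) stop("simulate_mscan: phantom column has no reflectors",
                            call. = FALSE)
  dk_uniform <- (max(k) - min(k)) / (n_px - 1)
  z_max_um <- 2 * pi / (2 * ri * dk_uniform) / 2 / 1000  # one-sided Nyquist
  if (any(refl$depth_um <= 0) || any(refl$depth_um >= 2 * z_max_um)) {
    stop("simulate_mscan: reflector beyond the unambiguous depth range (",
         round(2 * z_max_um), " um)", call. = FALSE)
  }

  tgrid <- (0:(n_t - 1)) / config$line_rate
  m <- modulation_waveform(tgrid, config$mod_frequency, config$mod_duty,
                           mode = truth$thermal_mode,
                           tau_s = truth$tau_ms / 1000)
  # center and normalize so A_j is the oscillation amplitude (half the
  # peak-to-peak excursion) of delta-OPL: pure_sine drives exactly
  # A_j * sin(2 pi f0 t); square_lowpass a +/-A_j low-passed square
  rng <- range(m)
  w <- (m - mean(rng)) / (diff(rng) / 2)
  theta <- dispersion[1] * (k - k0)^2 + dispersion[2] * (k - k0)^3

  with_seed(seed, {
    bulk <- if (truth$sigma_phi > 0) stats::rnorm(n_t, 0, truth$sigma_phi) else
      numeric(n_t)
    if (dropout) {
      # decorrelated column: random reflectors, no photothermal drive
      nj <- 10L
      refl <- data.frame(depth_um = stats::runif(nj, 30, 2 * z_max_um * 0.45),
                         amplitude = stats::runif(nj, 0.05, 0.3),
                         a_nm = 0)
    }
    phase_scale <- 4 * pi * ri * refl$a_nm / lam0        # peak delta-phi, rad
    U <- exp(1i * (2 * ri * outer(k, refl$depth_um * 1000) + theta))
    V <- exp(1i * (outer(phase_scale, w) +
                     matrix(bulk, nrow(refl), n_t, byrow = TRUE)))
    fringes <- Re((U * rep(refl$amplitude, each = n_px)) %*% V)
    dc <- 2 * sum(refl$amplitude) + 1
    S <- G * (dc + fringes)
    if (truth$sigma_s > 0) {
      S <- S + matrix(stats::rnorm(n_px * n_t, 0, truth$sigma_s), n_px, n_t)
    }
    S[S < 0] <- 0
    raw_mscan(S, lambda, config)
  })
}

#' Simulate a raw B-scan/volume with breathing motion plus a reference
#'
#' Renders every phantom column as an M-scan acquired sequentially (one
#' M-scan per lateral position, B-scans in order). A slow breathing
#' surrogate (sinusoid plus linear drift) displaces each column axially by
#' the trace value at its acquisition time; a seeded fraction of columns is
#' replaced by decorrelated noise (failed A-scans). A motion-free, quickly
#' acquired reference OCT volume (few repeats, drive off) is rendered
#' alongside, as used by the motion-correction stage.
#'
#' @param truth A [phantom_truth].
#' @param config An [acq_config()]; `n_ascans_per_bscan` is overridden by
#'   the phantom's lateral extent.
#' @param motion List with elements `amplitude_px`, `freq_hz`, `drift_px`,
#'   `phase` (radians) and `pixel_um` (axial size of one trace pixel, um).
#'   `amplitude_px = 0` disables motion.
#' @param dropout_prob Probability that a column is a corrupted A-scan.
#' @param reference_repeats Repeats per A-scan in the reference volume.
#' @param power,dispersion,seed Passed to [simulate_mscan()]; `seed`
#'   defaults to the phantom seed.
#' @return List of class `raw_volume`: `bscans` (list over B-scans of lists
#'   of [raw_mscan()]), `reference` (same layout), `config`,
#'   `reference_config`, and `truth` with `motion_trace` (um and px) and
#'   `dropout_columns` filled in.
#' @export
simulate_volume <- function(truth, config,
                            motion = list(amplitude_px = 5, freq_hz = 1.5,
                                          drift_px = 2, phase = 0,
                                          pixel_um = 1),
                            dropout_prob = 0,
                            reference_repeats = 4,
                            power = config$pt_power,
                            dispersion = c(0, 0),
                            seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  if (is.null(seed)) seed <- truth$seed
  n_lat <- dim(truth$absorber_map)[2]
  n_b <- dim(truth$absorber_map)[3]
  config$n_ascans_per_bscan <- as.integer(n_lat)
  mot <- utils::modifyList(list(amplitude_px = 5, freq_hz = 1.5,
                                drift_px = 2, phase = 0, pixel_um = 1),
                           as.list(motion))
  n_cols <- n_lat * n_b
  t_col <- (seq_len(n_cols) - 1) * config$n_repeats / config$line_rate
  total_t <- max(t_col[n_cols], 1e-9)
  trace_px <- mot$amplitude_px * sin(2 * pi * mot$freq_hz * t_col + mot$phase) +
    mot$drift_px * t_col / total_t
  trace_um <- trace_px * mot$pixel_um
  dropout <- with_seed(sub_seed(seed, 13L),
                       stats::runif(n_cols) < dropout_prob)

  ref_config <- config
  ref_config$n_repeats <- as.integer(reference_repeats)
  bscans <- vector("list", n_b)
  reference <- vector("list", n_b)
  idx <- 0L
  for (b in seq_len(n_b)) {
    bl <- vector("list", n_lat)
    rl <- vector("list", n_lat)
    for (l in seq_len(n_lat)) {
      idx <- idx + 1L
      bl[[l]] <- simulate_mscan(truth, config, power, l, b, dispersion,
                                axial_shift_um = trace_um[idx],
                                dropout = dropout[idx],
                                seed = sub_seed(seed, b, l, 7L))
      rl[[l]] <- simulate_mscan(truth, ref_config, power = 0, l, b, dispersion,
                                axial_shift_um = 0, dropout = FALSE,
                                seed = sub_seed(seed, b, l, 11L))
    }
    bscans[[b]] <- bl
    reference[[b]] <- rl
  }
  truth$motion_trace <- matrix(trace_px, n_lat, n_b)
  truth$motion_trace_um <- matrix(trace_um, n_lat, n_b)
  truth$dropout_columns <- which(dropout)
  structure(list(bscans = bscans, reference = reference, config = config,
                 reference_config = ref_config, truth = truth),
            class = "raw_volume")
}

#' @export
print.raw_volume <- function(x, ...) {
  cat(sprintf("raw_volume: %d B-scans x %d A-scans, %d repeats each\n",
              length(x$bscans), length(x$bscans[[1]]), x$config$n_repeats))
  invisible(x)
}
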