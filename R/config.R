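#' Acquisition configuration
#'
#' Describes one spectral-domain PT-OCT acquisition: the OCT source, the
#' spectrometer, the M-scan timing and the photothermal drive. Defaults match
#' a retinal PT-OCT system built around an 860 nm SLD with a 2048-pixel
#' spectrometer running at a 10 kHz line rate, a 500 Hz square-wave
#' photothermal modulation at 50% duty cycle, and 700 repeated A-scans per
#' lateral position.
#'
#' @param center_wavelength Center wavelength of the OCT source, nm.
#' @param bandwidth Full spectral bandwidth of the source, nm.
#' @param line_rate A-scan (line) rate, Hz.
#' @param mod_frequency Photothermal amplitude-modulation frequency, Hz.
#'   Must be below the Nyquist rate `line_rate / 2`.
#' @param mod_duty Duty cycle of the square-wave drive, in (0, 1).
#' @param n_repeats Number of repeated A-scans per M-scan.
#' @param refractive_index Group refractive index used to convert phase to
#'   optical path length and wavenumber to physical depth.
#' @param pt_power Photothermal laser power at the sample, mW.
#' @param n_spectrometer_pixels Number of spectrometer pixels.
#' @param n_ascans_per_bscan Number of lateral A-scan positions per B-scan.
#'
#' @return An object of class `acq_config` (a validated list).
#' @export
#' @examples
#' cfg <- acq_config()
#' modulation_periods(cfg)  # 35 with the defaults
acq_config <- function(center_wavelength = 860,
                       bandwidth = 40,
                       line_rate = 10000,
                       mod_frequency = 500,
                       mod_duty = 0.5,
                       n_repeats = 700,
                       refractive_index = 1.38,
                       pt_power = 8,
                       n_spectrometer_pixels = 2048,
                       n_ascans_per_bscan = 400) {
  cfg <- list(
    center_wavelength = as.numeric(center_wavelength),
    bandwidth = as.numeric(bandwidth),
    line_rate = as.numeric(line_rate),
    mod_frequency = as.numeric(mod_frequency),
    mod_duty = as.numeric(mod_duty),
    n_repeats = as.integer(n_repeats),
    refractive_index = as.numeric(refractive_index),
    pt_power = as.numeric(pt_power),
    n_spectrometer_pixels = as.integer(n_spectrometer_pixels),
    n_ascans_per_bscan = as.integer(n_ascans_per_bscan)
  )
  class(cfg) <- "acq_config"
  validate_acq_config(cfg)
}

#' @rdname acq_config
#' @param x Object to validate.
#' @export
validate_acq_config <- function(x) {
  stopifnot(inherits(x, "acq_config"))
  pos <- c("center_wavelength", "bandwidth", "line_rate", "mod_frequency",
           "refractive_index", "n_spectrometer_pixels", "n_ascans_per_bscan")
  for (f in pos) {
    if (!is.finite(x[[f]]) || x[[f]] <= 0) {
      stop("acq_config: field '", f, "' must be a positive finite number",
           call. = FALSE)
    }
  }
  if (!is.finite(x$pt_power) || x$pt_power < 0) {
    stop("acq_config: 'pt_power' must be >= 0", call. = FALSE)
  }
  if (x$mod_frequency >= x$line_rate / 2) {
    stop("acq_config: 'mod_frequency' must be below line_rate/2 (Nyquist)",
         call. = FALSE)
  }
  if (x$mod_duty <= 0 || x$mod_duty >= 1) {
    stop("acq_config: 'mod_duty' must lie strictly in (0, 1)", call. = FALSE)
  }
  if (x$n_repeats < 2) {
    stop("acq_config: 'n_repeats' must be at least 2", call. = FALSE)
  }
  x
}

#' Number of modulation periods captured in one M-scan
#'
#' The record duration is `n_repeats / line_rate`; multiplying by the
#' modulation frequency gives the number of heating/cooling cycles the
#' lock-in can average over (35 with the defaults).
#'
#' @param config An [acq_config()].
#' @return Number of modulation periods (may be fractional).
#' @export
modulation_periods <- function(config) {
  validate_acq_config(config)
  config$n_repeats / config$line_rate * config$mod_frequency
}

#' Theoretical axial resolution of a Gaussian-spectrum OCT source
#'
#' Round-trip coherence length `(2 ln 2 / pi) * lambda0^2 / dlambda`,
#' i.e. the FWHM of the axial point-spread function in air. Divide by the
#' tissue group index for the in-tissue value.
#'
#' @param center_wavelength Center wavelength, nm.
#' @param bandwidth FWHM spectral bandwidth, nm.
#' @return Axial resolution in micrometres.
#' @export
#' @examples
#' axial_resolution(860, 40)  # ~8.16 um in air
axial_resolution <- function(center_wavelength, bandwidth) {
  stopifnot(center_wavelength > 0, bandwidth > 0)
  (2 * log(2) / pi) * center_wavelength^2 / bandwidth / 1000
}

#' @export
print.acq_config <- function(x, ...) {
  cat("PT-OCT acquisition config\n")
  cat(sprintf("  source: %g nm center, %g nm bandwidth\n",
              x$center_wavelength, x$bandwidth))
  cat(sprintf("  spectrometer: %d pixels, line rate %g Hz\n",
              x$n_spectrometer_pixels, x$line_rate))
  cat(sprintf("  drive: %g Hz square wave, duty %g, power %g mW\n",
              x$mod_frequency, x$mod_duty, x$pt_power))
  cat(sprintf("  M-scan: %d repeats (%.1f modulation periods)\n",
              x$n_repeats, modulation_periods(x)))
  invisible(x)
}
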