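#' Photothermal phantom ground truth
#'
#' A `phantom_truth` object records everything the forward simulator needs
#' and everything a recovery experiment may check against: discrete
#' backscattering reflectors, the absorber concentration map `C(z, lateral,
#' bscan)` in arbitrary units, the photothermal responsivity `kappa`
#' (nm of optical path length per mW per concentration unit), the thermal
#' response model, noise levels and the seed.
#'
#' The per-pixel true photothermal amplitude at power `P` is
#' `A(z) = kappa * P * W[C](z)`, where `W` is one of three thermal coupling
#' operators (see [true_amplitude()]):
#' \describe{
#'   \item{local}{`W[C] = C`: each scatterer only feels the absorber at its
#'     own depth. Used for closed-form validation.}
#'   \item{cumulative}{`W[C](z) = sum of C above and at z`: pure optical
#'     path-length accumulation below an absorbing layer.}
#'   \item{diffusive}{`W[C](z) = sum_z' C(z') exp(-|z - z'| / l)`: heat
#'     spreading symmetrically from the absorber with confinement length
#'     `l`, giving a peaked layer signal plus a decaying background above
#'     and below. Default for the retina phantoms.}
#' }
#' All three are linear in both `P` and `C`.
#'
#' @name phantom_truth
NULL

new_phantom_truth <- function(kind, depth_grid, reflectors, absorber_map,
                              kappa, tau_ms, thermal_mode, coupling,
                              confinement_um, delta_T_scale,
                              sigma_phi, sigma_s, seed,
                              geometry = list()) {
  structure(list(
    kind = kind,
    depth_grid = depth_grid,
    reflectors = reflectors,        # data.frame: bscan, lateral, depth_um, amplitude
    absorber_map = absorber_map,    # [n_z x n_lateral x n_bscan]
    kappa = kappa,
    tau_ms = tau_ms,
    thermal_mode = thermal_mode,
    coupling = coupling,
    confinement_um = confinement_um,
    delta_T_scale = delta_T_scale,
    sigma_phi = sigma_phi,
    sigma_s = sigma_s,
    motion_trace = NULL,
    dropout_columns = integer(0),
    seed = seed,
    geometry = geometry
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$absorber_map)
  cat(sprintf("phantom_truth [%s]: %d x %d columns, depth 0-%g um, %d reflectors\n",
              x$kind, d[2], d[3], max(x$depth_grid), nrow(x$reflectors)))
  cat(sprintf("  kappa = %g nm/(mW unit), coupling = %s, thermal = %s (tau %g ms)\n",
              x$kappa, x$coupling, x$thermal_mode, x$tau_ms))
  invisible(x)
}

gaussian_band <- function(z, center, fwhm, content) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  g <- exp(-0.5 * ((z - center) / sigma)^2)
  s <- sum(g)
  if (s == 0) return(g)
  content * g / s
}

retina_reflectors <- function(geom, jitter_um, n_lateral, n_bscan) {
  base <- rbind(
    data.frame(depth_um = geom$ilm_depth, amplitude = 0.30),
    data.frame(depth_um = seq(geom$ilm_depth + 10, geom$rpe_depth - 12, by = 10),
               amplitude = 0.04),
    data.frame(depth_um = geom$rpe_depth + c(-6, -3, 0, 3, 6), amplitude = 0.25),
    data.frame(depth_um = seq(geom$rpe_depth + 22, geom$choroid_end, by = 8),
               amplitude = 0.12)
  )
  out <- vector("list", n_lateral * n_bscan)
  idx <- 1L
  for (b in seq_len(n_bscan)) {
    for (l in seq_len(n_lateral)) {
      r <- base
      if (jitter_um > 0) {
        r$depth_um <- r$depth_um + stats::rnorm(nrow(r), 0, jitter_um)
      }
      out[[idx]] <- data.frame(bscan = b, lateral = l,
                               depth_um = r$depth_um, amplitude = r$amplitude)
      idx <- idx + 1L
    }
  }
  do.call(rbind, out)
}

#' Build a photothermal phantom
#'
#' Constructs the ground truth for one of five study geometries:
#' \describe{
#'   \item{single_reflector}{One mirror at `reflector_depth` with local
#'     absorber concentration `concentration` at the same depth; the
#'     closed-form validation target (recovered signal is exactly
#'     `kappa * P * concentration`).}
#'   \item{pigmented_retina}{ILM, inner-retina, RPE and choroid scatterers
#'     with a melanin band at the RPE (Gaussian, `rpe_fwhm` wide, total
#'     content `rpe_concentration * melanin_factor`) plus a weak broad
#'     choroidal melanin band.}
#'   \item{albino_retina}{Same scattering geometry, zero absorber everywhere.}
#'   \item{lcnv_lesion}{Pigmented-retina base plus a dome-shaped subretinal
#'     lesion above the RPE containing scatterers and a uniform gold-nanorod
#'     absorber load (`gnr_content` per column at the lesion centre).}
#'   \item{lcnv_control}{Identical lesion geometry with zero nanorod load
#'     (melanin background only).}
#' }
#'
#' @param kind Phantom kind, see Details.
#' @param n_lateral,n_bscan Lateral extent of the phantom (columns per
#'   B-scan, number of B-scans).
#' @param depth_max_um,depth_step_um Truth depth grid.
#' @param reflector_depth,reflector_amplitude,concentration Single-reflector
#'   parameters (um, dimensionless, units).
#' @param ilm_depth,rpe_depth,rpe_fwhm,rpe_concentration,choroid_end,
#'   choroid_concentration Retinal geometry (um / concentration units).
#' @param melanin_factor Per-eye multiplier on both melanin bands.
#' @param lesion_center_lateral,lesion_radius_lateral,lesion_height_um,
#'   gnr_content Lesion geometry and nanorod load.
#' @param kappa Responsivity, nm per (mW x unit). The default 1.56 makes a
#'   unit-concentration local absorber yield 1.56 nm/mW.
#' @param tau_ms Thermal response time constant, ms.
#' @param thermal_mode `"square_lowpass"` (default) or `"pure_sine"`.
#' @param coupling Thermal coupling operator; default `"diffusive"` for the
#'   retina/lesion kinds and `"local"` for `single_reflector`.
#' @param confinement_um Confinement length of the diffusive kernel, um.
#' @param sigma_phi Per-sample bulk phase noise, rad.
#' @param sigma_s Additive spectral noise (counts).
#' @param jitter_um Seeded per-column jitter of reflector depths, um.
#' @param seed Integer seed; all phantom randomness derives from it.
#' @return A [phantom_truth] object.
#' @export
make_phantom <- function(kind = c("pigmented_retina", "albino_retina",
                                  "lcnv_lesion", "lcnv_control",
                                  "single_reflector"),
                         n_lateral = 1, n_bscan = 1,
                         depth_max_um = 400, depth_step_um = 1,
                         reflector_depth = 200, reflector_amplitude = 1,
                         concentration = 1,
                         ilm_depth = 100, rpe_depth = 200, rpe_fwhm = 15,
                         rpe_concentration = 2, choroid_end = 265,
                         choroid_concentration = 0.2,
                         melanin_factor = 1,
                         lesion_center_lateral = NULL,
                         lesion_radius_lateral = NULL,
                         lesion_height_um = 60,
                         gnr_content = 0.8,
                         kappa = 1.56, tau_ms = 0.2,
                         thermal_mode = c("square_lowpass", "pure_sine"),
                         coupling = NULL,
                         confinement_um = 15,
                         sigma_phi = 0, sigma_s = 0,
                         jitter_um = 0,
                         seed = 1L) {
  kind <- match.arg(kind)
  thermal_mode <- match.arg(thermal_mode)
  if (tau_ms <= 0) stop("make_phantom: tau_ms must be > 0", call. = FALSE)
  z <- seq(0, depth_max_um, by = depth_step_um)
  n_z <- length(z)
  C <- array(0, c(n_z, n_lateral, n_bscan))
  geom <- list(ilm_depth = ilm_depth, rpe_depth = rpe_depth,
               rpe_fwhm = rpe_fwhm, choroid_end = choroid_end)
  if (is.null(coupling)) {
    coupling <- if (kind == "single_reflector") "local" else "diffusive"
  }
  coupling <- match.arg(coupling, c("local", "cumulative", "diffusive"))

  with_seed(seed, {
    if (kind == "single_reflector") {
      if (reflector_depth <= 0 || reflector_depth >= depth_max_um) {
        stop("make_phantom: reflector_depth must lie inside the depth window",
             call. = FALSE)
      }
      refl <- expand.grid(bscan = seq_len(n_bscan), lateral = seq_len(n_lateral))
      refl <- data.frame(bscan = refl$bscan, lateral = refl$lateral,
                         depth_um = reflector_depth,
                         amplitude = reflector_amplitude)
      iz <- which.min(abs(z - reflector_depth))
      C[iz, , ] <- concentration
    } else {
      if (rpe_depth <= ilm_depth || choroid_end <= rpe_depth ||
          choroid_end >= depth_max_um || ilm_depth <= 0) {
        stop("make_phantom: retinal bands must be ordered within the depth window",
             call. = FALSE)
      }
      # background region must remain outside the bands
      if ((choroid_end - ilm_depth) >= depth_max_um) {
        stop("make_phantom: bands leave no background region", call. = FALSE)
      }
      refl <- retina_reflectors(geom, jitter_um, n_lateral, n_bscan)
      if (kind != "albino_retina") {
        prof <- gaussian_band(z, rpe_depth, rpe_fwhm,
                              rpe_concentration * melanin_factor) +
          gaussian_band(z, (rpe_depth + 18 + choroid_end) / 2, 40,
                        choroid_concentration * melanin_factor)
        C[] <- rep(prof, n_lateral * n_bscan)
      }
      if (kind %in% c("lcnv_lesion", "lcnv_control")) {
        if (is.null(lesion_center_lateral)) {
          lesion_center_lateral <- (n_lateral + 1) / 2
        }
        if (is.null(lesion_radius_lateral)) {
          lesion_radius_lateral <- max(2, n_lateral / 4)
        }
        bc <- (n_bscan + 1) / 2
        extra <- list()
        for (b in seq_len(n_bscan)) {
          for (l in seq_len(n_lateral)) {
            r2 <- ((l - lesion_center_lateral) / lesion_radius_lateral)^2 +
              ((b - bc) / max(lesion_radius_lateral, 1))^2
            if (r2 >= 1) next
            h <- lesion_height_um * sqrt(1 - r2)  # dome height at this column
            ztop <- rpe_depth - h
            zsel <- z >= ztop & z < rpe_depth
            if (!any(zsel)) next
            # lesion scatterers every 12 um through the dome
            zd <- seq(ztop + 4, rpe_depth - 4, by = 12)
            if (length(zd)) {
              extra[[length(extra) + 1L]] <-
                data.frame(bscan = b, lateral = l, depth_um = zd,
                           amplitude = 0.10)
            }
            if (kind == "lcnv_lesion") {
              C[zsel, l, b] <- C[zsel, l, b] +
                gnr_content * sqrt(1 - r2) / sum(zsel)
            }
          }
        }
        if (length(extra)) refl <- rbind(refl, do.call(rbind, extra))
      }
    }
  })
  refl <- refl[order(refl$bscan, refl$lateral, refl$depth_um), ]
  rownames(refl) <- NULL
  new_phantom_truth(kind, z, refl, C, kappa, tau_ms, thermal_mode, coupling,
                    confinement_um, delta_T_scale = 2,
                    sigma_phi = sigma_phi, sigma_s = sigma_s, seed = seed,
                    geometry = c(geom, list(
                      lesion_center_lateral = lesion_center_lateral,
                      lesion_radius_lateral = lesion_radius_lateral,
                      lesion_height_um = lesion_height_um,
                      gnr_content = if (kind == "lcnv_lesion") gnr_content else 0)))
}

#' True photothermal amplitude map
#'
#' Applies the phantom's thermal coupling operator to the absorber map and
#' scales by `kappa * P`, yielding the per-pixel ground-truth photothermal
#' amplitude in nm of optical path length.
#'
#' @param truth A [phantom_truth] object.
#' @param power Photothermal laser power, mW.
#' @param coupling Override the phantom's coupling operator (optional).
#' @return Array congruent with `truth$absorber_map`, nm.
#' @export
true_amplitude <- function(truth, power, coupling = NULL) {
  stopifnot(inherits(truth, "phantom_truth"), power >= 0)
  if (is.null(coupling)) coupling <- truth$coupling
  C <- truth$absorber_map
  W <- switch(coupling,
    local = C,
    cumulative = {
      out <- C
      for (b in seq_len(dim(C)[3])) {
        out[, , b] <- apply(C[, , b, drop = FALSE][, , 1, drop = FALSE],
                            2, cumsum)
      }
      out
    },
    diffusive = {
      z <- truth$depth_grid
      K <- exp(-abs(outer(z, z, "-")) / truth$confinement_um)
      out <- C
      for (b in seq_len(dim(C)[3])) {
        out[, , b] <- K %*% C[, , b]
      }
      out
    },
    stop("unknown coupling operator: ", coupling, call. = FALSE)
  )
  truth$kappa * power * W
}

#' True amplitude at each reflector of one column
#'
#' Linearly interpolates [true_amplitude()] at the reflector depths of one
#' (lateral, bscan) column.
#'
#' @inheritParams true_amplitude
#' @param lateral,bscan Column index.
#' @return Data frame `depth_um`, `amplitude` (scattering), `a_nm`
#'   (photothermal amplitude, nm).
#' @export
reflector_amplitudes <- function(truth, power, lateral = 1, bscan = 1,
                                 coupling = NULL) {
  A <- true_amplitude(truth, power, coupling)[, lateral, bscan]
  r <- truth$reflectors
  r <- r[r$lateral == lateral & r$bscan == bscan, ]
  a_nm <- stats::approx(truth$depth_grid, A, xout = r$depth_um, rule = 2)$y
  data.frame(depth_um = r$depth_um, amplitude = r$amplitude, a_nm = a_nm)
}

#' Photothermal modulation waveform
#'
#' Unit-peak time course of the photothermal optical-path-length drive over
#' one M-scan.
#'
#' @param t Uniform time grid, seconds.
#' @param f0 Modulation frequency, Hz.
#' @param duty Duty cycle of the square drive, in (0, 1).
#' @param mode `"pure_sine"`: `0.5 * (1 + sin(2 pi f0 t))`, the closed-form
#'   validation drive. `"square_lowpass"`: periodic steady-state first-order
#'   response (time constant `tau_s`) to the 0/1 square drive, normalized to
#'   peak 1.
#' @param tau_s Thermal time constant, seconds (square_lowpass only).
#' @return Numeric vector in `[0, 1]`, same length as `t`.
#' @export
modulation_waveform <- function(t, f0, duty = 0.5,
                                mode = c("square_lowpass", "pure_sine"),
                                tau_s = 2e-4) {
  mode <- match.arg(mode)
  if (mode == "pure_sine") {
    return(0.5 * (1 + sin(2 * pi * f0 * t)))
  }
  if (tau_s <= 0) stop("modulation_waveform: tau_s must be > 0", call. = FALSE)
  Tp <- 1 / f0
  ton <- duty * Tp
  toff <- Tp - ton
  # periodic steady state of dm/dt = (u - m)/tau with u the 0/1 square drive
  e_on <- exp(-ton / tau_s)
  e_off <- exp(-toff / tau_s)
  m0 <- (1 - e_on) * e_off / (1 - e_on * e_off)  # value at start of on-phase
  m1 <- 1 - (1 - m0) * e_on                      # peak, end of on-phase
  tp <- t %% Tp
  on <- tp < ton
  m <- numeric(length(t))
  m[on] <- 1 - (1 - m0) * exp(-tp[on] / tau_s)
  m[!on] <- m1 * exp(-(tp[!on] - ton) / tau_s)
  m / m1
}
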