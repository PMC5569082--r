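#' Summary-level cohort simulator: power series
#'
#' Draws per-eye, per-power PT-OCT summary signals directly at the result
#' table level: `value = slope * power * (1 + e)` with `e ~ N(0, cv)`,
#' optionally censored at a detection floor (values whose magnitude falls
#' below `floor_nm` are recorded as the |noise| actually measured there).
#' This emulates the between-eye variability of an in vivo power series
#' without re-rendering raw interferograms, and is the input for
#' Monte-Carlo checks of the fitting stage (confidence-interval coverage,
#' detection-limit flags).
#'
#' @param n_eyes Eyes per power level.
#' @param powers Power levels, mW.
#' @param slope True responsivity, nm/mW.
#' @param cv Relative (proportional) noise standard deviation.
#' @param floor_nm Detection floor; signals below it are replaced by
#'   folded noise of that scale (0 disables).
#' @param seed Integer seed.
#' @return Data frame: `eye_id`, `power`, `value`.
#' @export
simulate_power_cohort <- function(n_eyes = 6,
                                  powers = c(0, 0.2, 0.4, 1, 2, 4, 8, 10),
                                  slope = 1.56, cv = 0.2, floor_nm = 0,
                                  seed = 1) {
  with_seed(seed, {
    rows <- expand.grid(eye_id = paste0("eye", seq_len(n_eyes)),
                        power = powers, stringsAsFactors = FALSE)
    v <- slope * rows$power * (1 + stats::rnorm(nrow(rows), 0, cv))
    if (floor_nm > 0) {
      # below the detection floor only folded noise is recorded
      noise <- abs(stats::rnorm(nrow(rows), 0, floor_nm / 2))
      v <- ifelse(slope * rows$power < floor_nm, noise, pmax(v, 0))
    }
    rows$value <- v
    rows
  })
}

#' Per-eye phantom cohort
#'
#' Draws `n_eyes` phantoms of one kind with biological between-eye
#' variability: RPE band width varies by `fwhm_cv` and melanin content by
#' `melanin_cv` (log-normal), with per-column reflector jitter. All
#' randomness derives from `seed`.
#'
#' @param kind Passed to [make_phantom()].
#' @param n_eyes Number of eyes.
#' @param seed Integer seed.
#' @param fwhm_cv,melanin_cv Between-eye coefficients of variation.
#' @param ... Further arguments for [make_phantom()].
#' @return List of [phantom_truth] objects.
#' @export
make_eye_cohort <- function(kind, n_eyes = 6, seed = 1,
                            fwhm_cv = 0.15, melanin_cv = 0.25, ...) {
  fw <- with_seed(sub_seed(seed, 3L),
                  15 * (1 + stats::rnorm(n_eyes, 0, fwhm_cv)))
  sdlog <- sqrt(log(1 + melanin_cv^2))
  mf <- with_seed(sub_seed(seed, 5L),
                  stats::rlnorm(n_eyes, -sdlog^2 / 2, sdlog))
  lapply(seq_len(n_eyes), function(e) {
    make_phantom(kind, rpe_fwhm = max(fw[e], 6), melanin_factor = mf[e],
                 jitter_um = 2, sigma_phi = 0.05, sigma_s = 0.02,
                 seed = sub_seed(seed, 17L, e), ...)
  })
}

#' Lesion ROI mask from phantom geometry
#'
#' Rebuilds the dome-shaped lesion region of an `lcnv_lesion` /
#' `lcnv_control` phantom on an arbitrary reconstruction depth grid, for
#' use as the (in the study, manually drawn) lesion ROI.
#'
#' @param truth A [phantom_truth] of a lesion kind.
#' @param depth_grid Depth per reconstructed pixel, um.
#' @return An [roi_mask()] with shape `[length(depth_grid) x lateral x
#'   bscan]`.
#' @export
lesion_mask_from_truth <- function(truth, depth_grid) {
  stopifnot(inherits(truth, "phantom_truth"),
            truth$kind %in% c("lcnv_lesion", "lcnv_control"))
  g <- truth$geometry
  n_l <- dim(truth$absorber_map)[2]
  n_b <- dim(truth$absorber_map)[3]
  bc <- (n_b + 1) / 2
  m <- array(FALSE, c(length(depth_grid), n_l, n_b))
  for (b in seq_len(n_b)) {
    for (l in seq_len(n_l)) {
      r2 <- ((l - g$lesion_center_lateral) / g$lesion_radius_lateral)^2 +
        ((b - bc) / max(g$lesion_radius_lateral, 1))^2
      if (r2 >= 1) next
      ztop <- g$rpe_depth - g$lesion_height_um * sqrt(1 - r2)
      m[depth_grid >= ztop & depth_grid < g$rpe_depth, l, b] <- TRUE
    }
  }
  roi_mask(m, "lcnv_lesion")
}

#' Summary-level cohort simulator: lesion groups
#'
#' Draws per-eye lesion-ROI mean signals for a nanorod-injected and a
#' control group: control lesions carry the melanin-driven background
#' level, nanorod lesions that background plus the nanorod contribution,
#' both with log-normal between-eye variability.
#'
#' @param n_per_group Eyes per group.
#' @param control_mean Control lesion mean, nm.
#' @param gnr_extra Additional mean signal from nanorods, nm.
#' @param cv Between-eye coefficient of variation.
#' @param seed Integer seed.
#' @return Data frame: `eye_id`, `group` (`"gnr"` / `"control"`), `value`.
#' @export
simulate_lesion_cohort <- function(n_per_group = 7, control_mean = 3.4,
                                   gnr_extra = 3.1, cv = 0.25, seed = 1) {
  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    draw <- function(mu) {
      mu * stats::rlnorm(n_per_group, -sdlog^2 / 2, sdlog)
    }
    data.frame(
      eye_id = paste0("eye", seq_len(2 * n_per_group)),
      group = rep(c("control", "gnr"), each = n_per_group),
      value = c(draw(control_mean), draw(control_mean + gnr_extra)))
  })
}
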