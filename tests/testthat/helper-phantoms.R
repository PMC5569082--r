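# shared fixtures: small acquisition configs and phantoms built in code

small_config <- function(n_px = 512, n_t = 200, ...) {
  acq_config(n_spectrometer_pixels = n_px, n_repeats = n_t, ...)
}

# deterministic single-mirror phantom whose recovered signal is kappa * P
mirror_phantom <- function(kappa = 5, depth = 200, seed = 1, ...) {
  make_phantom("single_reflector", reflector_depth = depth, kappa = kappa,
               thermal_mode = "pure_sine", seed = seed, ...)
}

# a small but realistic pigmented-retina phantom (noise at study level)
retina_phantom <- function(kind = "pigmented_retina", seed = 1, ...) {
  make_phantom(kind, sigma_phi = 0.05, sigma_s = 0.02, jitter_um = 2,
               seed = seed, ...)
}

# uniform-k cosine-fringe k-space block, bypassing the simulator
kspace_fixture <- function(z_um = 200, n = 512, n_t = 4,
                           config = small_config(n, n_t)) {
  lam0 <- config$center_wavelength
  bw <- config$bandwidth
  lambda <- seq(lam0 - 1.5 * bw, lam0 + 1.5 * bw, length.out = n)
  k <- seq(2 * pi / max(lambda), 2 * pi / min(lambda), length.out = n)
  sp <- matrix(cos(2 * config$refractive_index * k * z_um * 1000), n, n_t)
  structure(list(spectra = sp, k_grid = k, config = config),
            class = "kspace_mscan")
}
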