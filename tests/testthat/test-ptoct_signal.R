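test_that("phase series reads the field argument and flags dead pixels", {
  cfg <- small_config(16, 50)
  t <- 0:49
  phi <- 0.1 * sin(2 * pi * 500 * t / 10000)
  field <- rbind(matrix(2 + 0i, 3, 50), exp(1i * phi))
  cm <- complex_mscan(field, seq(10, 40, length.out = 4), cfg)
  ps <- phase_series(cm, 1)
  expect_equal(ps$phase, rep(0, 50))
  expect_true(ps$valid)
  ps4 <- phase_series(cm, 4)
  expect_equal(ps4$phase, phi, tolerance = 1e-12)
  field[2, 7] <- 0
  cm0 <- complex_mscan(field, seq(10, 40, length.out = 4), cfg)
  expect_false(phase_series(cm0, 2)$valid)
})

test_that("wrapped first difference kills offsets and survives wrap-around", {
  expect_equal(temporal_derivative(rep(2.5, 10)), rep(0, 9))
  ramp <- 0.01 * (0:99)
  expect_equal(temporal_derivative(ramp), rep(0.01, 99), tolerance = 1e-12)
  # steep ramp crossing +/- pi repeatedly: increments stay near the slope
  steep <- seq(0, 40, by = 0.8)
  wrapped <- wrap_to_pi(steep)
  d <- temporal_derivative(wrapped)
  expect_equal(d, diff(steep), tolerance = 1e-12)   # unwrapped oracle
})

test_that("lock-in recovers a pure tone exactly and a square's fundamental", {
  fs <- 10000; f0 <- 500
  t <- (0:699) / fs
  phi <- 0.1 * sin(2 * pi * f0 * t)
  li <- lockin_amplitude(temporal_derivative(phi), f0, fs)
  expect_equal(li$phase_amplitude, 0.1, tolerance = 1e-6)
  # floor is only window leakage of the tone: negligible vs the amplitude
  expect_lt(li$noise_floor, 1e-3 * li$phase_amplitude)

  z <- lockin_amplitude(rep(0, 699), f0, fs)
  expect_equal(z$phase_amplitude, 0)
  expect_equal(z$noise_floor, 0)

  # ideal +/-A square-wave phase: fundamental (4/pi) A
  A <- 0.05
  sq <- A * sign(sin(2 * pi * f0 * t + 1e-9))
  lsq <- lockin_amplitude(temporal_derivative(sq), f0, fs)
  expect_equal(lsq$phase_amplitude, 4 / pi * A, tolerance = 0.01)

  # the nearest-bin reading agrees with the exact estimator to ~1%
  lb <- lockin_amplitude(temporal_derivative(phi), f0, fs, method = "bin")
  expect_equal(lb$phase_amplitude, 0.1, tolerance = 0.01)
  expect_error(lockin_amplitude(rep(0, 20), f0, fs), "2 modulation cycles")
})

test_that("phase-to-OPL conversion inverts the phase equation", {
  expect_equal(to_opl(0, 860, 1.38), 0)
  expect_equal(to_opl(4 * pi * 1.38 * 5 / 860, 860, 1.38), 5)
  expect_equal(to_opl(0.1, 860, 1.38), 860 * 0.1 / (4 * pi * 1.38))
  expect_equal(round(to_opl(0.1, 860, 1.38), 3), 4.959)
  expect_error(to_opl(0.1, 860, 0), "refractive_index")
})

test_that("phase modulation survives reconstruction with its amplitude", {
  # phase fidelity at the peak pixel, noiseless pure sine
  cfg <- small_config(512, 140)
  tr <- mirror_phantom(kappa = 5, seed = 1)
  raw <- simulate_mscan(tr, cfg, power = 1)
  ks <- resample_to_wavenumber(raw)
  ks$spectra <- analytic_signal(remove_source_envelope(ks$spectra) *
                                  tukey_window(512, 0.25))
  cm <- chirpz_to_depth(ks, c(150, 250), 128)
  ipk <- which.max(rowMeans(Mod(cm$field)))
  ph <- Arg(cm$field[ipk, ])
  dphi_true <- 4 * pi * cfg$refractive_index * 5 / cfg$center_wavelength
  rec <- lockin_amplitude(temporal_derivative(ph), 500, 10000)$phase_amplitude
  expect_equal(rec, dphi_true, tolerance = 0.01 * dphi_true)
})

test_that("full pipeline recovers a known mirror amplitude within 1%", {
  cfg <- small_config(512, 140)
  tr <- mirror_phantom(kappa = 5, seed = 1)
  p <- process_mscan(simulate_mscan(tr, cfg, power = 1),
                     depth_window_um = c(150, 250), n_out = 128)
  expect_equal(max(p$opl_amplitude), 5, tolerance = 0.01)
  # the mirror localizes at its true depth in the OCT intensity, and the
  # recovered amplitude there matches the drive
  ioct <- which.max(p$oct_db)
  expect_lt(abs(p$depth_grid[ioct] - 200), 2 * diff(p$depth_grid[1:2]))
  expect_equal(p$opl_amplitude[ioct], 5, tolerance = 0.01)
})

test_that("recovered amplitude is linear in drive and in power", {
  cfg <- small_config(512, 140)
  rec <- vapply(c(1, 2, 4, 7, 10), function(A) {
    tr <- mirror_phantom(kappa = A, seed = 1)
    max(process_mscan(simulate_mscan(tr, cfg, power = 1),
                      depth_window_um = c(150, 250), n_out = 128)$opl_amplitude)
  }, numeric(1))
  fit <- linear_fit_origin(c(1, 2, 4, 7, 10), rec)
  expect_gt(fit$r_squared, 0.999)
  expect_equal(fit$slope, 1, tolerance = 0.005)

  # doubling power doubles the retina-phantom peak
  tr <- make_phantom("pigmented_retina", seed = 2)
  pk <- vapply(c(2, 4), function(P) {
    max(process_mscan(simulate_mscan(tr, cfg, power = P),
                      depth_window_um = c(60, 340), n_out = 256)$opl_amplitude)
  }, numeric(1))
  expect_equal(pk[2] / pk[1], 2, tolerance = 0.05)
})

test_that("albino phantom yields no signal above the floor", {
  cfg <- small_config(512, 200)
  tr <- retina_phantom("albino_retina", seed = 5)
  p <- process_mscan(simulate_mscan(tr, cfg, power = 8),
                     depth_window_um = c(60, 340), n_out = 256)
  flr_sd <- stats::sd(p$noise_floor_nm[p$valid])
  expect_lt(mean(p$opl_amplitude[p$valid]), 3 * max(flr_sd, 0.05))
})

test_that("background sensitivity improves as 1/sqrt(repeats)", {
  resid_sd <- function(nt) {
    cfg <- small_config(256, nt)
    out <- c()
    for (s in 1:3) {
      tr <- retina_phantom(seed = 300 + s)
      p <- process_mscan(simulate_mscan(tr, cfg, power = 0),
                         depth_window_um = c(60, 340), n_out = 128)
      sig <- to_opl(p$phase_amplitude, cfg$center_wavelength,
                    cfg$refractive_index)
      out <- c(out, (sig - p$noise_floor_nm)[p$valid])
    }
    stats::sd(out)
  }
  s175 <- resid_sd(175); s350 <- resid_sd(350); s700 <- resid_sd(700)
  expect_equal(s175 / s700, 2, tolerance = 0.3)
  expect_equal(s350 / s700, sqrt(2), tolerance = 0.25)
  expect_gt(s175, s350)
  expect_gt(s350, s700)
})
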