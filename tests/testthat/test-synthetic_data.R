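test_that("phantom kinds satisfy their defining contracts", {
  alb <- make_phantom("albino_retina", seed = 1)
  expect_equal(max(alb$absorber_map), 0)

  mono <- make_phantom("single_reflector", reflector_depth = 200,
                       reflector_amplitude = 1, seed = 1)
  expect_equal(nrow(mono$reflectors), 1)
  expect_equal(mono$reflectors$depth_um, 200)

  # absorber band FWHM read back from the generated concentration profile
  pig <- make_phantom("pigmented_retina", rpe_fwhm = 12,
                      choroid_concentration = 0, seed = 1)
  prof <- pig$absorber_map[, 1, 1]
  m <- find_peak_fwhm(prof, pig$depth_grid)
  expect_equal(m$fwhm, 12, tolerance = 0.05)

  expect_error(make_phantom("pigmented_retina", ilm_depth = 300,
                            rpe_depth = 200), "ordered")
  expect_error(make_phantom("single_reflector", reflector_depth = 500),
               "depth window")
})

test_that("lesion phantoms share geometry and differ only in nanorod load", {
  les <- make_phantom("lcnv_lesion", n_lateral = 12, n_bscan = 3, seed = 2)
  ctl <- make_phantom("lcnv_control", n_lateral = 12, n_bscan = 3, seed = 2)
  expect_equal(les$reflectors, ctl$reflectors)
  diffmap <- les$absorber_map - ctl$absorber_map
  expect_true(all(diffmap >= 0))
  expect_gt(sum(diffmap), 0)
  mask <- lesion_mask_from_truth(les, les$depth_grid)
  # all the extra absorber sits inside the dome
  expect_true(all(diffmap[!mask$mask] == 0))
})

test_that("true amplitude is exactly linear in power and concentration", {
  tr <- retina_phantom(seed = 3)
  a1 <- true_amplitude(tr, 2)
  expect_equal(true_amplitude(tr, 4), 2 * a1)
  tr2 <- tr
  tr2$absorber_map <- 2 * tr$absorber_map
  expect_equal(true_amplitude(tr2, 2), 2 * a1)
  # holds in every coupling mode
  for (cp in c("local", "cumulative", "diffusive")) {
    expect_equal(true_amplitude(tr, 6, coupling = cp),
                 3 * true_amplitude(tr, 2, coupling = cp))
  }
})

test_that("modulation waveform has the analytic Fourier structure", {
  fs <- 10000; f0 <- 500
  t <- (0:699) / fs
  fourier_amp <- function(m) {
    # amplitude of the f0 component by direct projection (integer cycles)
    2 * Mod(sum(m * exp(-2i * pi * f0 * t))) / length(m)
  }
  m_sine <- modulation_waveform(t, f0, mode = "pure_sine")
  expect_true(all(m_sine >= 0 & m_sine <= 1))
  expect_equal(fourier_amp(m_sine), 0.5, tolerance = 1e-12)

  # tau -> 0: ideal square wave, fundamental 4/pi * (peak-to-peak / 2)
  m_sq <- modulation_waveform(t, f0, mode = "square_lowpass", tau_s = 1e-9)
  # continuous-time fundamental is 4/pi * (peak-to-peak/2); the 20-sample
  # discretization of one period deviates by sin-ratio factors ~0.4%
  expect_equal(fourier_amp(m_sq), (4 / pi) * 0.5, tolerance = 5e-3)

  # heavy low-pass attenuates the fundamental below the ideal square's
  m_lp <- modulation_waveform(t, f0, mode = "square_lowpass",
                              tau_s = 10 / f0)
  expect_lt(fourier_amp(m_lp), fourier_amp(m_sq))
  expect_true(all(m_lp >= 0 & m_lp <= 1))
  expect_error(modulation_waveform(t, f0, mode = "square_lowpass",
                                   tau_s = 0), "tau")
})

test_that("simulated record holds the expected number of modulation periods", {
  cfg <- acq_config()  # 700 repeats at 10 kHz, 500 Hz drive
  expect_equal(modulation_periods(cfg), 35)
  tr <- mirror_phantom(seed = 1)
  raw <- simulate_mscan(tr, small_config(128, 40), power = 1)
  expect_equal(ncol(raw$spectra), 40)
})

test_that("zero drive leaves the phase constant and the pipeline silent", {
  cfg <- small_config(256, 60)
  tr <- mirror_phantom(kappa = 5, seed = 2)
  raw <- simulate_mscan(tr, cfg, power = 0)
  # noiseless, P = 0: all time samples identical
  expect_lt(max(abs(raw$spectra - raw$spectra[, 1])), 1e-10)
  p <- process_mscan(raw, depth_window_um = c(150, 250), n_out = 64)
  expect_lt(max(p$opl_amplitude), 1e-6)
})

test_that("reflectors beyond the unambiguous range are rejected", {
  cfg <- small_config(256, 8)
  tr <- mirror_phantom(depth = 2300, seed = 1, depth_max_um = 2500)
  expect_error(simulate_mscan(tr, cfg, power = 1), "unambiguous")
})

test_that("volume simulation records truth and reproduces under a seed", {
  cfg <- small_config(128, 16)
  tr <- retina_phantom(n_lateral = 10, seed = 6)
  mot <- list(amplitude_px = 4, freq_hz = 1.5, drift_px = 1, pixel_um = 1)
  v1 <- simulate_volume(tr, cfg, motion = mot, dropout_prob = 0.2, seed = 9)
  v2 <- simulate_volume(tr, cfg, motion = mot, dropout_prob = 0.2, seed = 9)
  expect_identical(v1$truth$dropout_columns, v2$truth$dropout_columns)
  expect_identical(v1$bscans[[1]][[3]]$spectra, v2$bscans[[1]][[3]]$spectra)
  expect_length(v1$truth$motion_trace, 10)
  # requested zero-motion trace is recorded as exactly zero
  v0 <- simulate_volume(tr, cfg, motion = list(amplitude_px = 0, drift_px = 0),
                        seed = 9)
  expect_true(all(v0$truth$motion_trace == 0))
})
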