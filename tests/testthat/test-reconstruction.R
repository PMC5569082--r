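test_that("k-resampling preserves constants and already-uniform grids", {
  cfg <- small_config(256, 4)
  lam <- seq(800, 920, length.out = 256)
  raw <- raw_mscan(matrix(3, 256, 4), lam, cfg)
  ks <- resample_to_wavenumber(raw)
  expect_lt(max(abs(ks$spectra - 3)), 1e-9)
  expect_true(all(diff(ks$k_grid) > 0))

  # grid already uniform in k: resampling is the identity at the nodes
  kuni <- seq(2 * pi / 920, 2 * pi / 800, length.out = 256)
  lam_k <- rev(2 * pi / kuni)
  sp <- matrix(abs(rnorm(256 * 4)) + 1, 256, 4)
  raw2 <- raw_mscan(sp, lam_k, cfg)
  ks2 <- resample_to_wavenumber(raw2)
  expect_lt(max(abs(ks2$spectra - sp[rev(seq_len(256)), ])), 1e-10)
})

test_that("resampling sharpens the depth peak of a constant-z fringe", {
  cfg <- small_config(1024, 2)
  lam0 <- cfg$center_wavelength; bw <- cfg$bandwidth; ri <- cfg$refractive_index
  lam <- seq(lam0 - 1.5 * bw, lam0 + 1.5 * bw, length.out = 1024)
  z_nm <- 300 * 1000
  fr <- cos(2 * ri * (2 * pi / lam) * z_nm) + 1.5
  raw <- raw_mscan(matrix(fr, 1024, 2), lam, cfg)

  width_of <- function(mag) {
    pk <- max(mag)
    sum(mag >= pk / 2)     # FFT-oracle peak width in bins at half max
  }
  # FFT directly on the wavelength-ordered (non-uniform-k) samples
  mag_raw <- Mod(stats::fft(fr - mean(fr)))[1:512]
  ks <- resample_to_wavenumber(raw)
  s <- ks$spectra[, 1] - mean(ks$spectra[, 1])
  mag_res <- Mod(stats::fft(s))[1:512]
  expect_gt(width_of(mag_raw) / width_of(mag_res), 1)
})

test_that("temporal-mean background subtraction removes static content", {
  sp <- matrix(rep(sin(1:64) + 10, 5), 64, 5)
  out <- subtract_background(sp)
  expect_lt(max(abs(out)), 1e-12)

  fringe <- outer(sin((1:64) / 3), rep(1, 5)) + 100
  out2 <- subtract_background(fringe)
  expect_lt(max(abs(rowMeans(out2))), 1e-12)

  # time-varying fringe phase: per-sample amplitude preserved; only the
  # subtracted mean carries |mean(exp(i phi))|
  phi <- c(0, pi / 2, pi, 3 * pi / 2)
  k <- (1:64) / 3
  sp3 <- sapply(phi, function(p) cos(k + p))
  out3 <- subtract_background(sp3)
  expect_equal(out3, sp3 - Re(outer(exp(1i * k), rep(mean(exp(1i * phi)), 4))),
               tolerance = 1e-12)
})

test_that("chirp-z over the full range reproduces the FFT bin-for-bin", {
  ks <- kspace_fixture(z_um = 200, n = 512)
  n <- length(ks$k_grid)
  ri <- ks$config$refractive_index
  dk <- diff(ks$k_grid[1:2])
  z_full <- 2 * pi / (2 * ri * dk)            # full Nyquist span, nm
  cm <- chirpz_to_depth(ks, c(0, z_full / 1000), n_out = n)
  # FFT oracle with the analytic carrier from k_min
  zs <- (0:(n - 1)) * z_full / n
  oracle <- stats::fft(ks$spectra[, 1]) * exp(-2i * ri * ks$k_grid[1] * zs)
  err <- max(Mod(cm$field[, 1] - oracle)) / max(Mod(oracle))
  expect_lt(err, 1e-9)
})

test_that("zoomed chirp-z localizes a reflector at its true depth", {
  ks <- kspace_fixture(z_um = 200, n = 512)
  cm <- chirpz_to_depth(ks, c(150, 250), n_out = 200)
  pk <- cm$depth_grid[which.max(Mod(cm$field[, 1]))]
  expect_lt(abs(pk - 200), diff(cm$depth_grid[1:2]) / 2 + 1e-9)
})

test_that("delta-like broadband spectrum spreads flat across depth", {
  ks <- kspace_fixture(z_um = 200, n = 256)
  ks$spectra[] <- 0
  ks$spectra[128, ] <- 1
  cm <- chirpz_to_depth(ks, c(50, 350), n_out = 128)
  mag <- Mod(cm$field[, 1])
  expect_lt(diff(range(mag)) / mean(mag), 1e-9)
})

test_that("depth transform is linear and rejects out-of-range windows", {
  ks1 <- kspace_fixture(z_um = 150, n = 256)
  ks2 <- kspace_fixture(z_um = 230, n = 256)
  ks_sum <- ks1
  ks_sum$spectra <- ks1$spectra + ks2$spectra
  w <- c(100, 300)
  f1 <- chirpz_to_depth(ks1, w, 128)$field
  f2 <- chirpz_to_depth(ks2, w, 128)$field
  fs <- chirpz_to_depth(ks_sum, w, 128)$field
  expect_equal(fs, f1 + f2, tolerance = 1e-12)
  expect_error(chirpz_to_depth(ks1, c(0, 1e6), 128), "unambiguous")
})

test_that("depth transform conserves energy over the full range", {
  # Parseval for the unitary-normalized DFT case
  ks <- kspace_fixture(z_um = 120, n = 256)
  n <- 256
  ri <- ks$config$refractive_index
  dk <- diff(ks$k_grid[1:2])
  z_full <- 2 * pi / (2 * ri * dk) / 1000
  f <- chirpz_to_depth(ks, c(0, z_full), n_out = n)$field[, 1]
  expect_equal(sum(Mod(f)^2) / n, sum(ks$spectra[, 1]^2), tolerance = 1e-9)
})

test_that("dispersion estimation recovers known coefficients", {
  cfg <- small_config(1024, 8)
  tr <- mirror_phantom(kappa = 1.56, seed = 1)
  raw <- simulate_mscan(tr, cfg, power = 0, dispersion = c(3e7, 1e11))
  dm <- estimate_dispersion(resample_to_wavenumber(raw))
  expect_lt(abs(dm$a2 - 3e7) / 3e7, 0.05)
  expect_lt(abs(dm$a3 - 1e11) / 1e11, 0.05)

  # corrected peak within 1% of the dispersion-free reconstruction
  peak_of <- function(raw, model) {
    ks <- resample_to_wavenumber(raw)
    ks$spectra <- analytic_signal(remove_source_envelope(ks$spectra) *
                                    tukey_window(1024, 0.25))
    max(Mod(chirpz_to_depth(apply_dispersion(ks, model),
                            c(100, 300), 512)$field))
  }
  h_corr <- peak_of(raw, dm)
  h_free <- peak_of(simulate_mscan(tr, cfg, power = 0), dispersion_model(0, 0))
  expect_lt(abs(h_corr - h_free) / h_free, 0.01)

  # sharpness at the recovered optimum beats perturbed coefficients
  h_pert <- peak_of(raw, dispersion_model(dm$a2 * 1.5, dm$a3))
  expect_gt(h_corr, h_pert)

  # dispersion-free input: coefficients near zero
  dm0 <- estimate_dispersion(resample_to_wavenumber(
    simulate_mscan(tr, cfg, power = 0)))
  expect_lt(abs(dm0$a2), 3e7 * 0.02)

  # flat/noise-only input: warning and identity model
  flat <- simulate_mscan(tr, cfg, power = 0)
  flat$spectra[] <- 1
  expect_warning(dmf <- estimate_dispersion(resample_to_wavenumber(flat)),
                 "no clear reflector")
  expect_equal(c(dmf$a2, dmf$a3), c(0, 0))
})
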