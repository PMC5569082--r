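test_that("axial profile averages valid pixels only", {
  b <- matrix(2, 64, 10)
  expect_equal(axial_profile(b), rep(2, 64))
  b[, 1:5] <- 7
  v <- matrix(TRUE, 64, 10); v[, 1:5] <- FALSE
  expect_equal(axial_profile(b, v), rep(2, 64))
  expect_error(axial_profile(matrix(numeric(0), 0, 0)))
})

test_that("peak and FWHM match closed-form shapes", {
  z <- 1:201
  gauss <- exp(-0.5 * ((z - 100) / 5)^2)
  m <- find_peak_fwhm(gauss, z)
  expect_equal(m$peak_depth, 100)
  expect_equal(m$fwhm, 2 * sqrt(2 * log(2)) * 5, tolerance = 0.1)
  expect_true(m$band[1] < 100 && m$band[2] > 100)

  # scale invariance
  m5 <- find_peak_fwhm(5 * gauss, z)
  expect_equal(m5$fwhm, m$fwhm)
  # offset below half maximum does not move the crossings meaningfully
  tri <- pmax(0, 1 - abs(z - 50) / 8)   # triangle, half-width 8 -> fwhm 8
  mt <- find_peak_fwhm(tri, z)
  expect_equal(mt$fwhm, 8, tolerance = 1e-9)

  # plateau at the maximum: center used
  plat <- c(rep(0, 10), rep(1, 5), rep(0, 10))
  mp <- find_peak_fwhm(plat, seq_along(plat))
  expect_equal(mp$peak_depth, 13)
  # no crossing on one side: truncated with warning
  ramp <- seq(0, 1, length.out = 50)
  expect_warning(mr <- find_peak_fwhm(ramp, 1:50), "truncated")
  expect_equal(mr$band[2], 50)
})

test_that("background statistics follow their contracts", {
  z <- 1:101
  prof <- rep(1, 101); prof[48:52] <- c(5, 8, 10, 8, 5)
  m <- find_peak_fwhm(prof, z)
  bs <- background_stats(prof, m$band, z, margin = 1)
  expect_equal(bs$mean_background, 1)
  expect_equal(bs$peak_to_background, 10)

  prof0 <- rep(0, 101); prof0[50] <- 10
  m0 <- find_peak_fwhm(prof0, z)
  bs0 <- background_stats(prof0, m0$band, z, margin = 1)
  expect_true(is.na(bs0$peak_to_background))
  expect_error(background_stats(prof, c(-10, 120), z, margin = 1), "outside")
})

test_that("power series drives background up and peak-to-background down", {
  cfg <- small_config(512, 200)
  tr <- retina_phantom(n_lateral = 6, seed = 31)
  bg <- rt <- pk <- c()
  for (P in c(1, 2, 4, 8)) {
    prof <- NULL; dg <- NULL
    for (l in 1:6) {
      p <- process_mscan(simulate_mscan(tr, cfg, power = P, lateral = l),
                         depth_window_um = c(60, 340), n_out = 256)
      prof <- cbind(prof, p$opl_amplitude); dg <- p$depth_grid
    }
    pr <- rowMeans(prof)
    m <- find_peak_fwhm(pr, dg)
    b <- background_stats(pr, m$band, dg, margin = diff(dg[1:2]))
    bg <- c(bg, b$mean_background); rt <- c(rt, b$peak_to_background)
    pk <- c(pk, m$peak_value)
  }
  expect_true(all(diff(bg) > 0))
  expect_true(all(diff(rt) < 0))
  expect_true(all(diff(pk) > 0))
})

test_that("lesion means respect masks and the area inclusion filter", {
  v <- array(0, c(20, 10, 2))
  mask <- array(FALSE, c(20, 10, 2))
  mask[5:9, 3:4, 1] <- TRUE          # 10 voxels
  v[mask] <- 2
  v[1, 1, 1] <- 99                   # outside the mask: must not matter
  pt <- image_volume(v, 1, "ptoct_nm")
  ls <- lesion_mean(pt, roi_mask(mask), analysis_config(area_threshold = 5))
  expect_equal(ls$mean_signal, 2)
  expect_equal(ls$roi_voxels, 10)
  expect_true(ls$included)

  # boundary case: area equal to the threshold is excluded (> required)
  ls2 <- lesion_mean(pt, roi_mask(mask), analysis_config(area_threshold = 10))
  expect_false(ls2$included)
  expect_error(lesion_mean(pt, roi_mask(array(FALSE, c(20, 10, 2)))), "empty")
})

test_that("nanorod lesions read higher than controls over the same ROI", {
  cfg <- small_config(512, 140)
  res <- list()
  for (kind in c("lcnv_lesion", "lcnv_control")) {
    tr <- make_phantom(kind, n_lateral = 10, n_bscan = 1, sigma_phi = 0.05,
                       sigma_s = 0.02, jitter_um = 2, seed = 32)
    vol <- simulate_volume(tr, cfg, motion = list(amplitude_px = 0,
                                                  drift_px = 0), seed = 32)
    pv <- process_volume(vol, depth_window_um = c(60, 340), n_out = 256)
    mask <- lesion_mask_from_truth(tr, pv$depth_grid)
    res[[kind]] <- lesion_mean(pv$ptoct, mask,
                               analysis_config(area_threshold = 10),
                               group = kind)$mean_signal
  }
  expect_gt(res$lcnv_lesion, res$lcnv_control)
})

test_that("en-face projection localizes the lesion and averages exactly", {
  # single bright voxel projects to v / depth
  v <- array(0, c(25, 6, 3)); v[10, 2, 2] <- 5
  oct <- image_volume(array(1, c(25, 6, 3)), 1, "oct_log_intensity")
  ef <- enface_projection(oct, image_volume(v, 1, "ptoct_nm"))
  expect_equal(ef$ptoct[2, 2], 5 / 25)
  expect_equal(ef$ptoct[1, 1], 0)
  expect_equal(dim(ef$composite), c(6, 3, 3))

  # uniform volumes project uniformly
  ef0 <- enface_projection(oct, image_volume(array(2, c(25, 6, 3)), 1,
                                             "ptoct_nm"))
  expect_true(all(abs(ef0$ptoct - 2) < 1e-12))

  # lesion phantom: green-channel centroid colocalizes with the dome
  cfg <- small_config(256, 100)
  tr <- make_phantom("lcnv_lesion", n_lateral = 12, n_bscan = 3,
                     sigma_phi = 0.05, sigma_s = 0.02, seed = 33)
  vol <- simulate_volume(tr, cfg, motion = list(amplitude_px = 0,
                                                drift_px = 0), seed = 33)
  pv <- process_volume(vol, depth_window_um = c(60, 340), n_out = 128)
  ef2 <- enface_projection(pv$oct, pv$ptoct)
  w <- ef2$ptoct
  cx <- sum(row(w) * w) / sum(w)
  expect_lt(abs(cx - tr$geometry$lesion_center_lateral), 2)
})

test_that("retina-band mean summarizes the melanin signal per eye", {
  cfg <- small_config(512, 140)
  tr <- retina_phantom(n_lateral = 4, seed = 34)
  vol <- simulate_volume(tr, cfg, motion = list(amplitude_px = 0,
                                                drift_px = 0), seed = 34)
  pv <- process_volume(vol, depth_window_um = c(60, 340), n_out = 256)
  band <- c(tr$geometry$ilm_depth, tr$geometry$choroid_end)
  m_pig <- retina_band_mean(pv$ptoct, pv$depth_grid, band)
  expect_gt(m_pig, 0.5)
  expect_error(retina_band_mean(pv$ptoct, pv$depth_grid, c(500, 600)),
               "empty depth band")
})
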