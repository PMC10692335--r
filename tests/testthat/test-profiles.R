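test_that("band integration sums the expected rows and converts widths exactly", {
  img <- matrix(2, 60, 60)
  p <- extract_profile(img, axis = "lateral", half_width_px = 2.5,
                       pixel_pitch_nm = 40)
  expect_equal(p$band_px, 6L)
  expect_true(all(p$intensity == 12))
  expect_equal(p$band_nm, 240)
  expect_equal(px_to_nm(5, 40), 200)   # the nominal 5 px zone on this raster
  expect_equal(px_to_nm(6, 40), 240)   # the ratio offset used downstream
  expect_equal(px_to_nm(5, 31), 155)   # finer-raster instrument
  expect_equal(nm_to_px(562, 40), 14.05)
  # positions: uniform spacing, centred on the crop midline
  expect_equal(unique(round(diff(p$position_nm), 9)), 40)
  expect_equal(p$position_nm[30], -20)
  expect_equal(p$position_nm[31], 20)
  expect_lte(length(p$position_nm), 60)

  # exact row/column bookkeeping against manual sums
  set.seed(2)
  img2 <- matrix(runif(3600), 60, 60)
  pl <- extract_profile(img2, axis = "lateral", half_width_px = 2.5,
                        pixel_pitch_nm = 40)
  expect_identical(pl$intensity, unname(rowSums(img2[, 28:33])))
  pc <- extract_profile(img2, axis = "chromosomal", half_width_px = 20.5,
                        pixel_pitch_nm = 40)
  expect_identical(pc$intensity, unname(colSums(img2[10:51, ])))
  expect_error(extract_profile(img2, half_width_px = 40, pixel_pitch_nm = 40),
               "band")
})

test_that("a noiseless render's profile matches dense band integration of the model", {
  cfg <- fix_config()
  p <- render_particle(cfg, NULL, angle_deg = 0, separation_nm = 562)
  prof <- extract_profile(p$patch[, , 5, "cenpa"], axis = "lateral",
                          half_width_px = 2.5, pixel_pitch_nm = 40)
  oracle <- oracle_render_cenpa(cfg, 0, 562, oversample = 4)
  oracle_prof <- rowSums(oracle[, 28:33, 5])
  expect_lt(max(abs(prof$intensity - oracle_prof)) / max(oracle_prof), 2e-3)
})

test_that("exact Gaussian profiles are recovered with the right model order", {
  x <- (seq_len(60) - 30.5) * 40
  y1 <- 0.7 + 3 * exp(-(x - 110)^2 / (2 * 130^2))
  f1 <- fit_gaussians(list(position_nm = x, intensity = y1))
  expect_equal(f1$k, 1L)
  expect_equal(f1$peaks$center_nm, 110, tolerance = 1e-5)
  expect_equal(f1$peaks$sigma_nm, 130, tolerance = 1e-5)
  expect_equal(f1$offset, 0.7, tolerance = 1e-6)
  expect_true(is.na(peak_to_peak(f1)))

  f2 <- fit_gaussians(fix_two_gauss_profile(p2p = 562, sigma = 81))
  expect_equal(f2$k, 2L)
  expect_equal(peak_to_peak(f2), 562, tolerance = 1e-3)
  expect_equal(mean(f2$peaks$sigma_nm), 81, tolerance = 1e-3)
})

test_that("peak-to-peak estimates are invariant to scaling and offset", {
  prof <- fix_two_gauss_profile()
  base <- peak_to_peak(fit_gaussians(prof))
  prof2 <- prof; prof2$intensity <- prof$intensity * 37 + 1000
  expect_equal(peak_to_peak(fit_gaussians(prof2)), base, tolerance = 1e-6)
})

test_that("AIC selection never picks a dominated model and matches brute-force grid fits", {
  set.seed(5)
  x <- seq(-100, 95, by = 5)
  y <- 0.5 + exp(-(x - 30)^2 / (2 * 20^2)) + 0.8 * exp(-(x + 40)^2 / (2 * 15^2)) +
    rnorm(length(x), 0, 0.02)
  f <- fit_gaussians(list(position_nm = x, intensity = y), k_max = 2)
  expect_equal(unname(f$aic), min(f$aic_by_k))

  o1 <- oracle_grid_fit(x, y, 1, seq(-60, 60, 5), c(10, 15, 20, 30))
  o2 <- oracle_grid_fit(x, y, 2, seq(-60, 60, 5), c(10, 15, 20, 30))
  expect_equal(f$k, c(1, 2)[which.min(c(o1$aic, o2$aic))])
  expect_equal(sort(f$peaks$center_nm), o2$centers, tolerance = 5)

  # random profiles: the selected AIC is the attained minimum
  for (s in 1:3) {
    set.seed(s)
    yr <- 1 + exp(-(x - runif(1, -50, 50))^2 / (2 * 25^2)) +
      rnorm(length(x), 0, 0.05)
    fr <- fit_gaussians(list(position_nm = x, intensity = yr))
    expect_equal(unname(fr$aic), min(fr$aic_by_k))
  }
})

test_that("the cohesin lateral profile with flank bumps selects three peaks", {
  cfg <- geometry_config(cohesin_class = "central", cohesin_flank_frac = 0.25)
  p <- render_particle(cfg, NULL, angle_deg = 0, separation_nm = 562)
  prof <- extract_profile(p$patch[, , 5, "marker"], axis = "lateral",
                          half_width_px = 2.5, pixel_pitch_nm = 40)
  f <- fit_gaussians(prof, k_max = 3)
  expect_equal(f$k, 3L)
  centers <- sort(f$peaks$center_nm)
  expect_equal(centers[2], 0, tolerance = 10)
  expect_equal(abs(centers[c(1, 3)]), c(380, 380), tolerance = 40)
})

test_that("FWHM and cloud metrics recover constructed widths", {
  x <- (seq_len(60) - 30.5) * 40
  band <- pnorm((x + 400) / 50) - pnorm((x - 400) / 50)
  prof <- structure(list(position_nm = x, intensity = band, axis = "chromosomal",
                         band_px = 6, band_nm = 240, pixel_pitch_nm = 40),
                    class = "spa_profile")
  expect_equal(profile_fwhm(prof), 800, tolerance = 2)

  cfg <- preset_cenpb()
  fit <- fit_gaussians(structure(list(
    position_nm = x,
    intensity = exp(-(x - cfg$satellite_center_nm)^2 / (2 * 150^2)) +
      exp(-(x + cfg$satellite_center_nm)^2 / (2 * 150^2)),
    axis = "lateral", band_px = 6, band_nm = 240, pixel_pitch_nm = 40),
    class = "spa_profile"))
  cm <- cloud_metrics(fit)
  expect_equal(cm$peak_offset_nm, 209, tolerance = 1)
  expect_equal(cm$dip_width_nm, 418, tolerance = 2)
  expect_gt(cm$dip_depth_frac, 0.1)

  # a unimodal fit has no dip
  f1 <- fit_gaussians(list(position_nm = x,
                           intensity = exp(-x^2 / (2 * 200^2))), k_max = 1)
  expect_true(is.na(cloud_metrics(f1)$dip_width_nm))
})

test_that("kymograph columns equal individual profiles in the requested order", {
  cfg <- fix_config()
  als <- lapply(c(0, 40, 80), function(s) {
    p <- render_particle(cfg, noise_config(seed = s + 1), angle_deg = 0,
                         separation_nm = 500 + s)
    structure(list(patch = p$patch[, , 5, ], particle_id = s / 40 + 1,
                   pixel_pitch_nm = 40),
              class = "aligned_particle")
  })
  ky <- build_kymograph(als, channel = "marker", ordering = c(2, 3, 1))
  expect_equal(ncol(ky$data), 3L)
  p2 <- extract_profile(als[[2]], channel = "marker", axis = "chromosomal",
                        half_width_px = 2.5)
  expect_identical(ky$data[, 1], p2$intensity)
  expect_identical(ky$ordering, c(2, 3, 1))
})
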