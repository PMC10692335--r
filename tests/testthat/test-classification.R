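make_axial_profile <- function(intensity, pitch = 40) {
  x <- (seq_len(60) - 30.5) * pitch
  structure(list(position_nm = x, intensity = intensity, axis = "chromosomal",
                 band_px = 6, band_nm = 6 * pitch, pixel_pitch_nm = pitch),
            class = "spa_profile")
}

test_that("center ratio is 1 on flat profiles, directional for split/central, scale-invariant", {
  flat <- make_axial_profile(rep(3, 60))
  expect_equal(center_ratio(flat), 1)
  expect_equal(center_ratio(flat, mode = "flank_over_center"), 1)

  for (cl in c("split", "central", "uniform")) {
    cfg <- geometry_config(cohesin_class = cl)
    p <- render_particle(cfg, NULL, angle_deg = 0, separation_nm = 562)
    prof <- extract_profile(p$patch[, , 5, "marker"], axis = "chromosomal",
                            half_width_px = 2.5, pixel_pitch_nm = 40)
    r <- center_ratio(prof)
    want <- oracle_center_ratio(cfg, cl)
    expect_equal(r, want, tolerance = 0.05)
    if (cl == "split") expect_lt(r, 1)
    if (cl == "central") expect_gt(r, 1)
    # scaling invariance
    prof2 <- prof; prof2$intensity <- prof$intensity * 12.5
    expect_equal(center_ratio(prof2), r, tolerance = 1e-12)
    # the literal inverse mode is the reciprocal
    expect_equal(center_ratio(prof, mode = "flank_over_center"), 1 / r,
                 tolerance = 1e-12)
  }

  zero <- make_axial_profile(c(rep(0, 27), rep(1, 6), rep(0, 27)))
  r0 <- center_ratio(zero)
  expect_true(is.infinite(r0))
  short <- make_axial_profile(rep(1, 60))
  short$position_nm <- short$position_nm / 10
  expect_error(center_ratio(short), "cover")
})

test_that("ranking and partitioning reproduce the published class sizes and tie-break deterministically", {
  set.seed(31)
  ratios <- runif(463, 0.3, 2)
  a <- rank_and_partition(ratios)
  expect_identical(as.integer(table(a$class)[c("split", "uniform", "central")]),
                   c(200L, 150L, 113L))
  expect_identical(a$rank, 1:463)
  expect_identical(a$ratio, sort(ratios))
  # class blocks are contiguous in rank, split < uniform < central
  expect_identical(unique(a$class), c("split", "uniform", "central"))

  small <- rank_and_partition(c(3, 1, 2), boundaries = "equal")
  expect_identical(small$class, c("split", "uniform", "central"))
  expect_identical(small$particle_id, c(2L, 3L, 1L))

  tied <- rank_and_partition(rep(1, 6), boundaries = "equal")
  expect_identical(tied$particle_id, 1:6)
  expect_identical(tied, rank_and_partition(rep(1, 6), boundaries = "equal"))

  withinf <- rank_and_partition(c(0.5, Inf, 1, NA), boundaries = "equal")
  expect_true(all(withinf$particle_id[3:4] %in% c(2L, 4L)))
})

test_that("particles are assigned their generating class from rendered profiles", {
  # profile-level rendering (band + class modulation + noise), class mix in
  # the generator's proportions
  set.seed(77)
  cfg <- fix_config()
  n <- 232
  counts <- censpa:::.apportion(n, c(split = 200, uniform = 150,
                                     central = 113) / 463)
  classes <- sample(rep(c("split", "uniform", "central"), counts))
  x <- (seq_len(60) - 30.5) * 40
  ratios <- vapply(seq_len(n), function(i) {
    mod <- switch(classes[i],
      uniform = 1,
      split = 1 - cfg$dip_depth_frac * exp(-x^2 / (2 * 120^2)),
      central = 1 + cfg$enhancement_frac * exp(-x^2 / (2 * 120^2)))
    band <- (pnorm((x + 400) / 50) - pnorm((x - 400) / 50)) * mod
    # band-integrated counts over a 6 px lateral zone at the configured
    # amplitude, with shot + camera noise
    clean <- band * cfg$amplitudes[["marker"]] * 6 + cfg$background * 6
    noisy <- rpois(60, clean) + rnorm(60, 0, 3 * sqrt(6))
    center_ratio(make_axial_profile(noisy))
  }, numeric(1))
  a <- rank_and_partition(ratios)
  truth_by_id <- classes[a$particle_id]
  expect_gte(mean(a$class == truth_by_id), 0.85)
  # confusion concentrated at adjacent classes
  expect_lt(mean(a$class == "central" & truth_by_id == "split") +
              mean(a$class == "split" & truth_by_id == "central"), 0.02)
})

test_that("class summaries compare separations without inventing differences", {
  set.seed(12)
  n <- 120L
  particles <- data.frame(particle_id = 1:n,
                          separation_nm = rnorm(n, 562, 91.6))
  ratios <- rnorm(n, 1, 0.3)  # unrelated to separation: null is true
  a <- rank_and_partition(ratios, boundaries = "equal")
  cs <- class_summary(a, particles)
  expect_s3_class(cs, "class_summary")
  expect_identical(sort(cs$classes$class), c("central", "split", "uniform"))
  expect_identical(sum(cs$classes$n), n)
  expect_true(cs$kruskal$p.value >= 0 && cs$kruskal$p.value <= 1)
  expect_identical(nrow(cs$dunn), 3L)
  expect_true(all(cs$dunn$p_adj >= cs$dunn$p - 1e-12))

  # a gross separation shift is detected
  particles2 <- particles
  big <- a$particle_id[a$class == "central"]
  particles2$separation_nm[big] <- particles2$separation_nm[big] + 500
  cs2 <- class_summary(a, particles2)
  expect_lt(cs2$kruskal$p.value, 1e-6)

  # single class present: tests skipped with a notice
  a1 <- a; a1$class <- "uniform"
  expect_message(cs1 <- class_summary(a1, particles), "skipped")
  expect_null(cs1$kruskal)
})
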