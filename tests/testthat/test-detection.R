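test_that("a noiseless particle yields exactly two candidates and an all-zero image none", {
  p <- render_particle(fix_config(), NULL, angle_deg = 25, separation_nm = 562)
  cand <- detect_peaks(p$patch[, , , "cenpa"], threshold_quantile = 0.99)
  expect_equal(nrow(cand), 2L)
  expect_equal(sort(order(cand$intensity)), 1:2)

  expect_equal(nrow(detect_peaks(array(0, c(20, 20, 5)))), 0L)
  expect_equal(nrow(detect_peaks(array(7, c(20, 20, 5)))), 0L)
})

test_that("detection finds nearly all true clusters on a default-noise spread", {
  sp <- fix_spread(n = 20, seed = 42)
  cand <- detect_peaks(sp$stack[, , , "cenpa"])
  truth_pos <- truth_clusters(sp$truth)
  matched <- 0L
  for (i in seq_len(nrow(truth_pos))) {
    d <- sqrt((cand$x_nm - truth_pos[i, 1])^2 +
                (cand$y_nm - truth_pos[i, 2])^2)
    if (any(d <= 2 * 40)) matched <- matched + 1L
  }
  expect_gte(matched, 38L)
})

test_that("pairing handles doublets, orphans and matches exhaustive matching", {
  two <- data.frame(x_nm = c(1000, 1562), y_nm = 1000, z_nm = 500,
                    intensity = c(5, 5))
  pp <- pair_peaks(two)
  expect_equal(nrow(pp$pairs), 1L)
  expect_equal(pp$pairs$separation_nm, 562)

  one <- two[1, ]
  pp1 <- pair_peaks(one)
  expect_equal(nrow(pp1$pairs), 0L)
  expect_equal(pp1$orphans, 1L)

  # two particles 5 um apart: identical to brute-force matching
  four <- data.frame(
    x_nm = c(1000, 1562, 6000, 6600), y_nm = c(1000, 1000, 5000, 5000),
    z_nm = 500, intensity = c(5, 4, 6, 3))
  pp4 <- pair_peaks(four)
  or4 <- oracle_matching(cbind(four$x_nm, four$y_nm, four$z_nm), 200, 1200)
  expect_equal(as.matrix(pp4$pairs[, c("i", "j")]), or4$pairs,
               ignore_attr = TRUE)

  # randomised sets: every returned pair respects the gate and the
  # mutual-nearest-neighbour property, and never exceeds the exhaustive
  # maximum-cardinality matching
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    cand <- data.frame(x_nm = runif(n, 0, 4000), y_nm = runif(n, 0, 4000),
                       z_nm = runif(n, 0, 500), intensity = runif(n, 1, 10))
    got <- pair_peaks(cand)
    want <- oracle_matching(cbind(cand$x_nm, cand$y_nm, cand$z_nm), 200, 1200)
    expect_lte(nrow(got$pairs), want$npairs)
    if (nrow(got$pairs) > 0) {
      expect_true(all(got$pairs$separation_nm >= 200 &
                        got$pairs$separation_nm <= 1200))
      # each member's nearest gated neighbour is its partner
      d <- as.matrix(dist(cbind(cand$x_nm, cand$y_nm, cand$z_nm)))
      d[d < 200 | d > 1200] <- Inf
      diag(d) <- Inf
      for (r in seq_len(nrow(got$pairs))) {
        i <- got$pairs$i[r]; j <- got$pairs$j[r]
        expect_equal(min(d[i, ]), d[i, j])
        expect_equal(min(d[j, ]), d[i, j])
      }
    }
  }

  # order invariance
  perm <- c(3, 1, 4, 2)
  ppP <- pair_peaks(four[perm, ])
  remap <- t(apply(as.matrix(ppP$pairs[, c("i", "j")]), 1,
                   function(r) sort(perm[r])))
  expect_equal(remap[order(remap[, 1]), , drop = FALSE],
               as.matrix(pp4$pairs[, c("i", "j")]), ignore_attr = TRUE)
})

test_that("3D Gaussian refinement recovers an off-grid centre to sub-hundredth pixel", {
  # point-sampled noiseless Gaussian at a known off-grid position
  pitch <- 40; zst <- 125
  ctr <- c(21.37 * pitch, 19.81 * pitch, 4.62 * zst)
  xs <- (seq_len(41) - 0.5) * pitch
  zs <- (seq_len(9) - 0.5) * zst
  img <- outer(outer(exp(-(xs - ctr[1])^2 / (2 * 81^2)),
                     exp(-(xs - ctr[2])^2 / (2 * 81^2))),
               exp(-(zs - ctr[3])^2 / (2 * 200^2))) * 50 + 3
  fit <- refine_center_gaussian3d(img, c(21, 20, 5))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$center_nm[1:2] - ctr[1:2])), 0.01 * pitch)
  expect_equal(fit$sigma_xy_nm, 81, tolerance = 1e-3)

  # translation equivariance: whole-pixel shift moves the centre exactly
  img_sh <- array(3, dim = dim(img))
  img_sh[4:41, , ] <- img[1:38, , ]
  fit_sh <- refine_center_gaussian3d(img_sh, c(24, 20, 5))
  expect_equal(fit_sh$center_nm[1] - fit$center_nm[1], 3 * pitch,
               tolerance = 1e-9)
  expect_equal(fit_sh$center_nm[2], fit$center_nm[2], tolerance = 1e-9)

  expect_error(refine_center_gaussian3d(img, c(2, 2, 5)), "window")
})

test_that("refinement agrees with exhaustive grid search of the centre", {
  pitch <- 40
  xs <- (seq_len(21) - 0.5) * pitch
  zs <- (seq_len(7) - 0.5) * 125
  ctr <- c(10.72 * pitch, 10.28 * pitch, 3.5 * 125)
  img <- outer(outer(exp(-(xs - ctr[1])^2 / (2 * 81^2)),
                     exp(-(xs - ctr[2])^2 / (2 * 81^2))),
               exp(-(zs - ctr[3])^2 / (2 * 200^2))) * 20 + 1
  fit <- refine_center_gaussian3d(img, c(11, 10, 4), window_px = c(11, 11, 7))
  # exhaustive 0.05 px grid over the centre, other parameters at truth
  grid <- seq(-1, 1, by = 0.05) * pitch
  rss <- outer(grid, grid, Vectorize(function(dx, dy) {
    mu <- outer(outer(exp(-(xs - (ctr[1] + dx))^2 / (2 * 81^2)),
                      exp(-(xs - (ctr[2] + dy))^2 / (2 * 81^2))),
                exp(-(zs - ctr[3])^2 / (2 * 200^2))) * 20 + 1
    sum((img - mu)^2)
  }))
  am <- which(rss == min(rss), arr.ind = TRUE)[1, ]
  expect_equal(fit$center_nm[1], ctr[1] + grid[am[1]], tolerance = 0.05 * pitch)
  expect_equal(fit$center_nm[2], ctr[2] + grid[am[2]], tolerance = 0.05 * pitch)
})

test_that("nearly all generated particles are detected and paired with few false pairs", {
  sp <- fix_spread(n = 30, seed = 11)
  parts <- find_particles(sp$stack)
  idx <- match_truth(parts, sp$truth)
  expect_gte(sum(!is.na(idx)) / nrow(sp$truth), 0.95)
  expect_lte(mean(is.na(idx)), 0.02)
  # refined separations track the generated ones
  ok <- !is.na(idx)
  expect_lt(max(abs(parts$separation_nm[ok] -
                      sp$truth$separation_nm[idx[ok]])), 60)
})
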