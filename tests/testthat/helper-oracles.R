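# Independent oracles used to check pipeline operations. These re-state the
# models and algorithms in brute-force form and stay independent of the
# package code paths they validate.

# Dense re-evaluation of the two-cluster CENP-A model, integrated per pixel
# on an `oversample` x `oversample` in-plane grid (z at slice centres).
oracle_render_cenpa <- function(config, angle_deg, separation_nm,
                                oversample = 4) {
  crop <- config$crop_px
  pitch <- config$pixel_pitch_nm
  nz <- config$n_z
  cx <- crop / 2 * pitch
  cz <- nz / 2 * config$z_step_nm
  th <- angle_deg * pi / 180
  s2 <- separation_nm / 2
  sig <- config$cenpa_sigma_nm
  sigz <- config$cenpa_sigma_z_nm
  amp <- config$amplitudes[["cenpa"]]
  sub <- (seq_len(oversample) - (oversample + 1) / 2) / oversample * pitch
  out <- array(config$background, dim = c(crop, crop, nz))
  zc <- (seq_len(nz) - 0.5) * config$z_step_nm
  for (i in seq_len(crop)) {
    for (j in seq_len(crop)) {
      xs <- (i - 0.5) * pitch + sub - cx
      ys <- (j - 0.5) * pitch + sub - cx
      acc <- 0
      for (dx in xs) for (dy in ys) {
        xp <- dx * cos(th) + dy * sin(th)
        yp <- -dx * sin(th) + dy * cos(th)
        acc <- acc +
          exp(-((xp - s2)^2 + yp^2) / (2 * sig^2)) +
          exp(-((xp + s2)^2 + yp^2) / (2 * sig^2))
      }
      lat <- amp * acc / oversample^2
      out[i, j, ] <- out[i, j, ] + lat * exp(-(zc - cz)^2 / (2 * sigz^2))
    }
  }
  out
}

# Exhaustive maximum-cardinality, minimum-total-distance matching of
# candidates under a separation gate (recursion over all pairings).
oracle_matching <- function(pos, min_sep, max_sep) {
  n <- nrow(pos)
  d <- as.matrix(dist(pos))
  best <- list(npairs = -1, total = Inf, pairs = NULL)
  recurse <- function(avail, pairs, total) {
    if (length(avail) < 2) {
      np <- nrow(pairs)
      if (np > best$npairs || (np == best$npairs && total < best$total)) {
        best <<- list(npairs = np, total = total, pairs = pairs)
      }
      return(invisible())
    }
    i <- avail[1]
    # leave i unmatched
    recurse(avail[-1], pairs, total)
    for (j in avail[-1]) {
      if (d[i, j] >= min_sep && d[i, j] <= max_sep) {
        recurse(setdiff(avail, c(i, j)),
                rbind(pairs, c(min(i, j), max(i, j))), total + d[i, j])
      }
    }
  }
  recurse(seq_len(n), matrix(numeric(0), 0, 2), 0)
  if (best$npairs > 0) {
    best$pairs <- best$pairs[order(best$pairs[, 1]), , drop = FALSE]
  }
  best
}

# Brute-force k-Gaussian fit: centres on a 5 nm grid, sigmas on a coarse
# grid, amplitudes and offset solved linearly; returns the RSS-minimising
# parameter set for a given k.
oracle_grid_fit <- function(x, y, k, center_grid, sigma_grid) {
  best <- list(rss = Inf)
  center_sets <- if (k == 1) matrix(center_grid, ncol = 1) else
    t(utils::combn(center_grid, k))
  sigma_sets <- as.matrix(expand.grid(rep(list(sigma_grid), k)))
  for (ci in seq_len(nrow(center_sets))) {
    for (si in seq_len(nrow(sigma_sets))) {
      X <- cbind(1, vapply(seq_len(k), function(m) {
        exp(-(x - center_sets[ci, m])^2 / (2 * sigma_sets[si, m]^2))
      }, numeric(length(x))))
      fit <- lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) {
        best <- list(rss = rss, centers = sort(center_sets[ci, ]),
                     sigmas = sigma_sets[si, ], coefs = fit$coefficients)
      }
    }
  }
  best$aic <- length(y) * log(best$rss / length(y)) + 2 * (3 * k + 1)
  best
}

# Point-in-region peak counting by explicit loops over a data.frame
# representation (chrom, start, end; 0-based half-open).
oracle_count_midpoints <- function(peaks_df, regions_df) {
  count <- 0L
  for (i in seq_len(nrow(peaks_df))) {
    mid <- (peaks_df$start[i] + peaks_df$end[i]) %/% 2  # 0-based midpoint
    for (j in seq_len(nrow(regions_df))) {
      if (peaks_df$chrom[i] == regions_df$chrom[j] &&
          mid >= regions_df$start[j] && mid < regions_df$end[j]) {
        count <- count + 1L
        break
      }
    }
  }
  count
}

oracle_overlap_fraction <- function(query_df, subject_df) {
  hit <- logical(nrow(query_df))
  for (i in seq_len(nrow(query_df))) {
    for (j in seq_len(nrow(subject_df))) {
      if (query_df$chrom[i] == subject_df$chrom[j] &&
          query_df$start[i] < subject_df$end[j] &&
          subject_df$start[j] < query_df$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  mean(hit)
}

# Per-locus replicate support counting for consensus peaks: merge all
# intervals by sweep, then count supporting replicates per merged locus.
oracle_consensus <- function(rep_dfs, min_support) {
  all_iv <- do.call(rbind, rep_dfs)
  all_iv <- all_iv[order(all_iv$chrom, all_iv$start), ]
  loci <- list()
  for (i in seq_len(nrow(all_iv))) {
    placed <- FALSE
    for (k in seq_along(loci)) {
      if (loci[[k]]$chrom == all_iv$chrom[i] &&
          all_iv$start[i] <= loci[[k]]$end) {
        loci[[k]]$end <- max(loci[[k]]$end, all_iv$end[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      loci[[length(loci) + 1]] <- list(chrom = all_iv$chrom[i],
                                       start = all_iv$start[i],
                                       end = all_iv$end[i])
    }
  }
  keep <- list()
  for (lc in loci) {
    support <- 0L
    for (rd in rep_dfs) {
      ov <- any(rd$chrom == lc$chrom & rd$start < lc$end & lc$start < rd$end)
      if (ov) support <- support + 1L
    }
    if (support >= min_support) keep[[length(keep) + 1]] <- c(lc, support = support)
  }
  keep
}

# Direct evaluation of the forward model's marker axial profile at the same
# pixel-row centres the extractor integrates (rows whose centres fall within
# +/-120 nm, and within the 160-320 nm flank bands, on the even 40 nm crop
# grid), including the channel amplitude, the lateral integration band and
# the constant background, for the center-enriched ratio oracle.
oracle_center_ratio <- function(config, class) {
  mod <- switch(class,
    uniform = function(y) 1,
    split = function(y) 1 - config$dip_depth_frac *
      exp(-y^2 / (2 * config$class_mod_sigma_nm^2)),
    central = function(y) 1 + config$enhancement_frac *
      exp(-y^2 / (2 * config$class_mod_sigma_nm^2))
  )
  band <- function(y) {
    (pnorm((y + config$cohesin_axial_extent_nm / 2) /
             config$cohesin_shoulder_sigma_nm) -
       pnorm((y - config$cohesin_axial_extent_nm / 2) /
               config$cohesin_shoulder_sigma_nm)) * mod(y)
  }
  rows <- (seq_len(60) - 30.5) * 40
  # lateral integration: 6 central columns of the cohesin cross-profile
  cols <- rows[abs(rows) <= 120]
  lat <- sum(exp(-cols^2 / (2 * config$cohesin_lateral_sigma_nm^2)))
  amp <- config$amplitudes[["marker"]]
  bg <- 6 * config$background
  intensity <- function(y) amp * lat * band(y) + bg
  ctr <- mean(intensity(rows[abs(rows) <= 120]))
  flk <- mean(intensity(rows[abs(rows) >= 160 & abs(rows) <= 320]))
  ctr / flk
}
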