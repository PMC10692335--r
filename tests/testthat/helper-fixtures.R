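# Shared fixtures built in code at test time.

# Default-geometry config; single source for tests that need one.
fix_config <- function(...) geometry_config(...)

# A small noisy spread shared by detection/alignment tests (built lazily and
# memoised within one test run).
.spread_cache <- new.env(parent = emptyenv())
fix_spread <- function(n = 20, seed = 42, config = geometry_config(),
                       key = sprintf("n%d_s%d", n, seed)) {
  if (is.null(.spread_cache[[key]])) {
    .spread_cache[[key]] <- render_spread(n, config,
                                          noise_config(seed = seed))
  }
  .spread_cache[[key]]
}

# True cluster endpoint coordinates from a truth table.
truth_clusters <- function(truth) {
  th <- truth$angle_deg * pi / 180
  dx <- cos(th) * truth$separation_nm / 2
  dy <- sin(th) * truth$separation_nm / 2
  rbind(
    cbind(truth$x_nm - dx, truth$y_nm - dy, truth$z_nm),
    cbind(truth$x_nm + dx, truth$y_nm + dy, truth$z_nm)
  )
}

# Noise-free sampled two-Gaussian profile on the standard lateral grid.
fix_two_gauss_profile <- function(p2p = 562, sigma = 81, amp = 1,
                                  offset = 0.2, pitch = 40, crop = 60) {
  x <- (seq_len(crop) - (crop / 2 + 0.5)) * pitch
  y <- offset + amp * (exp(-(x - p2p / 2)^2 / (2 * sigma^2)) +
                         exp(-(x + p2p / 2)^2 / (2 * sigma^2)))
  structure(list(position_nm = x, intensity = y, axis = "lateral",
                 band_px = 6, band_nm = 6 * pitch, pixel_pitch_nm = pitch),
            class = "spa_profile")
}

# GRanges toy builders (0-based half-open data.frame -> GRanges).
gr_from_df <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}
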