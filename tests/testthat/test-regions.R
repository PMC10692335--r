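test_that("consensus peaks keep multi-replicate loci and drop singletons", {
  r1 <- gr_from_df(data.frame(chrom = "chr1", start = c(100, 500, 900),
                              end = c(150, 550, 950)))
  # identical replicates: consensus equals the input set
  cp <- consensus_peaks(list(r1, r1, r1), min_support = 2)
  expect_equal(GenomicRanges::start(cp), GenomicRanges::start(r1))
  expect_equal(GenomicRanges::end(cp), GenomicRanges::end(r1))
  expect_true(all(S4Vectors::mcols(cp)$support == 3))

  # a peak in only 1 of 3 replicates is dropped
  r2 <- gr_from_df(data.frame(chrom = "chr1", start = c(100, 500),
                              end = c(150, 550)))
  r3 <- gr_from_df(data.frame(chrom = "chr1", start = c(110, 510),
                              end = c(160, 560)))
  cp2 <- consensus_peaks(list(r1, r2, r3), min_support = 2)
  expect_length(cp2, 2L)
  expect_false(any(GenomicRanges::start(cp2) > 800))

  # min_support extremes: merged union vs full intersection support
  u <- consensus_peaks(list(r1, r2, r3), min_support = 1)
  expect_length(u, 3L)
  s3 <- consensus_peaks(list(r1, r2, r3), min_support = 3)
  expect_length(s3, 2L)
})

test_that("consensus matches exhaustive per-locus support counting on a toy set", {
  reps <- list(
    data.frame(chrom = "chr1", start = c(0, 200, 400, 800, 1200),
               end = c(50, 260, 450, 850, 1250)),
    data.frame(chrom = "chr1", start = c(10, 210, 810),
               end = c(60, 250, 860)),
    data.frame(chrom = "chr1", start = c(395, 1500), end = c(430, 1550))
  )
  want <- oracle_consensus(reps, 2)
  got <- consensus_peaks(lapply(reps, gr_from_df), 2)
  expect_length(got, length(want))
  expect_equal(GenomicRanges::start(got) - 1,
               vapply(want, function(w) w$start, numeric(1)))
  expect_equal(S4Vectors::mcols(got)$support,
               vapply(want, function(w) w$support, numeric(1)))
})

test_that("peak densities follow midpoint counting and flag empty regions", {
  rs <- region_set(data.frame(chrom = "chr1", start = 0, end = 2e6), "CenHap")
  pk <- gr_from_df(data.frame(chrom = "chr1",
                              start = c(1, 3, 5, 7, 9) * 1e5,
                              end = c(1, 3, 5, 7, 9) * 1e5 + 100))
  d <- density_per_region(pk, rs)
  expect_equal(d$n_peaks, 5L)
  expect_equal(d$peaks_per_mb, 2.5)
  expect_equal(d$log2_density, log2(2.5))

  empty <- density_per_region(pk[0], rs)
  expect_equal(empty$peaks_per_mb, 0)
  expect_true(is.na(empty$log2_density))

  # a peak straddling the region border counts by its midpoint only
  edge <- gr_from_df(data.frame(chrom = "chr1", start = 2e6 - 10,
                                end = 2e6 + 100))
  expect_equal(density_per_region(edge, rs)$n_peaks, 0L)
  expect_equal(density_per_region(edge, rs, assignment = "any")$n_peaks, 1L)
})

test_that("label counts match an exhaustive point-in-interval scan on a random toy genome", {
  set.seed(99)
  n <- 1000
  peaks_df <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                         start = sample.int(1e6, n))
  peaks_df$end <- peaks_df$start + sample(50:500, n, TRUE)
  regions_df <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                           start = c(0, 6e5, 3e5), end = c(2e5, 8e5, 9e5))
  rs <- region_set(regions_df, "custom")
  got <- density_per_region(gr_from_df(peaks_df), rs)
  want <- oracle_count_midpoints(peaks_df, regions_df)
  expect_equal(got$n_peaks, want)
  # invariance to input interval ordering
  shuf <- peaks_df[sample.int(n), ]
  expect_equal(density_per_region(gr_from_df(shuf), rs)$n_peaks, want)
})

test_that("read proportions recover generating label probabilities and sum to one", {
  set.seed(123)
  # genome: chr1 of 10 Mb; CenHap-like block of 520 kb => p = 0.052
  cen <- region_set(data.frame(chrom = "chr1", start = 4e6, end = 4e6 + 520e3),
                    "CenHap")
  rest <- region_set(data.frame(chrom = "chr1",
                                start = c(0, 4e6 + 520e3),
                                end = c(4e6, 1e7)), "nonCen")
  n <- 20000
  starts <- sample.int(1e7 - 200, n)
  frags <- gr_from_df(data.frame(chrom = "chr1", start = starts,
                                 end = starts + 200))
  p <- read_proportions(frags, list(cen, rest))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # within ~4 binomial standard errors of the generating probability
  expect_lt(abs(unname(p["CenHap"]) - 0.052), 4 * sqrt(0.052 * 0.948 / n))
  expect_error(read_proportions(frags[0], list(cen)), "empty")
})

test_that("random region sampling avoids exclusions, is seeded and uniform", {
  cs <- data.frame(chrom = c("chrA", "chrB"), size = c(1e6, 5e5))
  excl <- gr_from_df(data.frame(chrom = "chrA", start = 2e5, end = 8e5))
  rr <- sample_random_regions(cs, excl, n = 100, length_bp = 1e4, seed = 8)
  expect_length(rr$ranges, 100L)
  expect_equal(sum(suppressWarnings(
    GenomicRanges::countOverlaps(rr$ranges, excl))), 0L)
  rr2 <- sample_random_regions(cs, excl, n = 100, length_bp = 1e4, seed = 8)
  expect_identical(as.character(rr2$ranges), as.character(rr$ranges))

  # exclusion covering all but one slot forces that slot
  cs1 <- data.frame(chrom = "chrC", size = 1000)
  excl1 <- gr_from_df(data.frame(chrom = "chrC", start = 100, end = 1000))
  one <- sample_random_regions(cs1, excl1, n = 3, length_bp = 100, seed = 1)
  expect_true(all(GenomicRanges::start(one$ranges) == 1))

  # impossible request errors out
  expect_error(sample_random_regions(cs1,
    gr_from_df(data.frame(chrom = "chrC", start = 0, end = 1000)),
    n = 1, length_bp = 100, seed = 1, max_tries = 5), "could not place")

  # empirical start uniformity over the allowed space (chi-square GOF)
  big <- sample_random_regions(data.frame(chrom = "chrU", size = 1e6),
                               n = 10000, length_bp = 10, seed = 21)
  starts <- GenomicRanges::start(big$ranges)
  ct <- table(cut(starts, breaks = seq(0, 1e6 - 9 + 1, length.out = 21)))
  expect_gt(chisq.test(as.vector(ct))$p.value, 0.01)
})

test_that("overlap fractions match the exhaustive pairwise check", {
  q <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                  end = seq(0, 900, 100) + 40)
  expect_equal(overlap_fraction(gr_from_df(q), gr_from_df(q)), 1)
  disj <- data.frame(chrom = "chr1", start = seq(50, 950, 100),
                     end = seq(50, 950, 100) + 40)
  expect_equal(overlap_fraction(gr_from_df(q), gr_from_df(disj)), 0)
  set.seed(4)
  s <- data.frame(chrom = "chr1", start = sample.int(1000, 10))
  s$end <- s$start + 60
  got <- overlap_fraction(gr_from_df(q), gr_from_df(s))
  expect_equal(got, oracle_overlap_fraction(q, s))
})
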