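#' Read and write BED intervals
#'
#' Thin wrappers around `rtracklayer` for BED files (0-based half-open on
#' disk; `GRanges`, 1-based closed, in memory) and a two-column
#' chromosome-sizes TSV.
#'
#' @param path file path.
#' @param gr a `GRanges` to write.
#' @return `read_bed()` returns a `GRanges`; `read_chrom_sizes()` a
#'   data.frame with `chrom` and `size`; writers return the path invisibly.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_bed
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  if (any(df$size <= 0)) .stopf("read_chrom_sizes: non-positive size in %s", path)
  df
}

#' Labelled genomic region set
#'
#' Normalises intervals (per-chromosome reduce, so they are non-overlapping)
#' and records the label and total length. Labels follow the centromere
#' metagenome region classes: the active alpha-satellite higher-order-repeat
#' array (`asHOR`), the centromere haplotype (`CenHap`), its 2 Mb flanks
#' (`CenAdj`), random non-centromeric regions (`nonCen`), or `custom`.
#'
#' @param gr a `GRanges` (or data.frame with `chrom`, `start`, `end`,
#'   0-based half-open).
#' @param label region class label.
#' @return a `region_set`: list with `label`, `ranges` (reduced `GRanges`),
#'   `total_bp`.
#' @export
region_set <- function(gr, label = c("custom", "asHOR", "CenHap", "CenAdj",
                                     "nonCen")) {
  label <- match.arg(label)
  if (is.data.frame(gr)) {
    gr <- GenomicRanges::GRanges(gr$chrom,
                                 IRanges::IRanges(gr$start + 1, gr$end))
  }
  stopifnot(methods::is(gr, "GRanges"))
  red <- GenomicRanges::reduce(gr)
  structure(list(label = label, ranges = red,
                 total_bp = sum(as.numeric(GenomicRanges::width(red)))),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> '%s': %d interval(s), %.3f Mb\n",
              x$label, length(x$ranges), x$total_bp / 1e6))
  invisible(x)
}

#' Replicate-consensus peak set
#'
#' Merges all replicate peak intervals into candidate loci (union-reduce) and
#' keeps the loci overlapped by peaks from at least `min_support` distinct
#' replicates. `min_support = 1` returns the merged union;
#' `min_support = length(replicates)` requires support from every replicate.
#'
#' @param replicates list of `GRanges`, one per replicate.
#' @param min_support minimum number of distinct supporting replicates.
#' @return `GRanges` of consensus loci with a `support` metadata column.
#' @export
consensus_peaks <- function(replicates, min_support = 2) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  all_gr <- suppressWarnings(do.call(c, unname(replicates)))
  cand <- GenomicRanges::reduce(all_gr)
  support <- Reduce(`+`, lapply(replicates, function(r) {
    as.integer(GenomicRanges::countOverlaps(cand, r) > 0)
  }))
  out <- cand[support >= min_support]
  S4Vectors::mcols(out)$support <- support[support >= min_support]
  out
}

.midpoints <- function(gr) {
  GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr),
    IRanges::IRanges(start = (GenomicRanges::start(gr) +
                                GenomicRanges::end(gr)) %/% 2, width = 1)
  )
}

#' Peak density per region class
#'
#' Counts peaks per region set and reports densities in peaks/Mb and their
#' log2. By default a peak is assigned to a region iff its midpoint lies
#' inside (midpoint assignment keeps counts additive when the region labels
#' partition the genome); `assignment = "any"` counts any overlap instead.
#' Zero densities give `log2_density = NA` (no pseudocount) so they can be
#' excluded from box-plot style summaries.
#'
#' @param peaks `GRanges` of peaks.
#' @param regions a `region_set` or (possibly named) list of them.
#' @param assignment `"midpoint"` or `"any"`.
#' @param per_chromosome also emit per-chromosome rows.
#' @return data.frame with `label`, `chrom` (`"all"` for aggregates),
#'   `n_peaks`, `mb`, `peaks_per_mb`, `log2_density`.
#' @export
density_per_region <- function(peaks, regions,
                               assignment = c("midpoint", "any"),
                               per_chromosome = FALSE) {
  assignment <- match.arg(assignment)
  if (inherits(regions, "region_set")) regions <- list(regions)
  qry <- if (assignment == "midpoint") .midpoints(peaks) else peaks
  rows <- list()
  for (rs in regions) {
    stopifnot(inherits(rs, "region_set"))
    hits <- GenomicRanges::countOverlaps(qry, rs$ranges) > 0
    count_all <- sum(hits)
    mb_all <- rs$total_bp / 1e6
    rows[[length(rows) + 1L]] <- data.frame(
      label = rs$label, chrom = "all", n_peaks = count_all, mb = mb_all,
      peaks_per_mb = count_all / mb_all,
      log2_density = if (count_all > 0) log2(count_all / mb_all) else NA_real_,
      stringsAsFactors = FALSE)
    if (per_chromosome) {
      for (chr in unique(as.character(GenomeInfoDb::seqnames(rs$ranges)))) {
        sub <- rs$ranges[GenomeInfoDb::seqnames(rs$ranges) == chr]
        cnt <- sum(GenomicRanges::countOverlaps(qry, sub) > 0)
        mb <- sum(as.numeric(GenomicRanges::width(sub))) / 1e6
        rows[[length(rows) + 1L]] <- data.frame(
          label = rs$label, chrom = chr, n_peaks = cnt, mb = mb,
          peaks_per_mb = cnt / mb,
          log2_density = if (cnt > 0) log2(cnt / mb) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Proportion of mapped fragments per region class
#'
#' Fraction of fragment midpoints falling in each region set. Over disjoint,
#' exhaustive labels the proportions sum to 1.
#'
#' @param fragments `GRanges` of read/fragment intervals (non-empty).
#' @param regions a `region_set` or list of them.
#' @return named numeric vector of proportions.
#' @export
read_proportions <- function(fragments, regions) {
  if (length(fragments) == 0) .stopf("read_proportions: empty fragment set")
  if (inherits(regions, "region_set")) regions <- list(regions)
  mids <- .midpoints(fragments)
  out <- vapply(regions, function(rs) {
    mean(GenomicRanges::countOverlaps(mids, rs$ranges) > 0)
  }, numeric(1))
  names(out) <- vapply(regions, `[[`, character(1), "label")
  out
}

#' Sample random genomic regions outside an exclusion set
#'
#' Draws `n` fixed-length intervals uniformly over all allowed start
#' positions (chromosomes weighted by their number of valid starts),
#' rejecting any candidate overlapping the exclusion set. Deterministic
#' under `seed`. The default length (2 Mb) matches the scale of the
#' centromere-adjacent comparison regions.
#'
#' @param chrom_sizes data.frame with `chrom` and `size` (bp).
#' @param exclusion `GRanges` to avoid (may be empty), e.g. the centromere
#'   haplotypes.
#' @param n number of regions.
#' @param length_bp region length.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget per region.
#' @return a `region_set` labelled `nonCen`.
#' @export
sample_random_regions <- function(chrom_sizes, exclusion = GenomicRanges::GRanges(),
                                  n = 100, length_bp = 2e6, seed = NULL,
                                  max_tries = 10000) {
  ok_chr <- chrom_sizes[chrom_sizes$size >= length_bp, , drop = FALSE]
  if (nrow(ok_chr) == 0) .stopf("sample_random_regions: no chromosome can hold %d bp", length_bp)
  slots <- ok_chr$size - length_bp + 1
  .with_seed(seed, {
    chroms <- character(0); starts <- numeric(0)
    tries <- 0L
    while (length(starts) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        .stopf("sample_random_regions: could not place %d regions outside the exclusion set", n)
      }
      m <- n - length(starts)
      ci <- sample.int(nrow(ok_chr), m, replace = TRUE, prob = slots)
      s0 <- floor(runif(m, 0, slots[ci]))  # 0-based starts
      cand <- GenomicRanges::GRanges(ok_chr$chrom[ci],
                                     IRanges::IRanges(s0 + 1, s0 + length_bp))
      keep <- if (length(exclusion) == 0) rep(TRUE, m) else {
        suppressWarnings(GenomicRanges::countOverlaps(cand, exclusion)) == 0
      }
      chroms <- c(chroms, ok_chr$chrom[ci][keep])
      starts <- c(starts, s0[keep])
    }
    gr <- GenomicRanges::GRanges(chroms,
                                 IRanges::IRanges(starts + 1,
                                                  starts + length_bp))
    structure(list(label = "nonCen", ranges = gr,
                   total_bp = sum(as.numeric(GenomicRanges::width(gr)))),
              class = "region_set")
  })
}

#' Fraction of query peaks overlapping a subject set
#'
#' Proportion of query intervals with at least 1 bp overlap of any subject
#' interval (e.g. the fraction of CTCF sites overlapped by cohesin peaks).
#'
#' @param query,subject `GRanges`.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(query, subject) {
  if (length(query) == 0) return(NA_real_)
  mean(GenomicRanges::countOverlaps(query, subject) > 0)
}
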