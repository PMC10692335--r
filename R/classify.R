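#' Center-enriched intensity ratio of an axial profile
#'
#' Ratio of the mean marker intensity within 120 nm of the structure centre
#' to the mean intensity in the 160-320 nm band on either side, measured
#' along the chromosomal axis. In this canonical direction a low ratio means
#' a centre-depleted ("split") cohesin pattern and a high ratio a
#' centre-enriched ("central") one, so ascending-ratio ranks run from split
#' to central. `mode = "flank_over_center"` computes the reciprocal.
#'
#' @param profile an `spa_profile` along the chromosomal axis covering at
#'   least +/-320 nm.
#' @param center_halfwidth_nm half-width of the central zone.
#' @param flank_inner_nm,flank_outer_nm off-centre band (both sides pooled).
#' @param mode ratio direction (see above).
#' @return the ratio; `Inf` (flagged via attribute `degenerate`) when the
#'   denominator is zero.
#' @export
center_ratio <- function(profile, center_halfwidth_nm = 120,
                         flank_inner_nm = 160, flank_outer_nm = 320,
                         mode = c("center_over_flank", "flank_over_center")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "spa_profile"))
  pos <- profile$position_nm
  if (max(abs(pos)) < flank_outer_nm) {
    .stopf("center_ratio: profile must cover +/-%g nm", flank_outer_nm)
  }
  ctr <- mean(profile$intensity[abs(pos) <= center_halfwidth_nm])
  flk <- mean(profile$intensity[abs(pos) >= flank_inner_nm &
                                  abs(pos) <= flank_outer_nm])
  num <- if (mode == "center_over_flank") ctr else flk
  den <- if (mode == "center_over_flank") flk else ctr
  if (den == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  num / den
}

#' Rank particles by ratio and partition into classes
#'
#' Sorts particles by ascending center-enriched ratio (ties broken by
#' particle id, so the ordering is deterministic) and assigns contiguous rank
#' blocks to the `split`, `uniform` and `central` classes. The default
#' boundaries reproduce the 200/150/113 rank blocks used for a 463-particle
#' set; `boundaries = "equal"` partitions into three equal classes instead.
#' Non-finite ratios rank last.
#'
#' @param ratios numeric vector of center-enriched ratios.
#' @param particle_id optional ids (default `seq_along(ratios)`).
#' @param boundaries `"default"` (proportions 200:150:113), `"equal"`, or a
#'   numeric vector of three proportions.
#' @return data.frame with `particle_id`, `ratio`, `rank` (1-based,
#'   ascending ratio) and `class`, ordered by rank.
#' @export
rank_and_partition <- function(ratios, particle_id = seq_along(ratios),
                               boundaries = "default") {
  n <- length(ratios)
  stopifnot(n >= 3, length(particle_id) == n)
  props <- if (identical(boundaries, "default")) {
    c(split = 200, uniform = 150, central = 113) / 463
  } else if (identical(boundaries, "equal")) {
    c(split = 1, uniform = 1, central = 1) / 3
  } else {
    stopifnot(is.numeric(boundaries), length(boundaries) == 3)
    setNames(boundaries / sum(boundaries), c("split", "uniform", "central"))
  }
  r <- ratios
  r[!is.finite(r)] <- Inf
  ord <- order(r, particle_id)
  counts <- .apportion(n, props)
  cls <- rep(c("split", "uniform", "central"), counts)
  out <- data.frame(particle_id = particle_id[ord], ratio = ratios[ord],
                    rank = seq_len(n), class = cls,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Center-enriched ratios for a set of aligned particles
#'
#' Computes the axial marker profile and [center_ratio()] of every aligned
#' particle. Mirroring leaves the axial profile unchanged, so ratios are
#' computed on the original (unmirrored) patches.
#'
#' @param aligned list of `aligned_particle` objects.
#' @param channel marker channel name.
#' @param half_width_px integration half-width for the axial profile.
#' @param ... passed to [center_ratio()].
#' @return numeric vector of ratios, one per particle.
#' @export
particle_ratios <- function(aligned, channel = "marker", half_width_px = 2.5,
                            ...) {
  vapply(aligned, function(a) {
    p <- extract_profile(a, channel = channel, axis = "chromosomal",
                         half_width_px = half_width_px)
    as.numeric(center_ratio(p, ...))
  }, numeric(1))
}

## Dunn's rank-based post-hoc z test with tie correction; p-values adjusted
## by Benjamini-Hochberg. Written in-house: no post-hoc package ships with
## the package's dependency set.
.dunn_test <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  rk <- rank(values)
  tie_tab <- table(rk)
  ties <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_rk <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  lv <- levels(groups)
  combs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - ties) * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[i] <- (mean_rk[[a]] - mean_rk[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(comparison = paste(combs[1, ], combs[2, ], sep = " vs "),
             z = z, p = p, p_adj = p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Per-class summaries and class-wise separation comparison
#'
#' Builds per-class average images (when aligned patches are supplied),
#' collects per-class inter-CENP-A distance distributions, and compares them
#' with an unpaired Kruskal-Wallis test followed by Dunn's post-hoc z tests
#' with Benjamini-Hochberg adjustment. With fewer than two classes present
#' the tests are skipped with a notice.
#'
#' @param assignments data.frame from [rank_and_partition()].
#' @param particles data.frame from [find_particles()] (matched on
#'   `particle_id`).
#' @param aligned optional list of `aligned_particle` objects (unmirrored),
#'   indexed by the same particle ids.
#' @return a `class_summary`: list with `classes` (per-class n and separation
#'   summaries), `kruskal` (`htest` or `NULL`), `dunn` (data.frame or
#'   `NULL`), `averages` (named list of `average_image` or `NULL`),
#'   `separations` (named list of numeric vectors).
#' @export
class_summary <- function(assignments, particles, aligned = NULL) {
  m <- merge(assignments, particles[, c("particle_id", "separation_nm")],
             by = "particle_id")
  seps <- split(m$separation_nm, m$class)
  present <- names(seps)[vapply(seps, length, integer(1)) > 0]
  classes <- data.frame(
    class = present,
    n = vapply(seps[present], length, integer(1)),
    mean_separation_nm = vapply(seps[present], mean, numeric(1)),
    sd_separation_nm = vapply(seps[present], sd, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(classes) <- NULL
  if (length(present) >= 2) {
    kw <- kruskal.test(m$separation_nm, factor(m$class))
    dunn <- .dunn_test(m$separation_nm, m$class)
  } else {
    message("class_summary: fewer than two classes present; Kruskal-Wallis skipped")
    kw <- NULL
    dunn <- NULL
  }
  averages <- NULL
  if (!is.null(aligned)) {
    ids <- vapply(aligned, `[[`, integer(1), "particle_id")
    averages <- lapply(split(m$particle_id, m$class), function(cl_ids) {
      sum_particles(mirror_augment(aligned[ids %in% cl_ids]))
    })
  }
  structure(list(classes = classes, kruskal = kw, dunn = dunn,
                 averages = averages, separations = seps),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat("<class_summary>\n")
  print(x$classes, digits = 4)
  if (!is.null(x$kruskal)) {
    cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g\n",
                unname(x$kruskal$statistic), unname(x$kruskal$parameter),
                x$kruskal$p.value))
  }
  invisible(x)
}
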