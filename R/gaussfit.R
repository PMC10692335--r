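#' Fit 1-3 Gaussian peaks to an intensity profile
#'
#' Least-squares fit of `k` Gaussians plus a constant offset for each
#' candidate `k`, selecting the model that minimises
#' `AIC = n * log(RSS / n) + 2 * (3k + 1)` (the least-squares form; no
#' small-sample correction). AIC ties within `1e-9` resolve to the smaller
#' `k`. Initial centres come from the `k` largest local maxima of the lightly
#' smoothed profile; optimisation is Levenberg-Marquardt with box
#' constraints (amplitudes non-negative, centres inside the profile, sigmas
#' at least half a sample step).
#'
#' @param profile an `spa_profile`, or a list/data.frame with `position_nm`
#'   and `intensity`.
#' @param k_max maximum number of peaks to consider.
#' @param ks candidate peak counts; default `1:k_max`. Supplying a single
#'   value forces that model (used e.g. for a two-cluster CENP-A fit).
#' @return a `gauss_peaks` model object: list with `k`, `peaks` (data.frame
#'   `center_nm`, `sigma_nm`, `amplitude`, ordered by centre), `offset`,
#'   `rss`, `aic`, `aic_by_k`, `profile`, `converged`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `plot()`.
#' @examples
#' x <- seq(-1000, 1000, by = 40)
#' y <- 5 + exp(-(x - 281)^2 / (2 * 81^2)) + exp(-(x + 281)^2 / (2 * 81^2))
#' f <- fit_gaussians(list(position_nm = x, intensity = y))
#' f$k            # 2
#' peak_to_peak(f)  # ~562
#' @export
fit_gaussians <- function(profile, k_max = 3, ks = NULL) {
  x <- profile$position_nm
  y <- profile$intensity
  stopifnot(length(x) == length(y), length(x) >= 3 * k_max + 3)
  if (is.null(ks)) ks <- seq_len(k_max)
  dx <- min(diff(x))
  n <- length(y)
  # RSS is floored at machine-precision scale so that numerically perfect
  # fits of nested models tie and the parsimony penalty decides
  rss_floor <- 1e-22 * sum(y^2)
  fits <- list()
  for (k in ks) {
    lower <- c(-Inf, rep(c(0, min(x) - dx, dx / 2), k))
    upper <- c(Inf, rep(c(Inf, max(x) + dx, diff(range(x))), k))
    resid_fn <- function(p) y - .gauss_eval(p, x, k)
    best_fit <- NULL
    for (p0 in .gauss_inits(x, y, k)) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      if (is.null(best_fit) || sum(fit$fvec^2) < sum(best_fit$fvec^2)) {
        best_fit <- fit
      }
    }
    if (is.null(best_fit)) next
    rss <- sum(best_fit$fvec^2)
    fits[[as.character(k)]] <- list(
      k = k, par = best_fit$par, rss = rss,
      aic = n * log(max(rss, rss_floor, 1e-300) / n) + 2 * (3 * k + 1),
      converged = best_fit$info %in% 1:4
    )
  }
  if (length(fits) == 0) {
    return(structure(list(k = NA_integer_, peaks = NULL, offset = NA_real_,
                          rss = NA_real_, aic = NA_real_, aic_by_k = NULL,
                          profile = profile, converged = FALSE),
                     class = "gauss_peaks"))
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  best <- fits[[1]]
  for (f in fits[-1]) if (f$aic < best$aic - 1e-9) best <- f
  p <- best$par
  k <- best$k
  peaks <- data.frame(
    amplitude = p[1 + 3 * (seq_len(k) - 1) + 1],
    center_nm = p[1 + 3 * (seq_len(k) - 1) + 2],
    sigma_nm = p[1 + 3 * (seq_len(k) - 1) + 3]
  )
  peaks <- peaks[order(peaks$center_nm), c("center_nm", "sigma_nm", "amplitude")]
  rownames(peaks) <- NULL
  structure(list(k = k, peaks = peaks, offset = unname(p[1]),
                 rss = best$rss, aic = best$aic, aic_by_k = aics,
                 profile = list(position_nm = x, intensity = y),
                 converged = best$converged),
            class = "gauss_peaks")
}

.gauss_eval <- function(p, x, k) {
  out <- rep(p[1], length(x))
  for (i in seq_len(k)) {
    A <- p[1 + 3 * (i - 1) + 1]
    mu <- p[1 + 3 * (i - 1) + 2]
    s <- p[1 + 3 * (i - 1) + 3]
    out <- out + A * exp(-(x - mu)^2 / (2 * s^2))
  }
  out
}

## Candidate starting points for a k-peak fit: (a) the k largest local
## maxima of the lightly smoothed profile, padded with spread quantiles;
## (b) greedy residual peeling, which finds minor shoulders riding on a
## dominant peak. Both are fitted; the better RSS wins.
.gauss_inits <- function(x, y, k) {
  ys <- if (length(y) >= 5) stats::filter(y, rep(1 / 3, 3), sides = 2) else y
  ys[is.na(ys)] <- y[is.na(ys)]
  off0 <- min(y)
  A0 <- max(max(y) - off0, 1e-6)
  s0 <- diff(range(x)) / (4 * k)

  locmax <- which(diff(sign(diff(ys))) < 0) + 1L
  locmax <- locmax[order(-ys[locmax])]
  centers_a <- x[locmax]
  if (length(centers_a) < k) {
    extra <- quantile(x, probs = seq(0.2, 0.8,
                                     length.out = k - length(centers_a)),
                      names = FALSE)
    centers_a <- c(centers_a, extra)
  }
  centers_a <- centers_a[seq_len(k)]

  s_peel <- diff(range(x)) / (6 * k)
  r <- as.numeric(ys) - off0
  centers_b <- amps_b <- numeric(k)
  for (i in seq_len(k)) {
    j <- which.max(r)
    centers_b[i] <- x[j]
    amps_b[i] <- max(r[j], 1e-6)
    r <- r - r[j] * exp(-(x - x[j])^2 / (2 * s_peel^2))
  }

  pack <- function(centers, amps, s) {
    p <- c(off = off0)
    for (i in seq_len(k)) p <- c(p, amps[i], centers[i], s)
    names(p) <- c("off", paste0(rep(c("A", "mu", "s"), k),
                                rep(seq_len(k), each = 3)))
    p
  }
  list(pack(centers_a, rep(A0, k), s0),
       pack(centers_b, amps_b, s_peel))
}

#' @export
print.gauss_peaks <- function(x, ...) {
  if (is.na(x$k)) {
    cat("<gauss_peaks> fit failed\n")
    return(invisible(x))
  }
  cat(sprintf("<gauss_peaks> k = %d (AIC %.2f), offset %.3g, RSS %.4g\n",
              x$k, x$aic, x$offset, x$rss))
  print(x$peaks, digits = 4)
  invisible(x)
}

#' @export
summary.gauss_peaks <- function(object, ...) {
  print(object)
  if (!is.na(object$k)) {
    cat("AIC by k: ",
        paste(sprintf("k=%s: %.2f", names(object$aic_by_k), object$aic_by_k),
              collapse = ", "), "\n", sep = "")
    if (object$k >= 2) {
      cat(sprintf("peak-to-peak (outer centres): %.1f nm\n",
                  peak_to_peak(object)))
    }
  }
  invisible(object)
}

#' @export
coef.gauss_peaks <- function(object, ...) {
  c(offset = object$offset,
    setNames(as.vector(t(as.matrix(object$peaks))),
             paste0(rep(c("center", "sigma", "amplitude"), object$k),
                    rep(seq_len(object$k), each = 3))))
}

#' @export
predict.gauss_peaks <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$profile$position_nm
       else if (is.list(newdata)) newdata$position_nm else newdata
  out <- rep(object$offset, length(x))
  for (i in seq_len(nrow(object$peaks))) {
    out <- out + object$peaks$amplitude[i] *
      exp(-(x - object$peaks$center_nm[i])^2 /
            (2 * object$peaks$sigma_nm[i]^2))
  }
  out
}

#' @export
fitted.gauss_peaks <- function(object, ...) predict(object)

#' @export
residuals.gauss_peaks <- function(object, ...) {
  object$profile$intensity - fitted(object)
}

#' @export
plot.gauss_peaks <- function(x, ...) {
  plot(x$profile$position_nm, x$profile$intensity, pch = 16, cex = 0.7,
       xlab = "position (nm)", ylab = "intensity", ...)
  xs <- seq(min(x$profile$position_nm), max(x$profile$position_nm),
            length.out = 400)
  lines(xs, predict(x, xs), col = "magenta", lwd = 2)
  abline(v = x$peaks$center_nm, lty = 3)
  invisible(x)
}

#' Peak-to-peak distance of a multi-peak fit
#'
#' Distance between the outermost fitted peak centres; defined only for
#' `k >= 2` (returns `NA` otherwise, which is how "quantity absent" is
#' reported rather than as an error).
#'
#' @param fit a `gauss_peaks` object.
#' @return distance in nm, or `NA`.
#' @export
peak_to_peak <- function(fit) {
  stopifnot(inherits(fit, "gauss_peaks"))
  if (is.na(fit$k) || fit$k < 2) return(NA_real_)
  diff(range(fit$peaks$center_nm))
}

#' Peak and dip metrics of a fitted bimodal cloud
#'
#' Evaluates the fitted curve densely, locates the two intensity maxima
#' flanking the central depression and the minimum between them, and reports
#' the peak offset (mean absolute position of the maxima), the dip width
#' (distance between the two flanking maxima, i.e. the span of the
#' depression), and the fractional dip depth relative to the flanking-peak
#' level.
#'
#' @param fit a `gauss_peaks` object fitted to a lateral cloud profile.
#' @param n_grid grid resolution for curve evaluation.
#' @return list with `peak_offset_nm`, `dip_width_nm`, `dip_depth_frac`
#'   (all `NA` when the curve has no central depression).
#' @export
cloud_metrics <- function(fit, n_grid = 4001) {
  stopifnot(inherits(fit, "gauss_peaks"))
  if (is.na(fit$k)) {
    return(list(peak_offset_nm = NA_real_, dip_width_nm = NA_real_,
                dip_depth_frac = NA_real_))
  }
  xs <- seq(min(fit$profile$position_nm), max(fit$profile$position_nm),
            length.out = n_grid)
  ys <- predict(fit, xs)
  d <- diff(sign(diff(ys)))
  imax <- which(d < 0) + 1L
  if (length(imax) < 2) {
    return(list(peak_offset_nm = NA_real_, dip_width_nm = NA_real_,
                dip_depth_frac = NA_real_))
  }
  # two maxima flanking x = 0
  left <- imax[xs[imax] < 0]
  right <- imax[xs[imax] > 0]
  if (length(left) == 0 || length(right) == 0) {
    return(list(peak_offset_nm = NA_real_, dip_width_nm = NA_real_,
                dip_depth_frac = NA_real_))
  }
  il <- left[which.max(ys[left])]
  ir <- right[which.max(ys[right])]
  between <- il:ir
  imin <- between[which.min(ys[between])]
  peak_level <- mean(c(ys[il], ys[ir])) - fit$offset
  dip_level <- ys[imin] - fit$offset
  list(peak_offset_nm = mean(abs(xs[c(il, ir)])),
       dip_width_nm = xs[ir] - xs[il],
       dip_depth_frac = 1 - dip_level / peak_level)
}

#' Assemble the geometry report
#'
#' Collects the reported structural quantities from per-channel fits and the
#' per-particle refinement table. Quantities undefined for the available fits
#' (e.g. a peak-to-peak distance under a single-peak model) are reported as
#' `NA`, not as errors.
#'
#' The CENP-A cluster width in a summed average image is broadened by the
#' particle-to-particle separation jitter (each peak wanders by half the
#' separation spread about its mean position); `cenpa_sigma_deconv_nm`
#' removes this in quadrature using the pipeline's own measured separation
#' S.D. and is the estimate of a single cluster's S.D. The raw fitted sigma
#' is reported alongside.
#'
#' @param cenpa_lateral_fit `gauss_peaks` fit of the CENP-A lateral profile
#'   (two peaks).
#' @param marker_lateral_fit `gauss_peaks` fit of the marker-channel lateral
#'   profile (AIC-selected).
#' @param marker_axial_profile `spa_profile` of the marker channel along the
#'   chromosomal axis.
#' @param satellite_lateral_fit `gauss_peaks` fit of the satellite lateral
#'   profile (AIC-selected).
#' @param particles data.frame from [find_particles()].
#' @return data.frame with columns `quantity`, `value`, `unit`, `source`.
#' @export
measure_geometry <- function(cenpa_lateral_fit = NULL,
                             marker_lateral_fit = NULL,
                             marker_axial_profile = NULL,
                             satellite_lateral_fit = NULL,
                             particles = NULL) {
  rows <- list()
  add <- function(quantity, value, source) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, value = value, unit = "nm", source = source,
      stringsAsFactors = FALSE)
  }
  sep_sd <- NA_real_
  if (!is.null(particles) && nrow(particles) > 1) {
    add("separation_mean", mean(particles$separation_nm), "per-particle refinement")
    sep_sd <- sd(particles$separation_nm)
    add("separation_sd", sep_sd, "per-particle refinement")
    add("cluster_sigma_refined", mean(particles$sigma_xy_nm),
        "per-particle refinement")
  }
  if (!is.null(cenpa_lateral_fit)) {
    add("inter_cenpa_fit", peak_to_peak(cenpa_lateral_fit), "average-image fit")
    if (!is.na(cenpa_lateral_fit$k) && cenpa_lateral_fit$k >= 2) {
      sig_fit <- mean(cenpa_lateral_fit$peaks$sigma_nm)
      add("cenpa_sigma_fit", sig_fit, "average-image fit")
      if (!is.na(sep_sd)) {
        add("cenpa_sigma_deconv",
            sqrt(max(sig_fit^2 - (sep_sd / 2)^2, 0)),
            "average-image fit, jitter-deconvolved")
      }
    }
  }
  if (!is.null(marker_lateral_fit) && !is.na(marker_lateral_fit$k)) {
    pk <- marker_lateral_fit$peaks
    central <- pk[which.min(abs(pk$center_nm)), ]
    add("marker_lateral_sigma", central$sigma_nm, "average-image fit")
  }
  if (!is.null(marker_axial_profile)) {
    add("marker_axial_fwhm", profile_fwhm(marker_axial_profile),
        "average-image profile")
  }
  if (!is.null(satellite_lateral_fit)) {
    cm <- cloud_metrics(satellite_lateral_fit)
    add("satellite_peak_offset", cm$peak_offset_nm, "average-image fit")
    add("satellite_dip_width", cm$dip_width_nm, "average-image fit")
  }
  do.call(rbind, rows)
}
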