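#' Run the single-particle-averaging pipeline
#'
#' Chains simulation (or a supplied stack) through detection, pairing, 3D
#' Gaussian refinement, rotational alignment, mirror-augmented averaging,
#' profile extraction, multi-Gaussian fitting, geometry measurement and
#' (for the cohesin marker) center-enriched ratio classification. Fully
#' deterministic under a fixed seed.
#'
#' @param config a [geometry_config()] describing the rendered or imaged
#'   geometry.
#' @param noise a [noise_config()] (or `NULL` for noiseless synthetic data).
#' @param n number of particles to simulate (ignored when `stack` is given).
#' @param stack optional 4D array `[x, y, z, channel]` with channels `dna`,
#'   `cenpa`, `marker`; when supplied, no simulation is run.
#' @param class_mix class proportions for the simulated spread.
#' @param boundaries class rank boundaries for [rank_and_partition()].
#' @param half_width_px profile integration half-width.
#' @param seed RNG seed for simulation (defaults to `noise$seed`).
#' @param run run-stage parameters from [run_config()]; its raster
#'   calibration must match `config`.
#' @param out_dir if non-`NULL`, CSV tables, average-image TIFFs and the
#'   geometry report are written there.
#' @param verbose log per-stage attrition counts.
#' @return an `spa_run` object: list with `particles`, `truth` (when
#'   simulated), `aligned` (unmirrored), `average` (mirror-augmented
#'   [sum_particles()] image), `profiles`, `fits`, `geometry`,
#'   `assignments`, `classes`, `kymograph`, `config`, `n_requested`.
#' @export
run_pipeline <- function(config = geometry_config(), noise = noise_config(),
                         n = 400, stack = NULL,
                         class_mix = c(split = 200, uniform = 150, central = 113) / 463,
                         boundaries = "default", half_width_px = 2.5,
                         seed = NULL, run = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  pitch <- config$pixel_pitch_nm
  z_step <- config$z_step_nm
  truth <- NULL
  if (is.null(stack)) {
    sim <- render_spread(n, config, noise, class_mix = class_mix, seed = seed)
    stack <- sim$stack
    truth <- sim$truth
    .msg(verbose, "run_pipeline: simulated %d particles (field %d px)",
         n, dim(stack)[1])
  }
  particles <- find_particles(
    stack, pixel_pitch_nm = pitch, z_step_nm = z_step,
    smoothing_sigma_px = run$smoothing_sigma_px,
    min_distance_px = run$min_distance_px,
    threshold_quantile = run$threshold_quantile,
    min_sep_nm = run$min_sep_nm, max_sep_nm = run$max_sep_nm,
    verbose = verbose
  )
  if (nrow(particles) == 0) {
    warning("run_pipeline: zero particles detected; returning empty result")
    res <- structure(list(particles = particles, truth = truth, aligned = list(),
                          average = NULL, profiles = NULL, fits = NULL,
                          geometry = NULL, assignments = NULL, classes = NULL,
                          kymograph = NULL, config = config, n_requested = n),
                     class = "spa_run")
    if (!is.null(out_dir)) .write_run(res, out_dir)
    return(res)
  }
  aligned <- lapply(seq_len(nrow(particles)), function(i) {
    align_particle(stack, particles[i, ], crop_px = config$crop_px,
                   pixel_pitch_nm = pitch, z_step_nm = z_step)
  })
  .msg(verbose, "run_pipeline: aligned %d particles (%d edge-flagged)",
       length(aligned), sum(vapply(aligned, `[[`, logical(1), "edge")))
  avg <- sum_particles(mirror_augment(aligned))
  profiles <- list(
    cenpa_lateral = extract_profile(avg, "cenpa", "lateral", half_width_px),
    cenpa_axial_wide = extract_profile(avg, "cenpa", "chromosomal", 20.5),
    marker_lateral = extract_profile(avg, "marker", "lateral", half_width_px),
    marker_axial = extract_profile(avg, "marker", "chromosomal", half_width_px)
  )
  fits <- list(
    cenpa_lateral = fit_gaussians(profiles$cenpa_lateral, ks = 2),
    marker_lateral = fit_gaussians(profiles$marker_lateral, k_max = 3)
  )
  if (config$marker_model == "satellite") {
    geometry <- measure_geometry(
      cenpa_lateral_fit = fits$cenpa_lateral,
      satellite_lateral_fit = fits$marker_lateral,
      particles = particles
    )
  } else {
    geometry <- measure_geometry(
      cenpa_lateral_fit = fits$cenpa_lateral,
      marker_lateral_fit = fits$marker_lateral,
      marker_axial_profile = profiles$marker_axial,
      particles = particles
    )
  }
  assignments <- NULL; classes <- NULL; kymo <- NULL
  if (config$marker_model == "cohesin" && nrow(particles) >= 3) {
    ratios <- particle_ratios(aligned, half_width_px = half_width_px)
    assignments <- rank_and_partition(ratios, particles$particle_id,
                                      boundaries = boundaries)
    classes <- class_summary(assignments, particles, aligned)
    kymo <- build_kymograph(aligned, ordering = match(assignments$particle_id,
                                                      particles$particle_id))
  }
  res <- structure(list(particles = particles, truth = truth,
                        aligned = aligned, average = avg, profiles = profiles,
                        fits = fits, geometry = geometry,
                        assignments = assignments, classes = classes,
                        kymograph = kymo, config = config, n_requested = n),
                   class = "spa_run")
  if (!is.null(out_dir)) .write_run(res, out_dir)
  res
}

.write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pt <- res$particles
  if (!is.null(res$assignments) && nrow(pt) > 0) {
    pt <- merge(pt, res$assignments, by = "particle_id", sort = TRUE)
  }
  write.csv(pt, file.path(out_dir, "particles.csv"), row.names = FALSE)
  if (!is.null(res$truth)) {
    write.csv(res$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  if (!is.null(res$geometry)) {
    write.csv(res$geometry, file.path(out_dir, "geometry.csv"),
              row.names = FALSE)
  }
  if (!is.null(res$average)) {
    avg <- res$average$data
    write_stack(array(avg, dim = c(dim(avg)[1:2], 1L, dim(avg)[3]),
                      dimnames = list(NULL, NULL, NULL, dimnames(avg)[[3]])),
                file.path(out_dir, "average.tiff"),
                pixel_pitch_nm = res$config$pixel_pitch_nm,
                z_step_nm = res$config$z_step_nm)
  }
  if (!is.null(res$profiles)) {
    prof_df <- do.call(rbind, lapply(names(res$profiles), function(nm) {
      p <- res$profiles[[nm]]
      data.frame(profile = nm, position_nm = p$position_nm,
                 intensity = p$intensity, stringsAsFactors = FALSE)
    }))
    write.csv(prof_df, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.spa_run <- function(x, ...) {
  cat(sprintf("<spa_run> %d particle(s) from %d requested\n",
              nrow(x$particles), x$n_requested))
  if (!is.null(x$geometry)) {
    print(x$geometry, digits = 4)
  }
  invisible(x)
}

#' @export
summary.spa_run <- function(object, ...) {
  print(object)
  if (!is.null(object$classes)) print(object$classes)
  invisible(object)
}

#' @export
plot.spa_run <- function(x, ...) {
  if (is.null(x$average)) {
    warning("plot.spa_run: nothing to plot (no average image)")
    return(invisible(x))
  }
  old <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  plot(x$average, channel = "cenpa")
  plot(x$average, channel = "marker")
  plot(x$fits$cenpa_lateral, main = "CENP-A lateral")
  plot(x$fits$marker_lateral, main = "marker lateral")
  invisible(x)
}
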