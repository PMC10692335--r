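#' Ground-truth geometry of a synthetic centromere
#'
#' Builds the configuration object that fully determines the forward model
#' used by [render_particle()] and [render_spread()]. The defaults encode the
#' measured core geometry of human mitotic centromeres: paired CENP-A clusters
#' 562 nm apart (per-particle S.D. 91.6 nm) with 81 nm (S.D.) cluster width, a
#' cohesin band of 190 nm lateral S.D. extending ~800 nm along the chromosomal
#' axis, and (in the satellite presets) a broad alpha-satellite cloud whose
#' lateral intensity maxima sit at +/-209 nm with a shallow central
#' depression.
#'
#' All lengths are nanometres. Pixels are 0-based with pixel centres at
#' `(i + 0.5) * pixel_pitch_nm`; the lateral (inter-sister) axis is x after
#' alignment and the chromosomal axis is y; z slice 0 is the stack bottom.
#'
#' The satellite cloud is modelled as two equal lateral Gaussians whose
#' centres are solved numerically at build time so that the intensity maxima
#' of their sum lie exactly at `satellite_peak_offset_nm`; the solved centre
#' is stored in the returned object as `satellite_center_nm`. The central
#' depression of this model spans the distance between the two flanking
#' maxima (`2 * satellite_peak_offset_nm`), which is how the dip width is
#' measured downstream.
#'
#' @param cenpa_separation_nm mean lateral CENP-A peak-to-peak distance.
#' @param cenpa_separation_sd_nm per-particle S.D. of that distance.
#' @param cenpa_sigma_nm Gaussian S.D. of each CENP-A cluster (in xy).
#' @param cenpa_sigma_z_nm axial (z) S.D. of each cluster.
#' @param cenpa_z_offset_nm z offset between the two clusters (default 0; the
#'   inter-sister axis is kept in the imaging plane).
#' @param marker_model `"cohesin"` renders the pericentromeric band in the
#'   marker channel; `"satellite"` renders the alpha-satellite cloud (CENP-B
#'   or chromosome-specific FISH presets).
#' @param cohesin_lateral_sigma_nm S.D. of the band across the inter-sister
#'   axis (the reported lateral width).
#' @param cohesin_axial_extent_nm full axial extent of the band, realised as a
#'   top-hat convolved with a `cohesin_shoulder_sigma_nm` Gaussian; its FWHM
#'   equals the extent.
#' @param cohesin_shoulder_sigma_nm shoulder smoothing of the axial top-hat.
#' @param cohesin_z_sigma_nm z S.D. of the band.
#' @param cohesin_class one of `"central"`, `"uniform"`, `"split"`; the
#'   default class used when a particle does not carry its own label.
#' @param dip_depth_frac fractional intensity depression at the structure
#'   centre for the split class (0-1).
#' @param enhancement_frac fractional central enhancement for the central
#'   class.
#' @param class_mod_sigma_nm S.D. of the Gaussian used to carve the split dip
#'   / central enhancement along the chromosomal axis.
#' @param cohesin_flank_frac amplitude (as a fraction of the band peak) of the
#'   minor cohesin bumps just outside the CENP-A clusters; 0 disables them.
#' @param cohesin_flank_offset_nm lateral position of those bumps.
#' @param cohesin_flank_sigma_nm their isotropic S.D.
#' @param satellite_peak_offset_nm lateral position of the satellite cloud's
#'   intensity maxima from the centre.
#' @param satellite_sigma_nm S.D. of each lateral satellite Gaussian.
#' @param satellite_axial_sigma_nm axial (chromosomal-axis) spread of the
#'   cloud.
#' @param satellite_z_sigma_nm z S.D. of the cloud.
#' @param dapi_lateral_sigma_nm,dapi_axial_sigma_nm,dapi_z_sigma_nm diffuse
#'   DNA counterstain ellipse.
#' @param amplitudes named numeric vector of peak intensities (arbitrary
#'   units) for channels `dna`, `cenpa`, `marker`.
#' @param background constant background level added to every channel.
#' @param pixel_pitch_nm lateral pixel pitch.
#' @param z_step_nm z-stack step.
#' @param n_z number of z slices.
#' @param crop_px side of the square crop used in alignment/averaging (even).
#' @return an object of class `geometry_config` (a validated list).
#' @seealso [preset_cenpb()], [preset_chr7()], [noise_config()]
#' @examples
#' cfg <- geometry_config()
#' cfg$cenpa_separation_nm
#' @export
geometry_config <- function(cenpa_separation_nm = 562,
                            cenpa_separation_sd_nm = 91.6,
                            cenpa_sigma_nm = 81,
                            cenpa_sigma_z_nm = 200,
                            cenpa_z_offset_nm = 0,
                            marker_model = c("cohesin", "satellite"),
                            cohesin_lateral_sigma_nm = 190,
                            cohesin_axial_extent_nm = 800,
                            cohesin_shoulder_sigma_nm = 50,
                            cohesin_z_sigma_nm = 250,
                            cohesin_class = c("uniform", "central", "split"),
                            dip_depth_frac = 0.7,
                            enhancement_frac = 1.0,
                            class_mod_sigma_nm = 120,
                            cohesin_flank_frac = 0,
                            cohesin_flank_offset_nm = 380,
                            cohesin_flank_sigma_nm = 100,
                            satellite_peak_offset_nm = 209,
                            satellite_sigma_nm = 150,
                            satellite_axial_sigma_nm = 300,
                            satellite_z_sigma_nm = 250,
                            dapi_lateral_sigma_nm = 350,
                            dapi_axial_sigma_nm = 550,
                            dapi_z_sigma_nm = 300,
                            amplitudes = c(dna = 40, cenpa = 100, marker = 80),
                            background = 10,
                            pixel_pitch_nm = 40,
                            z_step_nm = 125,
                            n_z = 9,
                            crop_px = 60) {
  marker_model <- match.arg(marker_model)
  cohesin_class <- match.arg(cohesin_class)
  cfg <- list(
    cenpa_separation_nm = cenpa_separation_nm,
    cenpa_separation_sd_nm = cenpa_separation_sd_nm,
    cenpa_sigma_nm = cenpa_sigma_nm,
    cenpa_sigma_z_nm = cenpa_sigma_z_nm,
    cenpa_z_offset_nm = cenpa_z_offset_nm,
    marker_model = marker_model,
    cohesin_lateral_sigma_nm = cohesin_lateral_sigma_nm,
    cohesin_axial_extent_nm = cohesin_axial_extent_nm,
    cohesin_shoulder_sigma_nm = cohesin_shoulder_sigma_nm,
    cohesin_z_sigma_nm = cohesin_z_sigma_nm,
    cohesin_class = cohesin_class,
    dip_depth_frac = dip_depth_frac,
    enhancement_frac = enhancement_frac,
    class_mod_sigma_nm = class_mod_sigma_nm,
    cohesin_flank_frac = cohesin_flank_frac,
    cohesin_flank_offset_nm = cohesin_flank_offset_nm,
    cohesin_flank_sigma_nm = cohesin_flank_sigma_nm,
    satellite_peak_offset_nm = satellite_peak_offset_nm,
    satellite_sigma_nm = satellite_sigma_nm,
    satellite_axial_sigma_nm = satellite_axial_sigma_nm,
    satellite_z_sigma_nm = satellite_z_sigma_nm,
    dapi_lateral_sigma_nm = dapi_lateral_sigma_nm,
    dapi_axial_sigma_nm = dapi_axial_sigma_nm,
    dapi_z_sigma_nm = dapi_z_sigma_nm,
    amplitudes = amplitudes,
    background = background,
    pixel_pitch_nm = pixel_pitch_nm,
    z_step_nm = z_step_nm,
    n_z = n_z,
    crop_px = crop_px
  )
  cfg <- validate_geometry_config(cfg)
  cfg$satellite_center_nm <- solve_satellite_center(
    cfg$satellite_peak_offset_nm, cfg$satellite_sigma_nm
  )
  class(cfg) <- "geometry_config"
  cfg
}

#' @export
print.geometry_config <- function(x, ...) {
  cat("<geometry_config>\n")
  cat(sprintf("  CENP-A: separation %.1f nm (S.D. %.1f), cluster sigma %.1f nm\n",
              x$cenpa_separation_nm, x$cenpa_separation_sd_nm, x$cenpa_sigma_nm))
  if (x$marker_model == "cohesin") {
    cat(sprintf("  marker: cohesin band, lateral sigma %.0f nm, axial extent %.0f nm, class '%s'\n",
                x$cohesin_lateral_sigma_nm, x$cohesin_axial_extent_nm, x$cohesin_class))
  } else {
    cat(sprintf("  marker: satellite cloud, peaks at +/-%.0f nm (sigma %.0f nm, centres solved at +/-%.1f nm)\n",
                x$satellite_peak_offset_nm, x$satellite_sigma_nm, x$satellite_center_nm))
  }
  cat(sprintf("  raster: %.0f nm/px, z step %.0f nm, %d slices, crop %d px\n",
              x$pixel_pitch_nm, x$z_step_nm, x$n_z, x$crop_px))
  invisible(x)
}

validate_geometry_config <- function(cfg) {
  lens <- c("cenpa_separation_sd_nm", "cenpa_sigma_nm", "cenpa_sigma_z_nm",
            "cohesin_lateral_sigma_nm", "cohesin_axial_extent_nm",
            "cohesin_shoulder_sigma_nm", "cohesin_z_sigma_nm",
            "class_mod_sigma_nm", "cohesin_flank_offset_nm",
            "cohesin_flank_sigma_nm", "satellite_peak_offset_nm",
            "satellite_sigma_nm", "satellite_axial_sigma_nm",
            "satellite_z_sigma_nm", "dapi_lateral_sigma_nm",
            "dapi_axial_sigma_nm", "dapi_z_sigma_nm", "pixel_pitch_nm",
            "z_step_nm")
  for (f in lens) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      .stopf("geometry_config: field '%s' must be a positive length", f)
    }
  }
  if (cfg$cenpa_separation_nm < 0) {
    .stopf("geometry_config: field 'cenpa_separation_nm' must be >= 0")
  }
  for (f in c("dip_depth_frac", "enhancement_frac", "cohesin_flank_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      .stopf("geometry_config: field '%s' must be non-negative", f)
    }
  }
  if (cfg$dip_depth_frac > 1) {
    .stopf("geometry_config: field 'dip_depth_frac' must lie in [0, 1]")
  }
  if (!cfg$cohesin_class %in% c("central", "uniform", "split")) {
    .stopf("geometry_config: field 'cohesin_class' must be central/uniform/split")
  }
  if (cfg$n_z < 1 || cfg$n_z != round(cfg$n_z)) {
    .stopf("geometry_config: field 'n_z' must be a positive integer")
  }
  if (cfg$crop_px < 2 || cfg$crop_px %% 2 != 0) {
    .stopf("geometry_config: field 'crop_px' must be a positive even integer")
  }
  need <- cfg$cenpa_separation_nm + 6 * cfg$cenpa_sigma_nm
  if (cfg$pixel_pitch_nm * cfg$crop_px < need) {
    .stopf(paste0("geometry_config: crop too small: 'pixel_pitch_nm * crop_px'",
                  " (%.0f nm) must cover 'cenpa_separation_nm + 6 sigma' (%.0f nm)"),
           cfg$pixel_pitch_nm * cfg$crop_px, need)
  }
  if (!all(c("dna", "cenpa", "marker") %in% names(cfg$amplitudes))) {
    .stopf("geometry_config: field 'amplitudes' needs entries dna, cenpa, marker")
  }
  if (any(cfg$amplitudes < 0) || cfg$background < 0) {
    .stopf("geometry_config: field 'amplitudes'/'background' must be non-negative")
  }
  cfg
}

#' Solve the satellite Gaussian centre for a given peak position
#'
#' The satellite cloud's lateral profile is the sum of two equal Gaussians at
#' `+/-c`. Because the tails overlap, the intensity maxima of the sum sit
#' inside `c`; this solves for the `c` that places the maxima exactly at
#' `peak_offset_nm` given the cluster S.D.
#'
#' @param peak_offset_nm desired position of the intensity maxima (> sigma).
#' @param sigma_nm S.D. of each Gaussian.
#' @return the centre distance `c` in nm.
#' @export
solve_satellite_center <- function(peak_offset_nm, sigma_nm) {
  if (peak_offset_nm <= sigma_nm) {
    .stopf(paste0("satellite geometry: peak offset (%.0f nm) must exceed the",
                  " cluster sigma (%.0f nm) for a bimodal cloud"),
           peak_offset_nm, sigma_nm)
  }
  peak_of <- function(cc) {
    optimize(function(x) {
      exp(-(x - cc)^2 / (2 * sigma_nm^2)) + exp(-(x + cc)^2 / (2 * sigma_nm^2))
    }, c(1e-9, cc + 4 * sigma_nm), maximum = TRUE)$maximum
  }
  uniroot(function(cc) peak_of(cc) - peak_offset_nm,
          lower = sigma_nm * (1 + 1e-4),
          upper = peak_offset_nm + 8 * sigma_nm, tol = 1e-9)$root
}

#' Instrument and structure presets
#'
#' `preset_cenpb()` configures the satellite marker channel as the
#' pan-centromeric CENP-B box FISH cloud (lateral maxima at +/-209 nm, shallow
#' central depression spanning them). `preset_chr7()` configures the
#' chromosome-7 D7Z1 array geometry: inter-CENP-A distance 634 nm (S.D.
#' 102 nm), lateral satellite maxima at +/-206 nm with 175 nm cluster S.D. and
#' 247 nm axial spread. Both accept overrides passed through to
#' [geometry_config()].
#'
#' @param ... overrides forwarded to [geometry_config()].
#' @return a `geometry_config`.
#' @export
preset_cenpb <- function(...) {
  args <- list(
    marker_model = "satellite",
    satellite_peak_offset_nm = 209,
    satellite_sigma_nm = 150,
    satellite_axial_sigma_nm = 300
  )
  args[names(list(...))] <- list(...)
  do.call(geometry_config, args)
}

#' @rdname preset_cenpb
#' @export
preset_chr7 <- function(...) {
  args <- list(
    marker_model = "satellite",
    cenpa_separation_nm = 634,
    cenpa_separation_sd_nm = 102,
    satellite_peak_offset_nm = 206,
    satellite_sigma_nm = 175,
    satellite_axial_sigma_nm = 247
  )
  args[names(list(...))] <- list(...)
  do.call(geometry_config, args)
}

#' Acquisition noise configuration
#'
#' Photon (Poisson) noise followed by additive Gaussian camera noise. With
#' `poisson_scale = s`, a clean intensity `I` becomes
#' `rpois(I * s) / s + rnorm(0, gaussian_sd)`; `poisson_scale = 0` disables
#' the Poisson step. A `NULL` noise configuration everywhere in the package
#' means a noiseless render. Identical seed and configuration give
#' bit-identical output.
#'
#' @param poisson_scale photons per intensity unit (>= 0).
#' @param gaussian_sd camera noise S.D. in intensity units (>= 0).
#' @param seed RNG seed (integer or NULL).
#' @return an object of class `noise_config`.
#' @export
noise_config <- function(poisson_scale = 1, gaussian_sd = 3, seed = NULL) {
  if (poisson_scale < 0) .stopf("noise_config: field 'poisson_scale' must be >= 0")
  if (gaussian_sd < 0) .stopf("noise_config: field 'gaussian_sd' must be >= 0")
  structure(list(poisson_scale = poisson_scale, gaussian_sd = gaussian_sd,
                 seed = seed), class = "noise_config")
}

## Apply noise to a clean array; does not touch the RNG seed itself (callers
## seed the stream once so placement + noise share it deterministically).
.apply_noise <- function(arr, noise) {
  if (is.null(noise)) return(arr)
  out <- arr
  if (noise$poisson_scale > 0) {
    out[] <- rpois(length(out), pmax(out * noise$poisson_scale, 0)) /
      noise$poisson_scale
  }
  if (noise$gaussian_sd > 0) {
    out[] <- out + rnorm(length(out), 0, noise$gaussian_sd)
  }
  out
}
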