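## Forward model -------------------------------------------------------------
##
## Every structure is a sum of separable terms in the particle frame
## (lateral axis x', chromosomal axis y', stack axis z):
##   term(x', y', z) = amp * px(x') * py(y') * pz(z - cz)
## with peak-normalised 1D profiles. In-plane pixel values are obtained by
## 3-point Gauss-Legendre quadrature over each pixel; z is sampled at the
## slice centre. Structures are drawn already blurred (the profile S.D.s are
## post-PSF widths); there is no separate PSF convolution step.

.gauss_prof <- function(mu, s) {
  force(mu); force(s)
  function(t) exp(-(t - mu)^2 / (2 * s^2))
}

## Axial band: top-hat of full extent L with Gaussian shoulders; half maximum
## falls exactly at the top-hat edges, so the FWHM equals L.
.band_prof <- function(L, shoulder_sd, modulation = NULL) {
  force(L); force(shoulder_sd); force(modulation)
  function(t) {
    b <- pnorm((t + L / 2) / shoulder_sd) - pnorm((t - L / 2) / shoulder_sd)
    if (!is.null(modulation)) b <- b * modulation(t)
    b
  }
}

.class_modulation <- function(class, dip_depth_frac, enhancement_frac, mod_sd) {
  switch(class,
    uniform = NULL,
    split = {
      force(dip_depth_frac); force(mod_sd)
      function(t) 1 - dip_depth_frac * exp(-t^2 / (2 * mod_sd^2))
    },
    central = {
      force(enhancement_frac); force(mod_sd)
      function(t) 1 + enhancement_frac * exp(-t^2 / (2 * mod_sd^2))
    }
  )
}

## Terms for the three channels of one particle.
.model_terms <- function(config, separation_nm, class) {
  s2 <- separation_nm / 2
  amp <- config$amplitudes
  sig <- config$cenpa_sigma_nm
  cenpa_rad <- s2 + 5.5 * sig
  zoff <- config$cenpa_z_offset_nm / 2
  cenpa <- list(
    list(amp = amp[["cenpa"]], px = .gauss_prof(-s2, sig),
         py = .gauss_prof(0, sig), pz = .gauss_prof(-zoff, config$cenpa_sigma_z_nm)),
    list(amp = amp[["cenpa"]], px = .gauss_prof(s2, sig),
         py = .gauss_prof(0, sig), pz = .gauss_prof(zoff, config$cenpa_sigma_z_nm))
  )
  attr(cenpa, "radius_nm") <- cenpa_rad

  if (config$marker_model == "cohesin") {
    mod <- .class_modulation(class, config$dip_depth_frac,
                             config$enhancement_frac, config$class_mod_sigma_nm)
    marker <- list(
      list(amp = amp[["marker"]],
           px = .gauss_prof(0, config$cohesin_lateral_sigma_nm),
           py = .band_prof(config$cohesin_axial_extent_nm,
                           config$cohesin_shoulder_sigma_nm, mod),
           pz = .gauss_prof(0, config$cohesin_z_sigma_nm))
    )
    rad <- max(5.5 * config$cohesin_lateral_sigma_nm,
               config$cohesin_axial_extent_nm / 2 +
                 5.5 * config$cohesin_shoulder_sigma_nm)
    if (config$cohesin_flank_frac > 0) {
      fa <- amp[["marker"]] * config$cohesin_flank_frac
      fo <- config$cohesin_flank_offset_nm
      fs <- config$cohesin_flank_sigma_nm
      marker <- c(marker, list(
        list(amp = fa, px = .gauss_prof(-fo, fs), py = .gauss_prof(0, fs),
             pz = .gauss_prof(0, config$cohesin_z_sigma_nm)),
        list(amp = fa, px = .gauss_prof(fo, fs), py = .gauss_prof(0, fs),
             pz = .gauss_prof(0, config$cohesin_z_sigma_nm))
      ))
      rad <- max(rad, fo + 5.5 * fs)
    }
    attr(marker, "radius_nm") <- rad
  } else {
    cc <- config$satellite_center_nm
    ss <- config$satellite_sigma_nm
    marker <- list(
      list(amp = amp[["marker"]], px = .gauss_prof(-cc, ss),
           py = .gauss_prof(0, config$satellite_axial_sigma_nm),
           pz = .gauss_prof(0, config$satellite_z_sigma_nm)),
      list(amp = amp[["marker"]], px = .gauss_prof(cc, ss),
           py = .gauss_prof(0, config$satellite_axial_sigma_nm),
           pz = .gauss_prof(0, config$satellite_z_sigma_nm))
    )
    attr(marker, "radius_nm") <- max(cc + 5.5 * ss,
                                     5.5 * config$satellite_axial_sigma_nm)
  }

  dna <- list(
    list(amp = amp[["dna"]], px = .gauss_prof(0, config$dapi_lateral_sigma_nm),
         py = .gauss_prof(0, config$dapi_axial_sigma_nm),
         pz = .gauss_prof(0, config$dapi_z_sigma_nm))
  )
  attr(dna, "radius_nm") <- min(3.2 * max(config$dapi_lateral_sigma_nm,
                                          config$dapi_axial_sigma_nm), 1450)

  list(dna = dna, cenpa = cenpa, marker = marker)
}

## One particle's channel contributions as window patches. The caller adds
## them into its locally owned field array (keeping the large array's
## reference count at one, so the additions happen in place).
.render_contribs <- function(terms, cx, cy, cz, theta_rad, pitch, z_step,
                             dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  zc <- (seq_len(nz) - 0.5) * z_step
  ct <- cos(theta_rad); st <- sin(theta_rad)
  out <- vector("list", length(terms))
  for (ch in seq_along(terms)) {
    tl <- terms[[ch]]
    rad <- attr(tl, "radius_nm")
    ix1 <- max(1L, as.integer(ceiling((cx - rad) / pitch + 0.5 - 1e-9)))
    ix2 <- min(nx, as.integer(floor((cx + rad) / pitch + 0.5 + 1e-9)))
    iy1 <- max(1L, as.integer(ceiling((cy - rad) / pitch + 0.5 - 1e-9)))
    iy2 <- min(ny, as.integer(floor((cy + rad) / pitch + 0.5 + 1e-9)))
    if (ix1 > ix2 || iy1 > iy2) next
    X <- .px_centers_nm(ix1:ix2, pitch) - cx
    Y <- .px_centers_nm(iy1:iy2, pitch) - cy
    W <- vector("list", length(tl))
    for (a in seq_along(.gl3$nodes)) {
      Xa <- X + .gl3$nodes[a] * pitch
      for (b in seq_along(.gl3$nodes)) {
        Yb <- Y + .gl3$nodes[b] * pitch
        w <- .gl3$weights[a] * .gl3$weights[b]
        xp <- outer(Xa * ct, Yb * st, "+")
        yp <- outer(-Xa * st, Yb * ct, "+")
        for (k in seq_along(tl)) {
          contrib <- w * tl[[k]]$px(xp) * tl[[k]]$py(yp)
          W[[k]] <- if (is.null(W[[k]])) contrib else W[[k]] + contrib
        }
      }
    }
    wx <- ix2 - ix1 + 1L; wy <- iy2 - iy1 + 1L
    arr <- array(0, dim = c(wx, wy, nz))
    for (k in seq_along(tl)) {
      pz <- tl[[k]]$amp * tl[[k]]$pz(zc - cz)
      for (iz in seq_len(nz)) {
        if (pz[iz] < 1e-12) next
        arr[, , iz] <- arr[, , iz] + pz[iz] * W[[k]]
      }
    }
    out[[ch]] <- list(ch = ch, ix = ix1:ix2, iy = iy1:iy2, arr = arr)
  }
  out[!vapply(out, is.null, logical(1))]
}

.new_field <- function(nx, ny, nz, background) {
  field <- array(background, dim = c(nx, ny, nz, 3L))
  dimnames(field) <- list(NULL, NULL, NULL, c("dna", "cenpa", "marker"))
  field
}

#' Render one synthetic centromere particle
#'
#' Draws a single 3-channel z-stack patch of `crop_px` x `crop_px` pixels with
#' the particle centred on the crop centre (the corner shared by the four
#' central pixels), together with its ground-truth record. The CENP-A channel
#' contains two 3D Gaussian clusters at `+/-separation/2` along a lateral axis
#' at `angle_deg`; the marker channel contains either the cohesin band
#' (class-dependent axial profile, orthogonal to the lateral axis) or the
#' satellite cloud; the DNA channel a diffuse counterstain ellipse. Noise is
#' applied last.
#'
#' @param config a [geometry_config()].
#' @param noise a [noise_config()] or `NULL` for a noiseless render.
#' @param angle_deg in-plane angle of the inter-cluster axis; `NULL` draws
#'   uniformly from `[0, 360)`.
#' @param separation_nm cluster separation; `NULL` draws from the configured
#'   normal distribution (truncated at 0).
#' @param class cohesin class label; `NULL` uses `config$cohesin_class`.
#' @param seed RNG seed (defaults to `noise$seed`); identical seed and
#'   configuration give bit-identical output.
#' @return list with elements `patch` (array `[x, y, z, channel]`, channels
#'   `dna`, `cenpa`, `marker`), `truth` (one-row data.frame), and `config`.
#' @examples
#' p <- render_particle(geometry_config(), noise = NULL, angle_deg = 0)
#' dim(p$patch)
#' @export
render_particle <- function(config, noise = NULL, angle_deg = NULL,
                            separation_nm = NULL, class = NULL, seed = NULL) {
  stopifnot(inherits(config, "geometry_config"))
  if (is.null(seed) && !is.null(noise)) seed <- noise$seed
  .with_seed(seed, {
    if (is.null(angle_deg)) angle_deg <- runif(1, 0, 360)
    if (is.null(separation_nm)) {
      separation_nm <- max(0, rnorm(1, config$cenpa_separation_nm,
                                    config$cenpa_separation_sd_nm))
    }
    if (is.null(class)) class <- config$cohesin_class
    crop <- config$crop_px
    pitch <- config$pixel_pitch_nm
    cx <- crop / 2 * pitch
    cz <- config$n_z / 2 * config$z_step_nm
    field <- .new_field(crop, crop, config$n_z, config$background)
    terms <- .model_terms(config, separation_nm, class)
    contribs <- .render_contribs(terms, cx, cx, cz, angle_deg * pi / 180,
                                 pitch, config$z_step_nm, dim(field))
    for (co in contribs) {
      field[co$ix, co$iy, , co$ch] <- field[co$ix, co$iy, , co$ch] + co$arr
    }
    field <- .apply_noise(field, noise)
    truth <- data.frame(
      particle_id = 1L, x_nm = cx, y_nm = cx, z_nm = cz,
      angle_deg = angle_deg %% 360, separation_nm = separation_nm,
      class = class, cenpa_sigma_nm = config$cenpa_sigma_nm,
      stringsAsFactors = FALSE
    )
    list(patch = field, truth = truth, config = config)
  })
}

## Largest-remainder apportionment of n among proportions p.
.apportion <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    order_rem <- order(raw - cnt, decreasing = TRUE)
    cnt[order_rem[seq_len(rem)]] <- cnt[order_rem[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Render a synthetic metaphase-spread field
#'
#' Places `n` particles uniformly at random (minimum centre-to-centre spacing
#' 1.5 um, enforced by rejection sampling) in a square field sized to hold
#' them, renders each with its own separation, orientation and class, and
#' applies noise. Class labels are apportioned deterministically from
#' `class_mix` (largest-remainder rule), so `n = 463` with the default mix
#' yields exactly 200 split / 150 uniform / 113 central particles.
#'
#' @inheritParams render_particle
#' @param n number of particles (>= 1).
#' @param class_mix named proportions over `split`, `uniform`, `central`
#'   (normalised internally).
#' @param field_px side of the square field in pixels; `NULL` sizes it
#'   automatically.
#' @param min_spacing_nm minimum centre-to-centre distance.
#' @return list with `stack` (array `[x, y, z, channel]`), `truth` (one row
#'   per particle), `config`, `noise`.
#' @export
render_spread <- function(n, config, noise = NULL,
                          class_mix = c(split = 200, uniform = 150, central = 113) / 463,
                          field_px = NULL, min_spacing_nm = 1500, seed = NULL) {
  stopifnot(inherits(config, "geometry_config"))
  if (n < 1) .stopf("render_spread: n must be >= 1")
  if (!all(sort(names(class_mix)) == c("central", "split", "uniform"))) {
    .stopf("render_spread: class_mix needs names split/uniform/central")
  }
  if (is.null(seed) && !is.null(noise)) seed <- noise$seed
  pitch <- config$pixel_pitch_nm
  # margin covers the rotated crop's half-diagonal so aligned crops never
  # sample outside the field
  margin_nm <- (ceiling(config$crop_px / 2 * sqrt(2)) + 4) * pitch
  if (is.null(field_px)) {
    side_nm <- ceiling(sqrt(n)) * min_spacing_nm * 1.35 + 2 * margin_nm
    field_px <- ceiling(side_nm / pitch)
  }
  side_nm <- field_px * pitch
  lo <- margin_nm; hi <- side_nm - margin_nm
  if (hi <= lo) .stopf("render_spread: field too small to place %d particles", n)

  .with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L; max_tries <- 2000L * n
    while (length(xs) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        .stopf("render_spread: field too small to place %d particles at %.0f nm spacing",
               n, min_spacing_nm)
      }
      px <- runif(1, lo, hi); py <- runif(1, lo, hi)
      if (length(xs) == 0 ||
          min((xs - px)^2 + (ys - py)^2) >= min_spacing_nm^2) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    depth <- config$n_z * config$z_step_nm
    zs <- runif(n, depth / 2 - config$z_step_nm, depth / 2 + config$z_step_nm)
    angles <- runif(n, 0, 360)
    seps <- pmax(50, rnorm(n, config$cenpa_separation_nm,
                           config$cenpa_separation_sd_nm))
    counts <- .apportion(n, class_mix)
    classes <- sample(rep(names(class_mix), counts))

    field <- .new_field(field_px, field_px, config$n_z, config$background)
    for (i in seq_len(n)) {
      terms <- .model_terms(config, seps[i], classes[i])
      contribs <- .render_contribs(terms, xs[i], ys[i], zs[i],
                                   angles[i] * pi / 180, pitch,
                                   config$z_step_nm, dim(field))
      for (co in contribs) {
        field[co$ix, co$iy, , co$ch] <- field[co$ix, co$iy, , co$ch] + co$arr
      }
    }
    field <- .apply_noise(field, noise)
    truth <- data.frame(
      particle_id = seq_len(n), x_nm = xs, y_nm = ys, z_nm = zs,
      angle_deg = angles %% 360, separation_nm = seps, class = classes,
      cenpa_sigma_nm = config$cenpa_sigma_nm, stringsAsFactors = FALSE
    )
    list(stack = field, truth = truth, config = config, noise = noise)
  })
}
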