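## Bilinear sampling of one z-slice of a multi-channel stack at continuous
## pixel coordinates (1-based, pixel centre at integer index). Points outside
## the field sample 0.
.bilinear_sample <- function(slice2d, gx, gy) {
  nx <- nrow(slice2d); ny <- ncol(slice2d)
  x0 <- floor(gx); y0 <- floor(gy)
  fx <- gx - x0; fy <- gy - y0
  val <- function(ix, iy) {
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    out <- numeric(length(ix))
    out[ok] <- slice2d[cbind(ix[ok], iy[ok])]
    out
  }
  (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) +
    fx * fy * val(x0 + 1, y0 + 1)
}

#' Rotate, centre and crop one particle
#'
#' Extracts the z-slice nearest the particle's fitted midpoint, rotates the
#' field about the midpoint so the inter-cluster axis becomes horizontal
#' (lateral axis = x), translates the midpoint onto the crop centre (the
#' corner shared by the four central pixels of the even crop), and crops a
#' `crop_px` x `crop_px` patch per channel using bilinear interpolation.
#' Regions outside the field are zero-filled and flagged.
#'
#' @param stack 4D array `[x, y, z, channel]`.
#' @param particle one row of the data.frame from [find_particles()] (needs
#'   `mx_nm`, `my_nm`, `mz_nm`, `angle_deg`).
#' @param crop_px crop side (even).
#' @param pixel_pitch_nm,z_step_nm raster calibration.
#' @return an `aligned_particle`: list with `patch` (array
#'   `[crop, crop, channel]`), `particle_id`, `angle_applied_deg`,
#'   `z_slice`, `edge` flag.
#' @export
align_particle <- function(stack, particle, crop_px = 60,
                           pixel_pitch_nm = 40, z_step_nm = 125) {
  stopifnot(length(dim(stack)) == 4L)
  nz <- dim(stack)[3]
  zc <- (seq_len(nz) - 0.5) * z_step_nm
  iz <- which.min(abs(zc - particle$mz_nm))
  theta <- particle$angle_deg * pi / 180
  off <- .crop_offsets_nm(crop_px, pixel_pitch_nm)
  ox <- rep(off, times = crop_px)
  oy <- rep(off, each = crop_px)
  X <- particle$mx_nm + ox * cos(theta) - oy * sin(theta)
  Y <- particle$my_nm + ox * sin(theta) + oy * cos(theta)
  gx <- X / pixel_pitch_nm + 0.5
  gy <- Y / pixel_pitch_nm + 0.5
  nch <- dim(stack)[4]
  patch <- array(0, dim = c(crop_px, crop_px, nch))
  dimnames(patch) <- list(NULL, NULL, dimnames(stack)[[4]])
  for (ch in seq_len(nch)) {
    patch[, , ch] <- matrix(.bilinear_sample(stack[, , iz, ch], gx, gy),
                            crop_px, crop_px)
  }
  edge <- any(gx < 1 | gx > dim(stack)[1] | gy < 1 | gy > dim(stack)[2])
  structure(list(patch = patch,
                 particle_id = if (!is.null(particle$particle_id))
                   particle$particle_id else NA_integer_,
                 angle_applied_deg = particle$angle_deg,
                 z_slice = iz, edge = edge,
                 pixel_pitch_nm = pixel_pitch_nm),
            class = "aligned_particle")
}

#' Mirror augmentation of aligned particles
#'
#' Appends the left-right (lateral) mirror of every patch, doubling the list.
#' Because chromosome orientation in a spread is arbitrary, averaging the
#' original and mirrored sets makes every lateral profile exactly symmetric
#' about the structure centre.
#'
#' @param aligned list of `aligned_particle` objects.
#' @return list of doubled length; mirrored copies carry `mirrored = TRUE`.
#' @export
mirror_augment <- function(aligned) {
  mirrored <- lapply(aligned, function(a) {
    a$patch <- a$patch[rev(seq_len(dim(a$patch)[1])), , , drop = FALSE]
    a$mirrored <- TRUE
    a
  })
  c(aligned, mirrored)
}

#' Sum aligned particles into an average image
#'
#' Element-wise per-channel sum (the stored quantity is the sum, not the
#' mean; band profiles are shape-invariant to this choice).
#'
#' @param aligned non-empty list of `aligned_particle` objects of equal size.
#' @return an `average_image`: list with `data` (array
#'   `[crop, crop, channel]`), `n_contributing`, `mirrored` flag,
#'   `pixel_pitch_nm`.
#' @export
sum_particles <- function(aligned) {
  if (length(aligned) == 0) .stopf("sum_particles: empty particle list")
  acc <- aligned[[1]]$patch
  for (a in aligned[-1]) {
    if (!identical(dim(a$patch), dim(acc))) {
      .stopf("sum_particles: patches of unequal size")
    }
    acc <- acc + a$patch
  }
  structure(list(data = acc, n_contributing = length(aligned),
                 mirrored = any(vapply(aligned, function(a)
                   isTRUE(a$mirrored), logical(1))),
                 pixel_pitch_nm = aligned[[1]]$pixel_pitch_nm),
            class = "average_image")
}

#' @export
print.average_image <- function(x, ...) {
  cat(sprintf("<average_image> %d x %d px, %d channel(s), n = %d%s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$n_contributing, if (x$mirrored) " (mirror-augmented)" else ""))
  invisible(x)
}

#' @export
plot.average_image <- function(x, channel = "cenpa", ...) {
  img <- x$data[, , channel]
  ext <- .crop_offsets_nm(dim(img)[1], x$pixel_pitch_nm)
  image(ext, ext, img, col = hcl.colors(64, "inferno"), asp = 1,
        xlab = "lateral axis (nm)", ylab = "chromosomal axis (nm)",
        main = sprintf("average %s (n = %d)", channel, x$n_contributing), ...)
  invisible(x)
}
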