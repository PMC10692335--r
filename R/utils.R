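#' Convert between pixels and nanometres
#'
#' Helpers for the pixel/physical-unit bookkeeping used throughout the
#' package. Pixels are 0-based with the centre of pixel `i` at
#' `(i + 0.5) * pitch` nm; a width of `n` pixels corresponds to `n * pitch`
#' nm (so a 5-pixel integration band at 40 nm/px is 200 nm wide, and a point
#' 6 pixels from the centre is 240 nm away).
#'
#' @param px pixel count or coordinate (may be fractional).
#' @param nm distance in nanometres.
#' @param pitch_nm pixel pitch in nanometres per pixel.
#' @return `px_to_nm()` returns nanometres; `nm_to_px()` returns pixels.
#' @examples
#' px_to_nm(5, 40)  # 200
#' px_to_nm(6, 40)  # 240
#' nm_to_px(562, 40)
#' @export
px_to_nm <- function(px, pitch_nm) px * pitch_nm

#' @rdname px_to_nm
#' @export
nm_to_px <- function(nm, pitch_nm) nm / pitch_nm

## Gauss-Legendre 3-point rule on a unit pixel, used for in-plane pixel
## integration of the forward model (exact for polynomials to degree 5).
.gl3 <- list(
  nodes = c(-sqrt(3 / 5) / 2, 0, sqrt(3 / 5) / 2),
  weights = c(5, 8, 5) / 18
)

## Centre coordinate (nm) of 1-based pixel indices.
.px_centers_nm <- function(idx1, pitch_nm) (idx1 - 0.5) * pitch_nm

## Offsets (nm) of an even crop's pixel centres relative to the crop centre,
## which sits on the corner shared by the four central pixels.
.crop_offsets_nm <- function(crop_px, pitch_nm) {
  (seq_len(crop_px) - (crop_px / 2 + 0.5)) * pitch_nm
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msg <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

## Seed an RNG stream locally; NULL leaves the global stream untouched.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Full width at half maximum of a sampled profile, linear interpolation,
## measured relative to a baseline estimated from the outermost samples.
.fwhm_linear <- function(x, y, baseline = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  if (is.null(baseline)) {
    k <- max(2L, ceiling(length(y) * 0.08))
    baseline <- mean(c(head(y, k), tail(y, k)))
  }
  imax <- which.max(y)
  half <- baseline + (y[imax] - baseline) / 2
  cross <- function(idx) {
    # idx runs from the peak outward; first crossing below `half`
    for (i in seq_along(idx)[-1]) {
      a <- idx[i - 1L]; b <- idx[i]
      if ((y[a] - half) * (y[b] - half) <= 0 && y[a] != y[b]) {
        return(x[a] + (half - y[a]) * (x[b] - x[a]) / (y[b] - y[a]))
      }
    }
    NA_real_
  }
  xl <- cross(imax:1)
  xr <- cross(imax:length(y))
  if (is.na(xl) || is.na(xr)) return(NA_real_)
  xr - xl
}
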