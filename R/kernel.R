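#' Joint T2*-diffusion signal attenuation kernel
#'
#' Attenuation of the MR signal at echo time `echo_time` and diffusion
#' weighting `b_value` for a spin population with effective transverse
#' relaxation time `t2star` and apparent diffusion coefficient `adc`:
#'
#'   k = exp(-(TE - TEmin) / T2*) * exp(-b * ADC)
#'
#' The shortest echo time acquired, TEmin, is the reference point: the
#' b = 0, TE = TEmin measurement has attenuation exactly 1, so S0 is the
#' signal at that reference volume.
#'
#' All arguments are vectorised and recycled.
#'
#' @param echo_time Echo time in seconds (>= `te_min`).
#' @param b_value Diffusion weighting in s·mm^-2 (>= 0).
#' @param t2star Effective transverse relaxation time in seconds (> 0).
#' @param adc Apparent diffusion coefficient in mm^2·s^-1 (>= 0).
#' @param te_min Shortest echo time of the protocol, seconds.
#' @return Unitless attenuation in (0, 1].
#' @export
signal_kernel <- function(echo_time, b_value, t2star, adc, te_min) {
  if (any(!is.finite(t2star)) || any(t2star <= 0)) {
    stop("t2star must be positive", call. = FALSE)
  }
  if (any(!is.finite(adc)) || any(adc < 0)) {
    stop("adc must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(b_value)) || any(b_value < 0)) {
    stop("b_value must be non-negative", call. = FALSE)
  }
  if (any(echo_time < te_min - 1e-12)) {
    stop("echo_time must be >= te_min", call. = FALSE)
  }
  exp(-(echo_time - te_min) / t2star) * exp(-b_value * adc)
}

#' Noise-free signal vector for one spin population
#'
#' Evaluates the forward model S(TE, b) = S0 * k(TE, b) over every
#' measurement of a protocol, in protocol row order.
#'
#' @param s0 Signal at the reference volume (b = 0, TE = TEmin); arbitrary
#'   units, >= 0.
#' @param t2star,adc Population parameters as in [signal_kernel()].
#' @param protocol An [acquisition_protocol()].
#' @return Numeric vector with one element per protocol measurement.
#' @export
forward_signal <- function(s0, t2star, adc, protocol) {
  if (!is.finite(s0) || s0 < 0) stop("s0 must be non-negative", call. = FALSE)
  s0 * signal_kernel(protocol$echo_time, protocol$b_value, t2star, adc,
                     te_min(protocol))
}

#' Discretize the T2*-ADC plane
#'
#' Builds the rectangular, log-spaced grid over which component spectra are
#' represented. Both axes include their bounds. The default range spans the
#' placental regime with margin: T2* 0.01-0.30 s covers the reported low
#' (< 0.06 s) and high (> 0.09 s) peaks; the ADC axis extends to 1.0
#' mm^2·s^-1, above the free-water line at 0.3 mm^2·s^-1 used to flag
#' vascular spins.
#'
#' @param t2star_range Length-2 positive numeric, seconds.
#' @param adc_range Length-2 positive numeric, mm^2·s^-1.
#' @param n_t2star,n_adc Number of grid points per axis (>= 2).
#' @return An object of class `spectral_grid`: list with `t2star` and `adc`
#'   axis vectors (strictly increasing, log-spaced).
#' @export
build_spectral_grid <- function(t2star_range = c(0.01, 0.30),
                                adc_range = c(1e-4, 1.0),
                                n_t2star = 50, n_adc = 50) {
  check_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] >= r[2]) {
      stop(what, " range must be positive with min < max", call. = FALSE)
    }
  }
  check_range(t2star_range, "t2star")
  check_range(adc_range, "adc")
  if (n_t2star < 2 || n_adc < 2) {
    stop("grid sizes must be >= 2", call. = FALSE)
  }
  grid <- list(
    t2star = exp(seq(log(t2star_range[1]), log(t2star_range[2]),
                     length.out = n_t2star)),
    adc = exp(seq(log(adc_range[1]), log(adc_range[2]), length.out = n_adc))
  )
  class(grid) <- "spectral_grid"
  grid
}

#' All (T2*, ADC) pairs of a spectral grid
#'
#' Grid points are enumerated with the T2* axis varying fastest; this order
#' is the canonical column order of the kernel dictionary and of component
#' amplitude vectors.
#'
#' @param grid A `spectral_grid`.
#' @return A matrix with columns `t2star` and `adc`, one row per grid point.
#' @export
grid_points <- function(grid) {
  pts <- expand.grid(t2star = grid$t2star, adc = grid$adc,
                     KEEP.OUT.ATTRS = FALSE)
  as.matrix(pts)
}

#' Number of points in a spectral grid
#' @param grid A `spectral_grid`.
#' @return Integer.
#' @export
n_grid_points <- function(grid) length(grid$t2star) * length(grid$adc)

#' Kernel dictionary for a protocol over a spectral grid
#'
#' Entry (i, j) is the attenuation of grid atom j under measurement i. The
#' row belonging to the reference measurement (b = 0, TE = TEmin) is
#' identically 1.
#'
#' @param protocol An [acquisition_protocol()].
#' @param grid A `spectral_grid`.
#' @return Numeric matrix, `n_measurements(protocol)` rows by
#'   `n_grid_points(grid)` columns.
#' @export
kernel_matrix <- function(protocol, grid) {
  pts <- grid_points(grid)
  tm <- te_min(protocol)
  # outer sums of the two exponents, fully vectorised
  relax <- exp(-outer(protocol$echo_time - tm, 1 / pts[, "t2star"]))
  diff <- exp(-outer(protocol$b_value, pts[, "adc"]))
  K <- relax * diff
  attr(K, "n_t2star") <- length(grid$t2star)
  attr(K, "n_adc") <- length(grid$adc)
  K
}
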