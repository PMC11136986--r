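#' Add Rician noise to magnitude MR data
#'
#' Magnitude MRI noise: the observed value is the modulus of the complex
#' signal after independent Gaussian noise of standard deviation `sigma` on
#' the real and imaginary channels. Positive-biased at low SNR. A Gaussian
#' option is provided for testing linear solvers.
#'
#' @param signal Numeric array of noise-free magnitudes.
#' @param sigma Noise standard deviation per channel (same units as signal).
#' @param model `"rician"` (default) or `"gaussian"`.
#' @return Array of the same shape as `signal`.
#' @export
add_noise <- function(signal, sigma, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- if (model == "rician") {
    sqrt((signal + rnorm(n, sd = sigma))^2 + rnorm(n, sd = sigma)^2)
  } else {
    signal + rnorm(n, sd = sigma)
  }
  array(out, dim = dim(signal) %||% n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean of a Rician-distributed magnitude
#'
#' E|x| for x ~ Rice(nu, sigma), via the Laguerre polynomial form. Used to
#' predict the positive bias of magnitude data in calibration checks.
#'
#' @param nu Underlying noise-free magnitude.
#' @param sigma Per-channel noise standard deviation.
#' @return Expected observed magnitude.
#' @export
rician_mean <- function(nu, sigma) {
  if (sigma == 0) return(nu)
  x <- -nu^2 / (2 * sigma^2)
  # L_{1/2}(x) = e^{x/2} [ (1-x) I_0(-x/2) - x I_1(-x/2) ]; with x <= 0 the
  # e^{x/2} factor cancels the scaling of besselI(..., expon.scaled = TRUE)
  l_half <- (1 - x) * besselI(-x / 2, 0, expon.scaled = TRUE) -
    x * besselI(-x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * l_half
}

#' Estimate the Rician noise level from background voxels
#'
#' For pure-noise magnitude voxels E\[y^2\] = 2 sigma^2, so sigma is
#' estimated from the second moment of all measurements in voxels outside
#' the ROI mask.
#'
#' @param series A [volume_series()].
#' @param mask A [roi_mask()]; voxels outside it are treated as background.
#' @return Estimated per-channel noise standard deviation.
#' @export
estimate_noise_sigma <- function(series, mask) {
  dims <- dim(series$data)[1:3]
  bg <- which(!mask$data)
  if (length(bg) < 30) {
    stop("too few background voxels to estimate the noise level",
         call. = FALSE)
  }
  vals <- matrix(series$data, nrow = prod(dims))[bg, ]
  sqrt(mean(vals^2) / 2)
}

#' Remove the Rician noise floor from magnitude data
#'
#' Moment-based magnitude bias correction: since E\[y^2\] = nu^2 + 2 sigma^2
#' for a Rician measurement of underlying amplitude nu, the corrected value
#' is sqrt(max(y^2 - 2 sigma^2, 0)). Used ahead of linear decomposition so
#' heavily attenuated measurements are not inflated by the noise floor.
#'
#' @param data Numeric array of magnitudes.
#' @param sigma Per-channel noise standard deviation.
#' @return Corrected array of the same shape.
#' @export
rician_floor_correct <- function(data, sigma) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  sqrt(pmax(data^2 - 2 * sigma^2, 0))
}

#' Match estimated components to ground truth
#'
#' Finds the assignment of estimated to true components minimising the total
#' pairing cost, by exhaustive search over permutations (intended for the
#' small M of this analysis). Cost is supplied as a matrix with true
#' components in rows and estimated components in columns.
#'
#' @param cost Square numeric cost matrix (true x estimated).
#' @return Integer vector `perm` such that estimated component `perm[i]`
#'   matches true component `i`, with attribute `total_cost`.
#' @export
match_components <- function(cost) {
  m <- nrow(cost)
  if (ncol(cost) != m) stop("cost matrix must be square", call. = FALSE)
  if (m > 8) stop("exhaustive matching supported for M <= 8", call. = FALSE)
  perms <- permutations_of(m)
  totals <- vapply(perms, function(p) sum(cost[cbind(seq_len(m), p)]),
                   numeric(1))
  best <- perms[[which.min(totals)]]
  attr(best, "total_cost") <- min(totals)
  best
}

permutations_of <- function(m) {
  if (m == 1) return(list(1L))
  sub <- permutations_of(m - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(m)) {
      out[[length(out) + 1L]] <- append(p, m, after = pos - 1L)
    }
  }
  out
}

#' Project a vector onto the probability simplex
#'
#' Euclidean projection onto \{w : w >= 0, sum(w) = 1\} by the sorted
#' threshold construction.
#'
#' @param v Numeric vector.
#' @return Projected vector of the same length.
#' @export
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Derive a child RNG seed
#'
#' Deterministically derives a stream-specific 31-bit seed from a base seed,
#' so that independent stages (phantom geometry, noise, cohort sampling) do
#' not share random streams.
#'
#' @param seed Base integer seed.
#' @param stream Small integer stream index.
#' @return Integer seed in [0, 2^31).
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483647)
}

stopifnot_scalar <- function(x, what, positive = FALSE) {
  if (length(x) != 1 || !is.finite(x)) {
    stop(what, " must be a finite scalar", call. = FALSE)
  }
  if (positive && x <= 0) stop(what, " must be > 0", call. = FALSE)
  invisible(x)
}
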