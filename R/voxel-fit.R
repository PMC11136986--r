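# Voxelwise fitting of the joint T2*-ADC decay model.
#
# All voxels share the protocol design, so the nonlinear least-squares
# machinery is vectorised across voxels: one projected Levenberg-Marquardt
# iteration is a handful of (n_measurements x n_voxels) elementwise matrix
# operations plus a closed-form symmetric 3x3 solve per voxel.

# Vectorised solve of symmetric 3x3 systems via the adjugate. Inputs are
# vectors of the six unique entries and the right-hand side; returns a list
# (d1, d2, d3) with NA where the system is (near-)singular.
solve_sym3 <- function(a11, a12, a13, a22, a23, a33, b1, b2, b3) {
  c11 <- a22 * a33 - a23 * a23
  c12 <- a13 * a23 - a12 * a33
  c13 <- a12 * a23 - a13 * a22
  det <- a11 * c11 + a12 * c12 + a13 * c13
  scale <- pmax(abs(a11), abs(a22), abs(a33), 1e-300)
  bad <- !is.finite(det) | abs(det) < 1e-14 * scale^3
  det[bad] <- NA_real_
  c22 <- a11 * a33 - a13 * a13
  c23 <- a12 * a13 - a11 * a23
  c33 <- a11 * a22 - a12 * a12
  list(
    d1 = (c11 * b1 + c12 * b2 + c13 * b3) / det,
    d2 = (c12 * b1 + c22 * b2 + c23 * b3) / det,
    d3 = (c13 * b1 + c23 * b2 + c33 * b3) / det
  )
}

# Weighted log-linear closed form: regress log(signal) on (TE - TEmin) and b
# with weights signal^2 (first-order equivalent to linear-scale least
# squares). Returns list of per-voxel vectors s0, t2star, adc.
loglinear_start <- function(Y, dte, b, fix_adc = NULL) {
  tiny <- 1e-12
  W <- Y * Y
  W[Y <= tiny] <- 0
  L <- log(pmax(Y, tiny))
  x2 <- -dte
  x3 <- if (is.null(fix_adc)) -b else rep(0, length(b))
  if (!is.null(fix_adc)) L <- L + outer(b, rep(fix_adc, ncol(Y)))
  a11 <- colSums(W)
  a12 <- colSums(W * x2)
  a13 <- colSums(W * x3)
  a22 <- colSums(W * x2 * x2)
  a23 <- colSums(W * x2 * x3)
  a33 <- colSums(W * x3 * x3)
  b1 <- colSums(W * L)
  b2 <- colSums(W * x2 * L)
  b3 <- colSums(W * x3 * L)
  if (!is.null(fix_adc)) {
    a13 <- a23 <- b3 <- rep(0, ncol(Y))
    a33 <- rep(1, ncol(Y))
  }
  sol <- solve_sym3(a11, a12, a13, a22, a23, a33, b1, b2, b3)
  r2 <- sol$d2   # decay rate 1/T2*
  adc <- if (is.null(fix_adc)) sol$d3 else rep(fix_adc, ncol(Y))
  list(s0 = exp(pmin(sol$d1, 700)), t2star = 1 / r2, adc = adc)
}

#' Fit the T2*-ADC decay model to many voxels at once
#'
#' Least-squares fit of S(TE, b) = S0 exp(-(TE - TEmin)/T2*) exp(-b ADC) to
#' each column of a signal matrix. Initialisation is the weighted log-linear
#' closed form; refinement is a bounded (projected) Levenberg-Marquardt
#' iteration vectorised across voxels. Degenerate voxels (all-zero,
#' non-finite, or with fewer than three usable measurements) are flagged,
#' never silently imputed.
#'
#' @param Y Numeric matrix, measurements x voxels, in protocol row order.
#' @param protocol An [acquisition_protocol()].
#' @param t2star_bounds,adc_bounds Box constraints; defaults T2* in
#'   \[1 ms, 1 s\], ADC in \[0, 1\] mm^2/s.
#' @param fix_adc Optional fixed ADC value (fits S0 and T2* only).
#' @param refine If `FALSE`, return the log-linear start unrefined.
#' @param tol Relative cost-decrease convergence tolerance.
#' @param max_iter Maximum LM iterations.
#' @return List of per-voxel vectors: `s0`, `t2star`, `adc`, `residual`
#'   (residual 2-norm), `valid` (usable voxel), `converged`.
#' @export
fit_batch <- function(Y, protocol,
                      t2star_bounds = c(1e-3, 1), adc_bounds = c(0, 1),
                      fix_adc = NULL, refine = TRUE,
                      tol = 1e-10, max_iter = 200) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  n <- nrow(Y)
  V <- ncol(Y)
  if (n != n_measurements(protocol)) {
    stop("signal length does not match protocol measurement count",
         call. = FALSE)
  }
  dte <- protocol$echo_time - te_min(protocol)
  b <- protocol$b_value
  n_combo <- nrow(unique(cbind(dte, b)))
  min_combo <- if (is.null(fix_adc)) 3 else 2
  if (n_combo < min_combo) {
    stop("protocol must contain at least ", min_combo,
         " distinct (TE, b) combinations", call. = FALSE)
  }

  finite_ok <- colSums(!is.finite(Y)) == 0
  Y[, !finite_ok] <- 0
  usable <- finite_ok & colSums(Y > 0) >= min_combo
  valid <- usable

  st <- loglinear_start(Y, dte, b, fix_adc)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  s0 <- pmax(st$s0, 0)
  t2 <- clamp(st$t2star, t2star_bounds[1], t2star_bounds[2])
  adc <- clamp(st$adc, adc_bounds[1], adc_bounds[2])
  bad_start <- !is.finite(s0) | !is.finite(t2) | !is.finite(adc)
  ref <- reference_index(protocol)
  s0[bad_start] <- pmax(Y[ref, bad_start], 0)
  t2[bad_start] <- 0.05
  adc[bad_start] <- if (is.null(fix_adc)) 0.01 else fix_adc

  model_cost <- function(s0, t2, adc) {
    K <- exp(-outer(dte, 1 / t2) - outer(b, adc))
    R <- Y - sweep(K, 2, s0, `*`)
    list(K = K, R = R, cost = colSums(R * R))
  }
  cur <- model_cost(s0, t2, adc)
  cost <- cur$cost
  converged <- rep(FALSE, V)

  if (refine && any(usable)) {
    lambda <- rep(1e-3, V)
    active <- usable
    for (it in seq_len(max_iter)) {
      if (!any(active)) break
      K <- cur$K
      R <- cur$R
      J1 <- K
      J2 <- sweep(K, 2, s0 / t2^2, `*`) * dte
      J3 <- -sweep(K, 2, s0, `*`) * b
      a11 <- colSums(J1 * J1); a12 <- colSums(J1 * J2); a13 <- colSums(J1 * J3)
      a22 <- colSums(J2 * J2); a23 <- colSums(J2 * J3); a33 <- colSums(J3 * J3)
      g1 <- colSums(J1 * R); g2 <- colSums(J2 * R); g3 <- colSums(J3 * R)
      if (!is.null(fix_adc)) {
        a13 <- a23 <- g3 <- rep(0, V)
        a33 <- rep(1, V)
      }
      sol <- solve_sym3(a11 * (1 + lambda), a12, a13,
                        a22 * (1 + lambda), a23,
                        pmax(a33 * (1 + lambda), 1e-300), g1, g2, g3)
      d1 <- sol$d1; d2 <- sol$d2; d3 <- sol$d3
      no_step <- !is.finite(d1) | !is.finite(d2) | !is.finite(d3)
      d1[no_step] <- 0; d2[no_step] <- 0; d3[no_step] <- 0
      s0_new <- pmax(s0 + d1, 0)
      t2_new <- clamp(t2 + d2, t2star_bounds[1], t2star_bounds[2])
      adc_new <- if (is.null(fix_adc)) {
        clamp(adc + d3, adc_bounds[1], adc_bounds[2])
      } else adc
      prop <- model_cost(s0_new, t2_new, adc_new)
      improved <- active & (prop$cost < cost) & !no_step
      rel_drop <- (cost - prop$cost) / pmax(cost, 1e-300)
      s0[improved] <- s0_new[improved]
      t2[improved] <- t2_new[improved]
      adc[improved] <- adc_new[improved]
      cur$K[, improved] <- prop$K[, improved]
      cur$R[, improved] <- prop$R[, improved]
      cost[improved] <- prop$cost[improved]
      lambda[improved] <- pmax(lambda[improved] / 3, 1e-12)
      rejected <- active & !improved
      lambda[rejected] <- lambda[rejected] * 4
      done <- (improved & rel_drop < tol) | (rejected & lambda > 1e12)
      converged <- converged | (improved & rel_drop < tol)
      active <- active & !done
    }
  } else {
    converged <- usable
  }

  s0[!valid] <- NA_real_
  t2[!valid] <- NA_real_
  adc[!valid] <- NA_real_
  res_norm <- sqrt(cost)
  res_norm[!valid] <- NA_real_
  list(s0 = s0, t2star = t2, adc = adc, residual = res_norm,
       valid = valid, converged = converged & valid)
}

#' Fit the decay model to a single voxel
#'
#' Convenience wrapper around [fit_batch()] for one signal vector.
#'
#' @param signal Numeric vector in protocol row order.
#' @param protocol An [acquisition_protocol()].
#' @param ... Passed to [fit_batch()].
#' @return List with scalars `s0`, `t2star`, `adc`, `residual`, `valid`,
#'   `converged`.
#' @export
fit_voxel <- function(signal, protocol, ...) {
  out <- fit_batch(matrix(signal, ncol = 1), protocol, ...)
  lapply(out, `[`, 1)
}

#' Fit every ROI voxel of a scan and summarise
#'
#' Fits the decay model in each ROI voxel, producing S0/T2*/ADC maps plus
#' the ROI summaries used in cohort tables: mean and median T2* (reported in
#' ms), mean and median ADC, and the ROI volume. Summaries are computed over
#' valid voxels only; the number of excluded voxels is reported, and a
#' warning is raised when more than half the ROI fails to fit.
#'
#' @param series A [volume_series()].
#' @param mask A [roi_mask()] with the same spatial shape.
#' @param ... Passed to [fit_batch()].
#' @return List with `maps` (3-D arrays `s0`, `t2star`, `adc`, `residual`,
#'   logical `valid`; `NA` outside the ROI), `summary` (named list), and the
#'   raw per-voxel `fit`.
#' @export
fit_roi <- function(series, mask, ...) {
  check_mask_matches(series, mask)
  dims <- dim(series$data)[1:3]
  idx <- which(mask$data)
  Y <- t(matrix(series$data, nrow = prod(dims))[idx, , drop = FALSE])
  fit <- fit_batch(Y, series$protocol, ...)

  blank <- array(NA_real_, dim = dims)
  maps <- list(s0 = blank, t2star = blank, adc = blank, residual = blank,
               valid = array(FALSE, dim = dims))
  maps$s0[idx] <- fit$s0
  maps$t2star[idx] <- fit$t2star
  maps$adc[idx] <- fit$adc
  maps$residual[idx] <- fit$residual
  maps$valid[idx] <- fit$valid

  ok <- fit$valid
  n_excluded <- sum(!ok)
  if (n_excluded > length(ok) / 2) {
    warning(sprintf("%d of %d ROI voxels failed to fit", n_excluded,
                    length(ok)))
  }
  summary <- list(
    n_voxels = length(ok),
    n_excluded = n_excluded,
    volume_mm3 = roi_volume(mask),
    mean_t2star_ms = mean(fit$t2star[ok]) * 1000,
    median_t2star_ms = median(fit$t2star[ok]) * 1000,
    mean_adc = mean(fit$adc[ok]),
    median_adc = median(fit$adc[ok])
  )
  list(maps = maps, summary = summary, fit = fit)
}
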