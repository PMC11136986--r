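# Unsupervised diffusion-relaxation decomposition.
#
# The signal in every ROI voxel, normalised by its reference-volume value,
# is modelled as a simplex-weighted mixture of M canonical non-negative
# T2*-ADC spectra shared across scans:
#
#   y_v / s0_v  ~=  K F w_v,   F >= 0 (columns sum to 1),  w_v on the simplex
#
# with K the kernel dictionary over the spectral grid. Learning alternates
# an exact per-voxel simplex-constrained least-squares step for the weights
# with an exact block-coordinate simplex-QP step per spectrum under a
# spatial smoothness penalty on the spectral plane. Projecting new scans
# onto fixed spectra reuses only the weight step.

#' Construct a component set
#'
#' @param amplitudes Matrix (grid points x M) of non-negative spectral
#'   amplitudes; each column is normalised to sum to 1.
#' @param grid The `spectral_grid` the rows refer to (T2* axis fastest).
#' @param protocol Optional training protocol, stored for compatibility
#'   checks when projecting new scans.
#' @param reorder Apply the canonical component ordering (default `TRUE`).
#' @return Object of class `component_set`: `amplitudes`, `grid`,
#'   `order_key` (amplitude-weighted mean log T2* per component), `protocol`.
#' @export
component_set <- function(amplitudes, grid, protocol = NULL, reorder = TRUE) {
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != n_grid_points(grid)) {
    stop("amplitude rows must match the number of grid points", call. = FALSE)
  }
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  sums <- colSums(amplitudes)
  if (any(sums <= 0)) stop("every component needs positive amplitude", call. = FALSE)
  amplitudes <- sweep(amplitudes, 2, sums, `/`)
  pts <- grid_points(grid)
  key1 <- as.numeric(crossprod(amplitudes, log(pts[, "t2star"])))
  key2 <- as.numeric(crossprod(amplitudes, log(pts[, "adc"])))
  if (reorder) {
    ord <- order(key1, key2)
    amplitudes <- amplitudes[, ord, drop = FALSE]
    key1 <- key1[ord]
    key2 <- key2[ord]
  }
  structure(list(amplitudes = amplitudes, grid = grid,
                 order_key = key1, order_key_adc = key2,
                 protocol = protocol),
            class = "component_set")
}

#' Number of components in a set
#' @param components A `component_set`.
#' @return Integer M.
#' @export
n_components <- function(components) ncol(components$amplitudes)

#' Build a component set from parametric peaks
#'
#' Each peak is snapped to the nearest grid point in log space; amplitudes
#' accumulate on the grid and are normalised per component. Used to place
#' phantom ground-truth spectra on the same grid the decomposition searches.
#'
#' @param peaks List of data frames with columns `t2star`, `adc`,
#'   `amplitude`.
#' @param grid A `spectral_grid`.
#' @return A `component_set` in canonical order.
#' @export
component_set_from_peaks <- function(peaks, grid) {
  nt <- length(grid$t2star)
  na_ <- length(grid$adc)
  F <- matrix(0, nt * na_, length(peaks))
  for (m in seq_along(peaks)) {
    pk <- peaks[[m]]
    for (i in seq_len(nrow(pk))) {
      it <- which.min(abs(log(grid$t2star) - log(pk$t2star[i])))
      ia <- which.min(abs(log(grid$adc) - log(pk$adc[i])))
      j <- it + (ia - 1) * nt
      F[j, m] <- F[j, m] + pk$amplitude[i]
    }
  }
  component_set(F, grid)
}

#' Component signal signatures under a protocol
#'
#' The dictionary column for component m is K f_m: the noise-free normalised
#' signal of a voxel containing only that component.
#'
#' @param components A `component_set`.
#' @param protocol An [acquisition_protocol()].
#' @return Matrix, measurements x components.
#' @export
component_signatures <- function(components, protocol) {
  kernel_matrix(protocol, components$grid) %*% components$amplitudes
}

protocols_equal <- function(p1, p2) {
  nrow(p1) == nrow(p2) &&
    max(abs(p1$echo_time - p2$echo_time)) < 1e-9 &&
    max(abs(p1$b_value - p2$b_value)) < 1e-9
}

#' Construct per-scan weight maps
#'
#' @param weights ROI voxels x M matrix; rows on the simplex.
#' @param mask A [roi_mask()]; rows of `weights` correspond to
#'   `which(mask$data)` restricted to `roi_index`.
#' @param roi_index Linear voxel indices the weight rows refer to.
#' @param scan_id Character identifier.
#' @param components The `component_set` the weights refer to.
#' @return Object of class `weight_maps`.
#' @export
weight_maps <- function(weights, mask, roi_index, scan_id = "scan",
                        components = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != length(roi_index)) {
    stop("weights rows must match roi_index", call. = FALSE)
  }
  if (any(weights < -1e-9)) stop("weights must be non-negative", call. = FALSE)
  structure(list(weights = weights, mask = mask, roi_index = roi_index,
                 scan_id = scan_id, components = components),
            class = "weight_maps")
}

#' Mean ROI component weighting
#'
#' Unweighted mean over ROI voxels of each component's weight — the
#' per-scan summary fed into the cohort statistics. Sums to 1.
#'
#' @param maps A [weight_maps()].
#' @return Numeric vector of M fractions.
#' @export
mean_roi_weighting <- function(maps) {
  if (nrow(maps$weights) == 0) stop("empty ROI", call. = FALSE)
  colMeans(maps$weights)
}

# Normalised per-voxel data for one scan: divide each voxel by its measured
# reference-volume value (first b = 0 at the shortest echo time), so the
# normalised signal is exactly 1 at the reference — consistent with the
# mixture model, whose dictionary row there is identically 1. Voxels with a
# non-positive or non-finite reference value are dropped.
normalized_roi_signal <- function(series, mask, noise_sigma = NULL) {
  check_mask_matches(series, mask)
  dims <- dim(series$data)[1:3]
  idx <- which(mask$data)
  Y <- t(matrix(series$data, nrow = prod(dims))[idx, , drop = FALSE])
  if (!is.null(noise_sigma)) {
    if (identical(noise_sigma, "auto")) {
      noise_sigma <- estimate_noise_sigma(series, mask)
    }
    Y <- rician_floor_correct(Y, noise_sigma)
  }
  s0 <- Y[reference_index(series$protocol), ]
  ok <- is.finite(s0) & s0 > 0 & colSums(!is.finite(Y)) == 0
  list(Y = sweep(Y[, ok, drop = FALSE], 2, s0[ok], `/`),
       roi_index = idx[ok], n_dropped = sum(!ok), s0 = s0[ok])
}

# Degree vector of the 4-neighbour spectral-plane graph.
laplacian_degree <- function(nt, na_) {
  deg <- matrix(4, nt, na_)
  deg[1, ] <- deg[1, ] - 1; deg[nt, ] <- deg[nt, ] - 1
  deg[, 1] <- deg[, 1] - 1; deg[, na_] <- deg[, na_] - 1
  as.numeric(deg)
}

# Dense Laplacian submatrix on a small support set S.
laplacian_sub <- function(S, nt, na_, deg) {
  k <- length(S)
  ti <- (S - 1L) %% nt + 1L
  ai <- (S - 1L) %/% nt + 1L
  M <- matrix(0, k, k)
  diag(M) <- deg[S]
  if (k > 1) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      nb <- (ai[a] == ai[b] && abs(ti[a] - ti[b]) == 1L) ||
        (ti[a] == ti[b] && abs(ai[a] - ai[b]) == 1L)
      if (nb) M[a, b] <- M[b, a] <- -1
    }
  }
  M
}

# Exact simplex-constrained QP for one spectral column:
#   min_f  alpha * ||K f||^2 / 2-form  ... concretely
#   min_f  1/2 f' Q f - c' f   s.t. f >= 0, sum(f) = 1,
# with Q = alpha K'K + lambda L applied implicitly (L = spectral-plane
# Laplacian). Primal active-set (Lawson-Hanson structure); the support of
# the solution stays small, so every KKT solve is a small dense system.
simplex_qp_spectrum <- function(K, nt, na_, alpha, lambda, cvec,
                                deg, diagQ, max_iter = 500, warm = NULL) {
  n <- ncol(K)
  tol <- 1e-10 * (1 + max(abs(cvec)))
  if (!is.null(warm) && length(warm$S) > 0 && length(warm$S) < 200) {
    S <- warm$S
    w <- warm$w
    s <- sum(w)
    w <- if (s > 0) w / s else rep(1 / length(w), length(w))
  } else {
    S <- which.max(2 * cvec - diagQ)
    w <- 1
  }
  f_full <- numeric(n)
  f_full[S] <- w
  for (it in seq_len(max_iter)) {
    QSS <- alpha * crossprod(K[, S, drop = FALSE]) +
      lambda * laplacian_sub(S, nt, na_, deg)
    k <- length(S)
    KKT <- rbind(cbind(QSS + diag(1e-12 * (1 + mean(diag(QSS))), k), 1),
                 c(rep(1, k), 0))
    sol <- tryCatch(solve(KKT, c(cvec[S], 1)), error = function(e) NULL)
    if (is.null(sol)) break
    z <- sol[seq_len(k)]
    nu <- sol[k + 1]
    if (min(z) > -tol) {
      w <- z
      f_full[] <- 0
      f_full[S] <- pmax(w, 0)
      Qf <- alpha * as.numeric(crossprod(K, K[, S, drop = FALSE] %*% w)) +
        lambda * as.numeric(laplacian_apply(matrix(f_full), nt, na_))
      mu <- Qf - cvec + nu
      mu[S] <- 0
      j <- which.min(mu)
      if (mu[j] >= -tol) break
      S <- c(S, j)
      w <- c(w, 0)
    } else {
      shrink <- which(z <= tol)
      a <- 1
      drop_i <- integer(0)
      for (i in shrink) {
        den <- w[i] - z[i]
        if (den > 0) {
          ai_step <- w[i] / den
          if (ai_step < a) { a <- ai_step; drop_i <- i }
        }
      }
      w <- w + a * (z - w)
      if (length(drop_i) > 0) {
        keep <- setdiff(seq_along(S), drop_i)
        S <- S[keep]
        w <- w[keep]
      }
      if (length(S) == 0) {
        S <- which.max(2 * cvec - diagQ)
        w <- 1
      }
    }
  }
  f_full[] <- 0
  f_full[S] <- pmax(w, 0)
  s <- sum(f_full)
  f_full <- if (s > 0) f_full / s else f_full
  attr(f_full, "support") <- list(S = S, w = pmax(w, 0) / max(s, 1e-300))
  f_full
}

# Apply the 4-neighbour graph Laplacian of the spectral plane to each
# column of F (gradient of the smoothness penalty is 2*lambda*L*F).
laplacian_apply <- function(F, nt, na_) {
  out <- matrix(0, nrow(F), ncol(F))
  for (m in seq_len(ncol(F))) {
    f <- matrix(F[, m], nt, na_)
    deg <- matrix(4, nt, na_)
    deg[1, ] <- deg[1, ] - 1; deg[nt, ] <- deg[nt, ] - 1
    deg[, 1] <- deg[, 1] - 1; deg[, na_] <- deg[, na_] - 1
    nb <- matrix(0, nt, na_)
    nb[-1, ] <- nb[-1, ] + f[-nt, ]
    nb[-nt, ] <- nb[-nt, ] + f[-1, ]
    nb[, -1] <- nb[, -1] + f[, -na_]
    nb[, -na_] <- nb[, -na_] + f[, -1]
    out[, m] <- as.numeric(deg * f - nb)
  }
  out
}

smoothness_penalty <- function(F, nt, na_) {
  sum(F * laplacian_apply(F, nt, na_))
}

# Initial spectra: ridge-regularised non-negative per-voxel spectra
# (multiplicative updates) on a deterministic voxel subsample, clustered by
# k-means; cluster centroids become the initial components.
init_spectra <- function(K, Y, m, seed, n_sub = 1500, n_mult = 60) {
  set.seed(child_seed(seed, 3L))
  V <- ncol(Y)
  idx <- if (V > n_sub) sort(sample.int(V, n_sub)) else seq_len(V)
  Ys <- Y[, idx, drop = FALSE]
  KtK <- crossprod(K)
  KtY <- crossprod(K, Ys)
  ridge <- 1e-3
  X <- matrix(1 / nrow(KtK), nrow(KtK), ncol(Ys))
  for (i in seq_len(n_mult)) {
    X <- X * KtY / (KtK %*% X + ridge * X + 1e-12)
  }
  X <- sweep(X, 2, pmax(colSums(X), 1e-12), `/`)
  if (m == 1) {
    F0 <- matrix(rowMeans(X), ncol = 1)
  } else {
    km <- kmeans(t(X), centers = m, nstart = 5, iter.max = 50)
    F0 <- t(km$centers)
  }
  F0 <- pmax(F0, 0)
  sweep(F0, 2, pmax(colSums(F0), 1e-12), `/`)
}

#' Learn shared T2*-ADC component spectra and per-voxel weights
#'
#' The "full" decomposition: given one or more scans sharing a protocol,
#' learns M non-negative spectra over the spectral grid (columns summing to
#' one, smoothed by a spectral-plane penalty) together with per-voxel
#' simplex weights, by alternating an exact simplex-constrained
#' least-squares weight step with an exact per-component simplex-QP spectra
#' step (block-coordinate descent), so the penalised objective never
#' increases across iterations. Voxel signals are first normalised by their
#' reference-volume value (b = 0, shortest TE), making weights
#' interpretable as signal fractions. Components are returned in
#' canonical order (ascending amplitude-weighted mean log T2*, ties broken
#' by mean log ADC) so labels are reproducible across runs.
#'
#' @param scans A list of scans, each `list(series =, mask =)`, or a single
#'   such scan.
#' @param m_components Number of components M (default 7, the number
#'   previously found to best explain placental and adjacent uterine-wall
#'   T2*-diffusion signal).
#' @param grid Spectral grid (default [build_spectral_grid()]).
#' @param lambda Spectral smoothness penalty weight (default 1e-3).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param max_iter Maximum alternating iterations (default 500).
#' @param seed Seed for the deterministic k-means initialisation.
#' @param noise_sigma Optional Rician noise level for the magnitude
#'   noise-floor correction applied before decomposition: a number, or
#'   `"auto"` to estimate it from background voxels
#'   ([estimate_noise_sigma()]); `NULL` (default) disables the correction.
#' @return List of class `inspect_fit`: `components` (a `component_set`),
#'   `weight_maps` (per scan), `objective` (trace, recorded after each
#'   weight step), `converged`, `n_iter`, `dropped_voxels`.
#' @export
full_inspect <- function(scans, m_components = 7,
                         grid = build_spectral_grid(),
                         lambda = 1e-3, tol = 1e-6, max_iter = 500,
                         seed = 1, noise_sigma = NULL) {
  if (!is.null(scans$series)) scans <- list(scans)
  if (length(scans) < 1) stop("at least one scan required", call. = FALSE)
  if (m_components < 1) stop("m_components must be >= 1", call. = FALSE)
  protocol <- scans[[1]]$series$protocol
  for (s in scans) {
    if (!protocols_equal(s$series$protocol, protocol)) {
      stop("all scans must share one protocol", call. = FALSE)
    }
  }
  norm <- lapply(scans, function(s) {
    normalized_roi_signal(s$series, s$mask, noise_sigma)
  })
  Y <- do.call(cbind, lapply(norm, `[[`, "Y"))
  scan_of <- rep(seq_along(norm), vapply(norm, function(x) ncol(x$Y), 0L))
  if (m_components > ncol(Y)) {
    stop("m_components exceeds the number of usable ROI voxels", call. = FALSE)
  }

  K <- kernel_matrix(protocol, grid)
  nt <- length(grid$t2star)
  na_ <- length(grid$adc)
  F <- init_spectra(K, Y, m_components, seed)

  data_term <- function(A, W) {
    R <- Y - A %*% t(W)
    sum(R * R)
  }
  objective <- function(F, A, W) {
    data_term(A, W) + lambda * smoothness_penalty(F, nt, na_)
  }

  obj_trace <- numeric(0)
  converged <- FALSE
  W <- NULL
  deg <- laplacian_degree(nt, na_)
  K2 <- colSums(K * K)
  supports <- vector("list", m_components)
  for (it in seq_len(max_iter)) {
    A <- K %*% F
    W <- t(.simplex_lsq_batch(A, Y))
    obj <- objective(F, A, W)
    obj_trace <- c(obj_trace, obj)
    if (it > 1) {
      rel <- (obj_prev - obj) / max(obj_prev, 1e-300)
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
    obj_prev <- obj

    # spectra update: exact block-coordinate minimisation, one component at
    # a time, each an exact simplex-constrained QP — never increases the
    # objective
    R <- Y - A %*% t(W)
    for (m in seq_len(m_components)) {
      wm <- W[, m]
      alpha_m <- sum(wm * wm)
      if (alpha_m < 1e-12) next
      rm_wm <- as.numeric(R %*% wm) + A[, m] * alpha_m
      cvec <- as.numeric(crossprod(K, rm_wm))
      f_new <- simplex_qp_spectrum(K, nt, na_, alpha_m, lambda, cvec, deg,
                                   alpha_m * K2 + lambda * deg,
                                   warm = supports[[m]])
      supports[[m]] <- attr(f_new, "support")
      attr(f_new, "support") <- NULL
      sig_delta <- K %*% (F[, m] - f_new)
      R <- R + sig_delta %*% t(wm)
      F[, m] <- f_new
      A[, m] <- A[, m] - sig_delta
    }
  }
  # final weight step against the final spectra, so the returned maps are
  # exactly the fixed-point projection of the returned components
  W <- t(.simplex_lsq_batch(K %*% F, Y))

  cs <- component_set(F, grid, protocol = protocol, reorder = FALSE)
  ord <- order(cs$order_key, cs$order_key_adc)
  cs <- component_set(F[, ord, drop = FALSE], grid, protocol = protocol,
                      reorder = FALSE)
  W <- W[, ord, drop = FALSE]

  maps <- lapply(seq_along(scans), function(i) {
    rows <- scan_of == i
    weight_maps(W[rows, , drop = FALSE], scans[[i]]$mask,
                norm[[i]]$roi_index, scans[[i]]$series$scan_id, cs)
  })
  list(components = cs, weight_maps = maps, objective = obj_trace,
       converged = converged, n_iter = length(obj_trace),
       dropped_voxels = vapply(norm, `[[`, 0L, "n_dropped")) |>
    structure(class = "inspect_fit")
}

#' Project a scan onto fixed component spectra
#'
#' The "reduced" decomposition: keeps the learned T2*-ADC spectra fixed and
#' computes only the per-voxel simplex weights of a new scan against the
#' fixed component signatures. Guarantees identical component definitions
#' across all scans analysed.
#'
#' @param scan A `list(series =, mask =)` pair.
#' @param components A `component_set` (typically from [full_inspect()]).
#' @param noise_sigma Optional Rician noise-floor correction as in
#'   [full_inspect()]; use the same setting as at training.
#' @return A [weight_maps()] object.
#' @export
reduced_inspect <- function(scan, components, noise_sigma = NULL) {
  protocol <- scan$series$protocol
  if (!is.null(components$protocol) &&
      !protocols_equal(protocol, components$protocol)) {
    stop("scan protocol does not match the components' training protocol",
         call. = FALSE)
  }
  norm <- normalized_roi_signal(scan$series, scan$mask, noise_sigma)
  A <- component_signatures(components, protocol)
  W <- t(.simplex_lsq_batch(A, norm$Y))
  weight_maps(W, scan$mask, norm$roi_index, scan$series$scan_id, components)
}

#' Locate spectral peaks of a component
#'
#' Grid-local maxima of the component's amplitude over the 8-neighbourhood
#' of the T2*-ADC plane, above an amplitude floor, annotated with the
#' interpretation flags used to read components: `low_t2star` (< 0.06 s),
#' `high_t2star` (> 0.09 s) and `vascular_adc` (above the free-water line,
#' 0.3 mm^2/s, i.e. perfusing blood).
#'
#' @param spectrum Amplitude vector over grid points, or one column of a
#'   `component_set`.
#' @param grid The `spectral_grid`.
#' @param min_amplitude Ignore maxima at or below this amplitude fraction.
#' @return `data.frame` with columns `t2star`, `adc`, `amplitude`,
#'   `low_t2star`, `high_t2star`, `vascular_adc`, sorted by descending
#'   amplitude.
#' @export
find_peaks <- function(spectrum, grid, min_amplitude = 0) {
  nt <- length(grid$t2star)
  na_ <- length(grid$adc)
  f <- matrix(spectrum, nt, na_)
  is_peak <- matrix(TRUE, nt, na_)
  for (dt in -1:1) for (da in -1:1) {
    if (dt == 0 && da == 0) next
    nb <- matrix(-Inf, nt, na_)
    src_t <- seq_len(nt) + dt
    src_a <- seq_len(na_) + da
    ok_t <- src_t >= 1 & src_t <= nt
    ok_a <- src_a >= 1 & src_a <= na_
    nb[ok_t, ok_a] <- f[src_t[ok_t], src_a[ok_a]]
    is_peak <- is_peak & (f >= nb)
  }
  is_peak <- is_peak & f > min_amplitude
  idx <- which(is_peak, arr.ind = TRUE)
  out <- data.frame(
    t2star = grid$t2star[idx[, 1]],
    adc = grid$adc[idx[, 2]],
    amplitude = f[idx]
  )
  out$low_t2star <- out$t2star < 0.06
  out$high_t2star <- out$t2star > 0.09
  out$vascular_adc <- out$adc > 0.3
  out[order(-out$amplitude), , drop = FALSE]
}

#' Export per-component weight volumes
#'
#' Converts weight maps to one 3-D volume per component (values in [0, 1],
#' zero outside the ROI) and optionally writes them as NIfTI files.
#'
#' @param maps A [weight_maps()].
#' @param path_prefix If non-`NULL`, write `<prefix>_component<m>.nii.gz`
#'   per component.
#' @return Named list of 3-D arrays, invisibly if written to disk.
#' @export
export_component_maps <- function(maps, path_prefix = NULL) {
  dims <- dim(maps$mask$data)
  m <- ncol(maps$weights)
  vols <- lapply(seq_len(m), function(c) {
    v <- array(0, dim = dims)
    v[maps$roi_index] <- pmin(pmax(maps$weights[, c], 0), 1)
    v
  })
  names(vols) <- sprintf("component%d", seq_len(m))
  if (!is.null(path_prefix)) {
    for (c in seq_len(m)) {
      img <- RNifti::asNifti(vols[[c]])
      RNifti::pixdim(img) <- maps$mask$voxel_size
      RNifti::writeNifti(img, sprintf("%s_component%d.nii.gz", path_prefix, c))
    }
    return(invisible(vols))
  }
  vols
}

#' Serialize a component set to a plain-text file
#'
#' Stores the grid axes and the M amplitude vectors as a readable
#' tab-separated table with a small header.
#'
#' @param components A `component_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_component_set <- function(components, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# plaspect component set"),
    sprintf("# n_t2star\t%d", length(components$grid$t2star)),
    sprintf("# n_adc\t%d", length(components$grid$adc)),
    sprintf("# t2star\t%s", paste(format(components$grid$t2star, digits = 17),
                                  collapse = "\t")),
    sprintf("# adc\t%s", paste(format(components$grid$adc, digits = 17),
                               collapse = "\t"))
  ), con)
  write.table(components$amplitudes, con, sep = "\t", row.names = FALSE,
              col.names = sprintf("component%d", seq_len(n_components(components))))
  invisible(path)
}

#' Read a component set written by [write_component_set()]
#' @param path File path.
#' @return A `component_set`.
#' @export
read_component_set <- function(path) {
  lines <- readLines(path, n = 5)
  parse_axis <- function(line) as.numeric(strsplit(line, "\t")[[1]][-1])
  t2 <- parse_axis(lines[4])
  adc <- parse_axis(lines[5])
  grid <- list(t2star = t2, adc = adc)
  class(grid) <- "spectral_grid"
  amp <- as.matrix(read.table(path, sep = "\t", header = TRUE, skip = 5))
  component_set(amp, grid, reorder = FALSE)
}
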