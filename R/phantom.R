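# Digital placental phantoms: a lobulated ellipsoidal slab plus adjacent
# uterine-wall layer, populated with multi-component T2*-ADC mixtures and
# imaged through the forward signal model.

#' Default seven-component spectral peak list
#'
#' Parametric (T2*, ADC, amplitude) peaks for the seven tissue components
#' the phantom emulates, spanning the placental regime: component 1 has low
#' T2* (< 0.06 s) and low ADC (poorly oxygenated, low diffusivity, lobule
#' periphery); component 3 includes a high-ADC (> 0.1 mm^2/s) peak
#' (septa/uterine-wall vasculature); component 7 has multiple high-T2*
#' (> 0.09 s) peaks including one above the free-water line at 0.3 mm^2/s
#' (well-oxygenated inflow at lobule centres). Amplitude-weighted mean log
#' T2* increases with component index, so the canonical component ordering
#' reproduces the 1-7 labels.
#'
#' @return List of 7 data frames with columns `t2star`, `adc`, `amplitude`.
#' @export
default_component_peaks <- function() {
  list(
    data.frame(t2star = c(0.020, 0.031), adc = c(3e-4, 8e-4),
               amplitude = c(0.5, 0.5)),
    data.frame(t2star = 0.037, adc = 8e-3, amplitude = 1),
    data.frame(t2star = c(0.042, 0.072), adc = c(2.5e-2, 0.18),
               amplitude = c(0.35, 0.65)),
    data.frame(t2star = 0.072, adc = 1.5e-3, amplitude = 1),
    data.frame(t2star = 0.088, adc = 0.06, amplitude = 1),
    data.frame(t2star = 0.108, adc = 4e-3, amplitude = 1),
    data.frame(t2star = c(0.115, 0.135, 0.160), adc = c(1.5e-2, 0.5, 2e-3),
               amplitude = c(0.4, 0.3, 0.3))
  )
}

default_spatial_patterns <- function(m) {
  if (m == 7) {
    # each component dominates somewhere: rims, wall/septa, lobule centres,
    # or its own subset of lobule bodies — the spatial contrast structure of
    # real component maps
    return(c("lobule_periphery", "lobule_dominant", "septa_uterine_wall",
             "lobule_dominant", "lobule_dominant", "lobule_dominant",
             "lobule_center"))
  }
  pat <- rep("lobule_dominant", m)
  if (m >= 2) pat[1] <- "lobule_periphery"
  if (m >= 3) pat[3] <- "septa_uterine_wall"
  pat
}

#' Specify a digital placental phantom
#'
#' @param grid_shape Integer vector (3): voxel grid dimensions.
#' @param voxel_size Voxel edge length, mm (scalar or length 3).
#' @param n_lobules Number of placental lobules (Voronoi cells), >= 1.
#' @param components List of per-component peak tables (columns `t2star`,
#'   `adc`, `amplitude`); amplitudes are normalised to sum to 1.
#' @param spatial_pattern Character vector, one of `"uniform"`,
#'   `"lobule_center"`, `"lobule_periphery"`, `"septa_uterine_wall"`,
#'   `"lobule_partition"` per component. `"lobule_partition"` assigns whole
#'   lobules to one component (spatially disjoint one-hot weights, for
#'   identifiability testing).
#' @param target_means Desired ROI-mean weighting per component (simplex);
#'   default equal.
#' @param grid A `spectral_grid` on which component spectra are snapped.
#' @param s0_mean Reference-volume signal level inside the ROI.
#' @param snr Signal-to-noise ratio at the reference volume; `Inf` disables
#'   noise. Noise sigma is `s0_mean / snr` per channel (Rician).
#' @param slab_scale Relative placental volume scale (1 = default size);
#'   used by the cohort simulator to grow the slab with gestation.
#' @param lobule_sd,voxel_sd Log-normal heterogeneity of component fields at
#'   lobule and voxel scale (geometric s.d. of multiplicative texture).
#'   Emulates the between-lobule and within-lobule contrast of real
#'   component maps; 0 disables. Ignored by `"lobule_partition"` patterns.
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 16), voxel_size = 3,
                         n_lobules = 8,
                         components = default_component_peaks(),
                         spatial_pattern = NULL,
                         target_means = NULL,
                         grid = build_spectral_grid(),
                         s0_mean = 100, snr = 50, slab_scale = 1,
                         lobule_sd = 0.4, voxel_sd = 0.3, seed = 1) {
  if (length(grid_shape) != 3 || any(grid_shape < 4)) {
    stop("grid_shape must be 3 dimensions, each >= 4", call. = FALSE)
  }
  if (n_lobules < 1) stop("n_lobules must be >= 1", call. = FALSE)
  if (!is.finite(snr) && !is.infinite(snr)) stop("snr must be > 0", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  m <- length(components)
  if (m < 1) stop("at least one component required", call. = FALSE)
  components <- lapply(components, function(pk) {
    if (any(pk$amplitude < 0) || sum(pk$amplitude) <= 0) {
      stop("peak amplitudes must be non-negative with positive sum",
           call. = FALSE)
    }
    pk$amplitude <- pk$amplitude / sum(pk$amplitude)
    pk
  })
  if (is.null(spatial_pattern)) spatial_pattern <- default_spatial_patterns(m)
  if (length(spatial_pattern) != m) {
    stop("spatial_pattern must name one pattern per component", call. = FALSE)
  }
  ok <- c("uniform", "lobule_center", "lobule_periphery",
          "septa_uterine_wall", "lobule_dominant", "lobule_partition")
  if (!all(spatial_pattern %in% ok)) {
    stop("unknown spatial_pattern; valid: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(target_means)) target_means <- rep(1 / m, m)
  if (length(target_means) != m || any(target_means <= 0)) {
    stop("target_means must be positive, one per component", call. = FALSE)
  }
  target_means <- target_means / sum(target_means)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, n_lobules = as.integer(n_lobules),
                 components = components, spatial_pattern = spatial_pattern,
                 target_means = target_means, grid = grid, s0_mean = s0_mean,
                 snr = snr, slab_scale = slab_scale,
                 lobule_sd = lobule_sd, voxel_sd = voxel_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Geometry: placental slab = ellipsoid; uterine wall = one-sided shell below
# it; lobules = Voronoi cells of points seeded inside the slab.
phantom_geometry <- function(spec) {
  set.seed(child_seed(spec$seed, 1L))
  dims <- spec$grid_shape
  centre <- (dims + 1) / 2
  semi <- c(0.40 * dims[1], 0.40 * dims[2], 0.28 * dims[3]) *
    spec$slab_scale^(1 / 3)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                  z = seq_len(dims[3]),
                                  KEEP.OUT.ATTRS = FALSE))
  r2 <- ((coords[, 1] - centre[1]) / semi[1])^2 +
    ((coords[, 2] - centre[2]) / semi[2])^2 +
    ((coords[, 3] - centre[3]) / semi[3])^2
  placenta <- r2 <= 1
  wall <- r2 > 1 & r2 <= 1.45 & coords[, 3] <= centre[3]
  roi <- placenta | wall
  if (sum(placenta) < spec$n_lobules) {
    stop("grid too small to host ", spec$n_lobules, " lobules", call. = FALSE)
  }
  seeds_idx <- sample(which(placenta), spec$n_lobules)
  seeds <- coords[seeds_idx, , drop = FALSE]
  # nearest-seed (Voronoi) labels for every ROI voxel
  roi_idx <- which(roi)
  d2 <- matrix(0, length(roi_idx), spec$n_lobules)
  for (l in seq_len(spec$n_lobules)) {
    d2[, l] <- (coords[roi_idx, 1] - seeds[l, 1])^2 +
      (coords[roi_idx, 2] - seeds[l, 2])^2 +
      (coords[roi_idx, 3] - seeds[l, 3])^2
  }
  lobule <- integer(prod(dims))
  lobule[roi_idx] <- max.col(-d2, ties.method = "first")

  # periphery: placenta voxel with a 6-neighbour in another lobule or
  # outside the slab (within 1 voxel of a cell boundary)
  lob_arr <- array(lobule * placenta, dim = dims)
  shift <- function(a, d, k) {
    out <- array(0L, dim = dims)
    src <- dst <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    n <- dims[d]
    if (k == 1) { src[[d]] <- 1:(n - 1); dst[[d]] <- 2:n }
    else { src[[d]] <- 2:n; dst[[d]] <- 1:(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  periph <- array(FALSE, dim = dims)
  for (d in 1:3) for (k in 1:2) {
    nb <- shift(lob_arr, d, k)
    periph <- periph | (lob_arr > 0 & nb != lob_arr)
  }
  list(dims = dims, coords = coords, placenta = array(placenta, dims),
       wall = array(wall, dims), roi = array(roi, dims),
       lobule = array(lobule, dims), periphery = periph, seeds = seeds,
       semi = semi, centre = centre)
}

# Raw (unnormalised) spatial weight field for one component.
pattern_field <- function(pattern, geom, comp_index, m, spec) {
  roi_idx <- which(geom$roi)
  pl <- geom$placenta[roi_idx]
  wl <- geom$wall[roi_idx]
  pe <- geom$periphery[roi_idx]
  lob <- geom$lobule[roi_idx]
  f <- numeric(length(roi_idx))
  if (pattern == "uniform") {
    f[] <- 1
  } else if (pattern == "lobule_periphery") {
    f[pl] <- ifelse(pe[pl], 2.5, 0.1)
  } else if (pattern == "septa_uterine_wall") {
    f[wl] <- 2.5
    f[pl] <- ifelse(pe[pl], 1.2, 0.05)
  } else if (pattern == "lobule_center") {
    r0 <- 0.6 * (prod(geom$semi) / spec$n_lobules)^(1 / 3)
    co <- geom$coords[roi_idx, , drop = FALSE]
    sd2 <- (co[, 1] - geom$seeds[lob, 1])^2 +
      (co[, 2] - geom$seeds[lob, 2])^2 +
      (co[, 3] - geom$seeds[lob, 3])^2
    f[pl] <- 0.05 + 3 * exp(-sd2[pl] / (2 * r0^2))
  } else if (pattern == "lobule_dominant") {
    # this component dominates its own subset of lobule bodies
    dom <- which(spec$spatial_pattern == "lobule_dominant")
    k <- match(comp_index, dom)
    nd <- length(dom)
    mine <- ((lob - 1) %% nd) + 1 == k
    f[pl] <- ifelse(mine[pl] & !pe[pl], 2.5, 0.15)
  } else if (pattern == "lobule_partition") {
    f[((lob - 1) %% m) + 1 == comp_index] <- 1
  }
  f
}

#' Generate ground-truth weight maps and ROI mask for a phantom
#'
#' Builds the lobulated geometry and per-component weight fields following
#' each component's spatial pattern, then normalises to a per-voxel simplex.
#' Unless every pattern is `"lobule_partition"`, a small floor keeps all
#' components present everywhere in the ROI (so ROI-mean targets are
#' reachable by rescaling) and fields are scaled so ROI means equal the
#' spec's `target_means`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `weights` (ROI voxels x M matrix, rows on the simplex),
#'   `mask` (a [roi_mask()]), `roi_index` (linear voxel indices of the mask,
#'   matching the weight rows), and `geometry`.
#' @export
make_weight_maps <- function(spec) {
  geom <- phantom_geometry(spec)
  m <- length(spec$components)
  roi_idx <- which(geom$roi)
  W <- vapply(seq_len(m), function(c) {
    pattern_field(spec$spatial_pattern[c], geom, c, m, spec)
  }, numeric(length(roi_idx)))
  W <- matrix(W, ncol = m)
  partition_only <- all(spec$spatial_pattern == "lobule_partition")
  if (!partition_only) {
    W <- W + 0.02
    # lobule- and voxel-scale log-normal texture: distinct spatial
    # signatures per component (between/within-lobule contrast)
    set.seed(child_seed(spec$seed, 5L))
    lob <- geom$lobule[roi_idx]
    for (c in seq_len(m)) {
      if (spec$spatial_pattern[c] == "lobule_partition") next
      if (spec$lobule_sd > 0) {
        lmult <- exp(rnorm(spec$n_lobules + 1, sd = spec$lobule_sd))
        W[, c] <- W[, c] * lmult[lob + 1]
      }
      if (spec$voxel_sd > 0) {
        W[, c] <- W[, c] * exp(rnorm(length(roi_idx), sd = spec$voxel_sd))
      }
    }
    W <- sweep(W, 2, colMeans(W), `/`)
    W <- sweep(W, 2, spec$target_means, `*`)
  }
  W <- W / rowSums(W)
  if (!partition_only) {
    W <- rescale_to_target_means(W, spec$target_means)
  }
  mask <- roi_mask(array(as.integer(geom$roi), dim = geom$dims),
                   spec$voxel_size)
  list(weights = W, mask = mask, roi_index = roi_idx, geometry = geom)
}

#' Rescale simplex weights so their column means match a target
#'
#' Multiplicative raking: scales components and renormalises rows until the
#' ROI-mean weighting vector matches `target`. Requires strictly positive
#' weights to converge for arbitrary targets.
#'
#' @param W Voxels x M weight matrix (rows on the simplex).
#' @param target Simplex vector of desired column means.
#' @param tol Convergence tolerance on the largest mean deviation.
#' @param max_iter Iteration cap.
#' @return Rescaled weight matrix.
#' @export
rescale_to_target_means <- function(W, target, tol = 1e-12, max_iter = 1000) {
  target <- target / sum(target)
  for (i in seq_len(max_iter)) {
    mu <- colMeans(W)
    if (max(abs(mu - target)) < tol) break
    W <- sweep(W, 2, target / pmax(mu, 1e-300), `*`)
    W <- W / rowSums(W)
  }
  W
}

#' Synthesize a combined T2*-diffusion scan from a phantom
#'
#' Forward-models every ROI voxel as the weighted sum of its component
#' signatures (component spectra snapped to the spectral grid, attenuated
#' through the kernel dictionary), scales by `s0_mean`, and applies Rician
#' noise of sigma = `s0_mean / snr`. Background voxels contain noise only.
#'
#' @param spec A [phantom_spec()].
#' @param protocol An [acquisition_protocol()].
#' @return List: `series` (a [volume_series()]), `mask`, and `truth`
#'   (weights, roi_index, component set, signatures, s0, sigma).
#' @export
synthesize_scan <- function(spec, protocol) {
  maps <- make_weight_maps(spec)
  cs <- component_set_from_peaks(spec$components, spec$grid)
  K <- kernel_matrix(protocol, spec$grid)
  A <- K %*% cs$amplitudes            # n_meas x M component signatures
  S <- spec$s0_mean * (A %*% t(maps$weights))  # n_meas x V_roi
  dims <- spec$grid_shape
  data <- array(0, dim = c(dims, n_measurements(protocol)))
  n_vox <- prod(dims)
  flat <- matrix(data, nrow = n_vox)
  flat[maps$roi_index, ] <- t(S)
  sigma <- if (is.infinite(spec$snr)) 0 else spec$s0_mean / spec$snr
  if (sigma > 0) {
    set.seed(child_seed(spec$seed, 2L))
    flat <- add_noise(flat, sigma)
  }
  series <- volume_series(array(flat, dim = c(dims, n_measurements(protocol))),
                          spec$voxel_size, protocol,
                          scan_id = sprintf("phantom_seed%d", spec$seed))
  list(series = series, mask = maps$mask,
       truth = list(weights = maps$weights, roi_index = maps$roi_index,
                    components = cs, signatures = A, s0 = spec$s0_mean,
                    sigma = sigma, geometry = maps$geometry))
}
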