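# Builds a minimal two-component scan directly from known signatures.
two_component_scan <- function(weights, protocol = small_protocol(),
                               grid = small_grid(), s0 = 100) {
  peaks <- list(data.frame(t2star = 0.030, adc = 0.001, amplitude = 1),
                data.frame(t2star = 0.100, adc = 0.300, amplitude = 1))
  cs <- component_set_from_peaks(peaks, grid)
  A <- component_signatures(cs, protocol)
  V <- nrow(weights)
  dims <- c(V, 1, 1)
  dat <- array(0, dim = c(dims, nrow(protocol)))
  flat <- matrix(dat, nrow = V)
  flat[seq_len(V), ] <- t(s0 * (A %*% t(weights)))
  mask <- roi_mask(array(1L, dim = dims), 3)
  list(series = volume_series(array(flat, dim = c(dims, nrow(protocol))),
                              3, protocol),
       mask = mask, components = cs, signatures = A)
}

test_that("pure and mixed voxels project to their exact weights", {
  W <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5), c(0.2, 0.8))
  sc <- two_component_scan(W)
  maps <- reduced_inspect(sc, sc$components)
  expect_equal(maps$weights, W, tolerance = 1e-6, ignore_attr = TRUE)
  expect_simplex_rows(maps$weights, tol = 1e-6)
})

test_that("reduced weights match an exhaustive fine-grid simplex search", {
  set.seed(14)
  W <- cbind(runif(6)); W <- cbind(W, 1 - W)
  sc <- two_component_scan(W)
  # add mild gaussian noise so the optimum is interior and nontrivial
  noisy <- sc
  noisy$series$data <- abs(sc$series$data +
                             array(rnorm(length(sc$series$data), sd = 1),
                                   dim = dim(sc$series$data)))
  maps <- reduced_inspect(noisy, sc$components)
  # oracle: enumerate w1 on a 1e-3 grid against the same normalised data
  norm <- plaspect:::normalized_roi_signal(noisy$series, noisy$mask)
  A <- sc$signatures
  w1_grid <- seq(0, 1, by = 1e-3)
  for (v in seq_len(ncol(norm$Y))) {
    y <- norm$Y[, v]
    costs <- vapply(w1_grid, function(w1) {
      r <- y - A %*% c(w1, 1 - w1); sum(r * r)
    }, numeric(1))
    w1_best <- w1_grid[which.min(costs)]
    expect_lt(abs(maps$weights[v, 1] - w1_best), 2e-3)
  }
})

test_that("single-component decomposition yields unit weights", {
  sc <- two_component_scan(rbind(c(1, 0), c(0.7, 0.3), c(0.4, 0.6)))
  fit <- full_inspect(sc, m_components = 1, grid = small_grid(),
                      max_iter = 30)
  expect_true(all(fit$weight_maps[[1]]$weights == 1))
  expect_equal(sum(fit$components$amplitudes), 1, tolerance = 1e-9)
})

test_that("disjoint noiseless phantom is recovered essentially exactly", {
  p <- small_protocol()
  g <- small_grid()
  spec <- tiny_disjoint_phantom(snr = Inf, grid = g)
  sc <- synthesize_scan(spec, p)
  fit <- full_inspect(list(list(series = sc$series, mask = sc$mask)),
                      m_components = 3, grid = g, seed = 2, max_iter = 200)
  expect_true(fit$converged)
  # spectra concentrate near the true single peaks
  tr <- sc$truth$components
  nt <- length(g$t2star)
  top_idx <- function(a) { j <- which.max(a)
    c((j - 1) %% nt + 1, (j - 1) %/% nt + 1) }
  for (m in 1:3) {
    ti <- top_idx(tr$amplitudes[, m])
    est <- fit$components$amplitudes[, m]
    # amplitude within the one-step neighbourhood of the true atom (the
    # coarse 20 x 20 fixture grid has ~60% ADC steps, so concentration is
    # necessarily looser than on the full-resolution grid)
    keep <- outer(seq_len(nt), seq_len(nt), function(i, j)
      abs(i - ti[1]) <= 1 & abs(j - ti[2]) <= 1)
    expect_gt(sum(est[as.logical(keep)]), 0.75)
  }
  expect_lt(sqrt(mean((sc$truth$weights - fit$weight_maps[[1]]$weights)^2)),
            0.02)
})

test_that("objective is non-increasing and iterates stay feasible", {
  p <- small_protocol()
  g <- small_grid()
  spec <- phantom_spec(grid_shape = c(10, 10, 5), n_lobules = 3,
                       components = three_peaks(),
                       grid = g, snr = 50, seed = 4)
  sc <- synthesize_scan(spec, p)
  fit <- full_inspect(list(list(series = sc$series, mask = sc$mask)),
                      m_components = 3, grid = g, seed = 1, max_iter = 40)
  tr <- fit$objective
  expect_true(all(diff(tr) <= 1e-9 * (abs(tr[-length(tr)]) + 1)))
  expect_simplex_rows(fit$weight_maps[[1]]$weights, tol = 1e-6)
  expect_equal(unname(colSums(fit$components$amplitudes)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("projecting a training scan reproduces its training maps", {
  p <- small_protocol()
  g <- small_grid()
  spec <- phantom_spec(grid_shape = c(10, 10, 5), n_lobules = 3,
                       components = three_peaks(), grid = g, snr = 50,
                       seed = 5)
  sc <- synthesize_scan(spec, p)
  scan <- list(series = sc$series, mask = sc$mask)
  fit <- full_inspect(list(scan), m_components = 3, grid = g, seed = 1,
                      max_iter = 60)
  maps2 <- reduced_inspect(scan, fit$components)
  expect_lt(max(abs(maps2$weights - fit$weight_maps[[1]]$weights)), 1e-6)
})

test_that("component labels are stable across initialisation seeds", {
  p <- small_protocol()
  g <- small_grid()
  spec <- tiny_disjoint_phantom(snr = Inf, grid = g)
  sc <- synthesize_scan(spec, p)
  scan <- list(list(series = sc$series, mask = sc$mask))
  f1 <- full_inspect(scan, m_components = 3, grid = g, seed = 2,
                     max_iter = 150)
  f2 <- full_inspect(scan, m_components = 3, grid = g, seed = 31,
                     max_iter = 150)
  for (m in 1:3) {
    expect_lt(sum(abs(f1$components$amplitudes[, m] -
                        f2$components$amplitudes[, m])), 1e-3)
  }
})

test_that("mean ROI weighting averages the simplex and sums to one", {
  mask <- roi_mask(array(1L, dim = c(4, 1, 1)), 3)
  const <- matrix(rep(c(0.2, 0.3, 0.5), each = 4), 4, 3)
  maps <- weight_maps(const, mask, 1:4)
  expect_equal(mean_roi_weighting(maps), c(0.2, 0.3, 0.5))
  half <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  maps2 <- weight_maps(half, mask, 1:4)
  expect_equal(mean_roi_weighting(maps2), c(0.5, 0.5))
  expect_equal(sum(mean_roi_weighting(maps)), 1, tolerance = 1e-12)
})

test_that("spectral peaks are located and flagged by regime", {
  g <- build_spectral_grid(c(0.01, 0.3), c(1e-4, 1), 30, 30)
  # single-atom spectrum
  f <- numeric(n_grid_points(g))
  it <- which.min(abs(g$t2star - 0.10))
  ia <- which.min(abs(g$adc - 0.5))
  f[it + (ia - 1) * 30] <- 1
  pk <- find_peaks(f, g)
  expect_equal(nrow(pk), 1)
  expect_true(pk$high_t2star[1])
  expect_true(pk$vascular_adc[1])
  expect_false(pk$low_t2star[1])
  # low-T2* flag below 0.06 s
  f2 <- numeric(n_grid_points(g))
  f2[which.min(abs(g$t2star - 0.02))] <- 1
  pk2 <- find_peaks(f2, g)
  expect_true(pk2$low_t2star[1])
  expect_false(pk2$vascular_adc[1])
})

test_that("exported component volumes are bounded, masked and complete", {
  sc <- two_component_scan(rbind(c(0.3, 0.7), c(0.8, 0.2), c(0.5, 0.5)))
  maps <- reduced_inspect(sc, sc$components)
  vols <- export_component_maps(maps)
  expect_equal(length(vols), 2)
  s <- vols[[1]] + vols[[2]]
  expect_true(all(vols[[1]] >= 0 & vols[[1]] <= 1))
  expect_equal(s[maps$roi_index], rep(1, length(maps$roi_index)),
               tolerance = 1e-6)
  # outside-ROI voxels are exactly zero
  outside <- setdiff(seq_along(s), maps$roi_index)
  if (length(outside) > 0) expect_true(all(s[outside] == 0))
})

test_that("component sets round-trip through their text serialisation", {
  g <- small_grid(8)
  cs <- component_set_from_peaks(three_peaks(), g)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_component_set(cs, f)
  cs2 <- read_component_set(f)
  expect_equal(cs2$amplitudes, cs$amplitudes, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(cs2$grid$t2star, g$t2star, tolerance = 1e-12)
})

test_that("usage errors are caught", {
  sc <- two_component_scan(rbind(c(1, 0), c(0, 1)))
  expect_error(full_inspect(sc, m_components = 0), ">= 1")
  expect_error(full_inspect(sc, m_components = 50, grid = small_grid()),
               "exceeds")
  other <- sc
  other$series$protocol <- acquisition_protocol(c(0.078, 0.114), c(0, 0))
  cs <- sc$components
  cs$protocol <- small_protocol()
  expect_error(reduced_inspect(other, cs), "protocol")
})
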