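test_that("weight maps are simplex-valued and deterministic", {
  spec <- phantom_spec(grid_shape = c(14, 14, 7), n_lobules = 5,
                       grid = small_grid(), seed = 9)
  maps1 <- make_weight_maps(spec)
  expect_simplex_rows(maps1$weights, tol = 1e-12)
  maps2 <- make_weight_maps(spec)
  expect_identical(maps1$weights, maps2$weights)
  spec2 <- phantom_spec(grid_shape = c(14, 14, 7), n_lobules = 5,
                        grid = small_grid(), seed = 10)
  maps3 <- make_weight_maps(spec2)
  expect_false(identical(maps1$weights, maps3$weights))
  # ROI means match the requested targets after raking
  expect_equal(colMeans(maps1$weights), spec$target_means, tolerance = 1e-10)
})

test_that("single uniform component gives weight one everywhere", {
  spec <- phantom_spec(grid_shape = c(10, 10, 5), n_lobules = 2,
                       components = list(data.frame(t2star = 0.05, adc = 0.01,
                                                    amplitude = 1)),
                       spatial_pattern = "uniform", grid = small_grid(),
                       seed = 1)
  maps <- make_weight_maps(spec)
  expect_true(all(maps$weights == 1))
})

test_that("phantom geometry validates lobule capacity", {
  expect_error(make_weight_maps(phantom_spec(grid_shape = c(4, 4, 4),
                                             n_lobules = 500,
                                             grid = small_grid())),
               "too small")
})

test_that("noiseless scans equal the forward mixture exactly", {
  p <- small_protocol()
  spec <- tiny_disjoint_phantom(snr = Inf)
  sc <- synthesize_scan(spec, p)
  W <- sc$truth$weights
  A <- sc$truth$signatures
  expected <- spec$s0_mean * (A %*% t(W))
  flat <- matrix(sc$series$data, nrow = prod(dim(sc$mask$data)))
  expect_equal(t(flat[sc$truth$roi_index, ]), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # background voxels are exactly zero without noise
  expect_true(all(flat[-sc$truth$roi_index, ] == 0))
})

test_that("single-peak phantom voxels are recovered by the decay fit", {
  p <- default_protocol()
  spec <- phantom_spec(grid_shape = c(8, 8, 5), n_lobules = 2,
                       components = list(data.frame(t2star = 0.05,
                                                    adc = 0.002,
                                                    amplitude = 1)),
                       spatial_pattern = "uniform", grid = small_grid(40),
                       snr = Inf, seed = 3)
  sc <- synthesize_scan(spec, p)
  res <- fit_roi(sc$series, sc$mask)
  pk <- find_peaks(sc$truth$components$amplitudes[, 1], spec$grid)[1, ]
  ok <- res$fit$valid
  expect_lt(max(abs(res$fit$t2star[ok] - pk$t2star) / pk$t2star), 1e-6)
  expect_lt(max(abs(res$fit$adc[ok] - pk$adc) / pk$adc), 1e-6)
})

test_that("reference-volume mean under Rician noise matches the bias oracle", {
  p <- small_protocol()
  spec <- phantom_spec(grid_shape = c(16, 16, 8), n_lobules = 4,
                       grid = small_grid(), snr = 10, seed = 6)
  sc <- synthesize_scan(spec, p)
  ref <- reference_volume(sc$series)
  vals <- ref[sc$truth$roi_index]
  sigma <- spec$s0_mean / spec$snr
  expected <- rician_mean(spec$s0_mean, sigma)
  se <- sigma / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("cohort tables have the study's size and injected structure", {
  spec <- cohort_spec(seed = 2)
  tab <- simulate_cohort_table(spec)
  expect_equal(nrow(tab), 67)
  expect_equal(sum(tab$group == "control"), 50)
  expect_equal(sum(tab$group == "chd"), 17)
  expect_equal(length(unique(tab$participant_id[tab$group == "control"])), 36)
  expect_equal(length(unique(tab$participant_id[tab$group == "chd"])), 12)
  expect_false(any(duplicated(tab$scan_id)))
  expect_true(all(tab$ga_weeks >= 20 & tab$ga_weeks <= 42))
  W <- as.matrix(tab[, sprintf("w%d", 1:7)])
  expect_simplex_rows(W, tol = 1e-9)
  # determinism
  expect_identical(tab, simulate_cohort_table(cohort_spec(seed = 2)))
})

test_that("group offsets shift expected weightings only where injected", {
  spec <- effect_cohort_spec(offset3 = 0.05, offset4 = -0.05)
  # below the changepoint no trend is active: pure offset contrast
  wc <- expected_weightings(spec, 25, "control")
  wh <- expected_weightings(spec, 25, "chd")
  d <- wh - wc
  expect_gt(d[3], 0.03)
  expect_lt(d[4], -0.03)
  expect_lt(max(abs(d[c(1, 2, 5, 6, 7)])), 0.011)  # renormalisation only
  # null spec: no difference anywhere
  ns <- null_cohort_spec()
  expect_equal(expected_weightings(ns, 35, "control"),
               expected_weightings(ns, 35, "chd"), tolerance = 1e-12)
})

test_that("hinge trends activate only beyond the changepoint", {
  spec <- cohort_spec(seed = 1)
  w28 <- expected_weightings(spec, 28, "control")
  w30 <- expected_weightings(spec, 30, "control")
  expect_equal(w28, w30, tolerance = 1e-12)
  w36 <- expected_weightings(spec, 36, "control")
  expect_gt(w36[4] - w30[4], 0.04)   # component 4 rises in controls
  expect_lt(w36[7] - w30[7], -0.02)  # component 7 declines
})

test_that("infeasible group offsets raise an error naming the component", {
  expect_error(cohort_spec(group_offsets = c(0, 0, 0, -0.5, 0, 0, 0)),
               "component 4")
})

test_that("simulated imaging cohorts carry matching ground truth", {
  p <- small_protocol()
  cs_spec <- cohort_spec(n_control = 3, n_chd = 2, seed = 8)
  ph <- phantom_spec(grid_shape = c(10, 10, 5), n_lobules = 3,
                     grid = small_grid(), snr = Inf, seed = 1)
  coh <- simulate_cohort(cs_spec, ph, p)
  expect_equal(length(coh$scans), 5)
  expect_equal(nrow(coh$table), 5)
  for (i in seq_along(coh$scans)) {
    W <- coh$truth$weights[[i]]$weights
    expect_simplex_rows(W, tol = 1e-9)
    target <- as.numeric(coh$table[i, sprintf("w%d", 1:7)])
    expect_equal(colMeans(W), target, tolerance = 1e-8)
  }
  # placental volume grows with gestational age
  vols <- vapply(coh$scans, function(s) roi_volume(s$mask), numeric(1))
  expect_gt(cor(coh$table$ga_weeks, vols), 0)
})
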