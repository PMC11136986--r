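# Shared fixtures: small protocols, grids and phantoms built in code.

# Reduced protocol: all four echo times, a light diffusion set. Keeps the
# (TE, b) structure of the full acquisition — including several low-b
# shells, which carry the leverage on fast (vascular) diffusion — at a
# fraction of the volumes.
small_protocol <- function() {
  tes <- c(78, 114, 150, 186) / 1000
  bs <- c(0, 5, 10, 18, 36, 50, 100, 200, 400, 800, 1600)
  rows <- expand.grid(echo_time = tes, b_value = bs)
  acquisition_protocol(rows$echo_time, rows$b_value)
}

small_grid <- function(n = 20) {
  build_spectral_grid(c(0.01, 0.30), c(1e-4, 1.0), n, n)
}

# Three well-separated single-peak components.
three_peaks <- function() {
  list(
    data.frame(t2star = 0.030, adc = 0.001, amplitude = 1),
    data.frame(t2star = 0.065, adc = 0.020, amplitude = 1),
    data.frame(t2star = 0.110, adc = 0.300, amplitude = 1)
  )
}

tiny_disjoint_phantom <- function(seed = 7, snr = Inf, grid = small_grid()) {
  phantom_spec(grid_shape = c(12, 12, 6), n_lobules = 6,
               components = three_peaks(),
               spatial_pattern = rep("lobule_partition", 3),
               grid = grid, snr = snr, seed = seed)
}

# Deterministic small cohort where the only group difference is the offset
# pair in components 3 and 4 (both groups share the control hinge trends).
effect_cohort_spec <- function(offset3 = 0.05, offset4 = -0.05, seed = 1,
                               noise_sd = 0.03) {
  sl <- default_trend_slopes()
  sl[, "chd"] <- sl[, "control"]
  cohort_spec(ga_trend_slopes = sl,
              group_offsets = c(0, 0, offset3, offset4, 0, 0, 0),
              weighting_noise_sd = noise_sd, seed = seed)
}

null_cohort_spec <- function(seed = 1) {
  cohort_spec(ga_trend_slopes = matrix(0, 7, 2,
                                       dimnames = list(NULL, c("control", "chd"))),
              group_offsets = rep(0, 7), seed = seed)
}

expect_simplex_rows <- function(W, tol = 1e-9) {
  expect_true(all(W >= -tol))
  expect_true(max(abs(rowSums(W) - 1)) < tol)
}
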