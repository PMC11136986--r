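test_that("signal kernel matches hand-evaluated values", {
  # zero exponents at the reference point
  expect_identical(signal_kernel(0.078, 0, 0.04, 0.5, 0.078), 1)
  # TE - TEmin equal to T2* gives exactly exp(-1)
  expect_equal(signal_kernel(0.114, 0, 0.036, 0.3, 0.078), exp(-1),
               tolerance = 1e-15)
  # direct evaluation: exp(-0.72) * exp(-1.2)
  expect_equal(signal_kernel(0.114, 600, 0.050, 0.002, 0.078),
               exp(-0.72) * exp(-1.2), tolerance = 1e-15)
  # grid of hand-computed products of the two exponentials
  cases <- expand.grid(te = c(0.078, 0.114, 0.150, 0.186),
                       b = c(0, 18, 800), t2 = c(0.02, 0.09),
                       adc = c(5e-4, 0.25))
  k <- with(cases, signal_kernel(te, b, t2, adc, 0.078))
  k_hand <- with(cases, exp(-(te - 0.078) / t2) * exp(-b * adc))
  expect_equal(k, k_hand, tolerance = 1e-12)
})

test_that("signal kernel rejects invalid arguments", {
  expect_error(signal_kernel(0.114, 0, -0.01, 0, 0.078), "t2star")
  expect_error(signal_kernel(0.114, 0, 0, 0, 0.078), "t2star")
  expect_error(signal_kernel(0.114, -5, 0.05, 0, 0.078), "b_value")
  expect_error(signal_kernel(0.114, 0, 0.05, -1, 0.078), "adc")
  expect_error(signal_kernel(0.050, 0, 0.05, 0, 0.078), "te_min")
})

test_that("kernel is separable and monotone in TE and b", {
  tes <- seq(0.078, 0.186, length.out = 6)
  k_te <- signal_kernel(tes, 0, 0.05, 0.01, 0.078)
  expect_true(all(diff(k_te) < 0))
  bs <- c(0, 10, 100, 800, 1600)
  k_b <- signal_kernel(0.114, bs, 0.05, 0.01, 0.078)
  expect_true(all(diff(k_b) < 0))
  # separability: k(TE, b) = k(TE, 0) * k(TEmin, b)
  expect_equal(signal_kernel(0.15, 600, 0.04, 0.008, 0.078),
               signal_kernel(0.15, 0, 0.04, 0.008, 0.078) *
                 signal_kernel(0.078, 600, 0.04, 0.008, 0.078),
               tolerance = 1e-15)
})

test_that("forward signal is linear in s0 and anchored at the reference", {
  p <- small_protocol()
  s1 <- forward_signal(1, 0.05, 0.002, p)
  expect_equal(forward_signal(100, 0.05, 0.002, p), 100 * s1,
               tolerance = 1e-15)
  expect_identical(forward_signal(0, 0.05, 0.002, p), rep(0, nrow(p)))
  expect_equal(s1[reference_index(p)], 1)
  # per-element oracle over the full protocol
  pf <- default_protocol()
  sig <- forward_signal(1, 0.050, 0.002, pf)
  oracle <- exp(-(pf$echo_time - 0.078) / 0.050) * exp(-pf$b_value * 0.002)
  expect_equal(sig, oracle, tolerance = 1e-12)
})

test_that("default protocol reproduces the acquisition table", {
  p <- default_protocol()
  expect_equal(n_measurements(p), 244)
  expect_equal(te_min(p), 0.078)
  # per echo time: 1 b=0 + 10 shells x 3 + 18 x 8 + 36 x 7 + 800 x 15 = 61
  for (te in c(78, 114, 150, 186) / 1000) {
    sub <- p[p$echo_time == te, ]
    expect_equal(nrow(sub), 61)
    counts <- table(sub$b_value)
    expect_equal(unname(counts[as.character(c(0, 18, 36, 800))]),
                 c(1, 8, 7, 15), ignore_attr = TRUE)
    for (b in c(5, 10, 25, 50, 100, 200, 400, 600, 1200, 1600)) {
      expect_equal(sum(sub$b_value == b), 3)
    }
  }
})

test_that("protocol round-trips through CSV and validates", {
  p <- default_protocol()
  f <- withr::local_tempfile(fileext = ".csv")
  write_protocol(p, f)
  p2 <- read_protocol(f)
  expect_equal(p2$echo_time, p$echo_time, tolerance = 1e-12)
  expect_equal(p2$b_value, p$b_value)
  expect_error(acquisition_protocol(c(0.114, 0.150), c(5, 0)), "b = 0")
  expect_error(acquisition_protocol(0.078, -1), "non-negative")
})

test_that("spectral grid is log-spaced, rectangular and validated", {
  g <- build_spectral_grid(c(0.01, 0.3), c(1e-4, 1), 50, 50)
  expect_equal(n_grid_points(g), 2500)
  expect_true(all(diff(g$t2star) > 0))
  expect_true(all(diff(g$adc) > 0))
  ratios_t <- g$t2star[-1] / g$t2star[-50]
  expect_lt(max(abs(ratios_t - ratios_t[1])), 1e-10)
  ratios_a <- g$adc[-1] / g$adc[-50]
  expect_lt(max(abs(ratios_a - ratios_a[1])), 1e-10)
  expect_equal(range(g$t2star), c(0.01, 0.3))
  expect_error(build_spectral_grid(c(0.3, 0.01), c(1e-4, 1)), "range")
  expect_error(build_spectral_grid(c(0.01, 0.3), c(1e-4, 1), 1, 10), ">= 2")
})

test_that("kernel matrix matches elementwise kernel evaluation", {
  p <- small_protocol()
  g <- small_grid(10)
  K <- kernel_matrix(p, g)
  expect_equal(dim(K), c(nrow(p), 100))
  expect_true(all(K[reference_index(p), ] == 1))
  expect_true(all(K >= 0 & K <= 1))
  pts <- grid_points(g)
  set.seed(42)
  for (s in 1:5) {
    i <- sample(nrow(p), 1)
    j <- sample(100, 1)
    expect_equal(K[i, j],
                 unname(signal_kernel(p$echo_time[i], p$b_value[i],
                                      pts[j, "t2star"], pts[j, "adc"],
                                      te_min(p))),
                 tolerance = 1e-15)
  }
  # entries are positive wherever the exponent is representable
  expect_true(all(K[, pts[, "adc"] < 0.4] > 0))
})
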