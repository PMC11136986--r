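random_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    scan_id = sprintf("s%03d", seq_len(n)),
    group = sample(rep(c("control", "chd"), length.out = n)),
    ga_weeks = runif(n, 20, 40),
    maternal_age_years = rnorm(n, 33, 4),
    bmi = rnorm(n, 26, 3),
    y = rnorm(n)
  )
}

test_that("ancova group p-value agrees with the linear-model oracle", {
  worst <- 0
  for (s in 1:100) {
    tab <- random_table(n = sample(12:40, 1), seed = s)
    tab$y <- rnorm(nrow(tab)) + 0.1 * tab$ga_weeks +
      0.3 * (tab$group == "chd")
    res <- ancova_group(tab, "y")
    fit <- lm(y ~ I(group == "chd") + ga_weeks + maternal_age_years,
              data = tab)
    p_oracle <- summary(fit)$coefficients[2, 4]
    est_oracle <- coef(fit)[2]
    worst <- max(worst, abs(res$p - p_oracle) / p_oracle,
                 abs(res$estimate - est_oracle) / abs(est_oracle))
  }
  expect_lt(worst, 1e-8)
})

test_that("ancova detects degenerate and malformed inputs", {
  tab <- random_table(20)
  tab$y <- 2 * tab$ga_weeks  # outcome fully explained by a covariate
  expect_error(ancova_group(tab, "y"), "degenerate|zero residual")
  expect_error(ancova_group(random_table(20), "nope"), "missing column")
  one_group <- random_table(20)
  one_group$group <- "control"
  expect_error(ancova_group(one_group, "y"), "both")
})

test_that("ancova is invariant to row permutation", {
  tab <- random_table(24, seed = 9)
  res1 <- ancova_group(tab, "y")
  set.seed(1)
  res2 <- ancova_group(tab[sample(nrow(tab)), ], "y")
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-12)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("pearson trend matches the textbook formula and cor.test", {
  tab <- data.frame(group = "control",
                    ga_weeks = c(22.1, 25.4, 28.0, 33.3, 39.7),
                    y = c(0.31, 0.12, 0.55, 0.47, 0.28))
  res <- pearson_trend(tab, "y", "control")
  x <- tab$ga_weeks; y <- tab$y
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  # perfect linear relations
  tab$y <- 3 * tab$ga_weeks + 1
  expect_equal(pearson_trend(tab, "y", "control")$r, 1, tolerance = 1e-12)
  tab$y <- -tab$ga_weeks
  expect_equal(pearson_trend(tab, "y", "control")$r, -1, tolerance = 1e-12)
  tab$y <- rep(1, 5)
  expect_error(pearson_trend(tab, "y", "control"), "zero variance")
})

# independent brute-force step-up adjustment, written against the
# definition: adj_(i) = min_{j >= i} min(1, m p_(j) / j) in sorted order
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

test_that("BH adjustment matches the hand-derived example and brute force", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074)
  expect_equal(bh_fdr(p), c(0.007, 0.028, 0.0588, 0.0588, 0.0588, 0.07, 0.074),
               tolerance = 1e-12)
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(11)
  worst <- 0
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    worst <- max(worst, max(abs(bh_fdr(p) - bh_brute(p))))
  }
  expect_lt(worst, 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(bh_fdr(runif(10)) >= runif(0)))  # adjusted >= raw below
  p <- runif(10)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("Mann-Whitney handles separation, symmetry and the approximation", {
  # complete separation of 6 vs 6 ranks
  res <- mann_whitney_u(1:6, 7:12)
  expect_equal(res$statistic, 0)
  # identical distributions: U at its mean, exact two-sided p = 1
  x <- c(1.2, 3.4, 2.2, 5.0)
  res2 <- mann_whitney_u(x, x)
  expect_equal(res2$statistic, length(x)^2 / 2)
  expect_equal(res2$p, 1)
  # large samples: normal approximation close to wilcox.test
  set.seed(5)
  a <- rnorm(30); b <- rnorm(35, 0.5)
  res3 <- mann_whitney_u(a, b)
  wt <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res3$statistic, unname(wt$statistic))
  expect_equal(res3$p, wt$p.value, tolerance = 1e-10)
})

test_that("demographics tests choose tests by normality and report summaries", {
  set.seed(21)
  n1 <- 40; n2 <- 20
  tab <- data.frame(
    group = rep(c("control", "chd"), c(n1, n2)),
    ga_weeks = c(exp(rnorm(n1, 3.4, 0.12)), exp(rnorm(n2, 3.45, 0.12))),
    maternal_age_years = c(exp(rnorm(n1, 3.55, 0.1)), exp(rnorm(n2, 3.5, 0.1))),
    bmi = c(rnorm(n1, 26.2, 3), rnorm(n2, 26.3, 3))
  )
  out <- demographics_tests(tab)
  expect_named(out, c("ga_weeks", "maternal_age_years", "bmi"))
  expect_equal(out$bmi$test, "t_test")
  # pooled-variance formula oracle for the t statistic
  xc <- tab$bmi[tab$group == "control"]; xh <- tab$bmi[tab$group == "chd"]
  sp2 <- ((n1 - 1) * var(xc) + (n2 - 1) * var(xh)) / (n1 + n2 - 2)
  t_hand <- (mean(xh) - mean(xc)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(out$bmi$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$bmi$summary$convention[1], "mean_sd")
})

test_that("component analysis flags injected group effects in the right places", {
  spec <- effect_cohort_spec(offset3 = 0.12, offset4 = -0.12, seed = 4,
                             noise_sd = 0.02)
  tab <- simulate_cohort_table(spec)
  rep_ <- run_component_analysis(tab)
  expect_true(all(rep_$group_ancova$significant[c(3, 4)]))
  expect_false(any(rep_$group_ancova$significant[c(1, 2, 5, 6, 7)]))
  expect_equal(rep_$group_ancova$direction[3], "chd_higher")
  expect_equal(rep_$group_ancova$direction[4], "chd_lower")
  # trend families respect the sign of the injected slopes
  sl <- spec$ga_trend_slopes
  tc <- rep_$trend_control
  expect_true(all(tc$r[sl[, "control"] > 0] > 0))
  expect_true(all(tc$r[sl[, "control"] < 0] < 0))
  th <- rep_$trend_chd
  expect_true(all(th$r[sl[, "chd"] > 0] > 0))
  expect_true(all(th$r[sl[, "chd"] < 0] < 0))
  # adjusted never below raw
  expect_true(all(rep_$group_ancova$adjusted_p >= rep_$group_ancova$raw_p))
})

test_that("null cohorts rarely produce flags", {
  hits <- vapply(1:40, function(s) {
    tab <- simulate_cohort_table(null_cohort_spec(seed = s))
    any(run_component_analysis(tab)$group_ancova$significant)
  }, logical(1))
  expect_lt(mean(hits), 0.25)
})
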