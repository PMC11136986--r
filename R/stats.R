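# Cohort statistics: ANCOVA group comparisons adjusting for gestational and
# maternal age, Pearson trends over gestation per group, Benjamini-Hochberg
# FDR across the component family, and the demographics comparisons.
# The ANCOVA, Pearson p and Mann-Whitney machinery is written from first
# principles (design matrix, least squares, exact rank enumeration) so each
# piece is directly checkable against an independent oracle.

weighting_columns <- function(table) {
  grep("^w[0-9]+$", names(table), value = TRUE)
}

check_groups <- function(table, group_col = "group") {
  g <- table[[group_col]]
  lv <- unique(g)
  if (!all(c("control", "chd") %in% lv)) {
    stop("both 'control' and 'chd' groups must be present", call. = FALSE)
  }
  tab <- table(g)
  if (any(tab < 3)) stop("each group needs n >= 3", call. = FALSE)
  invisible(g)
}

#' ANCOVA group comparison of one outcome
#'
#' Ordinary least squares of `outcome ~ group + covariates` with group as a
#' two-level factor (CHD vs control, no interaction); the reported p-value
#' is the two-sided t-test of the group coefficient on the residual degrees
#' of freedom. Implemented directly from the design matrix so it can be
#' verified against an independent general-linear-model oracle.
#'
#' @param table Cohort table with `group` and covariate columns.
#' @param outcome Name of the numeric outcome column.
#' @param covariates Covariate column names (default gestational age at
#'   scan and maternal age, the study's adjustment set).
#' @return List of class `stat_test`: `test`, `estimate` (CHD - control
#'   adjusted difference), `statistic`, `df`, `p`, `direction`, `n`,
#'   `covariates`.
#' @export
ancova_group <- function(table, outcome,
                         covariates = c("ga_weeks", "maternal_age_years")) {
  check_groups(table)
  missing_cols <- setdiff(c(outcome, covariates), names(table))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(table[[outcome]])
  if (any(!is.finite(y))) stop("outcome must be finite numeric", call. = FALSE)
  g <- as.numeric(table$group == "chd")
  X <- cbind(intercept = 1, group_chd = g)
  for (cv in covariates) X <- cbind(X, as.numeric(table[[cv]]))
  colnames(X) <- c("intercept", "group_chd", covariates)
  n <- nrow(X)
  p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) stop("collinear design matrix", call. = FALSE)
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  df <- n - p
  rss <- sum(res^2)
  if (rss < 1e-12 * max(sum(y^2), 1)) {
    stop("degenerate model: zero residual variance", call. = FALSE)
  }
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  tstat <- beta[2] / se
  pval <- 2 * pt(-abs(tstat), df)
  structure(list(test = "ancova", outcome = outcome,
                 estimate = unname(beta[2]), statistic = unname(tstat),
                 df = df, p = unname(pval),
                 direction = ifelse(beta[2] > 0, "chd_higher", "chd_lower"),
                 n = n, covariates = covariates),
            class = "stat_test")
}

#' Pearson trend of an outcome over gestation within one group
#'
#' Sample Pearson correlation of the outcome against gestational age within
#' the requested group; two-sided p from the t distribution with n - 2
#' degrees of freedom.
#'
#' @param table Cohort table.
#' @param outcome Outcome column name.
#' @param group `"control"` or `"chd"`.
#' @param ga_col Gestational-age column (default `ga_weeks`).
#' @return List of class `stat_test` with `r`, `statistic`, `df`, `p`, `n`.
#' @export
pearson_trend <- function(table, outcome, group, ga_col = "ga_weeks") {
  rows <- table$group == group
  x <- as.numeric(table[[ga_col]][rows])
  y <- as.numeric(table[[outcome]][rows])
  n <- length(x)
  if (n < 3) stop("n >= 3 required within the group", call. = FALSE)
  sx <- sd(x)
  sy <- sd(y)
  if (sx == 0 || sy == 0) {
    stop("zero variance in gestational age or outcome", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  df <- n - 2
  if (abs(r) >= 1) {
    tstat <- sign(r) * Inf
    pval <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    pval <- 2 * pt(-abs(tstat), df)
  }
  structure(list(test = "pearson_trend", outcome = outcome, group = group,
                 r = r, statistic = tstat, df = df, p = pval, n = n),
            class = "stat_test")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, returned in
#' the input order. Adjusted values never fall below the raw values.
#'
#' @param raw_p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(raw_p) {
  if (any(!is.finite(raw_p)) || any(raw_p < 0) || any(raw_p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(raw_p, method = "BH")
}

#' Mann-Whitney U test for two independent samples
#'
#' Rank-sum comparison with midranks for ties. For small samples (both
#' n <= 10) the two-sided p-value is computed by exact enumeration of all
#' group assignments of the observed (mid)ranks; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @return List of class `stat_test` with `statistic` (U of the first
#'   sample), `p`, `n`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 10 && n2 <= 10) {
    combos <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    pval <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    nties <- table(r)
    sigma2 <- (n1 * n2 / 12) *
      ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
    if (sigma2 <= 0) {
      pval <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      pval <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  structure(list(test = "mann_whitney", statistic = u, p = pval,
                 n = c(n1, n2), method = method),
            class = "stat_test")
}

#' Demographic comparisons between groups
#'
#' For each demographic variable, Shapiro-Wilk normality (per group) decides
#' the comparison and the reporting convention: normally distributed
#' variables are compared by a pooled-variance two-sample t-test and
#' summarised as mean (sd); non-normal variables by the Mann-Whitney U test
#' and summarised as median (IQR). Gestational and maternal age are treated
#' as non-normal and BMI as normal whenever the Shapiro-Wilk tests are
#' equivocal, matching the convention of the cohort-table reporting.
#'
#' @param table Cohort table with `ga_weeks`, `maternal_age_years`, `bmi`.
#' @param alpha Normality-test level (default 0.05).
#' @return List of `stat_test` results, one per variable, each with a
#'   `summary` data frame (per-group location and spread).
#' @export
demographics_tests <- function(table, alpha = 0.05) {
  check_groups(table)
  vars <- intersect(c("ga_weeks", "maternal_age_years", "bmi"), names(table))
  out <- list()
  for (v in vars) {
    xc <- as.numeric(table[[v]][table$group == "control"])
    xh <- as.numeric(table[[v]][table$group == "chd"])
    if (length(xc) < 3 || length(xh) < 3) next
    sw <- function(x) {
      if (length(unique(x)) < 3) return(0)
      shapiro.test(x)$p.value
    }
    normal <- sw(xc) > alpha && sw(xh) > alpha
    if (normal) {
      tt <- t.test(xh, xc, var.equal = TRUE)
      res <- structure(list(test = "t_test", statistic = unname(tt$statistic),
                            p = tt$p.value, n = c(length(xc), length(xh)),
                            method = "pooled_variance"),
                       class = "stat_test")
      summ <- data.frame(group = c("control", "chd"),
                         location = c(mean(xc), mean(xh)),
                         spread = c(sd(xc), sd(xh)),
                         convention = "mean_sd")
    } else {
      res <- mann_whitney_u(xh, xc)
      iqr <- function(x) diff(stats::quantile(x, c(0.25, 0.75)))
      summ <- data.frame(group = c("control", "chd"),
                         location = c(median(xc), median(xh)),
                         spread = c(iqr(xc), iqr(xh)),
                         convention = "median_iqr")
    }
    res$variable <- v
    res$summary <- summ
    out[[v]] <- res
  }
  out
}

#' Component-weighting analysis across the cohort
#'
#' Runs the three test families over the M component-weighting columns,
#' each corrected across components by Benjamini-Hochberg separately:
#' (a) ANCOVA group comparisons adjusting for gestational and maternal age;
#' (b) Pearson trends over gestation in the control group;
#' (c) Pearson trends over gestation in the CHD group.
#' Components with adjusted p below `alpha` are flagged with their effect
#' direction.
#'
#' @param table Cohort table with `w1..wM` columns.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return List of class `component_analysis` with one data frame per
#'   family (`group_ancova`, `trend_control`, `trend_chd`), each holding
#'   raw and adjusted p-values, effect size/direction, and `significant`.
#' @export
run_component_analysis <- function(table, alpha = 0.05) {
  wcols <- weighting_columns(table)
  if (length(wcols) == 0) {
    stop("no component weighting columns (w1..wM) found", call. = FALSE)
  }
  fam_a <- lapply(wcols, function(wc) ancova_group(table, wc))
  a_df <- data.frame(
    component = seq_along(wcols),
    estimate = vapply(fam_a, `[[`, 0, "estimate"),
    statistic = vapply(fam_a, `[[`, 0, "statistic"),
    raw_p = vapply(fam_a, `[[`, 0, "p"),
    direction = vapply(fam_a, `[[`, "", "direction")
  )
  a_df$adjusted_p <- bh_fdr(a_df$raw_p)
  a_df$significant <- a_df$adjusted_p < alpha

  trend_family <- function(group) {
    fam <- lapply(wcols, function(wc) pearson_trend(table, wc, group))
    df <- data.frame(
      component = seq_along(wcols),
      r = vapply(fam, `[[`, 0, "r"),
      raw_p = vapply(fam, `[[`, 0, "p")
    )
    df$adjusted_p <- bh_fdr(df$raw_p)
    df$significant <- df$adjusted_p < alpha
    df$direction <- ifelse(df$r > 0, "increasing", "decreasing")
    df
  }
  structure(list(group_ancova = a_df,
                 trend_control = trend_family("control"),
                 trend_chd = trend_family("chd"),
                 alpha = alpha, m = length(wcols),
                 note = paste("repeat scans from one participant are",
                              "treated as independent rows")),
            class = "component_analysis")
}

#' @export
print.component_analysis <- function(x, ...) {
  cat("Component-weighting analysis (M =", x$m, ", alpha =", x$alpha, ")\n")
  cat("\n(a) ANCOVA group comparison (CHD vs control | GA, maternal age):\n")
  print(x$group_ancova, digits = 3)
  cat("\n(b) Control-group trends over gestation:\n")
  print(x$trend_control, digits = 3)
  cat("\n(c) CHD-group trends over gestation:\n")
  print(x$trend_chd, digits = 3)
  cat("\nNote:", x$note, "\n")
  invisible(x)
}
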