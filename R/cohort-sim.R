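# Synthetic cohorts with the statistical structure the analysis assumes:
# per-scan expected component weightings follow a baseline plus hinge trends
# over gestation (onset at the changepoint) plus group offsets, with
# between-scan biological noise; optionally full image volumes are
# synthesized so every downstream stage can be tested against ground truth.

#' Specify a synthetic cohort
#'
#' Defaults mirror the study design the analysis targets: 50 control scans
#' from 36 participants and 17 CHD scans from 12 participants (some
#' participants scanned twice), gestational ages 20-40 weeks, trends in
#' component weightings emerging after 30 weeks, and group offsets confined
#' to components 3 (higher in CHD) and 4 (lower in CHD).
#'
#' @param n_control,n_chd Number of scans per group.
#' @param ga_range Gestational-age range in weeks.
#' @param baseline_weights Simplex of per-component mean weightings at the
#'   changepoint for controls.
#' @param ga_trend_slopes M x 2 matrix (`control`, `chd` columns) of
#'   weighting change per week beyond the changepoint.
#' @param group_offsets Per-component weighting difference (CHD - control);
#'   `baseline + offset` must stay positive for every component.
#' @param changepoint_ga Trend onset, weeks (default 30).
#' @param maternal_age_dist 2 x 2 matrix, rows `control`/`chd`, columns
#'   mean/sd of maternal age (years).
#' @param bmi_dist Mean and sd of maternal BMI (kg/m^2), shared by groups.
#' @param repeat_scan_fraction Fraction of participants scanned twice.
#' @param weighting_noise_sd Between-scan biological s.d. of each observed
#'   mean weighting (before renormalisation).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 50, n_chd = 17,
                        ga_range = c(20, 40),
                        baseline_weights = c(0.20, 0.10, 0.15, 0.15,
                                             0.15, 0.15, 0.10),
                        ga_trend_slopes = default_trend_slopes(),
                        group_offsets = c(0, 0, 0.05, -0.05, 0, 0, 0),
                        changepoint_ga = 30,
                        maternal_age_dist = rbind(control = c(35, 3),
                                                  chd = c(32, 4)),
                        bmi_dist = c(26.2, 3.0),
                        repeat_scan_fraction = 0.4,
                        weighting_noise_sd = 0.03,
                        seed = 1) {
  if (n_control < 1 || n_chd < 0) stop("invalid group sizes", call. = FALSE)
  m <- length(baseline_weights)
  if (any(baseline_weights <= 0)) {
    stop("baseline weightings must be positive", call. = FALSE)
  }
  baseline_weights <- baseline_weights / sum(baseline_weights)
  if (!is.matrix(ga_trend_slopes) || nrow(ga_trend_slopes) != m ||
      ncol(ga_trend_slopes) != 2) {
    stop("ga_trend_slopes must be an M x 2 matrix (control, chd)",
         call. = FALSE)
  }
  if (length(group_offsets) != m) {
    stop("group_offsets must have one entry per component", call. = FALSE)
  }
  bad <- which(baseline_weights + group_offsets <= 0)
  if (length(bad) > 0) {
    stop("group offset makes the weighting simplex infeasible for component ",
         bad[1], call. = FALSE)
  }
  if (ga_range[1] < 20 || ga_range[2] > 42 || ga_range[1] >= ga_range[2]) {
    stop("ga_range must lie within [20, 42] weeks", call. = FALSE)
  }
  structure(list(n_control = as.integer(n_control), n_chd = as.integer(n_chd),
                 ga_range = ga_range, baseline_weights = baseline_weights,
                 ga_trend_slopes = ga_trend_slopes,
                 group_offsets = group_offsets,
                 changepoint_ga = changepoint_ga,
                 maternal_age_dist = maternal_age_dist, bmi_dist = bmi_dist,
                 repeat_scan_fraction = repeat_scan_fraction,
                 weighting_noise_sd = weighting_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default hinge-trend slopes
#'
#' Control scans gain component 4 after the changepoint and lose components
#' 5-7; CHD scans instead gain components 2 and 3 and lose components 5-7 —
#' the qualitative trend pattern the generator emulates.
#'
#' @return 7 x 2 matrix of weighting change per week (columns `control`,
#'   `chd`).
#' @export
default_trend_slopes <- function() {
  control <- c(0, 0, 0, 0.012, -0.006, -0.008, -0.008)
  chd <- c(0, 0.006, 0.012, 0, -0.008, -0.008, -0.010)
  cbind(control = control, chd = chd)
}

#' Expected mean component weightings for one scan
#'
#' baseline + slope * max(0, GA - changepoint) + group offset, clipped at
#' zero and renormalised to the simplex.
#'
#' @param spec A [cohort_spec()].
#' @param ga Gestational age, weeks.
#' @param group `"control"` or `"chd"`.
#' @return Simplex vector of M expected weightings.
#' @export
expected_weightings <- function(spec, ga, group = c("control", "chd")) {
  group <- match.arg(group)
  hinge <- max(0, ga - spec$changepoint_ga)
  w <- spec$baseline_weights + spec$ga_trend_slopes[, group] * hinge
  if (group == "chd") w <- w + spec$group_offsets
  w <- pmax(w, 0)
  if (sum(w) <= 0) stop("degenerate expected weightings", call. = FALSE)
  w / sum(w)
}

#' Simulate a cohort table of per-scan mean weightings and covariates
#'
#' Generates participants (some scanned twice), gestational ages, maternal
#' age and BMI, and observed per-scan mean component weightings = expected
#' weightings plus Gaussian between-scan noise, floored and renormalised.
#' This is the statistics-level simulator: no image volumes are built.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional override of the spec seed.
#' @return A `data.frame` (the cohort table) with columns `scan_id`,
#'   `participant_id`, `group`, `ga_weeks`, `maternal_age_years`, `bmi`,
#'   `w1`..`wM`; attribute `true_weightings` holds the noise-free expected
#'   weightings per scan.
#' @export
simulate_cohort_table <- function(spec, seed = NULL) {
  set.seed(child_seed(seed %||% spec$seed, 4L))
  m <- length(spec$baseline_weights)
  make_group <- function(n_scans, group) {
    if (n_scans == 0) return(NULL)
    n_part <- max(1L, round(n_scans / (1 + spec$repeat_scan_fraction)))
    n_repeat <- n_scans - n_part
    if (n_repeat < 0) { n_part <- n_scans; n_repeat <- 0 }
    age <- rnorm(n_part, spec$maternal_age_dist[group, 1],
                 spec$maternal_age_dist[group, 2])
    bmi <- rnorm(n_part, spec$bmi_dist[1], spec$bmi_dist[2])
    ga1 <- runif(n_part, spec$ga_range[1], spec$ga_range[2])
    twice <- seq_len(n_part) <= n_repeat
    rows <- data.frame(
      participant = rep(seq_len(n_part), times = 1 + twice),
      scan_no = unlist(lapply(twice, function(t) seq_len(1 + t)))
    )
    rows$ga <- ga1[rows$participant]
    second <- rows$scan_no == 2
    rows$ga[second] <- pmin(rows$ga[second] + runif(sum(second), 4, 8),
                            spec$ga_range[2])
    rows$age <- age[rows$participant]
    rows$bmi <- bmi[rows$participant]
    rows$group <- group
    rows
  }
  rows <- rbind(make_group(spec$n_control, "control"),
                make_group(spec$n_chd, "chd"))
  n <- nrow(rows)
  true_w <- t(vapply(seq_len(n), function(i) {
    expected_weightings(spec, rows$ga[i], rows$group[i])
  }, numeric(m)))
  obs_w <- true_w + matrix(rnorm(n * m, sd = spec$weighting_noise_sd), n, m)
  obs_w <- pmax(obs_w, 0.005)
  obs_w <- obs_w / rowSums(obs_w)
  tab <- data.frame(
    scan_id = sprintf("%s_%02d_s%d", rows$group, rows$participant,
                      rows$scan_no),
    participant_id = sprintf("%s_%02d", rows$group, rows$participant),
    group = rows$group,
    ga_weeks = rows$ga,
    maternal_age_years = rows$age,
    bmi = rows$bmi
  )
  w_df <- as.data.frame(obs_w)
  names(w_df) <- sprintf("w%d", seq_len(m))
  tab <- cbind(tab, w_df)
  attr(tab, "true_weightings") <- true_w
  tab
}

#' Simulate a full imaging cohort
#'
#' For every scan of the cohort table, builds a phantom whose placental slab
#' volume grows with gestational age and whose ROI-mean component
#' weightings equal the scan's (noisy) target weightings exactly, then
#' forward-models and noises the image volumes. Ground truth for every scan
#' is returned alongside.
#'
#' @param spec A [cohort_spec()].
#' @param phantom A [phantom_spec()] template (geometry, spectra, SNR).
#' @param protocol An [acquisition_protocol()].
#' @return List of class `synthetic_cohort`: `scans` (each
#'   `list(series, mask, covariates)`), `table` (cohort table), `truth`
#'   (per-scan weight matrices and the shared `component_set`), `spec`,
#'   `phantom`.
#' @export
simulate_cohort <- function(spec, phantom, protocol) {
  tab <- simulate_cohort_table(spec)
  m <- length(spec$baseline_weights)
  if (length(phantom$components) != m) {
    stop("phantom component count must match the cohort weighting dimension",
         call. = FALSE)
  }
  scans <- vector("list", nrow(tab))
  truth_w <- vector("list", nrow(tab))
  cs <- component_set_from_peaks(phantom$components, phantom$grid)
  for (i in seq_len(nrow(tab))) {
    target <- as.numeric(tab[i, sprintf("w%d", seq_len(m))])
    ps <- phantom
    ps$target_means <- target
    ps$slab_scale <- (tab$ga_weeks[i] / 30)^1.5
    ps$seed <- child_seed(spec$seed, 100L + i)
    out <- synthesize_scan(ps, protocol)
    out$series$scan_id <- tab$scan_id[i]
    scans[[i]] <- list(series = out$series, mask = out$mask,
                       covariates = tab[i, 1:6])
    truth_w[[i]] <- list(weights = out$truth$weights,
                         roi_index = out$truth$roi_index)
  }
  structure(list(scans = scans, table = tab,
                 truth = list(weights = truth_w, components = cs),
                 spec = spec, phantom = phantom),
            class = "synthetic_cohort")
}

#' Write a cohort table to CSV
#' @param table Cohort table data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema: identifier/covariate columns plus `w1..wM`
#' weighting columns summing to 1 per row.
#'
#' @param path CSV path.
#' @return Cohort table data frame.
#' @export
read_cohort_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "group", "ga_weeks", "maternal_age_years")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(duplicated(tab$scan_id))) {
    stop("duplicated scan_id in cohort table", call. = FALSE)
  }
  tab
}
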