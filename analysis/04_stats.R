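#!/usr/bin/env Rscript
# Stage 4: cohort statistics.
#
# Reproduces the statistical pipeline on the simulated cohort: demographic
# comparisons (normality-gated t / Mann-Whitney), ANCOVA group comparisons
# of volume, mean T2*, mean ADC and each component weighting (adjusting for
# gestational age and maternal age), Pearson trends over gestation per
# group, and Benjamini-Hochberg FDR across the seven components per family.

suppressPackageStartupMessages(library(plaspect))

tab <- read_cohort_table(file.path("results", "cohort_with_weightings.csv"))
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("== Demographics ==")
demo <- demographics_tests(tab)
demo_df <- do.call(rbind, lapply(demo, function(d) {
  data.frame(variable = d$variable, test = d$test, p = d$p,
             control = d$summary$location[1], chd = d$summary$location[2],
             convention = d$summary$convention[1])
}))
print(demo_df, digits = 3)
write.csv(demo_df, file.path(out_dir, "demographics.csv"), row.names = FALSE)

message("\n== Global MRI measures (ANCOVA, GA + maternal age adjusted) ==")
glob <- do.call(rbind, lapply(c("volume_mm3", "mean_t2star_ms", "mean_adc"),
                              function(v) {
  a <- ancova_group(tab, v)
  data.frame(measure = v, estimate = a$estimate, p = a$p,
             direction = a$direction)
}))
print(glob, digits = 3)
write.csv(glob, file.path(out_dir, "global_ancova.csv"), row.names = FALSE)

message("\n== Global trends over gestation (all scans pooled) ==")
trend <- do.call(rbind, lapply(c("volume_mm3", "mean_t2star_ms", "mean_adc"),
                               function(v) {
  tt <- rbind(
    data.frame(group = "control",
               r = pearson_trend(tab, v, "control")$r,
               p = pearson_trend(tab, v, "control")$p),
    data.frame(group = "chd",
               r = pearson_trend(tab, v, "chd")$r,
               p = pearson_trend(tab, v, "chd")$p))
  cbind(measure = v, tt)
}))
print(trend, digits = 3)
write.csv(trend, file.path(out_dir, "global_trends.csv"), row.names = FALSE)

message("\n== Component weighting analysis (three BH families of 7) ==")
comp <- run_component_analysis(tab)
print(comp)
write.csv(comp$group_ancova, file.path(out_dir, "component_ancova.csv"),
          row.names = FALSE)
write.csv(comp$trend_control, file.path(out_dir, "component_trend_control.csv"),
          row.names = FALSE)
write.csv(comp$trend_chd, file.path(out_dir, "component_trend_chd.csv"),
          row.names = FALSE)

sig <- comp$group_ancova$component[comp$group_ancova$significant]
message("\nComponents with significant group difference (p_FDR < 0.05): ",
        if (length(sig)) paste(sig, collapse = ", ") else "none")
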