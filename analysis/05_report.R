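#!/usr/bin/env Rscript
# Stage 5: figures.
#
# Component weighting vs gestation plots (one panel per component, y-axis
# fixed to 0-80% so panels are comparable; dotted lines join repeat scans
# of one participant), global T2*/ADC/volume vs gestation, and per-scan
# component montages (rows = components, columns = slices, colour scale
# fixed to 0-1).

suppressPackageStartupMessages({
  library(plaspect)
  library(ggplot2)
})

tab <- read_cohort_table(file.path("results", "cohort_with_weightings.csv"))
fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

long <- do.call(rbind, lapply(1:7, function(m) {
  data.frame(component = paste("Component", m), scan_id = tab$scan_id,
             participant_id = tab$participant_id, group = tab$group,
             ga_weeks = tab$ga_weeks, weighting = tab[[sprintf("w%d", m)]])
}))
p1 <- ggplot(long, aes(ga_weeks, 100 * weighting, colour = group)) +
  geom_line(aes(group = participant_id), linetype = "dotted", alpha = 0.5) +
  geom_point(size = 1.2) +
  facet_wrap(~component, nrow = 2) +
  scale_y_continuous(limits = c(0, 80)) +
  labs(x = "Gestational age (weeks)", y = "Mean ROI weighting (%)",
       colour = NULL) +
  theme_bw()
ggsave(file.path(fig_dir, "weightings_vs_ga.png"), p1,
       width = 11, height = 5.5, dpi = 150)

glong <- rbind(
  data.frame(measure = "Mean T2* (ms)", value = tab$mean_t2star_ms,
             tab[c("ga_weeks", "group", "participant_id")]),
  data.frame(measure = "Mean ADC (mm^2/s)", value = tab$mean_adc,
             tab[c("ga_weeks", "group", "participant_id")]),
  data.frame(measure = "ROI volume (mm^3)", value = tab$volume_mm3,
             tab[c("ga_weeks", "group", "participant_id")]))
p2 <- ggplot(glong, aes(ga_weeks, value, colour = group)) +
  geom_line(aes(group = participant_id), linetype = "dotted", alpha = 0.5) +
  geom_point(size = 1.2) +
  facet_wrap(~measure, scales = "free_y") +
  labs(x = "Gestational age (weeks)", y = NULL, colour = NULL) +
  theme_bw()
ggsave(file.path(fig_dir, "global_measures_vs_ga.png"), p2,
       width = 10, height = 3.5, dpi = 150)

# component montage for the first control and first CHD scan
montage_scan <- function(id) {
  vols <- lapply(1:7, function(m) {
    f <- file.path("results/decomposition",
                   sprintf("%s_component%d.nii.gz", id, m))
    array(as.numeric(RNifti::readNifti(f)), dim = dim(RNifti::readNifti(f)))
  })
  dims <- dim(vols[[1]])
  slices <- round(seq(2, dims[3] - 1, length.out = min(6, dims[3])))
  df <- do.call(rbind, lapply(1:7, function(m) {
    do.call(rbind, lapply(seq_along(slices), function(si) {
      sl <- vols[[m]][, , slices[si]]
      expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2])) |>
        transform(value = as.numeric(sl), component = m, slice = si)
    }))
  }))
  ggplot(df, aes(x, y, fill = value)) +
    geom_raster() +
    facet_grid(component ~ slice, switch = "y") +
    scale_fill_viridis_c(limits = c(0, 1), name = "weighting") +
    coord_fixed() +
    labs(title = id, x = NULL, y = "Component") +
    theme_void() +
    theme(strip.text.y.left = element_text(angle = 0))
}
for (id in c(head(tab$scan_id[tab$group == "control"], 1),
             head(tab$scan_id[tab$group == "chd"], 1))) {
  ggsave(file.path(fig_dir, sprintf("montage_%s.png", id)),
         montage_scan(id), width = 9, height = 9, dpi = 150)
}
message("Figures written to ", fig_dir)
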