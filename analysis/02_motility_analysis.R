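#!/usr/bin/env Rscript
# Quantify motility across the temperature sweep: simulate each condition's
# cohort, rebuild tracks from the rasterized masks, apply the inclusion
# criteria, compute per-cell deformation area / centroid displacement /
# circularity, and compare acclimated vs non-acclimated cells per
# temperature with Welch's t-test.
#
# Cohort sizes are kept at 6 cells x 40 frames per condition here so the
# sweep runs in about a minute; the acceptance script exercises the focal
# 26C contrast at the full 20 cells x 60 frames.
#
# Outputs under results/motility/:
#   cells.csv, pairs.csv, inclusion.csv, comparisons.csv, manifest.json
#   temperature_summary.csv - per-temperature AC vs non-AC panel table

library(coldmotility)

conditions <- read.csv("results/conditions.csv")
specs <- list()
for (i in seq_len(nrow(conditions))) {
  r <- conditions[i, ]
  name <- sprintf("%dC_%s", r$temperature_c,
                  if (r$acclimated) "AC" else "nonAC")
  specs[[name]] <- list(
    n_cells = 6, n_frames = 40L, frame_interval_s = r$frame_interval_s,
    pixel_size_um = r$pixel_size_um, field_size_px = c(420L, 420L),
    mean_speed_um_per_min = r$mean_speed_um_per_min,
    persistence = r$persistence,
    protrusion_amplitude = r$protrusion_amplitude,
    base_radius_um = r$base_radius_um)
}
pairs_to_compare <- lapply(unique(conditions$temperature_c), function(tp)
  c(sprintf("%dC_nonAC", tp), sprintf("%dC_AC", tp)))

res <- suppressWarnings(run_motility_pipeline(
  specs, seed = 2026L, interval_s = 180,
  comparisons = pairs_to_compare, out_dir = "results/motility"))

cat(sprintf("included %d cells across %d conditions\n",
            nrow(res$cells), length(specs)))

# per-temperature panel table (mean +/- SD, Welch p, stars, fold change)
cells <- res$cells
cells$temperature <- as.integer(sub("C_.*", "", cells$condition))
cells$state <- sub(".*C_", "", cells$condition)
panel <- do.call(rbind, lapply(
  c(acd = "mean_acd_um2", disp = "mean_displacement_um",
    circ = "mean_circularity"),
  function(metric) {
    d <- data.frame(temperature = cells$temperature,
                    condition = cells$state, value = cells[[metric]])
    out <- summarize_conditions(d, reference = "nonAC", test = "AC")
    out$metric <- metric
    out
  }))
write.csv(panel, "results/motility/temperature_summary.csv",
          row.names = FALSE)

sig <- panel[panel$stars != "ns", c("temperature", "metric", "stars",
                                    "fold_change")]
cat("significant AC vs non-AC contrasts by temperature:\n")
print(sig, row.names = FALSE)
at26 <- panel[panel$temperature == 26, ]
cat(sprintf("at 26C: deformation-area fold %.2f, displacement fold %.2f (AC / non-AC)\n",
            at26$fold_change[at26$metric == "mean_acd_um2"],
            at26$fold_change[at26$metric == "mean_displacement_um"]))
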