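# Stage 4 — trend mapping.
#
# Per-pixel Mann-Kendall significance (Zc) and Theil-Sen slope (beta) on
# the annual NDVI composites, the cover-level classification of mean
# annual NDVI, and basin-mean trend tests for NDVI and the climate
# variables.

source("analysis/00_config.R")

cfg <- study_config()

ndvi_annual <- read_stack(stack_path("ndvi_annual"))
tm <- trend_map(ndvi_annual, z_threshold = cfg$z_threshold)
mean_annual <- apply(ndvi_annual$values, c(2, 3), mean, na.rm = TRUE)
lv <- level_map(mean_annual)

write.csv(tm$zc, file.path(results_dir, "trend_zc.csv"), row.names = FALSE)
write.csv(tm$beta, file.path(results_dir, "trend_beta.csv"),
          row.names = FALSE)
write.csv(tm$class, file.path(results_dir, "trend_class.csv"),
          row.names = FALSE)

cat("Area fractions by trend class:\n")
print(round(tm$fractions$trend_class, 4))
cat("Area fractions by Theil-Sen band (units/yr):\n")
print(round(tm$fractions$beta_band, 4))
cat("Cover-level fractions (mean annual NDVI):\n")
print(round(lv$fractions, 4))

basin <- apply(ndvi_annual$values, 1, mean, na.rm = TRUE)
zc <- mk_z(basin); beta <- theil_sen(basin)
cat(sprintf("Basin-mean annual NDVI: Zc = %.2f, beta = %.5f/yr -> %s.\n",
            zc, beta, classify_trend(zc, beta, cfg$z_threshold)))

frac_up <- mean(tm$beta > 0, na.rm = TRUE)
cat(sprintf("%.2f%% of vegetated pixels have beta > 0.\n", 100 * frac_up))
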