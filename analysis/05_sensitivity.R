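# Stage 5 — vegetation memory and the sensitivity index.
#
# Excludes low-cover months, detrends and z-scores all four variables by
# calendar month, fits the per-pixel lag-1 regression (memory alpha and
# climate responses), derives PCR climate weights, mean-variance-residual
# variability scores, log-ratio sensitivities and the 0-100 VSI, then the
# memory classes, the alpha-vs-gradient regressions and the RGB weight
# composite.

source("analysis/00_config.R")

cfg <- study_config()

ndvi <- read_stack(stack_path("ndvi_monthly"))
tem <- read_stack(stack_path("tem"))
pre <- read_stack(stack_path("pre"))
tvdi <- read_stack(stack_path("tvdi"))

exclusion <- low_cover_month_mask(ndvi, cfg$ndvi_threshold)
ndvi_z <- detrend_and_standardize(ndvi, exclude = exclusion)
tem_z <- detrend_and_standardize(tem)
pre_z <- detrend_and_standardize(pre)
tvdi_z <- detrend_and_standardize(tvdi)
cat(sprintf("Low-cover exclusion removed %d pixel-months.\n",
            ndvi_z$dropped[["excluded"]]))

ar1 <- fit_ar1(ndvi_z, tem_z, pre_z, tvdi_z, min_months = cfg$min_months)
cat(sprintf("Lag-1 fits: %d pixels fitted, %d below %d joint months, %d rank-deficient.\n",
            ar1$counts[["fitted"]], ar1$counts[["too_few_months"]],
            cfg$min_months, ar1$counts[["rank_deficient"]]))
cat(sprintf("Memory coefficient alpha: median %.3f (IQR %.3f-%.3f).\n",
            median(ar1$alpha, na.rm = TRUE),
            quantile(ar1$alpha, 0.25, na.rm = TRUE),
            quantile(ar1$alpha, 0.75, na.rm = TRUE)))

mem <- memory_map(ar1$alpha)
cat("Memory-class fractions:\n"); print(round(mem$fractions, 4))

raw_w <- pcr_weights(ndvi_z, tem_z, pre_z, tvdi_z,
                     p_threshold = cfg$p_threshold,
                     min_months = cfg$min_months)
weights <- rescale_weights(raw_w, normalize = cfg$normalize_weights)
cat(sprintf("Median climate weights (tem/pre/tvdi): %.3f / %.3f / %.3f.\n",
            median(weights$tem, na.rm = TRUE),
            median(weights$pre, na.rm = TRUE),
            median(weights$tvdi, na.rm = TRUE)))

vscores <- list(ndvi = variability_scores(ndvi_z$detrended),
                tem = variability_scores(tem_z$detrended),
                pre = variability_scores(pre_z$detrended),
                tvdi = variability_scores(tvdi_z$detrended))
sens <- list(tem = sensitivity_scores(vscores$ndvi, vscores$tem),
             pre = sensitivity_scores(vscores$ndvi, vscores$pre),
             tvdi = sensitivity_scores(vscores$ndvi, vscores$tvdi))
vsi <- compute_vsi(weights, sens)
cat(sprintf("VSI: range [%.1f, %.1f], median %.1f; %.2f%% of pixels below 30.\n",
            min(vsi$vsi, na.rm = TRUE), max(vsi$vsi, na.rm = TRUE),
            median(vsi$vsi, na.rm = TRUE),
            100 * mean(vsi$vsi < 30, na.rm = TRUE)))

gs <- list(ndvi = growing_season_mean(ndvi, cfg$gs_months),
           tem = growing_season_mean(tem, cfg$gs_months),
           pre = growing_season_mean(pre, cfg$gs_months),
           tvdi = growing_season_mean(tvdi, cfg$gs_months))
grads <- list(
  ndvi = gradient_regression(ar1$alpha, gs$ndvi, "logarithmic"),
  tvdi = gradient_regression(ar1$alpha, gs$tvdi, "logarithmic"),
  pre = gradient_regression(ar1$alpha, gs$pre, "quadratic"),
  tem = gradient_regression(ar1$alpha, gs$tem, "quadratic"))
cat("Memory-gradient regressions (form, R2, p):\n")
for (nm in names(grads))
  cat(sprintf("  alpha ~ GS %-4s %-11s R2 = %.3f, p = %.3g\n",
              nm, grads[[nm]]$form, grads[[nm]]$r2, grads[[nm]]$p))

write.csv(ar1$alpha, file.path(results_dir, "alpha.csv"), row.names = FALSE)
write.csv(vsi$vsi, file.path(results_dir, "vsi.csv"), row.names = FALSE)
for (v in c("tem", "pre", "tvdi"))
  write.csv(weights[[v]], file.path(results_dir, paste0("weight_", v, ".csv")),
            row.names = FALSE)
grad_df <- do.call(rbind, lapply(names(grads), function(nm)
  data.frame(covariate = nm, form = grads[[nm]]$form, r2 = grads[[nm]]$r2,
             p = grads[[nm]]$p, n = grads[[nm]]$n)))
write.csv(grad_df, file.path(results_dir, "gradient_fits.csv"),
          row.names = FALSE)

rgb <- weights_rgb(weights)
if (requireNamespace("png", quietly = TRUE)) {
  img <- rgb / 255
  img[is.na(img)] <- 0
  png::writePNG(img, file.path(results_dir, "climate_weights_rgb.png"))
  cat("Wrote climate-weight RGB composite (tem = red, TVDI = green, pre = blue).\n")
}
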