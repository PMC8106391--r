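# Stage 1 — simulate the study scene.
#
# Generates the monthly climate stacks (air temperature, precipitation,
# LST with injected orbit/cloud gaps) and the NDVI stack driven by the
# configured lag-1 anomaly model, then writes the raw observables under
# results/stacks/. The generative TVDI driver is computed internally from
# the NDVI climatology and the gap-filled LST, closing the loop the
# anomaly model assumes.

source("analysis/00_config.R")

cfg <- study_config()
synth <- cfg$synth

clim <- generate_climate_stacks(synth)
lst_gapped <- inject_gaps(clim$lst, synth$gap_fraction,
                          stage_seed(synth$seed, "gaps"))
lst_filled <- fill_stack_gaps(lst_gapped)
driver <- tvdi_stack(ndvi_climatology(synth), lst_filled,
                     bin_width = cfg$bin_width,
                     min_count = cfg$min_count)$stack
ndvi <- generate_ndvi(synth, clim$tem, clim$pre, driver)

for (nm in c("tem", "pre")) write_stack(clim[[nm]], stack_path(nm))
write_stack(lst_gapped, stack_path("lst_gapped"))
write_stack(ndvi, stack_path("ndvi_raw"))

truth <- attr(ndvi, "truth")
jsonlite::write_json(
  list(alpha = truth$alpha, beta = truth$beta, gamma = truth$gamma,
       delta = truth$delta, noise_sd = truth$noise_sd, seed = synth$seed),
  file.path(results_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Simulated %d x %d pixels over %d months.\n",
            synth$n_rows, synth$n_cols, 12 * synth$n_years))
cat(sprintf("LST gap cells injected: %d (%.1f%%).\n",
            sum(attr(lst_gapped, "gap_mask")),
            100 * mean(attr(lst_gapped, "gap_mask"))))
cat(sprintf("NDVI range: [%.3f, %.3f]; generative (alpha, beta, gamma, delta) = (%.2f, %.2f, %.2f, %.2f).\n",
            min(ndvi$values), max(ndvi$values),
            truth$alpha, truth$beta, truth$gamma, truth$delta))
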