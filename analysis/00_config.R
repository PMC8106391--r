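# Shared study configuration for the analysis scripts: a 30 x 30 synthetic
# basin observed monthly over 2000-2018, moderate vegetation memory
# (alpha = 0.5) with temperature/precipitation/soil-dryness responses
# (0.2, 0.3, -0.2) and innovation SD 0.3, 10% LST gaps.

library(ecosens)

study_config <- function(seed = 42L) {
  pipeline_config(synth_config(
    n_rows = 30, n_cols = 30, n_years = 19, start_year = 2000, seed = seed,
    true_alpha = 0.5, true_beta = 0.2, true_gamma = 0.3, true_delta = -0.2,
    noise_sd = 0.3, gap_fraction = 0.1))
}

results_dir <- "results"
stack_path <- function(name) file.path(results_dir, "stacks", name)
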