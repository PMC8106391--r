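# Small fixture builders used across test files.

monthly_clock <- function(n_years, start_year = 2000L) {
  list(years = rep(start_year + seq_len(n_years) - 1L, each = 12L),
       months = rep(1:12, n_years))
}

# stack from a [time, row, col] cube with a standard monthly clock
cube_stack <- function(values, variable = "tem", units = "",
                       start_year = 2000L) {
  ck <- monthly_clock(dim(values)[1] / 12L, start_year)
  monthly_stack(values, ck$years, ck$months, variable, units)
}

# wrap per-pixel [time, pixel] matrices as a standardized-stack-like object
# accepted by fit_ar1 / pcr_weights
pixel_std <- function(m, n_years = nrow(m) / 12L) {
  ck <- monthly_clock(n_years)
  list(z = array(m, dim = c(nrow(m), ncol(m), 1)),
       time = data.frame(year = ck$years, month = ck$months))
}

# quick small synthetic scene used by several files
tiny_scene <- function(seed = 7, n = 10, years = 5) {
  cfg <- synth_config(n, n, n_years = years, seed = seed)
  clim <- generate_climate_stacks(cfg)
  list(cfg = cfg, clim = clim)
}
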