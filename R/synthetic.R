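#' Configuration of the synthetic scene generator
#'
#' Describes a seeded synthetic study area: a rectangular grid with a
#' north-south elevation gradient, monthly climate driven by seasonal cycles
#' with weak linear trends, and NDVI anomalies generated by a lag-1
#' autoregression on standardized climate anomalies
#' (`z_t = alpha * z_{t-1} + beta * Tem_t + gamma * Pre_t + delta * M_t + e_t`,
#' where `M` is the moisture driver — TVDI by default — and
#' `e_t ~ N(0, noise_sd^2)`). The configured coefficients are the ground
#' truth that downstream fits must recover.
#'
#' Defaults emulate an arid continental basin observed over 2000-2018:
#' annual mean air temperature of a few degC with a ~14 degC seasonal
#' half-amplitude, sparse precipitation increasing with elevation, LST in
#' Kelvin warmer over barren ground (so a dry edge exists in NDVI-LST
#' space), weak warming/wetting trends, and a moderate vegetation memory
#' (`alpha = 0.5`).
#'
#' @param n_rows,n_cols grid size (rows run north to south).
#' @param n_years number of years; the monthly clock has `12 * n_years` steps.
#' @param start_year first calendar year.
#' @param seed integer; fully determines all generated stacks.
#' @param true_alpha lag-1 NDVI anomaly coefficient, `|true_alpha| < 1`.
#' @param true_beta,true_gamma,true_delta standardized-anomaly response
#'   coefficients for temperature, precipitation and the moisture driver.
#' @param noise_sd innovation SD of the NDVI anomaly recursion (>= 0).
#' @param ndvi_anom_sd climatological SD used to re-embed unit-variance NDVI
#'   anomalies into the seasonal climatology (NDVI units).
#' @param seasonal_amplitude named vector of seasonal half-amplitudes
#'   (`tem`, `lst` in degC/K; `pre` in mm/month; `ndvi` as a relative
#'   modulation of the pixel NDVI level in [0, 1]).
#' @param linear_trend named vector of linear trends in units/yr
#'   (`tem`, `pre`, `lst`, `ndvi`).
#' @param climate_noise_sd named vector of white-noise SDs added to the
#'   deterministic climate surfaces (`tem`, `pre`, `lst`).
#' @param gap_fraction fraction of LST cells knocked out by [inject_gaps()]
#'   in the pipeline, in `[0, 1)`.
#' @param elevation_gradient scalar in `[0, 1]` scaling the north-south
#'   covariate structure (0 = flat scene).
#' @param ndvi_driver `"tvdi"` (default; the moisture driver passed to
#'   [generate_ndvi()] is a TVDI stack) or `"lst"` (drive by LST anomalies
#'   directly).
#'
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_rows, n_cols, n_years = 19L, start_year = 2000L,
                         seed = 42L,
                         true_alpha = 0.5, true_beta = 0.2,
                         true_gamma = 0.3, true_delta = -0.2,
                         noise_sd = 0.3, ndvi_anom_sd = 0.05,
                         seasonal_amplitude = c(tem = 14, pre = 10, lst = 14,
                                                ndvi = 0.45),
                         linear_trend = c(tem = 0.03, pre = 0.3, lst = 0.03,
                                          ndvi = 0.001),
                         climate_noise_sd = c(tem = 1.2, pre = 4, lst = 1.5),
                         gap_fraction = 0.1,
                         elevation_gradient = 1,
                         ndvi_driver = c("tvdi", "lst")) {
  if (n_rows < 1 || n_cols < 1 || n_years < 1)
    stop("grid dimensions and n_years must be positive")
  if (abs(true_alpha) >= 1)
    stop("|true_alpha| must be < 1 (stationary memory)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must lie in [0, 1)")
  need <- c("tem", "pre", "lst", "ndvi")
  if (!all(need %in% names(seasonal_amplitude)) ||
      !all(need %in% names(linear_trend)) ||
      !all(c("tem", "pre", "lst") %in% names(climate_noise_sd)))
    stop("seasonal_amplitude/linear_trend must name tem, pre, lst, ndvi; ",
         "climate_noise_sd must name tem, pre, lst")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    seed = as.integer(seed),
    true_alpha = true_alpha, true_beta = true_beta,
    true_gamma = true_gamma, true_delta = true_delta,
    noise_sd = noise_sd, ndvi_anom_sd = ndvi_anom_sd,
    seasonal_amplitude = seasonal_amplitude,
    linear_trend = linear_trend,
    climate_noise_sd = climate_noise_sd,
    gap_fraction = gap_fraction,
    elevation_gradient = elevation_gradient,
    ndvi_driver = match.arg(ndvi_driver)), class = "synth_config")
}

# Deterministic spatial base fields shared by all generated variables:
# elevation rises northwards (row 1 = north); the NDVI level follows
# elevation/moisture with a seeded smooth texture so pixels are not
# collinear. Texture is seeded from config$seed only.
synth_fields <- function(config) {
  nr <- config$n_rows; nc <- config$n_cols
  g <- config$elevation_gradient
  north <- if (nr > 1) (nr - row(matrix(0, nr, nc))) / (nr - 1) else
    matrix(0.5, nr, nc)
  set.seed(stage_seed(config$seed, "fields"))
  texture <- matrix(stats::rnorm(nr * nc, 0, 0.05), nr, nc)
  elev <- clip_range(g * north + texture, 0, 1)
  ndvi_base <- clip_range(0.06 + 0.6 * elev +
                            matrix(stats::rnorm(nr * nc, 0, 0.03), nr, nc),
                          0.02, 0.85)
  list(elev = elev, ndvi_base = ndvi_base)
}

seasonal_factor <- function(months) cos(2 * pi * (months - 7) / 12)

synth_clock <- function(config) {
  nt <- 12L * config$n_years
  list(years = rep(config$start_year + seq_len(config$n_years) - 1L,
                   each = 12L),
       months = rep(1:12, config$n_years),
       elapsed_yr = (seq_len(nt) - 1L) / 12)
}

#' Generate synthetic monthly climate stacks
#'
#' Builds air-temperature (degC), precipitation (mm/month) and land-surface
#' temperature (K) stacks on a common grid and monthly clock. Each variable
#' is a spatial base field (elevation gradient) plus a seasonal sinusoid
#' peaking in July, a linear trend and white noise. LST carries a negative
#' dependence on the NDVI base field, so barren ground runs hotter and a dry
#' edge exists in NDVI-LST space. Precipitation is truncated at zero.
#'
#' @param config a [synth_config()].
#' @return named list of three `monthly_stack`s: `tem`, `pre`, `lst`.
#' @export
generate_climate_stacks <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  f <- synth_fields(config)
  ck <- synth_clock(config)
  nt <- length(ck$years); nr <- config$n_rows; nc <- config$n_cols
  A <- config$seasonal_amplitude; tr <- config$linear_trend
  ns <- config$climate_noise_sd
  season <- seasonal_factor(ck$months)

  make <- function(base, amp, trend, noise, stage) {
    set.seed(stage_seed(config$seed, stage))
    vals <- array(0, dim = c(nt, nr, nc))
    for (t in seq_len(nt)) {
      vals[t, , ] <- base + amp * season[t] + trend * ck$elapsed_yr[t] +
        matrix(stats::rnorm(nr * nc, 0, noise), nr, nc)
    }
    vals
  }

  tem_base <- 9 - 10 * f$elev                       # warm plains, cool mountains
  pre_base <- 8 + 24 * f$elev                       # orographic gradient
  lst_base <- 273.15 + tem_base + 22 * (1 - f$ndvi_base)

  tem <- make(tem_base, A[["tem"]], tr[["tem"]], ns[["tem"]], "tem")
  pre <- pmax(make(pre_base, A[["pre"]], tr[["pre"]], ns[["pre"]], "pre"), 0)
  lst <- make(lst_base, A[["lst"]], tr[["lst"]], ns[["lst"]], "lst")

  gt <- c(0, 1, 0, 0, 0, -1)
  list(tem = monthly_stack(tem, ck$years, ck$months, "tem", "degC", gt),
       pre = monthly_stack(pre, ck$years, ck$months, "pre", "mm/month", gt),
       lst = monthly_stack(lst, ck$years, ck$months, "lst", "K", gt))
}

#' Deterministic seasonal NDVI climatology of a synthetic scene
#'
#' The noise-free NDVI surface into which generated anomalies are embedded:
#' per pixel, the base NDVI level modulated by a seasonal cycle (relative
#' half-amplitude `seasonal_amplitude["ndvi"]`, peaking in July) plus the
#' configured linear trend. Values are clipped to `[0.02, 1]` so winter
#' deserts stay positive but below typical low-cover thresholds.
#'
#' @param config a [synth_config()].
#' @return a `monthly_stack` of NDVI.
#' @export
ndvi_climatology <- function(config) {
  f <- synth_fields(config)
  ck <- synth_clock(config)
  nt <- length(ck$years); nr <- config$n_rows; nc <- config$n_cols
  amp <- config$seasonal_amplitude[["ndvi"]]
  trend <- config$linear_trend[["ndvi"]]
  season <- seasonal_factor(ck$months)
  vals <- array(0, dim = c(nt, nr, nc))
  for (t in seq_len(nt)) {
    vals[t, , ] <- clip_range(
      f$ndvi_base * (1 + amp * season[t]) + trend * ck$elapsed_yr[t],
      0.02, 1)
  }
  monthly_stack(vals, ck$years, ck$months, "ndvi", "")
}

#' Simulate standardized AR1 pixels with known coefficients
#'
#' The minimal generative core used for parameter-recovery checks: per pixel,
#' three mutually independent standard-normal predictor series (temperature,
#' precipitation, moisture anomalies) and an NDVI anomaly following
#' `z_t = alpha z_{t-1} + beta Tem_t + gamma Pre_t + delta M_t + e_t` with
#' `e_t ~ N(0, noise_sd^2)` and `z_1` drawn from the stationary
#' distribution.
#'
#' @param n_pixels,n_months dimensions of the returned matrices.
#' @param alpha,beta,gamma,delta,noise_sd generative coefficients;
#'   `|alpha| < 1`.
#' @param seed integer RNG seed.
#' @return list of `[n_months, n_pixels]` matrices `ndvi`, `tem`, `pre`,
#'   `moist`.
#' @export
simulate_ar1_pixels <- function(n_pixels, n_months, alpha = 0.5, beta = 0.2,
                                gamma = 0.3, delta = -0.2, noise_sd = 0.3,
                                seed = 1L) {
  if (abs(alpha) >= 1) stop("|alpha| must be < 1")
  set.seed(seed)
  tem <- matrix(stats::rnorm(n_months * n_pixels), n_months, n_pixels)
  pre <- matrix(stats::rnorm(n_months * n_pixels), n_months, n_pixels)
  moist <- matrix(stats::rnorm(n_months * n_pixels), n_months, n_pixels)
  z <- matrix(0, n_months, n_pixels)
  stat_sd <- sqrt((beta^2 + gamma^2 + delta^2 + noise_sd^2) / (1 - alpha^2))
  z[1, ] <- stats::rnorm(n_pixels, 0, stat_sd)
  for (t in 2:n_months) {
    z[t, ] <- alpha * z[t - 1, ] + beta * tem[t, ] + gamma * pre[t, ] +
      delta * moist[t, ] + stats::rnorm(n_pixels, 0, noise_sd)
  }
  list(ndvi = z, tem = tem, pre = pre, moist = moist)
}

#' Generate a synthetic NDVI stack from climate drivers
#'
#' Runs the configured lag-1 anomaly recursion per pixel, driven by the
#' standardized anomalies of the supplied predictor stacks (standardization
#' = slope detrend + per-calendar-month z-score, the same convention the
#' analysis applies), then re-embeds the anomalies into the seasonal NDVI
#' climatology as `climatology + z * ndvi_anom_sd`, clipped to `[-1, 1]`.
#' The initial anomaly is drawn from an approximate stationary distribution
#' whose variance uses the empirical variance of the pixel's combined
#' climate forcing.
#'
#' The generated stack carries the ground truth as
#' `attr(x, "truth")`: the anomaly cubes `z_ndvi`, `z_tem`, `z_pre`,
#' `z_moist` actually used in the recursion plus the generative
#' coefficients. Fitting the lag-1 regression on those surfaces recovers the
#' coefficients exactly when `noise_sd = 0`.
#'
#' @param config a [synth_config()].
#' @param tem,pre temperature and precipitation `monthly_stack`s.
#' @param moisture the moisture driver stack: TVDI (default pipeline) or LST.
#' @return an NDVI `monthly_stack` with a `truth` attribute.
#' @export
generate_ndvi <- function(config, tem, pre, moisture) {
  stopifnot(inherits(config, "synth_config"))
  if (abs(config$true_alpha) >= 1)
    stop("|true_alpha| must be < 1 (stationary memory)")
  check_aligned(tem, pre, moisture)
  nt <- n_time(tem); nr <- dim(tem$values)[2]; nc <- dim(tem$values)[3]
  if (nt != 12L * config$n_years)
    stop("predictor stacks do not match the configured clock")

  zs <- lapply(list(tem, pre, moisture), function(s)
    detrend_and_standardize(s)$z)
  # pixels x time matrices; NA anomalies (zero-variance months) forced to 0
  # so they contribute no forcing
  zm <- lapply(zs, function(a) {
    m <- as_pixel_matrix(a)
    m[!is.finite(m)] <- 0
    m
  })
  a <- config$true_alpha; b <- config$true_beta
  g <- config$true_gamma; d <- config$true_delta
  forcing <- b * zm[[1]] + g * zm[[2]] + d * zm[[3]]

  set.seed(stage_seed(config$seed, "ndvi"))
  np <- nr * nc
  z <- matrix(0, nt, np)
  stat_var <- (apply(forcing, 2, stats::var) + config$noise_sd^2) /
    (1 - a^2)
  z[1, ] <- stats::rnorm(np, 0, sqrt(stat_var))
  for (t in 2:nt) {
    z[t, ] <- a * z[t - 1, ] + forcing[t, ] +
      stats::rnorm(np, 0, config$noise_sd)
  }

  clim <- ndvi_climatology(config)
  vals <- clim$values + pixel_matrix_to_cube(z, nr, nc) * config$ndvi_anom_sd
  vals <- clip_range(vals, -1, 1)
  out <- monthly_stack(vals, clim$time$year, clim$time$month, "ndvi", "",
                       tem$geotransform)
  attr(out, "truth") <- list(
    z_ndvi = pixel_matrix_to_cube(z, nr, nc),
    z_tem = pixel_matrix_to_cube(zm[[1]], nr, nc),
    z_pre = pixel_matrix_to_cube(zm[[2]], nr, nc),
    z_moist = pixel_matrix_to_cube(zm[[3]], nr, nc),
    alpha = a, beta = b, gamma = g, delta = d,
    noise_sd = config$noise_sd, ndvi_anom_sd = config$ndvi_anom_sd)
  out
}

#' Inject exact-count random data gaps into a stack
#'
#' Flags a uniformly random subset of currently valid cells as nodata,
#' emulating the ubiquitous orbit/cloud gaps of satellite LST products. The
#' number of flagged cells is exactly `round(gap_fraction * n_valid)`
#' (exact-count sampling, not Bernoulli), so tests can assert counts. The
#' injected pattern is returned as `attr(x, "gap_mask")` so the withheld
#' truth can be compared against gap-filled values.
#'
#' @param stack a `monthly_stack`.
#' @param gap_fraction fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return the gapped stack with a `gap_mask` logical-cube attribute.
#' @export
inject_gaps <- function(stack, gap_fraction, seed) {
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must lie in [0, 1)")
  vals <- stack$values
  valid <- which(!is.na(vals))
  k <- round(gap_fraction * length(valid))
  gap_mask <- array(FALSE, dim = dim(vals))
  if (k > 0) {
    set.seed(as.integer(seed))
    hit <- valid[sample.int(length(valid), k)]
    vals[hit] <- NA_real_
    gap_mask[hit] <- TRUE
  }
  out <- stack
  out$values <- vals
  attr(out, "gap_mask") <- gap_mask
  out
}
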