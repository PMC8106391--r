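# Helpers shared across modules.

#' Derive a per-stage RNG seed from the run seed
#'
#' Hashes a stage name into the run seed so every pipeline stage is
#' independently reproducible from one configured seed. Always below
#' 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param stage stage name, e.g. `"gaps"`.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Linear interpolation of interior NA runs; ends extended with the nearest
# observed value. Errors on an all-NA series.
fill_linear <- function(x) {
  if (!anyNA(x)) return(x)
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop("cannot interpolate an all-missing series")
  if (length(obs) == 1L) return(rep(x[obs], length(x)))
  stats::approx(obs, x[obs], xout = seq_along(x), rule = 2)$y
}

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# slope of the OLS line y ~ t (two-pass, NA-tolerant); NA if < 2 points or
# degenerate t
ols_slope <- function(t, y) {
  ok <- is.finite(y) & is.finite(t)
  if (sum(ok) < 2L) return(NA_real_)
  t <- t[ok]; y <- y[ok]
  vt <- sum((t - mean(t))^2)
  if (vt == 0) return(NA_real_)
  sum((t - mean(t)) * (y - mean(y))) / vt
}
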