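#' Mann-Kendall S statistic and its tie-corrected variance
#'
#' `S = sum_{i<k} sgn(x_k - x_i)` over all ordered pairs of the series, with
#' `Var(S) = [n(n-1)(2n+5) - sum_t t(t-1)(2t+5)] / 18`, the sum running over
#' the extents `t` of tied groups.
#'
#' @param x numeric series, length `>= 4`, no missing values.
#' @return list with `S` and `var_s`.
#' @export
mk_statistic <- function(x) {
  n <- length(x)
  if (n < 4L) stop("series length must be >= 4")
  if (anyNA(x)) stop("series must not contain missing values")
  d <- sign(outer(x, x, "-"))           # d[i, k] = sgn(x_i - x_k)
  S <- -sum(d[upper.tri(d)])            # i < k pairs of sgn(x_k - x_i)
  ties <- tabulate(match(x, unique(x)))   # exact-equality tie groups
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  list(S = S, var_s = var_s)
}

#' Standardized Mann-Kendall statistic Zc
#'
#' The continuity-corrected normal deviate of `S`: `(S - 1) / sqrt(Var(S))`
#' for `S > 0`, `0` for `S = 0`, `(S + 1) / sqrt(Var(S))` for `S < 0`.
#' `|Zc| > 1.96` marks a significant monotonic trend at the 95% level.
#'
#' @inheritParams mk_statistic
#' @return scalar `Zc`.
#' @export
mk_z <- function(x) {
  st <- mk_statistic(x)
  if (st$S == 0) return(0)
  if (st$var_s == 0)
    stop("degenerate series: zero variance with nonzero S")
  if (st$S > 0) (st$S - 1) / sqrt(st$var_s) else (st$S + 1) / sqrt(st$var_s)
}

#' Theil-Sen slope
#'
#' The median of all pairwise slopes `(x_i - x_j) / (i - j)`, `i > j` — a
#' robust trend-rate estimator in units per time step. With an even pair
#' count the central two slopes are averaged.
#'
#' @param x numeric series of length `>= 2`; `t` optional time coordinates
#'   (defaults to `1:length(x)`).
#' @return scalar slope.
#' @export
theil_sen <- function(x, t = seq_along(x)) {
  n <- length(x)
  if (n < 2L) stop("series length must be >= 2")
  dx <- outer(x, x, "-")
  dt <- outer(t, t, "-")
  stats::median(dx[lower.tri(dx)] / dt[lower.tri(dt)])
}

#' Classify a pixel trend from (Zc, beta)
#'
#' Five classes driven by the standardized statistic and the significance
#' threshold: significant/non-significant increase, no trend (`Zc = 0`),
#' non-significant/significant decrease.
#'
#' @param zc standardized Mann-Kendall statistic(s).
#' @param beta Theil-Sen slope(s); carried for interface symmetry, the class
#'   is determined by `zc` alone.
#' @param z_threshold significance threshold (default 1.96, the 95% level).
#' @return character vector of classes.
#' @export
classify_trend <- function(zc, beta = NULL, z_threshold = 1.96) {
  out <- rep(NA_character_, length(zc))
  out[zc > z_threshold] <- "sig_increase"
  out[zc > 0 & zc <= z_threshold] <- "nonsig_increase"
  out[zc == 0] <- "no_trend"
  out[zc < 0 & zc >= -z_threshold] <- "nonsig_decrease"
  out[zc < -z_threshold] <- "sig_decrease"
  out
}

trend_classes <- c("sig_increase", "nonsig_increase", "no_trend",
                   "nonsig_decrease", "sig_decrease")

#' Per-pixel trend map with area-fraction summaries
#'
#' Applies the Mann-Kendall test and the Theil-Sen slope to every pixel of
#' an annual stack and summarizes the vegetated area: fractions of valid
#' pixels per trend class and per slope band. Fractions sum to 1 within each
#' partition.
#'
#' @param annual_stack a `monthly_stack` of annual composites (`>= 4`
#'   layers). Missing years are dropped pixel-wise.
#' @param z_threshold significance threshold (default 1.96).
#' @param beta_breaks interior breakpoints of the slope bands; the default
#'   `c(0, 0.001, 0.002)` yields bands `beta <= 0`, `0 < beta < 0.001`,
#'   `0.001 <= beta <= 0.002`, `beta > 0.002` (units/yr).
#' @param min_years minimum non-missing years per pixel (default 4).
#' @return list of class `trend_map`: matrices `zc`, `beta`, `s`, `n`,
#'   `class`, and `fractions` (list of named vectors `trend_class`,
#'   `beta_band`).
#' @export
trend_map <- function(annual_stack, z_threshold = 1.96,
                      beta_breaks = c(0, 0.001, 0.002), min_years = 4L) {
  d <- dim(annual_stack$values)
  if (d[1] < min_years) stop("need at least min_years annual layers")
  years <- annual_stack$time$year
  zc <- beta <- s <- matrix(NA_real_, d[2], d[3])
  nmat <- matrix(0L, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    x <- annual_stack$values[, i, j]
    ok <- is.finite(x)
    if (sum(ok) < min_years) next
    st <- mk_statistic(x[ok])
    s[i, j] <- st$S
    zc[i, j] <- if (st$S == 0) 0 else
      (st$S - sign(st$S)) / sqrt(st$var_s)
    beta[i, j] <- theil_sen(x[ok], years[ok])
    nmat[i, j] <- sum(ok)
  }
  valid <- is.finite(zc)
  if (!any(valid)) stop("no valid pixels")
  cls <- matrix(NA_character_, d[2], d[3])
  cls[valid] <- classify_trend(zc[valid], beta[valid], z_threshold)
  frac_class <- vapply(trend_classes,
                       function(k) mean(cls[valid] == k), numeric(1))
  b <- beta[valid]
  frac_beta <- c(
    "beta<=0" = mean(b <= 0),
    "0<beta<0.001" = mean(b > beta_breaks[1] & b < beta_breaks[2]),
    "0.001-0.002" = mean(b >= beta_breaks[2] & b <= beta_breaks[3]),
    "beta>0.002" = mean(b > beta_breaks[3]))
  structure(list(zc = zc, beta = beta, s = s, n = nmat, class = cls,
                 fractions = list(trend_class = frac_class,
                                  beta_band = frac_beta),
                 z_threshold = z_threshold),
            class = "trend_map")
}

#' Vegetation-cover level map
#'
#' Classifies mean annual NDVI into cover levels and reports area fractions
#' of valid pixels per level.
#'
#' @param mean_ndvi matrix of per-pixel mean annual NDVI.
#' @param breaks interior class breaks (default
#'   `c(0.1, 0.2, 0.4, 0.6, 0.8)`, six levels).
#' @return list with `class` (character matrix of interval labels) and
#'   `fractions` (named vector summing to 1 over valid pixels).
#' @export
level_map <- function(mean_ndvi, breaks = c(0.1, 0.2, 0.4, 0.6, 0.8)) {
  cut_lab <- cut(mean_ndvi, breaks = c(-Inf, breaks, Inf), right = FALSE)
  cls <- matrix(as.character(cut_lab), nrow(mean_ndvi), ncol(mean_ndvi))
  valid <- !is.na(cls)
  if (!any(valid)) stop("no valid pixels")
  fractions <- vapply(levels(cut_lab),
                      function(k) mean(cls[valid] == k), numeric(1))
  list(class = cls, fractions = fractions)
}
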