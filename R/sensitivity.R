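#' Detrend a monthly stack and z-score it by calendar month
#'
#' Removes the per-pixel linear trend (slope only: `x - slope * (t - tbar)`,
#' keeping the series level so the pixel mean survives for the
#' mean-variance variability step), then standardizes each calendar month
#' across years: `Z_{i,j} = (x_{i,j} - xbar_j) / sigma_j`, where `xbar_j`
#' and `sigma_j` are the mean and (sample) standard deviation of the
#' detrended variable in calendar month `j` over all years. By construction
#' every used pixel/month has mean 0 and SD 1 over the used years.
#'
#' @param stack a `monthly_stack`.
#' @param exclude optional logical array `[12, nrow, ncol]` of excluded
#'   pixel/calendar-month cells (e.g. from [low_cover_month_mask()]);
#'   excluded cells become nodata.
#' @param min_years minimum non-missing years a pixel/calendar-month needs
#'   to be standardized (default 3); months with fewer, or with zero
#'   variance, are set nodata and counted.
#' @return object of class `std_stack`: list with `z` (standardized cube),
#'   `detrended` (detrended cube, level retained), `slopes` (per-pixel
#'   trend, units per month), `time`, `dropped` (named counts of cells
#'   removed by each rule).
#' @export
detrend_and_standardize <- function(stack, exclude = NULL, min_years = 3L) {
  d <- dim(stack$values)
  nt <- d[1]; nr <- d[2]; nc <- d[3]
  months <- stack$time$month
  vals <- as_pixel_matrix(stack$values)     # [time, pixel]
  np <- nr * nc

  if (!is.null(exclude)) {
    if (!identical(dim(exclude), c(12L, nr, nc)))
      stop("exclude must be a [12, nrow, ncol] logical array")
    ex <- matrix(FALSE, nt, np)
    exm <- as_pixel_matrix(exclude)
    for (m in 1:12) ex[months == m, ] <-
      matrix(exm[m, ], sum(months == m), np, byrow = TRUE)
    vals[ex] <- NA_real_
    n_excluded <- sum(ex)
  } else n_excluded <- 0L

  tt <- seq_len(nt)
  slopes <- apply(vals, 2, function(y) ols_slope(tt, y))
  slopes[!is.finite(slopes)] <- 0
  detr <- vals - outer(tt - mean(tt), slopes)
  detr[is.na(vals)] <- NA_real_

  z <- matrix(NA_real_, nt, np)
  n_zero_sd <- 0L; n_few_years <- 0L
  for (m in 1:12) {
    idx <- which(months == m)
    if (length(idx) == 0L) next
    sub <- detr[idx, , drop = FALSE]
    n_ok <- colSums(is.finite(sub))
    mu <- colMeans(sub, na.rm = TRUE)
    sd_m <- apply(sub, 2, stats::sd, na.rm = TRUE)
    few <- n_ok > 0 & n_ok < min_years
    # zero variance up to floating-point residue of the detrending
    tiny <- 1e-10 * pmax(abs(mu), 1)
    zero <- is.finite(sd_m) & sd_m <= tiny & n_ok >= min_years
    usable <- n_ok >= min_years & is.finite(sd_m) & sd_m > tiny
    n_few_years <- n_few_years + sum(colSums(is.finite(sub[, few, drop = FALSE])))
    n_zero_sd <- n_zero_sd + sum(colSums(is.finite(sub[, zero, drop = FALSE])))
    zsub <- sweep(sweep(sub, 2, mu, "-"), 2, sd_m, "/")
    zsub[, !usable] <- NA_real_
    z[idx, ] <- zsub
  }

  structure(list(z = pixel_matrix_to_cube(z, nr, nc),
                 detrended = pixel_matrix_to_cube(detr, nr, nc),
                 slopes = matrix(slopes, nr, nc),
                 time = stack$time, variable = stack$variable,
                 dropped = c(excluded = n_excluded,
                             zero_sd = n_zero_sd,
                             too_few_years = n_few_years)),
            class = "std_stack")
}

# Time steps whose predecessor is the immediately preceding calendar month;
# returns an index vector `t` such that (t-1, t) are consecutive months.
consecutive_steps <- function(time) {
  key <- time$year * 12L + time$month
  which(c(FALSE, diff(key) == 1L))
}

std_values <- function(x) {
  if (inherits(x, "std_stack")) x$z
  else if (inherits(x, "monthly_stack")) x$values
  else if (is.list(x) && !is.null(x$z)) x$z
  else if (is.list(x) && !is.null(x$values)) x$values
  else x
}

#' Per-pixel lag-1 regression of NDVI anomalies on climate anomalies
#'
#' Fits, in every pixel, the no-intercept least-squares regression of the
#' standardized NDVI anomaly on its one-month-lagged value and the
#' contemporaneous standardized temperature, precipitation and TVDI
#' anomalies:
#' `NDVI_t = alpha NDVI_{t-1} + beta Tem_t + gamma Pre_t + delta TVDI_t + e_t`.
#' `alpha` is the vegetation memory coefficient (large `|alpha|` = strong
#' memory = low resilience); `beta`, `gamma`, `delta` measure the immediate
#' response magnitude to each climate variable. Only lag pairs of truly
#' consecutive calendar months with all five values valid enter the fit; no
#' gap bridging.
#'
#' @param ndvi_z,tem_z,pre_z,tvdi_z `std_stack`s (or bare cubes sharing the
#'   NDVI time index).
#' @param min_months minimum joint-valid lag pairs per pixel (default 36);
#'   pixels below it become nodata.
#' @return object of class `ar1_fit`: matrices `alpha`, `beta_tem`,
#'   `gamma_pre`, `delta_tvdi`, their standard errors (`se_*`), `n_months`,
#'   `r2`, `resid_var`, and `counts` (fitted / too-few / rank-deficient
#'   pixels).
#' @export
fit_ar1 <- function(ndvi_z, tem_z, pre_z, tvdi_z, min_months = 36L) {
  time <- if (inherits(ndvi_z, "std_stack")) ndvi_z$time else ndvi_z$time
  y_c <- std_values(ndvi_z); x1 <- std_values(tem_z)
  x2 <- std_values(pre_z); x3 <- std_values(tvdi_z)
  d <- dim(y_c)
  if (!all(vapply(list(x1, x2, x3), function(a) identical(dim(a), d),
                  logical(1))))
    stop("stacks are not on a common grid/time axis")
  nr <- d[2]; nc <- d[3]
  ym <- as_pixel_matrix(y_c); t1 <- as_pixel_matrix(x1)
  t2 <- as_pixel_matrix(x2); t3 <- as_pixel_matrix(x3)
  steps <- consecutive_steps(time)

  mats <- replicate(8, matrix(NA_real_, nr, nc), simplify = FALSE)
  names(mats) <- c("alpha", "beta_tem", "gamma_pre", "delta_tvdi",
                   "se_alpha", "se_beta_tem", "se_gamma_pre", "se_delta_tvdi")
  n_months <- matrix(0L, nr, nc)
  r2 <- resid_var <- matrix(NA_real_, nr, nc)
  n_fit <- 0L; n_few <- 0L; n_rank <- 0L

  for (p in seq_len(nr * nc)) {
    y <- ym[steps, p]
    X <- cbind(lag_ndvi = ym[steps - 1L, p], tem = t1[steps, p],
               pre = t2[steps, p], tvdi = t3[steps, p])
    ok <- is.finite(y) & rowSums(!is.finite(X)) == 0L
    n <- sum(ok)
    n_months[p] <- n
    if (n < min_months) { n_few <- n_few + 1L; next }
    Xo <- X[ok, , drop = FALSE]
    qr_x <- qr(Xo)
    if (qr_x$rank < 4L) { n_rank <- n_rank + 1L; next }
    cf <- qr.coef(qr_x, y[ok])
    res <- y[ok] - Xo %*% cf
    rss <- sum(res^2)
    s2 <- rss / (n - 4L)
    xtx_inv <- chol2inv(chol(crossprod(Xo)))
    se <- sqrt(diag(xtx_inv) * s2)
    tss <- sum(y[ok]^2)
    i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
    mats$alpha[i, j] <- cf[1]; mats$beta_tem[i, j] <- cf[2]
    mats$gamma_pre[i, j] <- cf[3]; mats$delta_tvdi[i, j] <- cf[4]
    mats$se_alpha[i, j] <- se[1]; mats$se_beta_tem[i, j] <- se[2]
    mats$se_gamma_pre[i, j] <- se[3]; mats$se_delta_tvdi[i, j] <- se[4]
    resid_var[i, j] <- s2
    r2[i, j] <- if (tss > 0) 1 - rss / tss else NA_real_
    n_fit <- n_fit + 1L
  }
  structure(c(mats, list(n_months = n_months, r2 = r2,
                         resid_var = resid_var,
                         counts = c(fitted = n_fit, too_few_months = n_few,
                                    rank_deficient = n_rank))),
            class = "ar1_fit")
}

#' Principal-components-regression variable importances
#'
#' Removes predictor collinearity before importance attribution: per pixel,
#' the (centered) predictors are decomposed into principal components, the
#' NDVI anomaly is regressed on the component scores, components whose
#' coefficients are significant at `p < p_threshold` are selected, and each
#' variable's importance is `|sum_k loading[v, k] * coef_k|` over the
#' selected components. The lagged-NDVI term can be included in the
#' decomposition (default) or left out; only the three climate importances
#' are returned as weights either way.
#'
#' @inheritParams fit_ar1
#' @param p_threshold component-selection significance level (default 0.1).
#' @param include_lag include `NDVI_{t-1}` among the decomposed predictors
#'   (default `TRUE`).
#' @return object of class `pcr_weights`: matrices `tem`, `pre`, `tvdi`
#'   (raw importances), `lag` (when included), logical matrix `zero_flag`
#'   (no significant component), `counts`.
#' @export
pcr_weights <- function(ndvi_z, tem_z, pre_z, tvdi_z, p_threshold = 0.1,
                        include_lag = TRUE, min_months = 36L) {
  time <- if (inherits(ndvi_z, "std_stack")) ndvi_z$time else ndvi_z$time
  y_c <- std_values(ndvi_z)
  preds <- lapply(list(tem_z, pre_z, tvdi_z), std_values)
  d <- dim(y_c); nr <- d[2]; nc <- d[3]
  ym <- as_pixel_matrix(y_c)
  pm <- lapply(preds, as_pixel_matrix)
  steps <- consecutive_steps(time)

  vars <- c(if (include_lag) "lag", "tem", "pre", "tvdi")
  k <- length(vars)
  out <- replicate(k, matrix(NA_real_, nr, nc), simplify = FALSE)
  names(out) <- vars
  zero_flag <- matrix(NA, nr, nc)
  n_fit <- 0L; n_few <- 0L; n_rank <- 0L

  for (p in seq_len(nr * nc)) {
    y <- ym[steps, p]
    X <- cbind(lag = ym[steps - 1L, p], tem = pm[[1]][steps, p],
               pre = pm[[2]][steps, p], tvdi = pm[[3]][steps, p])
    if (!include_lag) X <- X[, -1L, drop = FALSE]
    ok <- is.finite(y) & rowSums(!is.finite(X)) == 0L
    n <- sum(ok)
    if (n < min_months) { n_few <- n_few + 1L; next }
    Xc <- scale(X[ok, , drop = FALSE], center = TRUE, scale = FALSE)
    sv <- svd(Xc)
    if (min(sv$d) < 1e-10 * max(sv$d)) { n_rank <- n_rank + 1L; next }
    scores <- sv$u %*% diag(sv$d, k, k)
    yc <- y[ok] - mean(y[ok])
    # component scores are orthogonal: per-component OLS
    ss <- colSums(scores^2)
    coef <- colSums(scores * yc) / ss
    res <- yc - scores %*% coef
    df <- n - k - 1L
    s2 <- sum(res^2) / df
    tstat <- coef / sqrt(s2 / ss)
    pval <- 2 * stats::pt(-abs(tstat), df)
    sel <- pval < p_threshold
    i <- ((p - 1L) %% nr) + 1L; j <- ((p - 1L) %/% nr) + 1L
    zero_flag[i, j] <- !any(sel)
    imp <- if (any(sel))
      abs(sv$v[, sel, drop = FALSE] %*% coef[sel]) else rep(0, k)
    for (v in seq_len(k)) out[[vars[v]]][i, j] <- imp[v]
    n_fit <- n_fit + 1L
  }
  structure(c(out, list(zero_flag = zero_flag,
                        counts = c(fitted = n_fit, too_few_months = n_few,
                                   rank_deficient = n_rank),
                        p_threshold = p_threshold,
                        include_lag = include_lag)),
            class = "pcr_weights")
}

#' Rescale raw climate importances to climate weights
#'
#' A single global min-max — over all three climate variables and all valid
#' pixels jointly — maps the raw importances to `[0, 1]`; optionally each
#' pixel's three weights are then normalized to sum to 1 so the sensitivity
#' index is a convex combination.
#'
#' @param raw a [pcr_weights()] result, or a named list of matrices `tem`,
#'   `pre`, `tvdi`.
#' @param normalize per-pixel sum-to-1 normalization (default `TRUE`).
#' @return object of class `climate_weights`: matrices `tem`, `pre`, `tvdi`
#'   (normalized when requested), `rescaled` (the `[0, 1]` values before
#'   normalization), flags `normalized`, `degenerate`, count `n_zero_sum`.
#' @export
rescale_weights <- function(raw, normalize = TRUE) {
  w <- list(tem = raw$tem, pre = raw$pre, tvdi = raw$tvdi)
  allv <- unlist(w)
  allv <- allv[is.finite(allv)]
  if (length(allv) == 0L) stop("no valid pixels")
  mn <- min(allv); mx <- max(allv)
  degenerate <- mx <= mn
  rescaled <- lapply(w, function(m) {
    if (degenerate) ifelse(is.finite(m), 1 / 3, NA_real_)
    else (m - mn) / (mx - mn)
  })
  out <- rescaled
  n_zero <- 0L
  if (normalize) {
    ssum <- rescaled$tem + rescaled$pre + rescaled$tvdi
    zero <- is.finite(ssum) & ssum == 0
    n_zero <- sum(zero)
    out <- lapply(rescaled, function(m) {
      r <- m / ssum
      r[zero] <- 1 / 3
      r
    })
  }
  structure(list(tem = out$tem, pre = out$pre, tvdi = out$tvdi,
                 rescaled = rescaled, normalized = normalize,
                 degenerate = degenerate, n_zero_sum = n_zero),
            class = "climate_weights")
}

#' Mean-variance-residual variability scores
#'
#' For one variable: each pixel contributes the mean and variance of its
#' detrended monthly series; an across-pixel OLS of variance on mean
#' removes the systematic mean-variance relationship, and the residuals are
#' min-max standardized to `[0, 100]`. High scores mark pixels whose
#' temporal variance is large for their mean level.
#'
#' @param detrended numeric cube `[time, nrow, ncol]` of detrended values
#'   (e.g. `std_stack$detrended`).
#' @param min_obs minimum non-missing months per pixel (default 24).
#' @return matrix of scores in `[0, 100]` with attribute `fit`
#'   (the mean-variance regression coefficients); all-50 with attribute
#'   `degenerate = TRUE` when the residual range collapses.
#' @export
variability_scores <- function(detrended, min_obs = 24L) {
  d <- dim(detrended)
  m <- as_pixel_matrix(detrended)
  n_ok <- colSums(is.finite(m))
  mu <- colMeans(m, na.rm = TRUE)
  v <- apply(m, 2, stats::var, na.rm = TRUE)
  use <- n_ok >= min_obs & is.finite(mu) & is.finite(v)
  if (sum(use) < 10L) stop("fewer than 10 valid pixels")
  slope <- ols_slope(mu[use], v[use])
  if (is.na(slope)) slope <- 0   # all means equal: line reduces to the level
  icept <- mean(v[use]) - slope * mean(mu[use])
  resid <- rep(NA_real_, length(mu))
  resid[use] <- v[use] - (icept + slope * mu[use])
  rng <- range(resid[use])
  if (diff(rng) <= 1e-10 * max(abs(v[use]), 1)) {
    scores <- ifelse(use, 50, NA_real_)
    degenerate <- TRUE
  } else {
    scores <- 100 * (resid - rng[1]) / (rng[2] - rng[1])
    degenerate <- FALSE
  }
  out <- matrix(scores, d[2], d[3])
  attr(out, "fit") <- c(intercept = icept, slope = slope)
  attr(out, "degenerate") <- degenerate
  out
}

#' Log-ratio sensitivity score of NDVI vs one climate variable
#'
#' `log10((V_NDVI + offset) / (V_climate + offset))` per pixel: positive
#' where NDVI varies more than the climate variable (sensitive vegetation),
#' negative where less. The offset (default 1) keeps zero scores finite.
#'
#' @param v_ndvi,v_climate variability-score matrices in `[0, 100]`.
#' @param offset additive offset (default 1).
#' @return matrix of dimensionless log10 ratios.
#' @export
sensitivity_scores <- function(v_ndvi, v_climate, offset = 1) {
  log10((v_ndvi + offset) / (v_climate + offset))
}

#' Vegetation sensitivity index
#'
#' The weighted sum of the per-variable sensitivity scores,
#' `VSI = Tem_wei * Tem_sens + Pre_wei * Pre_sens + TVDI_wei * TVDI_sens`,
#' min-max rescaled over the map to the 0 (low sensitivity) - 100 (high
#' sensitivity) display range. The raw weighted sum is returned alongside.
#'
#' @param weights a [rescale_weights()] result (normalized weights).
#' @param sens named list of sensitivity-score matrices `tem`, `pre`,
#'   `tvdi`.
#' @return object of class `vsi_map`: `vsi` (matrix in `[0, 100]`), `raw`
#'   (pre-rescale weighted sums), `degenerate` flag.
#' @export
compute_vsi <- function(weights, sens) {
  raw <- weights$tem * sens$tem + weights$pre * sens$pre +
    weights$tvdi * sens$tvdi
  ok <- is.finite(raw)
  if (!any(ok)) stop("all pixels are nodata")
  rng <- range(raw[ok])
  if (diff(rng) <= 0) {
    vsi <- ifelse(ok, 50, NA_real_)
    degenerate <- TRUE
  } else {
    vsi <- 100 * (raw - rng[1]) / (rng[2] - rng[1])
    degenerate <- FALSE
  }
  structure(list(vsi = vsi, raw = raw, degenerate = degenerate),
            class = "vsi_map")
}

#' Memory-effect class map
#'
#' Classifies the lag-1 coefficient into weak (`alpha < 0.4`), moderate
#' (`0.4 <= alpha < 0.6`) and strong (`alpha >= 0.6`) memory, with area
#' fractions of valid pixels. Intervals are half-open; a boundary value
#' joins the upper bin's lower edge.
#'
#' @param alpha matrix of lag-1 coefficients.
#' @param breaks two interior breakpoints (default `c(0.4, 0.6)`).
#' @return list with `class` (character matrix) and `fractions` (named
#'   vector summing to 1).
#' @export
memory_map <- function(alpha, breaks = c(0.4, 0.6)) {
  labs <- c(sprintf("alpha<%.1f", breaks[1]),
            sprintf("%.1f-%.1f", breaks[1], breaks[2]),
            sprintf("alpha>=%.1f", breaks[2]))
  cls <- matrix(NA_character_, nrow(alpha), ncol(alpha))
  cls[alpha < breaks[1]] <- labs[1]
  cls[alpha >= breaks[1] & alpha < breaks[2]] <- labs[2]
  cls[alpha >= breaks[2]] <- labs[3]
  valid <- !is.na(cls)
  fractions <- vapply(labs, function(k) mean(cls[valid] == k), numeric(1))
  names(fractions) <- labs
  list(class = cls, fractions = fractions)
}

#' Regression of the memory coefficient on an environmental gradient
#'
#' Fits `alpha` against a growing-season covariate, either logarithmically
#' (`alpha ~ log(x)`; NDVI and TVDI gradients) or quadratically
#' (`alpha ~ x + x^2`; precipitation and temperature gradients).
#'
#' @param alpha matrix of lag-1 coefficients.
#' @param covariate matrix of the gradient variable (growing-season means).
#' @param form `"logarithmic"` or `"quadratic"`.
#' @return list with `form`, `coefficients`, `r2`, `p` (overall F), `n`,
#'   `n_dropped` (non-positive covariates under the logarithmic form).
#' @export
gradient_regression <- function(alpha, covariate,
                                form = c("logarithmic", "quadratic")) {
  form <- match.arg(form)
  a <- as.numeric(alpha); x <- as.numeric(covariate)
  ok <- is.finite(a) & is.finite(x)
  n_dropped <- 0L
  if (form == "logarithmic") {
    drop <- ok & x <= 0
    n_dropped <- sum(drop)
    ok <- ok & x > 0
  }
  if (sum(ok) < 10L) stop("fewer than 10 paired pixels")
  a <- a[ok]; x <- x[ok]
  X <- switch(form,
    logarithmic = cbind(`(Intercept)` = 1, `log(x)` = log(x)),
    quadratic = cbind(`(Intercept)` = 1, x = x, `x^2` = x^2))
  fit <- stats::lm.fit(X, a)
  rss <- sum(fit$residuals^2)
  tss <- sum((a - mean(a))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  df1 <- ncol(X) - 1L; df2 <- length(a) - ncol(X)
  fstat <- if (rss > 0) ((tss - rss) / df1) / (rss / df2) else Inf
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  list(form = form, coefficients = fit$coefficients, r2 = r2, p = p,
       n = length(a), n_dropped = n_dropped)
}

#' Growing-season mean of a stack
#'
#' Per-pixel mean over the configured growing-season calendar months across
#' all years.
#'
#' @param stack a `monthly_stack`.
#' @param months calendar months of the growing season (default May to
#'   September).
#' @return matrix of means.
#' @export
growing_season_mean <- function(stack, months = 5:9) {
  idx <- which(stack$time$month %in% months)
  if (length(idx) == 0L) stop("no growing-season months in the stack")
  apply(stack$values[idx, , , drop = FALSE], c(2, 3), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}
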