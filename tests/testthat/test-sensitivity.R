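test_that("monthly z-scores have exact zero mean and unit SD per calendar month", {
  sc <- tiny_scene(seed = 41, n = 5, years = 6)
  std <- detrend_and_standardize(sc$clim$tem)
  for (m in c(1, 6, 12)) {
    idx <- which(std$time$month == m)
    sub <- std$z[idx, , ]
    mu <- apply(sub, c(2, 3), mean)
    sdv <- apply(sub, c(2, 3), sd)
    expect_lt(max(abs(mu)), 1e-8)
    expect_lt(max(abs(sdv - 1)), 1e-6)
  }
})

test_that("standardization plugs in as (x - mean) / sd and honors exclusions", {
  # one pixel, 3 years; July values chosen so year 1 gives Z = 2.0 exactly:
  # detrended July values (0.6, 0.5, 0.4) have mean 0.5; rescale sd to 0.05
  vals <- array(0.5, dim = c(36, 1, 1))
  jul <- which(rep(1:12, 3) == 7)
  vals[jul, 1, 1] <- c(0.6, 0.5, 0.4)
  st <- cube_stack(vals, "ndvi")
  std <- detrend_and_standardize(st)
  z_jul <- std$z[jul, 1, 1]
  x <- std$detrended[jul, 1, 1]
  expect_equal(z_jul, (x - mean(x)) / sd(x))

  ex <- array(FALSE, dim = c(12, 1, 1))
  ex[7, 1, 1] <- TRUE
  std_ex <- detrend_and_standardize(st, exclude = ex)
  expect_true(all(is.na(std_ex$z[jul, 1, 1])))
  expect_gt(std_ex$dropped["excluded"], 0)
})

test_that("pure linear trends detrend to zero-variance months that become nodata", {
  vals <- array(rep(seq(0, 1, length.out = 48), 4), dim = c(48, 2, 2))
  st <- cube_stack(vals, "tem")
  std <- detrend_and_standardize(st)
  expect_lt(max(abs(std$detrended - mean(vals[, 1, 1]))), 1e-10)
  expect_true(all(is.na(std$z)))
  expect_gt(std$dropped["zero_sd"], 0)
})

test_that("lag-1 fits equal the brute-force normal-equations solve", {
  set.seed(51)
  sim <- simulate_ar1_pixels(100, 120, seed = 51)
  fit <- fit_ar1(pixel_std(sim$ndvi), pixel_std(sim$tem),
                 pixel_std(sim$pre), pixel_std(sim$moist))
  steps <- 2:120
  worst <- 0
  for (p in 1:100) {
    y <- sim$ndvi[steps, p]
    X <- cbind(sim$ndvi[steps - 1, p], sim$tem[steps, p],
               sim$pre[steps, p], sim$moist[steps, p])
    cf <- oracle_lm_noint(X, y)
    got <- c(fit$alpha[p, 1], fit$beta_tem[p, 1],
             fit$gamma_pre[p, 1], fit$delta_tvdi[p, 1])
    worst <- max(worst, max(abs(got - cf)))
  }
  expect_lt(worst, 1e-8)
})

test_that("lag pairs spanning excluded months are dropped, not bridged", {
  sim <- simulate_ar1_pixels(1, 120, seed = 3)
  std <- pixel_std(sim$ndvi)
  std$z[c(30, 60, 90), 1, 1] <- NA   # knock out three NDVI months
  others <- pixel_std(sim$tem)
  fit <- fit_ar1(std, others, pixel_std(sim$pre), pixel_std(sim$moist))
  # each missing month removes two lag pairs (as response and as lag)
  expect_equal(fit$n_months[1, 1], 119L - 6L)
})

test_that("null responses give coefficients consistent with zero at 2 SE", {
  set.seed(61)
  n <- 120; P <- 100
  fit <- fit_ar1(pixel_std(matrix(rnorm(n * P), n)),
                 pixel_std(matrix(rnorm(n * P), n)),
                 pixel_std(matrix(rnorm(n * P), n)),
                 pixel_std(matrix(rnorm(n * P), n)))
  cover <- c(abs(fit$beta_tem) < 2 * fit$se_beta_tem,
             abs(fit$gamma_pre) < 2 * fit$se_gamma_pre,
             abs(fit$delta_tvdi) < 2 * fit$se_delta_tvdi)
  expect_gt(mean(cover), 0.9)   # nominal 95% coverage
})

test_that("pixels with too few joint-valid months are dropped and counted", {
  sim <- simulate_ar1_pixels(2, 120, seed = 5)
  std <- pixel_std(sim$ndvi)
  std$z[1:100, 2, 1] <- NA
  fit <- fit_ar1(std, pixel_std(sim$tem), pixel_std(sim$pre),
                 pixel_std(sim$moist))
  expect_true(is.na(fit$alpha[2, 1]))
  expect_equal(unname(fit$counts["too_few_months"]), 1L)
  expect_equal(sum(fit$counts), 2L)   # drop accounting reconciles
})

test_that("PCR importances reduce to |OLS coefficients| under an orthogonal design", {
  set.seed(71)
  n <- 240
  X <- qr.Q(qr(matrix(rnorm(n * 4), n))) * sqrt(n)   # uncorrelated columns
  b <- c(0.5, 0.2, 0.3, -0.2)
  y <- X %*% b + rnorm(n, 0, 0.1)
  wrap <- function(v) pixel_std(matrix(v, n))
  # feed the columns as tem/pre/tvdi; keep every component
  pw <- pcr_weights(wrap(y), wrap(X[, 2]), wrap(X[, 3]), wrap(X[, 4]),
                    p_threshold = 1, include_lag = FALSE)
  rows <- 2:n                     # first step has no lag predecessor
  Xc <- scale(X[rows, 2:4], center = TRUE, scale = FALSE)
  ols <- oracle_lm_noint(Xc, as.numeric(y)[rows] - mean(y[rows]))
  got <- c(pw$tem[1, 1], pw$pre[1, 1], pw$tvdi[1, 1])
  expect_equal(got, abs(as.numeric(ols)), tolerance = 1e-6)
})

test_that("a temperature-driven response yields the largest temperature importance", {
  set.seed(72)
  sim <- simulate_ar1_pixels(40, 228, alpha = 0.2, beta = 0.6, gamma = 0.05,
                             delta = 0.05, noise_sd = 0.3, seed = 72)
  pw <- pcr_weights(pixel_std(sim$ndvi), pixel_std(sim$tem),
                    pixel_std(sim$pre), pixel_std(sim$moist))
  expect_gt(median(pw$tem, na.rm = TRUE), median(pw$pre, na.rm = TRUE))
  expect_gt(median(pw$tem, na.rm = TRUE), median(pw$tvdi, na.rm = TRUE))
})

test_that("pure-noise responses raise the zero-weight flag at roughly the selection rate", {
  set.seed(73)
  n <- 120; P <- 200
  pw <- pcr_weights(pixel_std(matrix(rnorm(n * P), n)),
                    pixel_std(matrix(rnorm(n * P), n)),
                    pixel_std(matrix(rnorm(n * P), n)),
                    pixel_std(matrix(rnorm(n * P), n)))
  # P(no component under p < 0.1) ~ 0.9^4 ~ 0.66
  expect_gt(mean(pw$zero_flag, na.rm = TRUE), 0.5)
  zero_pix <- which(pw$zero_flag)[1]
  expect_equal(pw$tem[zero_pix], 0)
})

test_that("weight rescaling is a joint global min-max with optional convex normalization", {
  raw <- list(tem = matrix(c(2, 4), 1), pre = matrix(c(2, 1), 1),
              tvdi = matrix(c(2, 3), 1))
  w <- rescale_weights(raw, normalize = FALSE)
  expect_equal(w$rescaled$pre[1, 2], 0)    # global min -> 0
  expect_equal(w$rescaled$tem[1, 2], 1)    # global max -> 1
  expect_true(all(unlist(w$rescaled) >= 0 & unlist(w$rescaled) <= 1))

  wn <- rescale_weights(list(tem = matrix(2), pre = matrix(2),
                             tvdi = matrix(2)))
  expect_equal(c(wn$tem, wn$pre, wn$tvdi), rep(1 / 3, 3))
  expect_true(wn$degenerate)

  wr <- rescale_weights(raw, normalize = TRUE)
  sums <- wr$tem + wr$pre + wr$tvdi
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
})

test_that("variability scores follow the mean-variance-residual min-max construction", {
  set.seed(81)
  cube <- array(rnorm(48 * 6 * 6, mean = rep(1:6, each = 48 * 6)),
                dim = c(48, 6, 6))
  sc <- variability_scores(cube)
  expect_true(all(sc >= 0 & sc <= 100, na.rm = TRUE))
  expect_equal(max(sc, na.rm = TRUE), 100)
  expect_equal(min(sc, na.rm = TRUE), 0)
  # independent reconstruction
  m <- matrix(cube, 48)
  mu <- colMeans(m); v <- apply(m, 2, var)
  r <- resid(lm(v ~ mu))
  want <- 100 * (r - min(r)) / diff(range(r))
  expect_equal(as.numeric(sc), as.numeric(want), tolerance = 1e-8)

  # pixels exactly on the line var = 2 * mean -> degenerate -> all 50
  line <- array(0, dim = c(30, 4, 4))
  for (p in 1:16) {
    u <- scale(rnorm(30))[, 1]              # sample mean 0, variance 1
    line[, ((p - 1) %% 4) + 1, ((p - 1) %/% 4) + 1] <- p + sqrt(2 * p) * u
  }
  sl <- variability_scores(line, min_obs = 10)
  expect_true(attr(sl, "degenerate"))
  expect_true(all(sl == 50, na.rm = TRUE))
})

test_that("log-ratio sensitivity scores obey their identities", {
  expect_equal(sensitivity_scores(matrix(40), matrix(40)), matrix(0))
  expect_equal(sensitivity_scores(matrix(9), matrix(0)), matrix(1))
  expect_lt(sensitivity_scores(matrix(10), matrix(60))[1, 1], 0)
})

test_that("VSI is the weighted sensitivity sum rescaled to [0, 100]", {
  s <- list(tem = matrix(runif(25), 5), pre = matrix(runif(25), 5),
            tvdi = matrix(runif(25), 5))
  w1 <- list(tem = matrix(1, 5, 5), pre = matrix(0, 5, 5),
             tvdi = matrix(0, 5, 5))
  v <- compute_vsi(w1, s)
  expect_equal(v$raw, s$tem)
  expect_equal(min(v$vsi), 0)
  expect_equal(max(v$vsi), 100)

  weq <- list(tem = matrix(0.2, 5, 5), pre = matrix(0.3, 5, 5),
              tvdi = matrix(0.5, 5, 5))
  same <- list(tem = s$tem, pre = s$tem, tvdi = s$tem)
  expect_equal(compute_vsi(weq, same)$raw, s$tem)
  expect_error(compute_vsi(w1, list(tem = matrix(NA_real_, 5, 5),
                                    pre = matrix(NA_real_, 5, 5),
                                    tvdi = matrix(NA_real_, 5, 5))),
               "nodata")
})

test_that("memory classes use half-open intervals and their fractions sum to one", {
  a <- matrix(c(0.5, 0.4, 0.6, 0.39, 0.61, NA), 2)
  mm <- memory_map(a)
  expect_equal(mm$class[1, 1], "0.4-0.6")
  expect_equal(mm$class[2, 1], "0.4-0.6")    # 0.4 joins the middle class
  expect_equal(mm$class[1, 2], "alpha>=0.6") # 0.6 joins the strong class
  expect_equal(mm$class[2, 2], "alpha<0.4")
  expect_equal(sum(mm$fractions), 1, tolerance = 1e-12)
  all05 <- memory_map(matrix(0.5, 3, 3))
  expect_equal(unname(all05$fractions["0.4-0.6"]), 1)
})

test_that("gradient regressions recover seeded logarithmic structure and fit exact quadratics", {
  set.seed(91)
  x <- runif(500, 0.05, 0.9)
  a <- 0.8 - 0.2 * log(x) + rnorm(500, 0, 0.02)
  g <- gradient_regression(matrix(a, 20), matrix(x, 20), "logarithmic")
  expect_equal(unname(g$coefficients[1]), 0.8, tolerance = 0.02)
  expect_equal(unname(g$coefficients[2]), -0.2, tolerance = 0.02)
  expect_gt(g$r2, 0.9)
  expect_lt(g$p, 0.05)

  xq <- seq(-2, 2, length.out = 50)
  aq <- 1 + 0.5 * xq - 0.3 * xq^2
  gq <- gradient_regression(matrix(aq, 5), matrix(xq, 5), "quadratic")
  expect_equal(gq$r2, 1, tolerance = 1e-10)

  xb <- c(-x[1:20], x[21:500])
  gb <- gradient_regression(matrix(a, 20), matrix(xb, 20), "logarithmic")
  expect_equal(gb$n_dropped, 20L)
  expect_error(gradient_regression(matrix(a[1:5]), matrix(x[1:5]),
                                   "logarithmic"), "10 paired")
})

test_that("growing-season means average the configured calendar months", {
  cube <- array(0, dim = c(24, 1, 1))
  cube[, 1, 1] <- rep(1:12, 2)
  st <- cube_stack(cube, "tem")
  expect_equal(growing_season_mean(st, 5:9)[1, 1], mean(5:9))
  expect_equal(growing_season_mean(st, 7)[1, 1], 7)
})

test_that("raising the generative temperature response raises the temperature weight", {
  med_w <- function(beta, seed) {
    sim <- simulate_ar1_pixels(40, 228, alpha = 0.4, beta = beta,
                               gamma = 0.2, delta = -0.2, noise_sd = 0.3,
                               seed = seed)
    pw <- pcr_weights(pixel_std(sim$ndvi), pixel_std(sim$tem),
                      pixel_std(sim$pre), pixel_std(sim$moist))
    median(rescale_weights(pw)$tem, na.rm = TRUE)
  }
  expect_gt(med_w(0.6, 5), med_w(0.1, 5))
})
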