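test_that("noise- and trend-free climate stacks are exactly periodic and seeded runs are bit-identical", {
  cfg <- synth_config(4, 4, n_years = 3, seed = 5,
                      linear_trend = c(tem = 0, pre = 0, lst = 0, ndvi = 0),
                      climate_noise_sd = c(tem = 0, pre = 0, lst = 0))
  clim <- generate_climate_stacks(cfg)
  for (s in clim) {
    v <- s$values
    expect_equal(v[1:12, , ], v[13:24, , ])
    expect_equal(v[1:12, , ], v[25:36, , ])
  }
  clim2 <- generate_climate_stacks(cfg)
  expect_identical(clim$tem$values, clim2$tem$values)
  expect_identical(clim$lst$values, clim2$lst$values)
})

test_that("a configured temperature trend is recovered by OLS on annual means", {
  cfg <- synth_config(3, 3, n_years = 19, seed = 2,
                      linear_trend = c(tem = 0.02, pre = 0, lst = 0, ndvi = 0),
                      climate_noise_sd = c(tem = 0, pre = 0, lst = 0))
  tem <- generate_climate_stacks(cfg)$tem
  x <- tem$values[, 1, 1]
  annual <- tapply(x, rep(1:19, each = 12), mean)
  slope <- coef(lm(annual ~ seq_len(19)))[2]
  expect_equal(unname(slope), 0.02, tolerance = 1e-10)
})

test_that("NDVI equals its seasonal climatology when all coefficients and noise are zero", {
  cfg <- synth_config(5, 5, n_years = 3, seed = 9,
                      true_alpha = 0, true_beta = 0, true_gamma = 0,
                      true_delta = 0, noise_sd = 0)
  clim <- generate_climate_stacks(cfg)
  nd <- generate_ndvi(cfg, clim$tem, clim$pre, clim$lst)
  expect_equal(nd$values, ndvi_climatology(cfg)$values)
})

test_that("stronger memory raises the lag-1 autocorrelation of generated anomalies", {
  ac1 <- function(z) cor(z[-1], z[-length(z)])
  hi <- simulate_ar1_pixels(20, 240, alpha = 0.9, noise_sd = 0.3, seed = 3)
  lo <- simulate_ar1_pixels(20, 240, alpha = 0.1, noise_sd = 0.3, seed = 3)
  expect_gt(mean(apply(hi$ndvi, 2, ac1)), mean(apply(lo$ndvi, 2, ac1)))
})

test_that("anomaly variance converges to the stationary value on long series", {
  sim <- simulate_ar1_pixels(1, 10000, alpha = 0.6, beta = 0, gamma = 0,
                             delta = 0, noise_sd = 0.3, seed = 4)
  expect_equal(var(sim$ndvi[, 1]), 0.3^2 / (1 - 0.6^2), tolerance = 0.1)
})

test_that("seeded parameter recovery from generated pixels is accurate", {
  sim <- simulate_ar1_pixels(50, 228, alpha = 0.5, beta = 0.2, gamma = 0.3,
                             delta = -0.2, noise_sd = 0.3, seed = 11)
  fit <- fit_ar1(pixel_std(sim$ndvi), pixel_std(sim$tem),
                 pixel_std(sim$pre), pixel_std(sim$moist))
  expect_lt(max(abs(fit$alpha - 0.5)), 0.10)
  expect_lt(max(abs(fit$beta_tem - 0.2)), 0.10)
  expect_lt(max(abs(fit$gamma_pre - 0.3)), 0.10)
  expect_lt(max(abs(fit$delta_tvdi + 0.2)), 0.10)
})

test_that("noiseless generative output yields exact downstream coefficient recovery", {
  cfg <- synth_config(6, 6, n_years = 10, seed = 13, noise_sd = 0)
  clim <- generate_climate_stacks(cfg)
  nd <- generate_ndvi(cfg, clim$tem, clim$pre, clim$lst)
  tr <- attr(nd, "truth")
  wrap <- function(z) list(z = z, time = nd$time)
  fit <- fit_ar1(wrap(tr$z_ndvi), wrap(tr$z_tem), wrap(tr$z_pre),
                 wrap(tr$z_moist))
  expect_lt(max(abs(fit$alpha - cfg$true_alpha)), 1e-6)
  expect_lt(max(abs(fit$beta_tem - cfg$true_beta)), 1e-6)
  expect_lt(max(abs(fit$gamma_pre - cfg$true_gamma)), 1e-6)
  expect_lt(max(abs(fit$delta_tvdi - cfg$true_delta)), 1e-6)
})

test_that("gap injection flags an exact count, is seeded, and is the identity at zero fraction", {
  vals <- array(runif(100 * 10 * 10), dim = c(100, 10, 10))
  ck <- monthly_clock(100 / 12)   # fractional years not needed; build directly
  years <- rep(2000:2008, each = 12)[1:100]
  months <- rep(1:12, 9)[1:100]
  st <- monthly_stack(vals, years, months, "lst", "K")
  g <- inject_gaps(st, 0.2, seed = 21)
  expect_identical(sum(is.na(g$values)), 2000L)
  expect_identical(sum(attr(g, "gap_mask")), 2000L)
  g2 <- inject_gaps(st, 0.2, seed = 21)
  expect_identical(g$values, g2$values)
  g0 <- inject_gaps(st, 0, seed = 21)
  expect_identical(g0$values, st$values)
  # withheld truth is recoverable through the mask
  expect_true(all(is.na(g$values[attr(g, "gap_mask")])))
  expect_identical(st$values[!attr(g, "gap_mask")],
                   g$values[!attr(g, "gap_mask")])
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(0, 4), "positive")
  expect_error(synth_config(4, 4, true_alpha = 1), "stationary")
  expect_error(synth_config(4, 4, noise_sd = -1), "noise_sd")
  expect_error(synth_config(4, 4, gap_fraction = 1), "gap_fraction")
  expect_error(simulate_ar1_pixels(5, 50, alpha = 1.2), "alpha")
})
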