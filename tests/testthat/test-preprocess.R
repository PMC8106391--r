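test_that("Savitzky-Golay reproduces polynomials and matches closed-form weights", {
  t <- 0:19
  expect_equal(savitzky_golay(t^2, window = 7, order = 2), t^2,
               tolerance = 1e-9)
  expect_equal(sg_central_weights(5, 2), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
  expect_equal(sg_central_weights(7, 3), oracle_sg_weights(7, 3),
               tolerance = 1e-12)
  expect_equal(sg_central_weights(9, 2), oracle_sg_weights(9, 2),
               tolerance = 1e-12)
  expect_equal(savitzky_golay(rep(3, 30), 5, 2), rep(3, 30))
})

test_that("Savitzky-Golay is linear and handles edge modes and bad inputs", {
  set.seed(1)
  x <- rnorm(40); y <- rnorm(40)
  f <- function(v) savitzky_golay(v, 7, 2)
  expect_equal(f(2 * x + 3 * y), 2 * f(x) + 3 * f(y), tolerance = 1e-10)
  for (mode in c("reflect", "nearest")) {
    out <- savitzky_golay(x, 5, 2, edge_mode = mode)
    expect_length(out, length(x))
    expect_equal(out[10:30], savitzky_golay(x, 5, 2)[10:30],
                 tolerance = 1e-10)  # interior agrees across modes
  }
  expect_error(savitzky_golay(x, 6, 2), "odd")
  expect_error(savitzky_golay(x, 7, 7), "order")
  expect_error(savitzky_golay(rnorm(5), 7, 2), "shorter")
  # interior gaps interpolated before filtering
  xg <- x; xg[15] <- NA
  expect_false(anyNA(savitzky_golay(xg, 5, 2)))
})

test_that("maximum value composite takes per-period maxima, ignores nodata, and is idempotent", {
  # two sub-monthly composites in one month
  vals <- array(NA_real_, dim = c(4, 1, 1))
  vals[, 1, 1] <- c(0.3, 0.5, NA, 0.4)
  st <- monthly_stack(vals, years = c(2000, 2000, 2000, 2000),
                      months = c(1, 1, 2, 2), days = c(1, 16, 1, 16))
  mo <- maximum_value_composite(st, "month")
  expect_equal(mo$values[, 1, 1], c(0.5, 0.4))

  # annual from 12 monthly values
  v12 <- array(seq(0.1, 0.66, length.out = 12), dim = c(12, 1, 1))
  st12 <- cube_stack(v12, "ndvi")
  yr <- maximum_value_composite(st12, "year")
  expect_equal(yr$values[1, 1, 1], 0.66)
  expect_true(is.na(yr$time$month[1]))

  # idempotence on a gappy monthly stack
  set.seed(2)
  cube <- array(runif(24 * 3 * 3), dim = c(24, 3, 3))
  cube[sample(length(cube), 30)] <- NA
  stack <- cube_stack(cube, "ndvi")
  once <- maximum_value_composite(stack, "month")
  twice <- maximum_value_composite(once, "month")
  expect_identical(once$values, twice$values)

  # all-missing group becomes nodata
  cube[1:12, 2, 2] <- NA
  st2 <- cube_stack(cube, "ndvi")
  expect_true(is.na(maximum_value_composite(st2, "year")$values[1, 2, 2]))
})

test_that("DCT-PLS preserves constants, reproduces gap-free data as s -> 0, and fills accurately", {
  const <- matrix(5, 12, 15)
  expect_equal(dct_pls_fill(const, s = 10)$filled, const, tolerance = 1e-9)
  gappy <- const
  gappy[sample(length(gappy), 0.3 * length(gappy))] <- NA
  expect_equal(dct_pls_fill(gappy)$filled, const, tolerance = 1e-6)

  set.seed(3)
  smooth <- outer(1:16, 1:20, function(i, j) sin(i / 3) + cos(j / 4))
  noisy <- smooth + rnorm(length(smooth), 0, 0.01)
  expect_equal(dct_pls_fill(noisy, s = 1e-10)$filled, noisy,
               tolerance = 1e-8)

  # seeded sinusoid with noise and 20% gaps: gap-cell RMSE below the noise SD
  set.seed(4)
  truth <- outer(1:64, 1:64, function(i, j)
    sin(2 * pi * i / 32) * cos(2 * pi * j / 32))
  obs <- truth + rnorm(length(truth), 0, 0.1)
  gaps <- sample(length(obs), 0.2 * length(obs))
  obs[gaps] <- NA
  fit <- dct_pls_fill(obs)
  rmse <- sqrt(mean((fit$filled[gaps] - truth[gaps])^2))
  expect_lt(rmse, 0.1)
  expect_gt(fit$s_opt, 0)
  # smoother output stays within the observed range up to a small overshoot
  rng <- range(obs, na.rm = TRUE)
  overshoot <- max(rng[1] - min(fit$filled), max(fit$filled) - rng[2], 0)
  expect_lt(overshoot, 0.05 * diff(rng))
})

test_that("DCT-PLS rejects unusable grids", {
  expect_error(dct_pls_fill(matrix(NA_real_, 5, 5)), "missing")
  sparse <- matrix(NA_real_, 10, 10)
  sparse[1:5] <- 1
  expect_error(dct_pls_fill(sparse), "10%")
})

test_that("nearest-neighbour resampling replicates blocks and scales the geotransform", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_identical(resample_nearest(m, 1), m)
  r <- resample_nearest(m, 4)
  expect_equal(dim(r), c(8L, 8L))
  expect_true(all(r[1:4, 1:4] == 1))
  expect_true(all(r[5:8, 5:8] == 4))
  m[1, 2] <- NA
  expect_true(all(is.na(resample_nearest(m, 3)[1:3, 4:6])))

  cube <- array(runif(12 * 2 * 2), dim = c(12, 2, 2))
  st <- cube_stack(cube, "lst", "K")
  rs <- resample_nearest(st, 2)
  expect_equal(dim(rs$values), c(12L, 4L, 4L))
  expect_equal(rs$geotransform[2], st$geotransform[2] / 2)
})

test_that("low-cover masking excludes calendar months by climatological mean at the 0.1 threshold", {
  # pixel 1: all months mean 0.05 -> fully excluded
  # pixel 2: Jan mean 0.09 (excluded), Jul mean 0.11 (kept)
  cube <- array(0.5, dim = c(24, 1, 2))
  cube[, 1, 1] <- 0.05
  jan <- which(rep(1:12, 2) == 1); jul <- which(rep(1:12, 2) == 7)
  cube[jan, 1, 2] <- 0.09
  cube[jul, 1, 2] <- 0.11
  st <- cube_stack(cube, "ndvi")
  mask <- low_cover_month_mask(st)
  expect_true(all(mask[, 1, 1]))
  expect_true(mask[1, 1, 2])
  expect_false(mask[7, 1, 2])
  expect_false(any(low_cover_month_mask(st, threshold = 0)))
  one_year <- monthly_stack(cube[1:12, , , drop = FALSE],
                            rep(2000L, 12), 1:12, "ndvi")
  expect_error(low_cover_month_mask(one_year), "2 years")
})

test_that("masking more months never increases downstream regression observations", {
  sc <- tiny_scene(seed = 31, n = 6, years = 6)
  nd <- generate_ndvi(sc$cfg, sc$clim$tem, sc$clim$pre, sc$clim$lst)
  m1 <- low_cover_month_mask(nd, 0.1)
  m2 <- m1
  m2[1, , ] <- TRUE   # strictly larger exclusion
  z1 <- detrend_and_standardize(nd, exclude = m1)
  z2 <- detrend_and_standardize(nd, exclude = m2)
  expect_lte(sum(is.finite(z2$z)), sum(is.finite(z1$z)))
})
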