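#' Monthly raster stack
#'
#' The central data container of the pipeline: a `time x row x col` cube of
#' one variable (NDVI, air temperature, precipitation, land-surface
#' temperature or TVDI) with a calendar index, an affine north-up
#' geotransform and `NA` marking nodata cells.
#'
#' @param values numeric array `[time, row, col]`; `NA` = nodata.
#' @param years,months integer vectors of length `dim(values)[1]`; months are
#'   1-based calendar months, or all `NA` for an annual stack. An optional
#'   `days` vector disambiguates sub-monthly composites.
#' @param variable short tag: `"ndvi"`, `"tem"`, `"pre"`, `"lst"` or `"tvdi"`.
#' @param units free-text units (`""`, `"degC"`, `"mm/month"`, `"K"`).
#' @param geotransform affine north-up transform
#'   `c(x_origin, dx, 0, y_origin, 0, -dy)`.
#' @param days optional integer vector (sub-monthly composites only).
#'
#' @return an object of class `monthly_stack`.
#' @export
monthly_stack <- function(values, years, months, variable = "ndvi",
                          units = "", geotransform = c(0, 1, 0, 0, 0, -1),
                          days = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array [time, row, col]")
  nt <- dim(values)[1]
  years <- as.integer(years); months <- as.integer(months)
  if (length(years) != nt || length(months) != nt)
    stop("time index length must match dim(values)[1]")
  annual <- all(is.na(months))
  if (!annual && (anyNA(months) || any(months < 1L | months > 12L)))
    stop("months must all be in 1..12, or all NA for an annual stack")
  if (length(geotransform) != 6L)
    stop("geotransform must have 6 elements")
  key <- years * 10000 + (if (annual) 0L else months) * 100 +
    (if (is.null(days)) 0L else as.integer(days))
  if (any(diff(key) <= 0))
    stop("time index must be strictly increasing")
  if (variable == "ndvi") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < -1 || max(v) > 1))
      stop("NDVI values must lie in [-1, 1]")
  }
  if (variable == "tvdi") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("TVDI values must lie in [0, 1]")
  }
  time <- data.frame(year = years, month = months)
  if (!is.null(days)) time$day <- as.integer(days)
  structure(list(values = values, time = time, variable = variable,
                 units = units, geotransform = as.numeric(geotransform)),
            class = "monthly_stack")
}

#' @export
print.monthly_stack <- function(x, ...) {
  d <- dim(x$values)
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "<monthly_stack> %s [%s]: %d steps x %d x %d, %s..%s, range [%.4g, %.4g], %.1f%% nodata\n",
    x$variable, x$units, d[1], d[2], d[3],
    time_label(x$time[1, ]), time_label(x$time[nrow(x$time), ]),
    rng[1], rng[2], 100 * mean(is.na(x$values))))
  invisible(x)
}

time_label <- function(row) {
  if (is.na(row$month)) sprintf("%d", row$year)
  else sprintf("%d-%02d", row$year, row$month)
}

#' @export
dim.monthly_stack <- function(x) dim(x$values)

n_time <- function(stack) dim(stack$values)[1]

#' Nodata mask of a stack
#'
#' @param stack a `monthly_stack`.
#' @return logical cube, `TRUE` where nodata.
#' @export
stack_mask <- function(stack) is.na(stack$values)

# shared-grid / shared-clock guard used by every multi-stack operation
check_aligned <- function(...) {
  stacks <- list(...)
  ref <- stacks[[1]]
  for (s in stacks[-1]) {
    if (!identical(dim(s$values), dim(ref$values)))
      stop("stacks are not on a common grid/time axis")
    if (!identical(s$time$year, ref$time$year) ||
        !identical(s$time$month, ref$time$month))
      stop("stacks do not share a time index")
  }
  invisible(TRUE)
}

# series of one pixel
pixel_series <- function(stack, row, col) stack$values[, row, col]

# matrix [time, pixel] view; pixels in column-major (row fastest) order
as_pixel_matrix <- function(values) {
  d <- dim(values)
  dim(values) <- c(d[1], d[2] * d[3])
  values
}

pixel_matrix_to_cube <- function(m, nr, nc) {
  array(m, dim = c(nrow(m), nr, nc))
}
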