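#' Savitzky-Golay smoothing of a composite series
#'
#' Local least-squares polynomial smoothing of a 1-D vegetation-index
#' series, the standard noise filter for satellite NDVI composites. Interior
#' points are convolved with the central Savitzky-Golay weights; the filter
#' reproduces polynomials of degree `<= order` exactly under the default
#' edge handling.
#'
#' @param x numeric series; interior `NA` runs are linearly interpolated
#'   before filtering.
#' @param window odd window length `>= 3`, in composites.
#' @param order polynomial order, `< window`.
#' @param edge_mode `"fit"` (default: least-squares polynomial fit within the
#'   first/last window — exact on polynomials up to the boundary),
#'   `"reflect"` or `"nearest"` (pad, then apply the central weights).
#' @return smoothed series of the same length.
#' @export
savitzky_golay <- function(x, window = 7L, order = 2L,
                           edge_mode = c("fit", "reflect", "nearest")) {
  edge_mode <- match.arg(edge_mode)
  window <- as.integer(window); order <- as.integer(order)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  if (order >= window) stop("order must be < window")
  if (window >= length(x)) stop("window must be shorter than the series")
  x <- fill_linear(x)
  if (edge_mode == "fit")
    return(as.numeric(signal::sgolayfilt(x, p = order, n = window)))
  h <- (window - 1L) %/% 2L
  pad <- switch(edge_mode,
    reflect = c(x[(h + 1L):2L], x, x[(length(x) - 1L):(length(x) - h)]),
    nearest = c(rep(x[1L], h), x, rep(x[length(x)], h)))
  w <- sg_central_weights(window, order)
  y <- stats::filter(pad, w, sides = 2)
  as.numeric(y[(h + 1L):(h + length(x))])
}

#' Central Savitzky-Golay convolution weights
#'
#' @param window odd window length; @param order polynomial order.
#' @return numeric vector of length `window` (the interior filter row).
#' @export
sg_central_weights <- function(window, order) {
  F <- signal::sgolay(p = order, n = window)
  as.numeric(F[(window + 1L) %/% 2L, ])
}

#' Maximum value composite
#'
#' Per pixel and period, the maximum over non-missing values — the standard
#' compositing step that suppresses cloud and atmospheric depression of
#' vegetation indices. All-missing groups become nodata. Compositing an
#' already-monthly stack by month is the identity.
#'
#' @param stack a `monthly_stack` (monthly or sub-monthly).
#' @param period `"month"` or `"year"`.
#' @return a composited `monthly_stack`; annual stacks carry `NA` months.
#' @export
maximum_value_composite <- function(stack, period = c("month", "year")) {
  period <- match.arg(period)
  nt <- n_time(stack)
  if (nt == 0L) stop("empty stack")
  key <- switch(period,
    month = stack$time$year * 100L + stack$time$month,
    year = stack$time$year)
  groups <- unique(key)
  d <- dim(stack$values)
  out <- array(NA_real_, dim = c(length(groups), d[2], d[3]))
  for (i in seq_along(groups)) {
    m <- stack$values[key == groups[i], , , drop = FALSE]
    out[i, , ] <- apply(m, c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  }
  years <- as.integer(if (period == "month") groups %/% 100L else groups)
  months <- if (period == "month") as.integer(groups %% 100L) else
    rep(NA_integer_, length(groups))
  monthly_stack(out, years, months, stack$variable, stack$units,
                stack$geotransform)
}

# DCT-II orthonormal basis matrix (n x n); C %*% x is the transform of x
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

#' Fill gaps in a 2-D grid by DCT-based penalized least squares
#'
#' A penalized least-squares smoother solved in the 2-D discrete cosine
#' basis: the smoothed field applies filter factors `1 / (1 + s * lambda^2)`
#' to the DCT coefficients, where `lambda` are the Laplacian eigenvalues of
#' the grid graph. Missing cells get weight zero and are iterated to
#' convergence; the smoothing parameter `s` is chosen by minimizing the
#' generalized cross-validation score over a log-spaced search grid. This is
#' the standard fast gap-filling approach for satellite LST scenes.
#'
#' @param grid numeric matrix; `NA` marks missing cells. At least 10% of
#'   cells must be observed.
#' @param s optional fixed smoothing parameter; if `NULL` (default), chosen
#'   by GCV each iteration.
#' @param s_grid log-spaced candidate values searched by GCV.
#' @param tol convergence tolerance on the max absolute change of the field.
#' @param max_iter maximum number of gap-update iterations.
#' @return an object of class `gap_fill`: list with `filled` (gap-free
#'   matrix), `s_opt`, `gcv_curve` (data.frame of `s`, `score` at the final
#'   iteration), `iterations`.
#' @export
dct_pls_fill <- function(grid, s = NULL,
                         s_grid = 10^seq(-6, 6, length.out = 61),
                         tol = 1e-6, max_iter = 100L) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  W <- !is.na(grid)
  n_obs <- sum(W)
  if (n_obs == 0L) stop("fully missing grid")
  if (n_obs < 0.1 * length(grid))
    stop("fewer than 10% of cells observed")
  m <- nrow(grid); n <- ncol(grid)
  Cm <- dct_matrix(m); Cn <- dct_matrix(n)
  dct2 <- function(A) Cm %*% A %*% t(Cn)
  idct2 <- function(A) t(Cm) %*% A %*% Cn
  lam <- outer(-2 + 2 * cos(pi * (0:(m - 1)) / m),
               -2 + 2 * cos(pi * (0:(n - 1)) / n), "+")
  lam2 <- lam^2

  y0 <- grid
  y0[!W] <- 0
  z <- matrix(mean(grid[W]), m, n)          # flat start at the observed mean
  gcv_curve <- NULL
  s_opt <- if (!is.null(s)) s else NA_real_
  fixed_s <- !is.null(s)
  ntot <- m * n
  s_hist <- c(NA_real_, NA_real_)           # last two GCV choices
  for (iter in seq_len(max_iter)) {
    input <- W * (y0 - z) + z
    coef <- dct2(input)
    if (!fixed_s) {
      scores <- vapply(s_grid, function(si) {
        gamma <- 1 / (1 + si * lam2)
        zi <- idct2(gamma * coef)
        rss <- sum(W * (y0 - zi)^2)
        tr_h <- sum(gamma)
        denom <- (1 - tr_h / ntot)^2
        if (denom <= 0) Inf else (rss / n_obs) / denom
      }, numeric(1))
      s_opt <- s_grid[which.min(scores)]
      gcv_curve <- data.frame(s = s_grid, score = scores)
      # a period-2 oscillation between two near-optimal grid points stalls
      # the gap iteration: freeze s at the better-scoring of the pair
      if (!is.na(s_hist[1]) && s_opt == s_hist[1] && s_opt != s_hist[2]) {
        alt <- s_hist[2]
        if (scores[match(alt, s_grid)] < scores[match(s_opt, s_grid)])
          s_opt <- alt
        fixed_s <- TRUE
      }
      s_hist <- c(s_hist[2], s_opt)
    }
    gamma <- 1 / (1 + s_opt * lam2)
    z_new <- idct2(gamma * coef)
    delta <- max(abs(z_new - z))
    z <- z_new
    if (all(W) || delta < tol) {
      return(structure(list(filled = z, s_opt = s_opt,
                            gcv_curve = gcv_curve, iterations = iter),
                       class = "gap_fill"))
    }
  }
  stop(sprintf(
    "DCT-PLS did not converge after %d iterations (last change %.3g, s = %.3g)",
    max_iter, delta, s_opt))
}

#' Fill gaps in every scene of a stack
#'
#' Applies [dct_pls_fill()] to each 2-D time slice that has missing cells;
#' gap-free slices pass through untouched.
#'
#' @param stack a `monthly_stack` with `NA` gaps.
#' @param ... passed to [dct_pls_fill()].
#' @return the filled stack; per-scene `s_opt` values in
#'   `attr(x, "fill_info")`.
#' @export
fill_stack_gaps <- function(stack, ...) {
  out <- stack
  info <- data.frame(step = seq_len(n_time(stack)), n_gaps = 0L,
                     s_opt = NA_real_, iterations = NA_integer_)
  for (t in seq_len(n_time(stack))) {
    scene <- stack$values[t, , ]
    ng <- sum(is.na(scene))
    if (ng > 0L) {
      fit <- dct_pls_fill(scene, ...)
      out$values[t, , ] <- fit$filled
      info$s_opt[t] <- fit$s_opt
      info$iterations[t] <- fit$iterations
    }
    info$n_gaps[t] <- ng
  }
  attr(out, "fill_info") <- info
  out
}

#' Nearest-neighbour block resampling
#'
#' Replicates each source cell into a `factor x factor` block, the
#' nearest-neighbour disaggregation used to bring coarse LST onto the finer
#' NDVI grid. Nodata cells become nodata blocks. For a stack, the
#' geotransform pixel size is divided by `factor`.
#'
#' @param x a matrix or a `monthly_stack`.
#' @param factor integer `>= 1`.
#' @return the resampled matrix or stack.
#' @export
resample_nearest <- function(x, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (inherits(x, "monthly_stack")) {
    d <- dim(x$values)
    out <- array(NA_real_, dim = c(d[1], d[2] * factor, d[3] * factor))
    for (t in seq_len(d[1]))
      out[t, , ] <- resample_nearest(x$values[t, , , drop = TRUE], factor)
    gt <- x$geotransform
    gt[c(2, 6)] <- gt[c(2, 6)] / factor
    return(monthly_stack(out, x$time$year, x$time$month, x$variable,
                         x$units, gt))
  }
  if (factor == 1L) return(x)
  x %x% matrix(1, factor, factor)
}

#' Per-pixel low-cover calendar-month exclusion mask
#'
#' For each pixel and calendar month, flags the month as excluded when the
#' across-years mean NDVI falls below `threshold` — removing noisy
#' observations over extremely sparse or absent vegetation before anomaly
#' regression.
#'
#' @param ndvi an NDVI `monthly_stack` spanning `>= 2` years.
#' @param threshold exclusion threshold (default 0.1); months with mean
#'   strictly below it are excluded.
#' @return logical array `[12, nrow, ncol]`; `TRUE` = excluded.
#' @export
low_cover_month_mask <- function(ndvi, threshold = 0.1) {
  if (length(unique(ndvi$time$year)) < 2L)
    stop("at least 2 years required")
  d <- dim(ndvi$values)
  mask <- array(FALSE, dim = c(12L, d[2], d[3]))
  for (m in 1:12) {
    idx <- which(ndvi$time$month == m)
    if (length(idx) == 0L) next
    clim <- apply(ndvi$values[idx, , , drop = FALSE], c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    mask[m, , ] <- !is.na(clim) & clim < threshold
  }
  mask
}
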