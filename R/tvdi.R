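#' Fit dry and wet edges of the NDVI-LST feature space
#'
#' Partitions the NDVI axis into bins, extracts the maximum (dry) and
#' minimum (wet) LST per sufficiently populated bin, and fits ordinary
#' least-squares lines through the bin maxima and minima. The dry edge is
#' the soil-moisture-limited upper boundary of the triangle/trapezoid
#' scatter; the wet edge its evaporative lower boundary.
#'
#' @param ndvi_scene,lst_scene co-registered numeric matrices (NDVI
#'   dimensionless, LST in K).
#' @param bin_width NDVI bin width (default 0.02).
#' @param min_count minimum joint-valid pixels a bin needs to enter the fits
#'   (default 10).
#' @param wet_slope_tol if the fitted wet-edge slope exceeds this positive
#'   tolerance, fall back to a constant wet edge at the mean bin minimum
#'   (default 5 K per NDVI unit).
#' @return an object of class `edge_fit`: `dry_intercept`, `dry_slope`,
#'   `wet_intercept`, `wet_slope`, `wet_constant` (logical), `n_bins_used`,
#'   `r2_dry`, `ndvi_range`.
#' @export
fit_edges <- function(ndvi_scene, lst_scene, bin_width = 0.02,
                      min_count = 10L, wet_slope_tol = 5) {
  if (!identical(dim(ndvi_scene), dim(lst_scene)))
    stop("scenes are not co-registered")
  ok <- is.finite(ndvi_scene) & is.finite(lst_scene)
  v <- ndvi_scene[ok]; ts <- lst_scene[ok]
  if (length(v) < 5L * min_count)
    stop("too few joint valid pixels for edge fitting")
  bin <- floor(v / bin_width)
  counts <- table(bin)
  keep <- names(counts)[counts >= min_count]
  if (length(keep) < 5L)
    stop(sprintf("only %d NDVI bins with >= %d pixels (need >= 5)",
                 length(keep), min_count))
  centers <- (as.numeric(keep) + 0.5) * bin_width
  tmax <- vapply(keep, function(b) max(ts[bin == as.numeric(b)]), numeric(1))
  tmin <- vapply(keep, function(b) min(ts[bin == as.numeric(b)]), numeric(1))

  dry <- stats::lm.fit(cbind(1, centers), tmax)
  wet <- stats::lm.fit(cbind(1, centers), tmin)
  wet_constant <- FALSE
  if (wet$coefficients[2] > wet_slope_tol) {
    wet$coefficients <- c(mean(tmin), 0)
    wet_constant <- TRUE
  }
  a_d <- unname(dry$coefficients[1]); b_d <- unname(dry$coefficients[2])
  a_w <- unname(wet$coefficients[1]); b_w <- unname(wet$coefficients[2])
  rng <- range(centers)
  if (any((a_d + b_d * rng) <= (a_w + b_w * rng)))
    stop("degenerate edges: dry edge not above wet edge over the fitted range")
  tss <- sum((tmax - mean(tmax))^2)
  r2_dry <- if (tss > 0) 1 - sum(dry$residuals^2) / tss else NA_real_
  structure(list(dry_intercept = a_d, dry_slope = b_d,
                 wet_intercept = a_w, wet_slope = b_w,
                 wet_constant = wet_constant,
                 n_bins_used = length(keep), r2_dry = r2_dry,
                 ndvi_range = rng),
            class = "edge_fit")
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf(
    "<edge_fit> dry: %.2f %+.2f*NDVI; wet: %.2f %+.2f*NDVI%s; %d bins, R2(dry)=%.3f\n",
    x$dry_intercept, x$dry_slope, x$wet_intercept, x$wet_slope,
    if (x$wet_constant) " (constant fallback)" else "", x$n_bins_used,
    x$r2_dry))
  invisible(x)
}

#' Temperature vegetation dryness index of a scene
#'
#' `TVDI = (LST - wet(NDVI)) / (dry(NDVI) - wet(NDVI))` per pixel: the
#' normalized position of the pixel between the wet edge (0, wettest soil)
#' and the dry edge (1, driest). Values outside `[0, 1]` — pixels beyond the
#' fitted edges — are clipped, and the clip count recorded. Pixels where the
#' dry edge does not exceed the wet edge become nodata.
#'
#' @param ndvi_scene,lst_scene co-registered matrices.
#' @param edges an [fit_edges()] result.
#' @return TVDI matrix in `[0, 1]` with attributes `n_clipped` and
#'   `n_degenerate`.
#' @export
compute_tvdi <- function(ndvi_scene, lst_scene, edges) {
  stopifnot(inherits(edges, "edge_fit"))
  if (!identical(dim(ndvi_scene), dim(lst_scene)))
    stop("scenes are not co-registered")
  wet <- edges$wet_intercept + edges$wet_slope * ndvi_scene
  dry <- edges$dry_intercept + edges$dry_slope * ndvi_scene
  denom <- dry - wet
  tvdi <- (lst_scene - wet) / denom
  bad <- is.finite(denom) & denom <= 0
  tvdi[bad] <- NA_real_
  clipped <- sum(is.finite(tvdi) & (tvdi < 0 | tvdi > 1))
  tvdi <- clip_range(tvdi, 0, 1)
  attr(tvdi, "n_clipped") <- clipped
  attr(tvdi, "n_degenerate") <- sum(bad)
  tvdi
}

#' Monthly TVDI stack with per-scene edge fits
#'
#' Fits dry/wet edges independently for every monthly scene (the dry edge
#' drifts with the seasonal cycle) and evaluates TVDI.
#'
#' @param ndvi,lst aligned `monthly_stack`s.
#' @inheritParams fit_edges
#' @return list with `stack` (TVDI `monthly_stack`) and `edges` (data.frame:
#'   year, month, a_d, b_d, a_w, b_w, r2_dry, n_bins_used, n_clipped).
#' @export
tvdi_stack <- function(ndvi, lst, bin_width = 0.02, min_count = 10L) {
  check_aligned(ndvi, lst)
  nt <- n_time(ndvi)
  vals <- array(NA_real_, dim = dim(ndvi$values))
  rows <- vector("list", nt)
  for (t in seq_len(nt)) {
    e <- fit_edges(ndvi$values[t, , ], lst$values[t, , ],
                   bin_width = bin_width, min_count = min_count)
    sc <- compute_tvdi(ndvi$values[t, , ], lst$values[t, , ], e)
    vals[t, , ] <- sc
    rows[[t]] <- data.frame(
      year = ndvi$time$year[t], month = ndvi$time$month[t],
      a_d = e$dry_intercept, b_d = e$dry_slope,
      a_w = e$wet_intercept, b_w = e$wet_slope,
      r2_dry = e$r2_dry, n_bins_used = e$n_bins_used,
      n_clipped = attr(sc, "n_clipped"))
  }
  list(stack = monthly_stack(vals, ndvi$time$year, ndvi$time$month,
                             "tvdi", "", ndvi$geotransform),
       edges = do.call(rbind, rows))
}
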