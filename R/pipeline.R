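#' Pipeline configuration
#'
#' Bundles the synthetic-scene configuration with every stage parameter of
#' the analysis. Unknown arguments are rejected. The single `seed` (taken
#' from the synthetic configuration) feeds a per-stage seed-derivation rule
#' so each stage is independently reproducible.
#'
#' @param synth a [synth_config()] describing the scene (or the ingested
#'   data's dimensions).
#' @param sg_window,sg_order Savitzky-Golay window/order for NDVI smoothing.
#' @param ndvi_threshold low-cover exclusion threshold (default 0.1).
#' @param bin_width,min_count TVDI edge-fitting parameters.
#' @param z_threshold Mann-Kendall significance threshold (default 1.96).
#' @param p_threshold PCR component-selection level (default 0.1).
#' @param min_months minimum joint-valid lag pairs per pixel (default 36).
#' @param gs_months growing-season calendar months (default May-September).
#' @param normalize_weights per-pixel sum-to-1 weight normalization.
#' @param resample_factor nearest-neighbour disaggregation factor applied to
#'   the LST stack before TVDI (default 1 = already on the common grid).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth,
                            sg_window = 7L, sg_order = 2L,
                            ndvi_threshold = 0.1,
                            bin_width = 0.02, min_count = 10L,
                            z_threshold = 1.96, p_threshold = 0.1,
                            min_months = 36L, gs_months = 5:9,
                            normalize_weights = TRUE,
                            resample_factor = 1L) {
  stopifnot(inherits(synth, "synth_config"))
  structure(list(synth = synth, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 ndvi_threshold = ndvi_threshold,
                 bin_width = bin_width, min_count = as.integer(min_count),
                 z_threshold = z_threshold, p_threshold = p_threshold,
                 min_months = as.integer(min_months),
                 gs_months = as.integer(gs_months),
                 normalize_weights = isTRUE(normalize_weights),
                 resample_factor = as.integer(resample_factor),
                 seed = synth$seed),
            class = "pipeline_config")
}

#' Run the full vegetation-sensitivity pipeline on a synthetic scene
#'
#' Sequences every stage end-to-end: scene simulation (climate stacks, LST
#' gap injection), preprocessing (DCT-PLS gap filling, optional
#' nearest-neighbour resampling, Savitzky-Golay NDVI smoothing, monthly and
#' annual maximum-value composites), monthly TVDI with per-scene edge fits,
#' per-pixel trend mapping on annual NDVI plus basin-mean trend tests,
#' and the sensitivity chain (low-cover exclusion, detrend/standardize,
#' lag-1 regression, PCR climate weights, variability scores, log-ratio
#' sensitivities, VSI, memory classes, gradient regressions).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, all rasters and
#'   tables are written there along with a JSON manifest (file list, md5
#'   checksums, parameter hash, seed) enabling exact re-runs.
#' @return a list with all stage results (`stacks`, `tvdi`, `trend`,
#'   `sensitivity`, `log`) and, when `out_dir` is set, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$synth
  log <- list()

  ## --- simulate -----------------------------------------------------------
  clim <- generate_climate_stacks(cfg)
  lst_gapped <- inject_gaps(clim$lst, cfg$gap_fraction,
                            stage_seed(cfg$seed, "gaps"))
  log$simulate <- c(n_gap_cells = sum(attr(lst_gapped, "gap_mask")))

  ## --- preprocess ---------------------------------------------------------
  lst_filled <- fill_stack_gaps(lst_gapped)
  if (config$resample_factor > 1L)
    lst_filled <- resample_nearest(lst_filled, config$resample_factor)
  log$preprocess <- c(n_scenes_filled =
                        sum(attr(lst_filled, "fill_info")$n_gaps > 0))

  ## --- generate NDVI (driver TVDI computed from the filled LST) -----------
  moisture <- if (cfg$ndvi_driver == "tvdi") {
    tvdi_stack(ndvi_climatology(cfg), lst_filled,
               bin_width = config$bin_width,
               min_count = config$min_count)$stack
  } else lst_filled
  ndvi_raw <- generate_ndvi(cfg, clim$tem, clim$pre, moisture)

  ## --- NDVI smoothing and composites --------------------------------------
  ndvi_sm <- ndvi_raw
  pm <- as_pixel_matrix(ndvi_sm$values)
  for (p in seq_len(ncol(pm)))
    pm[, p] <- savitzky_golay(pm[, p], config$sg_window, config$sg_order)
  ndvi_sm$values <- clip_range(
    pixel_matrix_to_cube(pm, dim(ndvi_sm$values)[2], dim(ndvi_sm$values)[3]),
    -1, 1)
  ndvi_month <- maximum_value_composite(ndvi_sm, "month")
  ndvi_annual <- maximum_value_composite(ndvi_sm, "year")

  ## --- analysis TVDI from smoothed NDVI + filled LST -----------------------
  tv <- tvdi_stack(ndvi_month, lst_filled, bin_width = config$bin_width,
                   min_count = config$min_count)
  log$tvdi <- c(n_clipped = sum(tv$edges$n_clipped))

  ## --- trend ---------------------------------------------------------------
  trend <- trend_map(ndvi_annual, z_threshold = config$z_threshold)
  mean_annual <- apply(ndvi_annual$values, c(2, 3), mean, na.rm = TRUE)
  levels <- level_map(mean_annual)
  basin_trends <- do.call(rbind, lapply(
    list(ndvi = ndvi_annual,
         tem = maximum_value_composite(clim$tem, "year"),
         pre = maximum_value_composite(clim$pre, "year"),
         tvdi = maximum_value_composite(tv$stack, "year")),
    function(s) {
      x <- apply(s$values, 1, mean, na.rm = TRUE)
      data.frame(zc = mk_z(x), beta = theil_sen(x),
                 class = classify_trend(mk_z(x),
                                        z_threshold = config$z_threshold))
    }))
  basin_trends$variable <- rownames(basin_trends)

  ## --- sensitivity chain ---------------------------------------------------
  exclusion <- low_cover_month_mask(ndvi_month, config$ndvi_threshold)
  ndvi_z <- detrend_and_standardize(ndvi_month, exclude = exclusion)
  tem_z <- detrend_and_standardize(clim$tem)
  pre_z <- detrend_and_standardize(clim$pre)
  tvdi_z <- detrend_and_standardize(tv$stack)

  ar1 <- fit_ar1(ndvi_z, tem_z, pre_z, tvdi_z,
                 min_months = config$min_months)
  raw_w <- pcr_weights(ndvi_z, tem_z, pre_z, tvdi_z,
                       p_threshold = config$p_threshold,
                       min_months = config$min_months)
  weights <- rescale_weights(raw_w, normalize = config$normalize_weights)

  vscores <- list(ndvi = variability_scores(ndvi_z$detrended),
                  tem = variability_scores(tem_z$detrended),
                  pre = variability_scores(pre_z$detrended),
                  tvdi = variability_scores(tvdi_z$detrended))
  sens <- list(tem = sensitivity_scores(vscores$ndvi, vscores$tem),
               pre = sensitivity_scores(vscores$ndvi, vscores$pre),
               tvdi = sensitivity_scores(vscores$ndvi, vscores$tvdi))
  vsi <- compute_vsi(weights, sens)
  memory <- memory_map(ar1$alpha)

  gs <- list(ndvi = growing_season_mean(ndvi_month, config$gs_months),
             tem = growing_season_mean(clim$tem, config$gs_months),
             pre = growing_season_mean(clim$pre, config$gs_months),
             tvdi = growing_season_mean(tv$stack, config$gs_months))
  gradients <- list(
    ndvi = gradient_regression(ar1$alpha, gs$ndvi, "logarithmic"),
    tvdi = gradient_regression(ar1$alpha, gs$tvdi, "logarithmic"),
    pre = gradient_regression(ar1$alpha, gs$pre, "quadratic"),
    tem = gradient_regression(ar1$alpha, gs$tem, "quadratic"))

  log$sensitivity <- c(ar1$counts,
                       excluded_cells = unname(ndvi_z$dropped["excluded"]))

  result <- list(
    config = config,
    stacks = list(tem = clim$tem, pre = clim$pre, lst = lst_filled,
                  ndvi = ndvi_month, ndvi_annual = ndvi_annual,
                  tvdi = tv$stack),
    tvdi = tv, trend = trend, levels = levels,
    basin_trends = basin_trends,
    sensitivity = list(ar1 = ar1, raw_weights = raw_w, weights = weights,
                       variability = vscores, sens = sens, vsi = vsi,
                       memory = memory, gradients = gradients),
    log = log)

  if (!is.null(out_dir))
    result$manifest <- write_pipeline_outputs(result, out_dir)
  result
}

# Serialize all pipeline products under out_dir and build the run manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sdir <- file.path(out_dir, "stacks")
  for (nm in names(result$stacks))
    write_stack(result$stacks[[nm]], file.path(sdir, nm))

  write_mat <- function(m, nm) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(m, f, row.names = FALSE)
    f
  }
  sen <- result$sensitivity
  write_mat(result$trend$zc, "trend_zc")
  write_mat(result$trend$beta, "trend_beta")
  write_mat(result$trend$class, "trend_class")
  write_mat(sen$ar1$alpha, "alpha")
  write_mat(sen$weights$tem, "weight_tem")
  write_mat(sen$weights$pre, "weight_pre")
  write_mat(sen$weights$tvdi, "weight_tvdi")
  write_mat(sen$vsi$vsi, "vsi")
  write_mat(sen$memory$class, "memory_class")

  utils::write.csv(result$tvdi$edges, file.path(out_dir, "tvdi_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(result$basin_trends,
                   file.path(out_dir, "basin_trends.csv"), row.names = FALSE)
  summ <- data.frame(
    metric = c(names(result$trend$fractions$trend_class),
               names(result$trend$fractions$beta_band),
               names(result$levels$fractions),
               names(sen$memory$fractions)),
    partition = rep(c("trend_class", "beta_band", "ndvi_level",
                      "memory_class"),
                    times = c(length(result$trend$fractions$trend_class),
                              length(result$trend$fractions$beta_band),
                              length(result$levels$fractions),
                              length(sen$memory$fractions))),
    fraction = c(result$trend$fractions$trend_class,
                 result$trend$fractions$beta_band,
                 result$levels$fractions,
                 sen$memory$fractions))
  utils::write.csv(summ, file.path(out_dir, "area_fractions.csv"),
                   row.names = FALSE)
  grad <- do.call(rbind, lapply(names(sen$gradients), function(nm) {
    g <- sen$gradients[[nm]]
    data.frame(covariate = nm, form = g$form, r2 = g$r2, p = g$p, n = g$n)
  }))
  utils::write.csv(grad, file.path(out_dir, "gradient_fits.csv"),
                   row.names = FALSE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    seed = result$config$seed,
    parameter_hash = unname(tools::md5sum(
      write_temp_json(config_fingerprint(result$config)))),
    files = data.frame(path = sub(paste0("^", out_dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))),
    log = result$log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

config_fingerprint <- function(config) {
  f <- unclass(config)
  f$synth <- unclass(f$synth)
  f
}

write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  f
}
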