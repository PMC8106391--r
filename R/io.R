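#' Write a monthly stack to disk
#'
#' Stores a stack as three sidecar files sharing a path prefix:
#' `<prefix>_values.csv` (long format `band,row,col,value`, full `%.17g`
#' precision so the roundtrip is bit-identical, nodata as empty fields),
#' `<prefix>_time_index.csv` (`band,year,month[,day]`) and
#' `<prefix>_meta.json` (variable tag, units, dimensions, affine
#' geotransform).
#'
#' @param stack a `monthly_stack`.
#' @param prefix path prefix (directories are created as needed).
#' @return invisibly, the three file paths.
#' @export
write_stack <- function(stack, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$values)
  f_values <- paste0(prefix, "_values.csv")
  f_time <- paste0(prefix, "_time_index.csv")
  f_meta <- paste0(prefix, "_meta.json")

  idx <- which(!is.na(stack$values), arr.ind = TRUE)
  dt <- data.table::data.table(
    band = idx[, 1], row = idx[, 2], col = idx[, 3],
    value = sprintf("%.17g", stack$values[idx]))
  data.table::setorder(dt, band, row, col)
  data.table::fwrite(dt, f_values)

  ti <- data.table::as.data.table(stack$time)
  ti[, band := .I]
  data.table::setcolorder(ti, "band")
  data.table::fwrite(ti, f_time)

  jsonlite::write_json(list(
    variable = stack$variable, units = stack$units,
    n_time = d[1], n_rows = d[2], n_cols = d[3],
    geotransform = stack$geotransform, nodata = "omitted cells"),
    f_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(values = f_values, time_index = f_time, meta = f_meta))
}

#' Read a monthly stack from disk
#'
#' Inverse of [write_stack()]. Rows of the time-index sidecar may arrive in
#' any order: the stack is reordered to chronological, with the band-value
#' pairing preserved. A missing geotransform falls back to the identity
#' with a warning.
#'
#' @param prefix path prefix used at write time.
#' @return a `monthly_stack`.
#' @export
read_stack <- function(prefix) {
  f_values <- paste0(prefix, "_values.csv")
  f_time <- paste0(prefix, "_time_index.csv")
  f_meta <- paste0(prefix, "_meta.json")
  if (!file.exists(f_values) || !file.exists(f_time))
    stop("stack files not found at prefix: ", prefix)
  meta <- if (file.exists(f_meta)) jsonlite::read_json(f_meta,
                                                       simplifyVector = TRUE)
  else NULL
  ti <- data.table::fread(f_time)
  vals <- data.table::fread(f_values, colClasses = list(character = "value"))

  if (is.null(meta) || is.null(meta$geotransform)) {
    warning("missing georeferencing; using the identity transform")
    gt <- c(0, 1, 0, 0, 0, -1)
  } else gt <- as.numeric(meta$geotransform)

  nt <- nrow(ti)
  if (!is.null(meta) && !is.null(meta$n_time) && meta$n_time != nt)
    stop("band count / time index mismatch")
  if (nrow(vals) && max(vals$band) > nt)
    stop("band count / time index mismatch")
  nr <- if (!is.null(meta)) meta$n_rows else max(vals$row)
  nc <- if (!is.null(meta)) meta$n_cols else max(vals$col)

  ord <- order(ti$year, ti$month,
               if ("day" %in% names(ti)) ti$day else rep(0L, nt))
  pos <- match(seq_len(nt), ti$band[ord])   # band id -> chronological slot

  cube <- array(NA_real_, dim = c(nt, nr, nc))
  cube[cbind(pos[vals$band], vals$row, vals$col)] <- as.numeric(vals$value)
  monthly_stack(cube, ti$year[ord], ti$month[ord],
                variable = if (!is.null(meta)) meta$variable else "ndvi",
                units = if (!is.null(meta)) meta$units else "",
                geotransform = gt,
                days = if ("day" %in% names(ti)) ti$day[ord] else NULL)
}

#' RGB composite of climate weights
#'
#' Encodes the three normalized climate weights of each pixel as one byte
#' triplet: temperature in the red channel, TVDI in green, precipitation in
#' blue, each `round(weight * 255)`. Nodata pixels get `NA` in all bands.
#'
#' @param weights a [rescale_weights()] result with normalized weights.
#' @return integer array `[nrow, ncol, 3]` (R, G, B).
#' @export
weights_rgb <- function(weights) {
  stopifnot(inherits(weights, "climate_weights"))
  if (!isTRUE(weights$normalized))
    stop("weights must be normalized (sum-to-1) for the RGB composite")
  d <- dim(weights$tem)
  rgb <- array(NA_integer_, dim = c(d[1], d[2], 3))
  rgb[, , 1] <- as.integer(round(weights$tem * 255))
  rgb[, , 2] <- as.integer(round(weights$tvdi * 255))
  rgb[, , 3] <- as.integer(round(weights$pre * 255))
  rgb
}
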