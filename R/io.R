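#' Read a time series from CSV
#'
#' Expects a header with `time` and `value` columns. Missing values may be
#' encoded as empty fields or `NA`. The time column must be strictly
#' increasing; a warning is emitted when its spacing is not uniform (the
#' quantifiers assume regular sampling).
#'
#' @param path CSV file path.
#' @param step_unit Unit label attached to the inferred step.
#' @return An [itq_series].
#' @export
read_timeseries_csv <- function(path, step_unit = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  if (!all(c("time", "value") %in% names(df)))
    stop("CSV must have 'time' and 'value' columns")
  tt <- df$time
  if (anyNA(tt)) stop("time column must not contain missing values")
  if (length(tt) > 1L && any(diff(tt) <= 0))
    stop("time column must be strictly increasing")
  step <- if (length(tt) > 1L) stats::median(diff(tt)) else 1
  if (length(tt) > 2L && any(abs(diff(tt) - step) > 1e-8 * max(abs(step), 1)))
    warning("non-uniform time spacing: treating series as regularly sampled at the median step")
  itq_series(as.numeric(df$value), step = step,
             step_unit = if (is.null(step_unit)) "steps" else step_unit)
}

#' Write a time series to CSV
#'
#' @param series An [itq_series] or numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series, path) {
  series <- as_itq_series(series)
  n <- length(series$values)
  df <- data.frame(time = seq(0, by = series$step, length.out = n),
                   value = fmt_num(series$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# 12 significant digits keeps CSV round-trips stable at double precision noise
fmt_num <- function(x) {
  out <- trimws(formatC(x, digits = 12, format = "g"))
  out[is.na(x)] <- NA
  out
}

#' Read a gridded field from long-format CSV
#'
#' The text interchange format for grids: a header `time,lat,lon,value` with
#' one row per cell and time step (missing value rows may be omitted or have
#' empty/`NA` value). Coordinates are reconstructed from the unique sorted
#' `time`, `lat`, `lon` values.
#'
#' @param path CSV file path.
#' @return A [gridded_field].
#' @export
read_grid_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  need <- c("time", "lat", "lon", "value")
  if (!all(need %in% names(df)))
    stop("grid CSV must have time, lat, lon, value columns")
  tt <- sort(unique(df$time)); la <- sort(unique(df$lat)); lo <- sort(unique(df$lon))
  arr <- array(NA_real_, dim = c(length(tt), length(la), length(lo)))
  it <- match(df$time, tt); ia <- match(df$lat, la); io <- match(df$lon, lo)
  arr[cbind(it, ia, io)] <- df$value
  gridded_field(arr, time = tt, lat = la, lon = lo)
}

#' Write a gridded field to long-format CSV
#'
#' @param grid A [gridded_field].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "gridded_field"))
  d <- dim(grid$values)
  df <- expand.grid(time = grid$time, lat = grid$lat, lon = grid$lon,
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- fmt_num(as.numeric(grid$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a gridded field from a NetCDF file
#'
#' Requires the optional `ncdf4` package. The variable's dimensions are
#' reordered to time x lat x lon by matching dimension names (`time`/`t`,
#' `lat`/`latitude`/`y`, `lon`/`longitude`/`x`); fill values become `NA`.
#'
#' @param path NetCDF file path.
#' @param variable Variable name.
#' @return A [gridded_field].
#' @export
read_grid_netcdf <- function(path, variable) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("reading NetCDF requires the 'ncdf4' package; use read_grid_csv otherwise")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop(sprintf("variable '%s' not found; available: %s", variable,
                 paste(names(nc$var), collapse = ", ")))
  v <- nc$var[[variable]]
  if (v$ndims != 3L) stop("variable must have exactly 3 dimensions")
  dimnames_nc <- vapply(v$dim, function(d) d$name, character(1))
  axis_of <- function(nm) {
    nm <- tolower(nm)
    if (nm %in% c("time", "t")) "time"
    else if (nm %in% c("lat", "latitude", "y")) "lat"
    else if (nm %in% c("lon", "longitude", "x")) "lon"
    else NA_character_
  }
  axes <- vapply(dimnames_nc, axis_of, character(1))
  if (anyNA(axes) || !setequal(axes, c("time", "lat", "lon")))
    stop(sprintf("cannot identify time/lat/lon among dimensions: %s",
                 paste(dimnames_nc, collapse = ", ")))
  arr <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  perm <- match(c("time", "lat", "lon"), axes)
  arr <- aperm(arr, perm)
  coords <- lapply(v$dim, function(d) d$vals)
  gridded_field(arr, time = coords[[perm[1]]], lat = coords[[perm[2]]],
                lon = coords[[perm[3]]])
}

#' Write a gridded field to a NetCDF file
#'
#' Requires the optional `ncdf4` package.
#'
#' @param grid A [gridded_field].
#' @param path Output path.
#' @param variable Variable name to store under.
#' @param units Units attribute.
#' @return `path`, invisibly.
#' @export
write_grid_netcdf <- function(grid, path, variable = "value", units = "") {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("writing NetCDF requires the 'ncdf4' package; use write_grid_csv otherwise")
  stopifnot(inherits(grid, "gridded_field"))
  dt <- ncdf4::ncdim_def("time", "steps", grid$time)
  dla <- ncdf4::ncdim_def("lat", "degrees_north", grid$lat)
  dlo <- ncdf4::ncdim_def("lon", "degrees_east", grid$lon)
  fill <- -9999
  v <- ncdf4::ncvar_def(variable, units, list(dt, dla, dlo), missval = fill,
                        prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, grid$values)
  invisible(path)
}

#' Serialize a quantifier result as a JSON record
#'
#' @param result An `itq_result`.
#' @return Single-line JSON string with fields `H`, `C`, `F`, `D`, `tau`,
#'   `weighted`, `n_windows`.
#' @export
itq_result_json <- function(result) {
  stopifnot(inherits(result, "itq_result"))
  sprintf(paste0('{"H": %.12g, "C": %.12g, "F": %.12g, "D": %d, "tau": %d, ',
                 '"weighted": %s, "n_windows": %d}'),
          result$H, result$C, result$F, result$config$D, result$config$tau,
          if (result$weighted) "true" else "false", result$n_windows)
}

#' Write an ordinal distribution to CSV
#'
#' Columns: `pattern_rank`, `permutation` (hyphen-joined time offsets),
#' `probability`, `count_or_weight`.
#'
#' @param dist An [ordinal_distribution].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(dist, path) {
  df <- as.data.frame(dist)
  df$probability <- fmt_num(df$probability)
  df$count_or_weight <- fmt_num(df$count_or_weight)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
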