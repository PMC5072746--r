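#' Space-time gridded field
#'
#' Container for a 3-D `time x lat x lon` array of a physical variable with
#' coordinate vectors. Missing cells/steps are `NA`. No regridding is
#' performed anywhere in the package: fields to be compared must already
#' share coordinates.
#'
#' @param values 3-D numeric array, dimensions time, lat, lon.
#' @param time Time stamps (numeric), length `dim(values)[1]`.
#' @param lat,lon Strictly monotone coordinate vectors (degrees, cell
#'   centers) matching dimensions 2 and 3.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(values, time = NULL, lat = NULL, lon = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array (time x lat x lon)")
  d <- dim(values)
  if (is.null(time)) time <- seq_len(d[1])
  if (is.null(lat)) lat <- seq_len(d[2])
  if (is.null(lon)) lon <- seq_len(d[3])
  if (length(time) != d[1] || length(lat) != d[2] || length(lon) != d[3])
    stop("coordinate lengths must match array dimensions")
  mono <- function(v) all(diff(v) > 0) || all(diff(v) < 0)
  if (length(lat) > 1L && !mono(lat)) stop("lat must be strictly monotone")
  if (length(lon) > 1L && !mono(lon)) stop("lon must be strictly monotone")
  structure(list(values = values, time = as.numeric(time),
                 lat = as.numeric(lat), lon = as.numeric(lon)),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gridded_field> %d time x %d lat x %d lon (%.1f%% missing)\n",
              d[1], d[2], d[3], 100 * mean(is.na(x$values))))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$time, b$time)) &&
    isTRUE(all.equal(a$lat, b$lat)) &&
    isTRUE(all.equal(a$lon, b$lon))
}

#' Per-cell information quantifier maps
#'
#' Applies [itq_suite()] to the time series of every grid cell, producing
#' `lat x lon` maps of entropy, complexity and Fisher information. Cells
#' whose fraction of valid (non-missing) time steps falls below
#' `min_valid_fraction`, or that cannot form enough embedding windows, are
#' missing in all three maps.
#'
#' @param grid A [gridded_field].
#' @param config An [ordinal_config].
#' @param min_valid_fraction Minimum fraction of non-missing time steps a
#'   cell needs to be evaluated (default 0.9).
#' @return An object of class `itq_maps`: list with matrices `H`, `C`, `F`
#'   (`lat x lon`), coordinate vectors, and `config`.
#' @export
itq_map <- function(grid, config = ordinal_config(), min_valid_fraction = 0.9) {
  stopifnot(inherits(grid, "gridded_field"))
  d <- dim(grid$values)
  nfac <- factorial(config$D)
  H <- C <- F <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      x <- grid$values[, i, j]
      if (mean(!is.na(x)) < min_valid_fraction) next
      v <- validate_series(x, config)
      if (v$n_windows < nfac) next
      r <- tryCatch(itq_suite(x, config), error = function(e) NULL)
      if (is.null(r)) next
      H[i, j] <- r$H; C[i, j] <- r$C; F[i, j] <- r$F
    }
  }
  if (all(is.na(H))) stop("empty grid: no cell passed the validity criteria")
  structure(list(H = H, C = C, F = F, lat = grid$lat, lon = grid$lon,
                 config = config, min_valid_fraction = min_valid_fraction),
            class = "itq_maps")
}

#' @export
print.itq_maps <- function(x, ...) {
  cat(sprintf("<itq_maps> %d x %d cells (%.1f%% missing); mean H = %.3f, C = %.3f, F = %.3f\n",
              nrow(x$H), ncol(x$H), 100 * mean(is.na(x$H)),
              mean(x$H, na.rm = TRUE), mean(x$C, na.rm = TRUE),
              mean(x$F, na.rm = TRUE)))
  invisible(x)
}

#' RGB composite of quantifier maps
#'
#' Encodes the three maps in one image: entropy in the red, complexity in
#' the green and Fisher information in the blue channel, each scaled
#' linearly from the theoretical `[0, 1]` range to `0:255` (round half up),
#' so composites are comparable across datasets. Missing cells receive
#' `fill`.
#'
#' @param maps An [itq_maps] object.
#' @param fill Value stored in all channels of missing cells (default `NA`).
#' @return Integer array `lat x lon x 3` with values in `0:255` (or `fill`).
#' @export
rgb_composite <- function(maps, fill = NA_integer_) {
  stopifnot(inherits(maps, "itq_maps"))
  chan <- function(m) {
    v <- floor(m * 255 + 0.5)  # round half up
    v[v < 0] <- 0L; v[v > 255] <- 255L
    v
  }
  out <- array(NA_real_, dim = c(dim(maps$H), 3L))
  out[, , 1] <- chan(maps$H)
  out[, , 2] <- chan(maps$C)
  out[, , 3] <- chan(maps$F)
  out[is.na(out)] <- fill
  storage.mode(out) <- "integer"
  out
}

#' Per-cell Jensen-Shannon divergence between two fields
#'
#' For every grid cell, builds the ordinal pattern distribution of the
#' observed and the modeled time series and computes their Jensen-Shannon
#' divergence: a map of mismatch in dynamics that is invariant to bias and
#' monotone rescaling of either field.
#'
#' @param obs,mod [gridded_field]s on identical grids and time axes.
#' @param config An [ordinal_config].
#' @param min_valid_fraction Minimum valid fraction per cell in both fields.
#' @return A `lat x lon` matrix of divergences (nats); `NA` where either
#'   cell is insufficiently observed.
#' @export
jsd_map <- function(obs, mod, config = ordinal_config(),
                    min_valid_fraction = 0.9) {
  stopifnot(inherits(obs, "gridded_field"), inherits(mod, "gridded_field"))
  if (!same_grid(obs, mod)) stop("grid mismatch: obs and mod must share coordinates")
  d <- dim(obs$values)
  nfac <- factorial(config$D)
  out <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      xo <- obs$values[, i, j]; xm <- mod$values[, i, j]
      if (mean(!is.na(xo)) < min_valid_fraction ||
          mean(!is.na(xm)) < min_valid_fraction) next
      po <- tryCatch(ordinal_distribution(xo, config), error = function(e) NULL)
      pm <- tryCatch(ordinal_distribution(xm, config), error = function(e) NULL)
      if (is.null(po) || is.null(pm) || po$n_windows < nfac || pm$n_windows < nfac)
        next
      out[i, j] <- jensen_shannon_divergence(po, pm)
    }
  }
  out
}

#' Per-cell root-mean-square error between two fields
#'
#' The conventional amplitude-sensitive mismatch map, complementary to
#' [jsd_map()]: a constant offset between model and observation gives a
#' nonzero RMSE but zero ordinal divergence, and vice versa a model with the
#' right values in the wrong temporal order can have low RMSE but large
#' divergence.
#'
#' @param obs,mod [gridded_field]s on identical grids and time axes.
#' @return A `lat x lon` matrix; per cell the root mean squared difference
#'   over time steps where both fields are non-missing.
#' @export
rmse_map <- function(obs, mod) {
  stopifnot(inherits(obs, "gridded_field"), inherits(mod, "gridded_field"))
  if (!same_grid(obs, mod)) stop("grid mismatch: obs and mod must share coordinates")
  diff2 <- (obs$values - mod$values)^2
  apply(diff2, c(2, 3), function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else sqrt(mean(v))
  })
}

#' Correlation between two mismatch maps
#'
#' Pearson correlation of two per-cell metric maps over the cells where both
#' are defined; used to quantify whether two benchmarking metrics are
#' redundant.
#'
#' @param a,b Numeric matrices of identical shape.
#' @return Pearson correlation coefficient.
#' @export
metric_correlation <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("maps must share shape")
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) stop("need at least 3 jointly valid cells")
  stats::cor(a[ok], b[ok])
}
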