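#' Temporal aggregation by block means
#'
#' Replaces non-overlapping blocks of `factor` consecutive samples by their
#' mean. A block containing any missing value yields a missing aggregate;
#' a trailing partial block is dropped. Aggregation increases serial
#' correlation and so, on correlated series, lowers permutation entropy and
#' moves the series left/up in the entropy-complexity plane.
#'
#' @param series An [itq_series] or numeric vector.
#' @param factor Integer aggregation factor >= 1.
#' @return An [itq_series] with `step` multiplied by `factor`.
#' @examples
#' ts_aggregate(c(1, 2, 3, 4, 5, 6), 2)$values  # 1.5 3.5 5.5
#' @export
ts_aggregate <- function(series, factor) {
  series <- as_itq_series(series)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  n <- length(series$values)
  if (factor > n) stop("factor exceeds series length")
  if (factor == 1L) return(series)
  nb <- n %/% factor
  m <- matrix(series$values[seq_len(nb * factor)], nrow = factor)
  agg <- colMeans(m)  # NA propagates: any missing member -> missing block
  itq_series(agg, step = series$step * factor, step_unit = series$step_unit)
}

#' Temporal decimation (thinning)
#'
#' Keeps every `factor`-th sample starting at the first. Decimation
#' diminishes serial correlation and so, on correlated series, raises
#' permutation entropy — the opposite shift to [ts_aggregate()].
#'
#' @inheritParams ts_aggregate
#' @return An [itq_series] with `step` multiplied by `factor`.
#' @examples
#' ts_decimate(c(1, 2, 3, 4, 5, 6), 2)$values  # 1 3 5
#' @export
ts_decimate <- function(series, factor) {
  series <- as_itq_series(series)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  n <- length(series$values)
  if (factor > n) stop("factor exceeds series length")
  if (factor == 1L) return(series)
  itq_series(series$values[seq(1L, n, by = factor)],
             step = series$step * factor, step_unit = series$step_unit)
}

#' Information quantifiers across a ladder of temporal resolutions
#'
#' Aggregates the series by each factor in turn and computes the quantifier
#' triple at each resolution, tracing the trajectory of the series through
#' the causal information planes as oscillatory components (diurnal, annual)
#' come into and out of the embedding window's reach.
#'
#' @param series An [itq_series] or numeric vector.
#' @param factors Strictly increasing integer vector of aggregation factors.
#' @param config An [ordinal_config].
#' @return An object of class `resolution_sweep`: a data.frame with columns
#'   `factor`, `step`, `H`, `C`, `F`, `n_windows`, plus attributes
#'   `step_unit` and `config`.
#' @export
resolution_sweep <- function(series, factors, config = ordinal_config()) {
  series <- as_itq_series(series)
  factors <- as.integer(factors)
  if (length(factors) < 1L || anyNA(factors) || any(factors < 1L) ||
      any(diff(factors) <= 0))
    stop("factors must be strictly increasing integers >= 1")
  nfac <- factorial(config$D)
  rows <- lapply(factors, function(f) {
    agg <- ts_aggregate(series, f)
    v <- validate_series(agg, config)
    if (v$n_windows < nfac)
      stop(sprintf("factor %d leaves %d windows < %d = D! (series too short)",
                   f, v$n_windows, nfac))
    r <- itq_suite(agg, config)
    data.frame(factor = f, step = agg$step, H = r$H, C = r$C, F = r$F,
               n_windows = r$n_windows)
  })
  out <- do.call(rbind, rows)
  attr(out, "step_unit") <- series$step_unit
  attr(out, "config") <- config
  class(out) <- c("resolution_sweep", "data.frame")
  out
}
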