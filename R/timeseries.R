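#' Regularly sampled time series
#'
#' Light container for a univariate, regularly sampled scalar series.
#' Missing observations are represented as `NA` in `values`; all quantifier
#' code treats `NA` as a gap and skips embedding windows that touch one.
#'
#' @param values Numeric vector of observations. `NA` marks missing samples;
#'   non-missing entries must be finite.
#' @param step Positive sampling interval (in `step_unit`s).
#' @param step_unit Label for the sampling interval unit (e.g. `"hours"`,
#'   `"months"`). Informational only.
#' @return An object of class `itq_series` with fields `values`, `step`,
#'   `step_unit`.
#' @examples
#' x <- itq_series(sin(2 * pi * (1:240) / 12), step = 1, step_unit = "months")
#' length(x$values)
#' @export
itq_series <- function(values, step = 1, step_unit = "steps") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("series must contain at least one value")
  if (any(!is.finite(values) & !is.na(values)))
    stop("non-missing values must be finite (no Inf/NaN)")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("step must be a single positive number")
  structure(
    list(values = values, step = step, step_unit = as.character(step_unit)),
    class = "itq_series"
  )
}

#' @export
print.itq_series <- function(x, ...) {
  n <- length(x$values)
  nmiss <- sum(is.na(x$values))
  cat(sprintf("<itq_series> n = %d (%d missing), step = %g %s\n",
              n, nmiss, x$step, x$step_unit))
  invisible(x)
}

#' @export
length.itq_series <- function(x) length(x$values)

# Coerce numeric vectors on the fly so every quantifier accepts both.
as_itq_series <- function(x) {
  if (inherits(x, "itq_series")) return(x)
  if (is.numeric(x)) return(itq_series(x))
  stop("expected an itq_series or a numeric vector")
}

#' Pre-analysis validation of a series against an ordinal configuration
#'
#' Checks whether a series supports a stable ordinal-pattern distribution at
#' the requested embedding dimension and delay. The hard floor requires at
#' least `D!` complete windows (fewer windows than patterns cannot populate
#' the distribution); the soft floor of `5 * D!` windows flags estimates
#' likely dominated by sampling noise. The fractions of tied windows and of
#' windows skipped because of missing data are always reported. Weak
#' stationarity (the probability of `x[t] < x[t+k]` not depending on `t`) is
#' an assumption of the ordinal approach and is not tested here.
#'
#' @param series An [itq_series] or numeric vector.
#' @param config An [ordinal_config].
#' @return A list of class `itq_validation`: `ok` (logical), `errors`,
#'   `warnings` (character vectors), `n_windows`, `n_tied`, `n_skipped`,
#'   `tied_fraction`, `skipped_fraction`.
#' @examples
#' validate_series(rnorm(500), ordinal_config(D = 4))
#' @export
validate_series <- function(series, config = ordinal_config()) {
  series <- as_itq_series(series)
  st <- window_stats(series$values, config$D, config$tau)
  nfac <- factorial(config$D)
  errors <- character(0)
  warnings <- character(0)
  n_ok <- st$n_complete
  if (config$tie_rule == "reject") n_ok <- n_ok - st$n_tied
  if (n_ok < nfac) {
    errors <- c(errors, sprintf("%d windows < %d patterns (need n_windows >= D!)",
                                n_ok, nfac))
  } else if (n_ok < 5L * nfac) {
    warnings <- c(warnings, sprintf(
      "%d windows < %d (5*D!): pattern probabilities will be noisy", n_ok, 5L * nfac))
  }
  if (st$n_total > 0L && st$n_tied > 0L) {
    warnings <- c(warnings, sprintf("tied windows: %.3f of complete windows",
                                    st$n_tied / max(st$n_complete, 1L)))
  }
  if (st$n_skipped > 0L) {
    warnings <- c(warnings, sprintf("windows skipped for missing data: %.3f",
                                    st$n_skipped / st$n_total))
  }
  structure(list(
    ok = length(errors) == 0L,
    errors = errors,
    warnings = warnings,
    n_windows = n_ok,
    n_tied = st$n_tied,
    n_skipped = st$n_skipped,
    tied_fraction = if (st$n_complete > 0L) st$n_tied / st$n_complete else NA_real_,
    skipped_fraction = if (st$n_total > 0L) st$n_skipped / st$n_total else NA_real_
  ), class = "itq_validation")
}

#' @export
print.itq_validation <- function(x, ...) {
  cat(sprintf("<itq_validation> %s; n_windows = %d\n",
              if (x$ok) "ok" else "NOT ok", x$n_windows))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Count total/complete/tied/skipped windows without building distributions.
window_stats <- function(values, D, tau) {
  n <- length(values)
  span <- (D - 1L) * tau
  n_total <- n - span
  if (n_total < 1L) {
    return(list(n_total = max(n_total, 0L), n_complete = 0L,
                n_skipped = max(n_total, 0L), n_tied = 0L))
  }
  emb <- embed_matrix(values, D, tau)
  complete <- stats::complete.cases(emb)
  tied <- rep(FALSE, nrow(emb))
  for (a in seq_len(D - 1L)) {
    for (b in (a + 1L):D) {
      tied <- tied | (emb[, a] == emb[, b])
    }
  }
  tied[!complete] <- FALSE
  list(n_total = n_total,
       n_complete = sum(complete),
       n_skipped = sum(!complete),
       n_tied = sum(tied, na.rm = TRUE))
}

# n_windows x D matrix of embedded vectors (x_j, x_{j+tau}, ..., x_{j+(D-1)tau}).
embed_matrix <- function(values, D, tau) {
  n <- length(values)
  span <- (D - 1L) * tau
  nw <- n - span
  stopifnot(nw >= 1L)
  idx <- outer(seq_len(nw), (0:(D - 1L)) * tau, `+`)
  matrix(values[idx], nrow = nw, ncol = D)
}
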