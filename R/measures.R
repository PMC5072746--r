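#' @keywords internal
# Accept an ordinal_distribution or bare probability vector; validate.
probs_of <- function(P, tol = 1e-8) {
  if (inherits(P, "ordinal_distribution")) P <- P$p
  P <- as.numeric(P)
  if (length(P) < 1L || anyNA(P) || any(P < 0) || abs(sum(P) - 1) > tol)
    stop("not a probability vector (entries >= 0 summing to 1)")
  P
}

#' Shannon entropy of a discrete distribution
#'
#' `S = -sum p_i log(p_i)` in nats, with `0 log 0 := 0`.
#'
#' @param P An [ordinal_distribution] or probability vector.
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(rep(1 / 6, 6))  # log(6)
#' @export
shannon_entropy <- function(P) {
  p <- probs_of(P)
  pos <- p > 0
  -sum(p[pos] * log(p[pos])) + 0  # + 0 normalizes IEEE negative zero
}

#' Normalized Shannon (permutation) entropy
#'
#' `H = S / log(N)` where `N` is the number of states; in `[0, 1]`, 1 for
#' the uniform distribution and 0 for a point mass.
#'
#' @inheritParams shannon_entropy
#' @return Normalized entropy in `[0, 1]`.
#' @export
normalized_entropy <- function(P) {
  p <- probs_of(P)
  if (length(p) < 2L) return(0)
  shannon_entropy(p) / log(length(p))
}

#' Jensen-Shannon disequilibrium from the uniform distribution
#'
#' The normalized Jensen-Shannon divergence between `P` and the uniform
#' distribution over the same `N` states:
#' `Q_J = Q0 * (S[(P+Pe)/2] - S[P]/2 - S[Pe]/2)` with
#' `Q0 = -2 / (((N+1)/N) log(N+1) - 2 log(2N) + log N)`, the constant that
#' makes `Q_J = 1` exactly when `P` is a point mass.
#'
#' @inheritParams shannon_entropy
#' @return Disequilibrium in `[0, 1]`.
#' @export
disequilibrium <- function(P) {
  p <- probs_of(P)
  N <- length(p)
  if (N < 2L) return(0)
  pe <- rep(1 / N, N)
  J <- shannon_entropy((p + pe) / 2) - shannon_entropy(p) / 2 - log(N) / 2
  Q0 <- -2 / (((N + 1) / N) * log(N + 1) - 2 * log(2 * N) + log(N))
  max(0, Q0 * J)
}

#' Jensen-Shannon statistical complexity
#'
#' `C = Q_J * H`: the product of the disequilibrium from the uniform
#' distribution and the normalized entropy. Zero both for a point mass
#' (`H = 0`) and for the uniform distribution (`Q_J = 0`); large for
#' structured dynamics between the two extremes.
#'
#' @inheritParams shannon_entropy
#' @return Complexity in `[0, 1]`.
#' @export
statistical_complexity <- function(P) {
  p <- probs_of(P)
  disequilibrium(p) * normalized_entropy(p)
}

#' Discrete normalized Fisher information
#'
#' `F = F0 * sum_i (sqrt(p[i+1]) - sqrt(p[i]))^2`, built from probability
#' amplitudes; `F0 = 1` when `p` is a point mass at the first or last state
#' and `1/2` otherwise. The value depends on the ordering of the states,
#' which is why the pattern ordering is part of the configuration: the
#' distribution must already be arranged in the ordering the result refers
#' to. Behaves opposite to the entropy at the extremes: 0 for the uniform
#' distribution, 1 for a point mass at an end state.
#'
#' @inheritParams shannon_entropy
#' @return Fisher information in `[0, 1]`.
#' @export
fisher_information <- function(P) {
  p <- probs_of(P)
  N <- length(p)
  if (N < 2L) return(0)
  delta_end <- (p[1] == 1 || p[N] == 1)
  F0 <- if (delta_end) 1 else 1 / 2
  a <- sqrt(p)
  F0 * sum(diff(a)^2)
}

#' Renyi entropy of order q
#'
#' `H_q = log2(sum p_i^q) / (1 - q)` in bits; the `q -> 1` limit is the
#' Shannon entropy (in bits). For `q > 1` low-probability patterns are
#' suppressed, a single-exponent analogue of variance weighting.
#'
#' @inheritParams shannon_entropy
#' @param q Positive order, `q != 1`.
#' @param normalized Divide by `log2(N)`.
#' @return Renyi entropy in bits (or normalized, unitless).
#' @export
renyi_entropy <- function(P, q, normalized = FALSE) {
  p <- probs_of(P)
  if (!is.numeric(q) || length(q) != 1L || q <= 0) stop("q must be positive")
  if (q == 1) stop("q = 1 is the Shannon limit: use shannon_entropy")
  h <- log2(sum(p[p > 0]^q)) / (1 - q)
  if (normalized) h / log2(length(p)) else h
}

#' Jensen-Shannon divergence between two pattern distributions
#'
#' `J = S[(P+Q)/2] - S[P]/2 - S[Q]/2` in nats: a symmetric, bounded
#' (`<= log 2`) distance between ordinal distributions, zero iff they are
#' equal. This is the model-benchmark distance: computed between the ordinal
#' distributions of an observed and a simulated series it measures mismatch
#' in dynamics while being blind to bias and scale.
#'
#' @param P,Q [ordinal_distribution] objects sharing `D`, `tau` and ordering,
#'   or bare probability vectors of equal length.
#' @param normalized Divide by `log(2)` so the maximum is 1.
#' @return Divergence in nats (or normalized).
#' @export
jensen_shannon_divergence <- function(P, Q, normalized = FALSE) {
  if (inherits(P, "ordinal_distribution") && inherits(Q, "ordinal_distribution")) {
    if (P$D != Q$D || P$tau != Q$tau || P$ordering != Q$ordering)
      stop("incomparable distributions: D, tau and ordering must match")
  }
  p <- probs_of(P); q <- probs_of(Q)
  if (length(p) != length(q))
    stop("incomparable distributions: different number of states")
  J <- shannon_entropy((p + q) / 2) - shannon_entropy(p) / 2 - shannon_entropy(q) / 2
  J <- max(0, J)
  if (normalized) J / log(2) else J
}

#' Limit curves of the entropy-complexity plane
#'
#' For a fixed number of states `N`, the attainable complexity at a given
#' entropy `H` lies between curves `Cmin(H)` and `Cmax(H)`. The lower curve
#' is traced by the one-parameter family `(p, (1-p)/(N-1), ...)`; the upper
#' curve is the envelope over families having `m` components exactly zero and
#' the remaining mass split as one free component plus equal shares,
#' `m = 0..N-2`. Curves are evaluated on dense parameter grids and returned
#' on a regular `H` grid by linear interpolation.
#'
#' @param N Number of states (e.g. `factorial(D)`), >= 2.
#' @param grid_points Number of points of the returned `H` grid (>= 10).
#' @param param_points Points per one-parameter family curve.
#' @return An object of class `complexity_bounds`: `N`, `h_grid`, `c_min`,
#'   `c_max`.
#' @examples
#' b <- complexity_bounds(factorial(4))
#' max(b$c_max)
#' @export
complexity_bounds <- function(N, grid_points = 500L, param_points = 2000L) {
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("N must be an integer >= 2")
  if (grid_points < 10L) stop("grid_points must be >= 10")
  Q0 <- -2 / (((N + 1) / N) * log(N + 1) - 2 * log(2 * N) + log(N))
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  # closed-form H and C along the family (p, q, ..., q, 0 x m) with
  # q = (1 - p)/(nz - 1); vectorized over the parameter grid
  hc_family <- function(pp, nz, m) {
    q <- (1 - pp) / (nz - 1L)
    S <- -(xlx(pp) + (nz - 1L) * xlx(q))
    H <- S / log(N)
    Smix <- -(xlx((pp + 1 / N) / 2) + (nz - 1L) * xlx((q + 1 / N) / 2) +
                m * xlx(1 / (2 * N)))
    J <- Smix - S / 2 - log(N) / 2
    cbind(H = H, C = pmax(0, Q0 * J) * H)
  }
  # lower curve: p in [1/N, 1], rest equal, no zeros
  low <- hc_family(seq(1 / N, 1, length.out = param_points), N, 0L)
  # upper envelope families: m zeros, one free component, equal remainder
  env <- vector("list", N - 1L)
  for (m in 0:(N - 2L)) {
    nz <- N - m              # nonzero states
    if (nz == 1L) next
    env[[m + 1L]] <- hc_family(seq(0, 1 / nz, length.out = param_points), nz, m)
  }
  up <- do.call(rbind, env)
  h_grid <- seq(0, 1, length.out = grid_points)
  interp_min <- stats::approx(low[, "H"], low[, "C"], xout = h_grid,
                              rule = 2, ties = min)$y
  # envelope: for each h bin take the maximum C among nearby family points,
  # then interpolate the per-bin maxima
  ob <- order(up[, "H"])
  up <- up[ob, , drop = FALSE]
  bins <- cut(up[, "H"], breaks = seq(0, 1, length.out = grid_points + 1L),
              include.lowest = TRUE)
  cmax_bin <- tapply(up[, "C"], bins, max)
  hmid_bin <- tapply(up[, "H"], bins, mean)
  keep <- !is.na(cmax_bin)
  interp_max <- stats::approx(c(0, hmid_bin[keep], 1), c(0, cmax_bin[keep], 0),
                              xout = h_grid, rule = 2, ties = max)$y
  interp_max <- pmax(interp_max, interp_min)
  structure(list(N = N, h_grid = h_grid,
                 c_min = pmax(interp_min, 0), c_max = interp_max),
            class = "complexity_bounds")
}

#' Evaluate limit curves at given entropy values
#'
#' @param bounds A [complexity_bounds] object.
#' @param h Entropy values in `[0, 1]`.
#' @return A data.frame with `h`, `c_min`, `c_max`.
#' @export
bounds_at <- function(bounds, h) {
  stopifnot(inherits(bounds, "complexity_bounds"))
  data.frame(
    h = h,
    c_min = stats::approx(bounds$h_grid, bounds$c_min, xout = h, rule = 2)$y,
    c_max = stats::approx(bounds$h_grid, bounds$c_max, xout = h, rule = 2)$y
  )
}

#' Entropy, complexity and Fisher information of a series
#'
#' Builds the (optionally variance-weighted) ordinal pattern distribution and
#' returns the triple `(H, C, F)` that locates the series in the causal
#' information planes: the entropy-complexity plane `H x C` and the
#' Shannon-Fisher plane `H x F`.
#'
#' @param series An [itq_series] or numeric vector.
#' @param config An [ordinal_config].
#' @return An object of class `itq_result` with fields `H`, `C`, `F`,
#'   `weighted`, `config`, `n_windows`.
#' @examples
#' itq_suite(rnorm(1000), ordinal_config(D = 4, weighted = FALSE))
#' @export
itq_suite <- function(series, config = ordinal_config()) {
  dist <- ordinal_distribution(series, config)
  itq_from_distribution(dist)
}

#' @rdname itq_suite
#' @param dist An [ordinal_distribution].
#' @export
itq_from_distribution <- function(dist) {
  stopifnot(inherits(dist, "ordinal_distribution"))
  structure(list(
    H = normalized_entropy(dist$p),
    C = statistical_complexity(dist$p),
    F = fisher_information(dist$p),
    weighted = dist$weighted,
    config = dist$config,
    n_windows = dist$n_windows
  ), class = "itq_result")
}

#' @export
print.itq_result <- function(x, ...) {
  cat(sprintf("<itq_result> H = %.4f, C = %.4f, F = %.4f (D = %d, tau = %d, %s, %d windows)\n",
              x$H, x$C, x$F, x$config$D, x$config$tau,
              if (x$weighted) "weighted" else "unweighted", x$n_windows))
  invisible(x)
}

#' @export
as.data.frame.itq_result <- function(x, ...) {
  data.frame(H = x$H, C = x$C, F = x$F, D = x$config$D, tau = x$config$tau,
             weighted = x$weighted, n_windows = x$n_windows)
}
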