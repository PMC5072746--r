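#' Ordinal symbolization configuration
#'
#' Parameters governing the Bandt-Pompe symbolization: embedding dimension
#' `D` (pattern length), delay `tau` (lag between the points of a window),
#' whether pattern frequencies are weighted by window variance, the pattern
#' ordering used to index the distribution (which the Fisher information is
#' sensitive to), and how ties inside a window are handled.
#'
#' The defaults (`D = 4`, `tau = 1`, `weighted = TRUE`) are the standard
#' choice for seasonal environmental records of moderate length: `D = 4`
#' keeps the number of patterns (24) small enough for monthly multi-decadal
#' series, and variance weighting down-weights low-amplitude dormant-season
#' windows whose ordinal patterns are mostly noise.
#'
#' @param D Integer embedding dimension, 2..8.
#' @param tau Integer delay >= 1.
#' @param weighted Logical; weight each window by its variance.
#' @param ordering `"lehmer"` (default) indexes patterns by the Lehmer rank
#'   of the permutation; `"custom"` uses `ordering_table`.
#' @param tie_rule `"stable_first_occurrence"` (default) breaks ties by the
#'   earlier time offset; `"reject"` drops tied windows.
#' @param ordering_table For `ordering = "custom"`: an integer permutation of
#'   `1:factorial(D)` giving, for each Lehmer rank `r` (0-based, position
#'   `r + 1`), the 1-based position of that pattern in the distribution.
#' @return An object of class `ordinal_config`.
#' @examples
#' ordinal_config(D = 6, tau = 1, weighted = FALSE)
#' @export
ordinal_config <- function(D = 4L, tau = 1L, weighted = TRUE,
                           ordering = c("lehmer", "custom"),
                           tie_rule = c("stable_first_occurrence", "reject"),
                           ordering_table = NULL) {
  D <- as.integer(D); tau <- as.integer(tau)
  if (is.na(D) || D < 2L || D > 8L) stop("D must be an integer in 2..8")
  if (is.na(tau) || tau < 1L) stop("tau must be an integer >= 1")
  ordering <- match.arg(ordering)
  tie_rule <- match.arg(tie_rule)
  if (ordering == "custom") {
    nfac <- factorial(D)
    if (is.null(ordering_table) ||
        !setequal(as.integer(ordering_table), seq_len(nfac)) ||
        length(ordering_table) != nfac)
      stop("ordering_table must be a permutation of 1:factorial(D)")
    ordering_table <- as.integer(ordering_table)
  } else {
    ordering_table <- NULL
  }
  structure(list(D = D, tau = tau, weighted = isTRUE(weighted),
                 ordering = ordering, tie_rule = tie_rule,
                 ordering_table = ordering_table),
            class = "ordinal_config")
}

#' @export
print.ordinal_config <- function(x, ...) {
  cat(sprintf("<ordinal_config> D = %d, tau = %d, %s, ordering = %s, ties = %s\n",
              x$D, x$tau, if (x$weighted) "weighted" else "unweighted",
              x$ordering, x$tie_rule))
  invisible(x)
}

#' Lehmer rank of a permutation
#'
#' Maps a permutation of `0:(D-1)` to its rank in the factorial number
#' system: `rank = sum_i c_i * (D-1-i)!` where `c_i` counts entries after
#' position `i` that are smaller than the entry at `i`. The map is a
#' bijection onto `0:(factorial(D)-1)` and is the canonical pattern ordering
#' used for the Fisher information.
#'
#' @param perm Integer vector, a permutation of `0:(D-1)`.
#' @return Integer rank in `0:(factorial(D) - 1)`.
#' @examples
#' lehmer_rank(c(0, 1, 2))  # 0
#' lehmer_rank(c(2, 1, 0))  # 5
#' @export
lehmer_rank <- function(perm) {
  perm <- as.integer(perm)
  D <- length(perm)
  if (D < 1L || anyNA(perm) || !setequal(perm, 0:(D - 1L)))
    stop("not a permutation of 0:(D-1)")
  r <- 0
  for (i in seq_len(D - 1L)) {
    c_i <- sum(perm[(i + 1L):D] < perm[i])
    r <- r + c_i * factorial(D - i)
  }
  as.integer(r)
}

#' Permutation with a given Lehmer rank
#'
#' Inverse of [lehmer_rank()].
#'
#' @param rank Integer in `0:(factorial(D) - 1)`.
#' @param D Permutation length.
#' @return Integer vector, permutation of `0:(D-1)`.
#' @export
lehmer_unrank <- function(rank, D) {
  rank <- as.integer(rank); D <- as.integer(D)
  if (is.na(rank) || rank < 0L || rank >= factorial(D))
    stop("rank out of range")
  pool <- 0:(D - 1L)
  out <- integer(D)
  for (i in seq_len(D)) {
    f <- factorial(D - i)
    k <- rank %/% f
    rank <- rank %% f
    out[i] <- pool[k + 1L]
    pool <- pool[-(k + 1L)]
  }
  out
}

#' Extract ordinal pattern ranks from a series
#'
#' Slides a window `(x_j, x_{j+tau}, ..., x_{j+(D-1)tau})` along the series
#' and symbolizes each complete window as the permutation of time offsets
#' sorted by ascending value, returned as its Lehmer rank. Ties are broken by
#' the earlier time offset (so the symbolization is deterministic), or the
#' window is rejected when `tie_rule = "reject"`. Windows containing missing
#' values are always skipped. Pattern ranks are invariant under strictly
#' increasing transformations of the series.
#'
#' @param series An [itq_series] or numeric vector.
#' @param config An [ordinal_config].
#' @return Integer vector of Lehmer ranks in `0:(factorial(D)-1)`, one per
#'   retained window, with attributes `n_skipped` (missing-data windows) and
#'   `n_tied` (tied windows, rejected or not).
#' @examples
#' extract_patterns(c(1, 3, 2, 5), ordinal_config(D = 3, tau = 1))  # 1 2
#' @export
extract_patterns <- function(series, config = ordinal_config()) {
  series <- as_itq_series(series)
  pr <- pattern_ranks(series$values, config)
  if (length(pr$ranks) == 0L)
    stop(sprintf("series too short for (D = %d, tau = %d): no complete window",
                 config$D, config$tau))
  structure(pr$ranks, n_skipped = pr$n_skipped, n_tied = pr$n_tied)
}

# Vectorized symbolization. For each window let r_i be the 0-based rank of
# x_i within the window (ties to the earlier offset) and d_i the number of
# earlier entries strictly greater than x_i. Then the Lehmer code of the
# argsort permutation has c_{r_i} = d_i, so
#   rank = sum_i d_i * (D - 1 - r_i)!
# which needs only the D*(D-1)/2 pairwise comparisons, vectorized over all
# windows at once.
pattern_ranks <- function(values, config) {
  D <- config$D; tau <- config$tau
  n <- length(values)
  span <- (D - 1L) * tau
  if (n - span < 1L)
    return(list(ranks = integer(0), n_skipped = 0L, n_tied = 0L,
                keep = logical(0), emb = NULL))
  emb <- embed_matrix(values, D, tau)
  complete <- stats::complete.cases(emb)
  nw <- nrow(emb)
  rnk <- matrix(0L, nw, D)   # r_i: rank of column i within its row
  dcnt <- matrix(0L, nw, D)  # d_i: earlier entries strictly greater
  tied <- rep(FALSE, nw)
  for (a in seq_len(D - 1L)) {
    xa <- emb[, a]
    for (b in (a + 1L):D) {
      xb <- emb[, b]
      lt <- xb < xa           # later entry strictly smaller
      eq <- xb == xa
      tied <- tied | eq
      # earlier-offset-first: on ties the earlier column a ranks lower
      rnk[, a] <- rnk[, a] + lt
      rnk[, b] <- rnk[, b] + (!lt & !eq)  # xa < xb
      rnk[, b] <- rnk[, b] + eq           # tie: b ranks above a
      dcnt[, b] <- dcnt[, b] + lt         # xa > xb, a earlier
    }
  }
  w <- factorial((D - 1L) - rnk)  # per-entry positional weight (D-1-r_i)!
  ranks <- as.integer(rowSums(dcnt * w))
  keep <- complete
  n_tied <- sum(tied & complete, na.rm = TRUE)
  if (config$tie_rule == "reject") keep <- keep & !(tied %in% TRUE) & !is.na(tied)
  keep[is.na(keep)] <- FALSE
  list(ranks = ranks[keep], n_skipped = sum(!complete), n_tied = n_tied,
       keep = keep, emb = emb)
}

#' Ordinal pattern probability distribution
#'
#' Builds the Bandt-Pompe probability distribution over the `D!` ordinal
#' patterns of a series. Unweighted, each retained window contributes 1 to
#' its pattern; weighted, each window contributes its variance (computed over
#' the embedded vector, so symbolization and weighting see the same points),
#' and probabilities are the normalized weight totals. The distribution is
#' indexed by Lehmer rank unless a custom ordering table is supplied.
#'
#' @param series An [itq_series] or numeric vector.
#' @param config An [ordinal_config].
#' @return An object of class `ordinal_distribution`: `p` (probability vector
#'   of length `D!`), `mass` (count or total weight per pattern), `D`, `tau`,
#'   `ordering`, `weighted`, `n_windows`, `total_weight`, `n_skipped`,
#'   `n_tied`.
#' @examples
#' d <- ordinal_distribution(rnorm(500), ordinal_config(D = 4, weighted = FALSE))
#' sum(d$p)
#' @export
ordinal_distribution <- function(series, config = ordinal_config()) {
  series <- as_itq_series(series)
  pr <- pattern_ranks(series$values, config)
  if (length(pr$ranks) == 0L)
    stop(sprintf("series too short for (D = %d, tau = %d): no complete window",
                 config$D, config$tau))
  nfac <- factorial(config$D)
  if (config$weighted) {
    emb_kept <- pr$emb[pr$keep, , drop = FALSE]
    # population variance of each embedded vector (Eq-style 1/D normalization)
    mu <- rowMeans(emb_kept)
    wts <- rowMeans((emb_kept - mu)^2)
    total <- sum(wts)
    if (total <= 0)
      stop("degenerate series: zero total weight (all windows constant)")
    mass <- vapply(seq_len(nfac) - 1L,
                   function(r) sum(wts[pr$ranks == r]), numeric(1))
  } else {
    mass <- tabulate(pr$ranks + 1L, nbins = nfac)
    total <- sum(mass)
  }
  p <- mass / sum(mass)
  if (config$ordering == "custom") {
    pos <- config$ordering_table
    p2 <- numeric(nfac); m2 <- numeric(nfac)
    p2[pos] <- p; m2[pos] <- mass
    p <- p2; mass <- m2
  }
  structure(list(
    p = p, mass = mass, D = config$D, tau = config$tau,
    ordering = config$ordering, weighted = config$weighted,
    n_windows = length(pr$ranks),
    total_weight = if (config$weighted) total else as.numeric(total),
    n_skipped = pr$n_skipped, n_tied = pr$n_tied,
    config = config
  ), class = "ordinal_distribution")
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("<ordinal_distribution> D = %d, tau = %d, %s, %d patterns, %d windows\n",
              x$D, x$tau, if (x$weighted) "weighted" else "unweighted",
              length(x$p), x$n_windows))
  invisible(x)
}

#' Tabulate an ordinal distribution
#'
#' @param x An [ordinal_distribution].
#' @param ... Unused.
#' @return A data.frame with columns `pattern_rank` (position in the
#'   configured ordering, 0-based), `permutation` (hyphen-joined time
#'   offsets), `probability`, `count_or_weight`.
#' @export
as.data.frame.ordinal_distribution <- function(x, ...) {
  nfac <- length(x$p)
  # position -> Lehmer rank (identity unless custom ordering)
  lehmer_of_pos <- seq_len(nfac) - 1L
  if (x$ordering == "custom") {
    pos <- x$config$ordering_table
    lehmer_of_pos[pos] <- seq_len(nfac) - 1L
  }
  perms <- vapply(lehmer_of_pos,
                  function(r) paste(lehmer_unrank(r, x$D), collapse = "-"),
                  character(1))
  data.frame(pattern_rank = seq_len(nfac) - 1L,
             permutation = perms,
             probability = x$p,
             count_or_weight = x$mass,
             stringsAsFactors = FALSE)
}
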