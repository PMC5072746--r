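# Naive reference implementations used as independent oracles in tests.
# These deliberately use per-window sorting and direct formula arithmetic,
# not the vectorized identities of the package code.

# Lehmer rank by explicit enumeration over all permutations in factorial
# (lexicographic) order: rank = position in the lexicographic listing.
lex_rank <- function(perm) {
  D <- length(perm)
  perms <- all_perms(D)
  which(vapply(seq_len(nrow(perms)), function(i) all(perms[i, ] == perm),
               logical(1))) - 1L
}

all_perms <- function(D) {
  if (D == 1) return(matrix(0L, 1, 1))
  sub <- all_perms(D - 1)
  out <- NULL
  for (first in 0:(D - 1)) {
    rest <- setdiff(0:(D - 1), first)
    block <- matrix(rest[sub + 1L], nrow = nrow(sub))
    out <- rbind(out, cbind(first, block))
  }
  unname(out)
}

# Per-window sort-and-rank oracle for pattern extraction.
naive_patterns <- function(values, D, tau, tie_rule = "stable_first_occurrence") {
  n <- length(values)
  span <- (D - 1) * tau
  out <- integer(0)
  if (n - span < 1) return(out)
  for (j in seq_len(n - span)) {
    w <- values[j + (0:(D - 1)) * tau]
    if (anyNA(w)) next
    if (tie_rule == "reject" && anyDuplicated(w)) next
    perm <- order(w) - 1L  # order() is stable: ties to the earlier offset
    out <- c(out, lex_rank(perm))
  }
  out
}

# Direct-formula quantifier oracles.
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_complexity <- function(p) {
  N <- length(p)
  pe <- rep(1 / N, N)
  J <- oracle_entropy((p + pe) / 2) - oracle_entropy(p) / 2 - oracle_entropy(pe) / 2
  Q0 <- -2 / (((N + 1) / N) * log(N + 1) - 2 * log(2 * N) + log(N))
  Q0 * J * (oracle_entropy(p) / log(N))
}

random_probs <- function(N) {
  x <- stats::rexp(N)
  x / sum(x)
}
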