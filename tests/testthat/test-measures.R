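p_half <- c(0.5, 0.5, 0, 0, 0, 0)
delta6 <- c(1, 0, 0, 0, 0, 0)
unif6 <- rep(1 / 6, 6)

test_that("Shannon entropy has its closed-form values and rejects non-PDFs", {
  expect_equal(shannon_entropy(unif6), log(6), tolerance = 1e-12)
  expect_equal(shannon_entropy(delta6), 0)
  expect_equal(shannon_entropy(p_half), log(2), tolerance = 1e-12)
  expect_error(shannon_entropy(c(0.5, 0.6)), "not a probability vector")
  expect_error(shannon_entropy(c(1.2, -0.2)), "not a probability vector")
})

test_that("normalized entropy maps uniform to 1 and delta to 0", {
  expect_equal(normalized_entropy(unif6), 1, tolerance = 1e-12)
  expect_equal(normalized_entropy(delta6), 0)
  expect_equal(normalized_entropy(p_half), log(2) / log(6), tolerance = 1e-12)
})

test_that("disequilibrium is normalized so a point mass scores exactly 1", {
  expect_equal(disequilibrium(unif6), 0, tolerance = 1e-12)
  for (N in c(2, 6, 24, 120)) {
    expect_equal(disequilibrium(c(1, rep(0, N - 1))), 1, tolerance = 1e-12)
    # delta position must not matter for the Jensen-Shannon distance to uniform
    expect_equal(disequilibrium(c(rep(0, N - 1), 1)), 1, tolerance = 1e-12)
  }
  expect_equal(disequilibrium(p_half), 0.7011, tolerance = 1e-4)
})

test_that("statistical complexity is the product form and matches the direct oracle", {
  expect_equal(statistical_complexity(unif6), 0, tolerance = 1e-12)
  expect_equal(statistical_complexity(delta6), 0)
  expect_lt(abs(statistical_complexity(p_half) - 0.2713), 1e-4)
  set.seed(11)
  for (i in 1:20) {
    p <- random_probs(sample(c(6, 24), 1))
    expect_equal(statistical_complexity(p), oracle_complexity(p),
                 tolerance = 1e-12)
  }
})

test_that("Fisher information uses amplitude differences and the end-state rule", {
  expect_equal(fisher_information(unif6), 0, tolerance = 1e-12)
  expect_equal(fisher_information(delta6), 1)
  expect_equal(fisher_information(c(0, 0, 0, 0, 0, 1)), 1)
  # interior point mass: F0 = 1/2, two unit jumps
  expect_equal(fisher_information(c(0, 1, 0, 0, 0, 0)), 1)
  expect_equal(fisher_information(p_half), 0.25, tolerance = 1e-12)
})

test_that("Renyi entropy has closed-form anchors and the Shannon limit", {
  expect_equal(renyi_entropy(unif6, 2), log2(6), tolerance = 1e-12)
  expect_equal(renyi_entropy(unif6, 0.5), log2(6), tolerance = 1e-12)
  expect_equal(renyi_entropy(delta6, 2), 0)
  expect_equal(renyi_entropy(p_half, 2), 1, tolerance = 1e-12)
  expect_equal(renyi_entropy(unif6, 2, normalized = TRUE), 1, tolerance = 1e-12)
  expect_error(renyi_entropy(unif6, 1), "shannon")
  set.seed(3)
  p <- random_probs(24)
  sh_bits <- shannon_entropy(p) / log(2)
  # H_q is differentiable in q: each side approaches linearly and the
  # symmetric mean cancels the first-order term
  hi <- renyi_entropy(p, 1 + 1e-4); lo <- renyi_entropy(p, 1 - 1e-4)
  expect_lt(abs(hi - sh_bits), 1e-3)
  expect_lt(abs(lo - sh_bits), 1e-3)
  expect_lt(abs((hi + lo) / 2 - sh_bits), 1e-6)
})

test_that("Jensen-Shannon divergence is a symmetric bounded distance", {
  set.seed(5)
  for (i in 1:20) {
    p <- random_probs(24); q <- random_probs(24)
    J <- jensen_shannon_divergence(p, q)
    expect_gte(J, 0)
    expect_lte(J, log(2) + 1e-12)
    expect_equal(J, jensen_shannon_divergence(q, p), tolerance = 1e-12)
    expect_equal(jensen_shannon_divergence(p, p), 0, tolerance = 1e-12)
  }
  d1 <- c(1, rep(0, 5)); d2 <- c(rep(0, 5), 1)
  expect_equal(jensen_shannon_divergence(d1, d2), log(2), tolerance = 1e-12)
  expect_equal(jensen_shannon_divergence(d1, d2, normalized = TRUE), 1,
               tolerance = 1e-12)
  a <- ordinal_distribution(rnorm(100), ordinal_config(D = 3, weighted = FALSE))
  b <- ordinal_distribution(rnorm(100), ordinal_config(D = 4, weighted = FALSE))
  expect_error(jensen_shannon_divergence(a, b), "incomparable")
})

test_that("all quantifiers stay in [0,1] on random probability vectors", {
  set.seed(9)
  for (i in 1:50) {
    N <- sample(c(2, 6, 24, 120), 1)
    p <- random_probs(N)
    # occasionally sparsify to visit the boundary regions
    if (i %% 3 == 0) { p[sample(N, N %/% 2)] <- 0; p <- p / sum(p) }
    for (v in c(normalized_entropy(p), disequilibrium(p),
                statistical_complexity(p), fisher_information(p))) {
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("limit curves vanish at the entropy extremes and bound random PDFs", {
  b <- complexity_bounds(24)
  expect_lt(b$c_max[1], 0.02)
  expect_lt(b$c_max[length(b$c_max)], 0.02)
  expect_true(all(b$c_min >= 0))
  expect_true(all(b$c_min <= b$c_max + 1e-12))
  set.seed(13)
  H <- C <- numeric(500)
  for (i in 1:500) {
    p <- random_probs(24)
    H[i] <- normalized_entropy(p)
    C[i] <- statistical_complexity(p)
  }
  ba <- bounds_at(b, H)
  expect_true(all(C >= ba$c_min - 1e-6))
  expect_true(all(C <= ba$c_max + 1e-6))
  expect_error(complexity_bounds(1), "N must be")
})

test_that("the quantifier suite reproduces the canonical plane anchors", {
  # monotone ramp: single pattern
  r <- itq_suite(seq_len(200), ordinal_config(D = 4, weighted = FALSE))
  expect_equal(c(r$H, r$C, r$F), c(0, 0, 1))
  # and its mirror image at the extremes: uniform-ish noise
  rn <- itq_suite(white_noise(20000, seed = 1),
                  ordinal_config(D = 4, weighted = FALSE))
  expect_gt(rn$H, 0.98)
  expect_lt(rn$C, 0.05)
  expect_lt(rn$F, 0.05)
  expect_s3_class(as.data.frame(r), "data.frame")
})

test_that("suite results respect the complexity limit band on random series", {
  set.seed(17)
  b <- complexity_bounds(24)
  for (i in 1:20) {
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.8, 0.8)), 300))
    r <- itq_suite(x, ordinal_config(D = 4, weighted = (i %% 2 == 0)))
    ba <- bounds_at(b, r$H)
    expect_gte(r$C, ba$c_min - 1e-6)
    expect_lte(r$C, ba$c_max + 1e-6)
  }
})
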