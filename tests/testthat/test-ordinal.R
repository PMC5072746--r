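cfg3 <- ordinal_config(D = 3, tau = 1, weighted = FALSE)

test_that("lehmer_rank matches the lexicographic enumeration oracle and is bijective", {
  expect_identical(lehmer_rank(c(0, 1, 2)), 0L)
  expect_identical(lehmer_rank(c(2, 1, 0)), 5L)
  expect_identical(lehmer_rank(c(1, 0, 2)), 2L)
  for (D in 2:5) {
    perms <- all_perms(D)
    ranks <- apply(perms, 1, lehmer_rank)
    expect_identical(sort(ranks), 0:(factorial(D) - 1L))
    # lexicographic position == Lehmer rank
    lex <- apply(perms, 1, lex_rank)
    expect_identical(ranks, as.integer(lex))
    # unrank inverts rank
    for (i in seq_len(nrow(perms)))
      expect_identical(lehmer_unrank(ranks[i], D), as.integer(perms[i, ]))
  }
  expect_error(lehmer_rank(c(0, 0, 1)), "not a permutation")
  expect_error(lehmer_rank(c(1, 2, 3)), "not a permutation")
})

test_that("extract_patterns symbolizes windows by ascending-value argsort", {
  expect_equal(as.integer(extract_patterns(c(1, 3, 2, 5), cfg3)), c(1L, 2L))
  expect_equal(as.integer(extract_patterns(c(1, 2, 3, 4, 5), cfg3)), rep(0L, 3))
  # invariance under a nonlinear monotone transform
  expect_identical(as.integer(extract_patterns(c(1, 3, 2, 5), cfg3)),
                   as.integer(extract_patterns(c(1, 3, 2, 5)^3, cfg3)))
  expect_error(extract_patterns(c(1, 2), cfg3), "too short")
})

test_that("pattern extraction matches the naive per-window sort oracle", {
  set.seed(42)
  for (rep in 1:10) {
    D <- sample(3:5, 1)
    tau <- sample(1:3, 1)
    x <- rnorm(200)
    cfg <- ordinal_config(D = D, tau = tau, weighted = FALSE)
    expect_identical(as.integer(extract_patterns(x, cfg)),
                     as.integer(naive_patterns(x, D, tau)))
  }
})

test_that("ties are broken by earlier time offset, or rejected on request", {
  x <- c(2, 2, 1, 2, 2)  # several tied windows
  cfg_stable <- ordinal_config(D = 3, weighted = FALSE)
  cfg_reject <- ordinal_config(D = 3, weighted = FALSE, tie_rule = "reject")
  p_stable <- extract_patterns(x, cfg_stable)
  expect_identical(as.integer(p_stable),
                   as.integer(naive_patterns(x, 3, 1)))
  expect_identical(as.integer(naive_patterns(x, 3, 1, "reject")), integer(0))
  expect_error(extract_patterns(x, cfg_reject), "too short")
  # constant window: all ties -> identity pattern under stable rule
  expect_equal(as.integer(extract_patterns(c(7, 7, 7), cfg_stable)), 0L)
  expect_gt(attr(p_stable, "n_tied"), 0)
})

test_that("windows containing missing values are skipped and counted", {
  x <- c(1, 2, NA, 4, 5, 6, 7)
  pat <- extract_patterns(x, cfg3)
  # windows starting at 1,2,3 touch the NA; windows 4 and 5 survive
  expect_length(as.integer(pat), 2L)
  expect_identical(attr(pat, "n_skipped"), 3L)
  d <- ordinal_distribution(x, cfg3)
  expect_equal(sum(d$mass), d$n_windows)
})

test_that("unweighted distribution is the relative pattern frequency", {
  d <- ordinal_distribution(c(1, 2, 3, 4, 5), cfg3)
  expect_equal(d$p, c(1, 0, 0, 0, 0, 0))
  d2 <- ordinal_distribution(c(1, 3, 2, 5), cfg3)
  expect_equal(d2$p, c(0, 0.5, 0.5, 0, 0, 0))
  expect_equal(sum(d2$p), 1, tolerance = 1e-12)
})

test_that("variance weighting reproduces the hand-computed worked example", {
  cfg <- ordinal_config(D = 3, tau = 1, weighted = TRUE)
  d <- ordinal_distribution(c(0, 1, 0, 10, 20, 10), cfg)
  # windows: variances 2/9, 546/27, 200/3, 600/27; patterns ranks 1, 2, 0, 1
  expect_equal(d$p[2], 606 / 2952, tolerance = 1e-12)
  expect_equal(d$p[3], 546 / 2952, tolerance = 1e-12)
  expect_equal(d$p[1], 1800 / 2952, tolerance = 1e-12)
  expect_equal(d$total_weight, 2952 / 27, tolerance = 1e-12)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
})

test_that("weighted equals unweighted when all window variances are equal", {
  # windows are cyclic shifts of the same multiset -> identical variances
  x <- rep(c(1, 2, 3), 20)
  dw <- ordinal_distribution(x, ordinal_config(D = 3, weighted = TRUE))
  du <- ordinal_distribution(x, ordinal_config(D = 3, weighted = FALSE))
  expect_equal(dw$p, du$p, tolerance = 1e-12)
})

test_that("weighting a constant series is rejected as degenerate", {
  expect_error(ordinal_distribution(rep(1, 50), ordinal_config(D = 3, weighted = TRUE)),
               "degenerate")
})

test_that("tau > 1 embeds with the requested delay in both symbols and weights", {
  x <- c(1, 9, 2, 8, 3, 7, 4, 6)
  cfg <- ordinal_config(D = 3, tau = 2, weighted = FALSE)
  expect_identical(as.integer(extract_patterns(x, cfg)),
                   as.integer(naive_patterns(x, 3, 2)))
  # weighted tau=2: weight of first window is var of (x1, x3, x5)
  dw <- ordinal_distribution(x, ordinal_config(D = 3, tau = 2, weighted = TRUE))
  w1 <- mean((c(1, 2, 3) - 2)^2)
  expect_equal(dw$total_weight,
               sum(sapply(1:4, function(j) {
                 w <- x[c(j, j + 2, j + 4)]
                 mean((w - mean(w))^2)
               })), tolerance = 1e-12)
  expect_true(w1 > 0)
})

test_that("a custom ordering table permutes the distribution as specified", {
  x <- c(1, 3, 2, 5, 4, 6)
  tab <- c(6L, 1L, 2L, 3L, 4L, 5L)  # Lehmer rank 0 -> position 6, etc.
  d_lehmer <- ordinal_distribution(x, ordinal_config(D = 3, weighted = FALSE))
  d_custom <- ordinal_distribution(x, ordinal_config(D = 3, weighted = FALSE,
                                                     ordering = "custom",
                                                     ordering_table = tab))
  expect_equal(d_custom$p[tab], d_lehmer$p)
  expect_error(ordinal_config(D = 3, ordering = "custom",
                              ordering_table = c(1L, 1L, 2L, 3L, 4L, 5L)),
               "permutation")
})

test_that("validate_series applies hard and soft window floors and reports ties", {
  cfg4 <- ordinal_config(D = 4)
  v_ok <- validate_series(rnorm(500), cfg4)
  expect_true(v_ok$ok)
  expect_equal(v_ok$n_windows, 497)
  v_short <- validate_series(rnorm(20), cfg4)
  expect_false(v_short$ok)
  expect_match(v_short$errors[1], "17 windows < 24")
  # heavy ties produce a warning with the tied fraction
  set.seed(7)
  x <- sample(1:3, 100, replace = TRUE)
  v_tied <- validate_series(x, ordinal_config(D = 3))
  expect_gt(v_tied$tied_fraction, 0.5)
  expect_true(any(grepl("tied", v_tied$warnings)))
  # missing data reported
  x2 <- rnorm(200); x2[seq(5, 200, by = 7)] <- NA
  v_miss <- validate_series(x2, ordinal_config(D = 3))
  expect_gt(v_miss$skipped_fraction, 0)
})

test_that("distribution tabulation carries permutations and masses", {
  d <- ordinal_distribution(c(1, 3, 2, 5), cfg3)
  df <- as.data.frame(d)
  expect_equal(names(df), c("pattern_rank", "permutation", "probability",
                            "count_or_weight"))
  expect_equal(df$permutation[1], "0-1-2")
  expect_equal(df$probability[df$pattern_rank == 1], 0.5)
  expect_equal(sum(df$count_or_weight), 2)
})
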