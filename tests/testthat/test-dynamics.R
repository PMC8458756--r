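test_that("occupancy pools window counts within groups", {
  solo <- occupancy(list(rep(2L, 10)), k = 7)
  expect_equal(unname(solo$group[1, ]), c(0, 1, 0, 0, 0, 0, 0))

  toy <- occupancy(list(c(1L, 1L, 3L), c(3L, 3L, 3L)), grouping = "g", k = 7)
  expect_equal(unname(toy$group[1, c(1, 3)]), c(2 / 6, 4 / 6))
  expect_equal(sum(toy$group), 1)
  expect_equal(unname(rowSums(toy$recording)), c(1, 1))

  expect_error(occupancy(list(c(1L, 9L)), k = 7), "1\\.\\.k")

  # equivariance under label permutation
  seqs <- list(c(1L, 2L, 2L, 3L), c(3L, 1L, 1L, 1L))
  perm <- c(4L, 1L, 2L, 3L, 5L, 6L, 7L)
  direct <- occupancy(lapply(seqs, function(s) perm[s]), k = 7)$group
  moved <- occupancy(seqs, k = 7)$group[, order(perm), drop = FALSE]
  expect_equal(unname(direct), unname(moved))
})

test_that("transition counts match hand counts and chain expectations", {
  expect_identical(count_transitions(rep(4L, 50)), 0L)
  expect_identical(count_transitions(c(1L, 1L, 2L, 2L, 1L)), 2L)
  expect_identical(count_transitions(3L), 0L)
  # invariant under label permutation
  s <- c(1L, 3L, 3L, 2L, 1L, 1L)
  expect_identical(count_transitions(s), count_transitions(c(5L, 6L, 7L)[s]))

  # Monte Carlo vs. the analytic expectation (L-1) * mean leave probability:
  # two equal-mass states at mean_dwell D have leave probability
  # c*(1 - pi_i) with c = 1/(D*(1 - sum(pi^2))), here 1/D * ... = 0.2 at D = 5
  spec <- group_spec("AWAKE", 1, c(0.5, 0.5), mean_dwell = 5)
  L <- 200
  counts <- vapply(1:500, function(i) {
    count_transitions(sample_state_sequence(spec, L, seed = 7000 + i))
  }, integer(1))
  expected <- (L - 1) * 0.2
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("the transition matrix is a symmetric unordered-pair distribution", {
  const <- transition_matrix(list(rep(3L, 10), rep(5L, 4)), k = 7)
  expect_equal(sum(diag(const)), 1)
  expect_equal(const[3, 3], 9 / 12)
  expect_equal(const[5, 5], 3 / 12)

  tm <- transition_matrix(list(c(1L, 2L, 1L)), k = 7)
  expect_equal(tm[1, 2], 1)  # both adjacent pairs are {1, 2}
  expect_identical(tm, t(tm))
  expect_equal(sum(tm[upper.tri(tm)]) + sum(diag(tm)), 1)

  # generator-forbidden pairs give exactly zero estimated probability
  spec <- group_spec("UWS", 1, c(0.4, 0.3, 0.3, rep(0, 4)), mean_dwell = 3,
                     forbidden_pairs = list(c(2, 3)))
  seqs <- lapply(1:5, function(i) sample_state_sequence(spec, 2000, seed = 100 + i))
  tmf <- transition_matrix(seqs, k = 7)
  expect_identical(tmf[2, 3], 0)
  expect_gt(tmf[1, 2], 0)
})

test_that("rank-sum comparisons match exact enumeration and are calibrated", {
  same <- compare_groups_ranksum(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p_corrected, 1)

  sep <- compare_groups_ranksum(c(1, 2, 3, 10, 11, 12),
                                rep(c("a", "b"), each = 3))
  # exact two-sided rank-sum p for the most extreme ranking at n = m = 3
  # is 2 / choose(6, 3) = 0.1; corrected by the factor 6 -> 0.6
  expect_equal(sep$p_raw, 0.1)
  expect_equal(sep$p_corrected, 0.6)

  # type-I calibration of the underlying test (factor 1)
  set.seed(71)
  rejections <- vapply(1:2000, function(i) {
    v <- rnorm(20)
    compare_groups_ranksum(v, rep(c("a", "b"), each = 10),
                           bonferroni_factor = 1)$p_corrected < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))

  expect_error(compare_groups_ranksum(1:3, c("a", "a", "a")), "two groups")
})

test_that("the pattern-distribution chi-square matches hand computation", {
  identical_tables <- pattern_distribution_chi2(list(c(1L, 1L, 2L)), list(c(1L, 1L, 2L)))
  expect_equal(identical_tables$statistic, 0)
  expect_equal(identical_tables$p_value, 1)

  # rows (10, 0) and (0, 10): expected counts all 5, X^2 = 4 * 25/5 = 20, df 1
  res <- pattern_distribution_chi2(list(rep(1L, 10)), list(rep(2L, 10)))
  expect_equal(res$statistic, 20)
  expect_identical(as.integer(res$df), 1L)

  expect_error(pattern_distribution_chi2(list(rep(1L, 5)), list(rep(1L, 5))),
               "degenerate")
})

test_that("AWAKE and PROP occupancies differ overwhelmingly on synthetic sequences", {
  cfg <- default_cohort_config()
  awake_seqs <- lapply(1:25, function(i)
    sample_state_sequence(cfg$group_specs$AWAKE, 267, seed = 300 + i))
  prop_seqs <- lapply(1:11, function(i)
    sample_state_sequence(cfg$group_specs$PROP, 267, seed = 400 + i))
  res <- pattern_distribution_chi2(awake_seqs, prop_seqs)
  expect_lt(res$p_value, 0.001)
})
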