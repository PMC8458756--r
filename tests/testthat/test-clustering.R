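test_that("k = 1 reduces to the component-wise median", {
  set.seed(61)
  x <- matrix(rnorm(40), 20, 2)
  fit <- kmeans_l1(x, k = 1, n_restarts = 3, seed = 1)
  med <- apply(x, 2, median)
  expect_equal(unname(fit$centroids[1, ]), unname(med))
  expect_equal(fit$objective, sum(abs(sweep(x, 2, med))))
})

test_that("the clustering objective matches the brute-force bipartition optimum", {
  # 100 seeded random instances of 8 points in 2-D, k = 2: the iterative
  # solution with 20 restarts should hit the enumerated optimum (127
  # bipartitions, median centroids) in at least 95
  hits <- 0L
  for (i in 1:100) {
    set.seed(1000 + i)
    x <- matrix(rnorm(16), 8, 2)
    fit <- kmeans_l1(x, k = 2, n_restarts = 20, seed = i)
    if (isTRUE(all.equal(fit$objective, brute_force_l1_k2(x), tolerance = 1e-8))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95)
})

test_that("well-separated blobs are recovered exactly", {
  set.seed(62)
  blob1 <- matrix(rnorm(60, mean = 0, sd = 0.1), 30, 2)
  blob2 <- matrix(rnorm(60, mean = 10, sd = 0.1), 30, 2)
  fit <- kmeans_l1(rbind(blob1, blob2), k = 2, n_restarts = 5, seed = 3)
  truth <- rep(1:2, each = 30)
  expect_equal(adjusted_rand_index(fit$labels, truth), 1)
})

test_that("the within-restart objective is monotonically non-increasing", {
  set.seed(63)
  x <- matrix(rnorm(400), 100, 4)
  fit <- kmeans_l1(x, k = 3, n_restarts = 8, seed = 4)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
})

test_that("clustering is invariant to row order up to label permutation", {
  set.seed(64)
  x <- rbind(matrix(rnorm(80, 0, 0.3), 40, 2),
             matrix(rnorm(80, 5, 0.3), 40, 2),
             matrix(rnorm(80, -5, 0.3), 40, 2))
  fit1 <- kmeans_l1(x, k = 3, n_restarts = 10, seed = 5)
  shuffle <- sample(nrow(x))
  fit2 <- kmeans_l1(x[shuffle, ], k = 3, n_restarts = 10, seed = 6)
  expect_equal(fit1$objective, fit2$objective, tolerance = 1e-9)
  expect_equal(adjusted_rand_index(fit1$labels[shuffle], fit2$labels), 1)
})

test_that("component-wise medians minimize the within-cluster L1 sum", {
  set.seed(65)
  x <- matrix(rnorm(60), 20, 3)
  fit <- kmeans_l1(x, k = 2, n_restarts = 10, seed = 7)
  for (j in 1:2) {
    members <- x[fit$labels == j, , drop = FALSE]
    for (col in 1:3) {
      obj_at <- function(c0) sum(abs(members[, col] - c0))
      best_at_centroid <- obj_at(fit$centroids[j, col])
      # scan every member value as candidate: none may beat the median
      expect_true(all(vapply(members[, col], obj_at, numeric(1)) >= best_at_centroid - 1e-9))
    }
  }
})

test_that("k larger than the number of distinct rows errors", {
  x <- matrix(rep(c(1, 2), each = 6), 4, 3, byrow = TRUE)  # 2 distinct rows
  expect_error(kmeans_l1(x, k = 3, n_restarts = 2, seed = 1), "distinct rows")
})

test_that("pattern assignment picks the L1-nearest centroid with low-id ties", {
  model <- structure(list(centroids = rbind(c(0, 0), c(1, 3), c(2, 0)),
                          k = 3L), class = "pattern_model")
  expect_identical(assign_patterns(rbind(c(1, 3)), model), 2L)
  # (1, 0) is L1-distance 1 from centroid 1 and centroid 3: tie -> lowest id
  expect_identical(assign_patterns(rbind(c(1, 0)), model), 1L)

  d <- pattern_distances(rbind(c(1, 1)), model)
  expect_equal(unname(d[1, 1:2]), c(2, 2))  # hand computation
  # assigned label is always the argmin of the distances
  set.seed(66)
  pts <- matrix(rnorm(40), 20, 2)
  expect_identical(assign_patterns(pts, model),
                   apply(pattern_distances(pts, model), 1, which.min))
  expect_error(assign_patterns(matrix(1, 1, 5), model), "does not match")
})

test_that("relabeling recovers the generating permutation", {
  set.seed(67)
  ref <- matrix(rnorm(5 * 8, sd = 3), 5, 8)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  model <- structure(list(centroids = ref[perm, ] + rnorm(40, sd = 0.01), k = 5L),
                     class = "pattern_model")
  expect_identical(relabel_to_reference(model, ref), perm)

  ident <- structure(list(centroids = ref, k = 5L), class = "pattern_model")
  expect_identical(relabel_to_reference(ident, ref), 1:5)

  relabeled <- apply_relabeling(list(c(1L, 2L, 5L)), perm)
  expect_identical(relabeled[[1]], c(3L, 5L, 4L))
})

test_that("window majority states summarize frame-level truth", {
  states <- rep(c(1L, 2L), c(30, 20))
  wm <- window_majority_states(states, window = 10)
  expect_length(wm, 40)
  expect_identical(wm[1:20], rep(1L, 20))   # fully inside the first run
  expect_identical(wm[31:40], rep(2L, 10))
  expect_identical(wm[26], 1L)  # frames 26..35 split 5/5: tie -> lowest id
  expect_identical(wm[27], 2L)  # frames 27..36: majority state 2
})

test_that("our adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(68)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
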