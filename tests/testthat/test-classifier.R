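test_that("Fisher scores follow the two-class formula", {
  x <- cbind(flat = rep(1, 8),
             good = c(0, 1, 0, 1, 2, 3, 2, 3))
  y <- rep(c(FALSE, TRUE), each = 4)
  sc <- fisher_scores(x, y)
  expect_equal(unname(sc["flat"]), 0)
  # class means 0.5 and 2.5, unbiased variances 1/3 each:
  # (2.5 - 0.5)^2 / (1/3 + 1/3) = 6; with values {0,1} vs {2,3}
  xx <- cbind(f = c(0, 1, 2, 3))
  yy <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(unname(fisher_scores(xx, yy)), (2.5 - 0.5)^2 / (0.5 + 0.5))

  # affine invariance
  sc2 <- fisher_scores(cbind(good = 100 + 7 * x[, "good"]), y)
  expect_equal(unname(sc2), unname(sc["good"]))

  expect_error(fisher_scores(x, rep(TRUE, 8)), "classes")
})

test_that("the classifier separates conscious from unconscious synthetic recordings", {
  sc <- sequence_cohort(seed = 9)
  feats <- feature_table(sc$states, sc$recordings, k = 7)
  expect_equal(unname(rowSums(feats[, paste0("pattern", 1:7)])), rep(1, nrow(feats)))
  expect_identical(feats$conscious, feats$group == "AWAKE")

  train <- feats[feats$cohort == "train", ]
  test <- feats[feats$cohort == "test", ]
  expect_identical(nrow(train), 50L)
  expect_identical(nrow(test), 38L)

  clf <- train_classifier(train, n_features = 2)
  # the AWAKE-specific pattern 1 and the anesthesia pattern 7 dominate
  expect_setequal(clf$features, c("pattern1", "pattern7"))

  rate <- evaluate_classifier(clf, test)
  expect_gte(rate, 0.95)

  chance <- permutation_chance(clf, test, n_permutations = 100, seed = 2)
  expect_lt(abs(chance$mean - 0.5), 3 * chance$se + 1e-9)

  # full feature set is allowed (warns if a rare pattern is constant in
  # training); out-of-range is not
  clf7 <- suppressWarnings(train_classifier(train, n_features = 7))
  expect_length(clf7$features, 7)
  expect_error(train_classifier(train, n_features = 8), "1\\.\\.7")
})

test_that("feature ranking and scaling use training data only", {
  sc <- sequence_cohort(seed = 10)
  feats <- feature_table(sc$states, sc$recordings, k = 7)
  train <- feats[feats$cohort == "train", ]
  clf <- train_classifier(train, n_features = 3)
  # ranking must equal Fisher scores computed on the training set alone
  scores <- fisher_scores(train[, paste0("pattern", 1:7)], train$conscious)
  expect_identical(clf$features,
                   names(sort(scores, decreasing = TRUE))[1:3])
  expect_equal(unname(clf$center),
               unname(colMeans(as.matrix(train[, clf$features]))))
  # the fitted model is a fixed function of train: evaluating on different
  # test sets cannot change it
  before <- clf$svm$coefs
  invisible(evaluate_classifier(clf, feats[feats$cohort == "test", ]))
  expect_identical(clf$svm$coefs, before)
})

test_that("perfect separation and degenerate test sets behave as contracted", {
  feats <- data.frame(pattern1 = c(0.9, 0.8, 0.85, 0.1, 0.2, 0.15),
                      pattern2 = c(0.1, 0.2, 0.15, 0.9, 0.8, 0.85),
                      conscious = rep(c(TRUE, FALSE), each = 3))
  clf <- train_classifier(feats, n_features = 1)
  expect_equal(evaluate_classifier(clf, feats), 1.0)
  flipped <- feats
  flipped$conscious <- !flipped$conscious
  expect_equal(evaluate_classifier(clf, flipped), 0.0)

  # single-class test set: permuting its labels changes nothing
  solo <- feats[feats$conscious, ]
  pc <- permutation_chance(clf, solo, n_permutations = 20, seed = 1)
  expect_equal(pc$se, 0)
  expect_equal(pc$mean, evaluate_classifier(clf, solo))

  # permutation chance is reproducible under a fixed seed
  sc <- sequence_cohort(seed = 11)
  fts <- feature_table(sc$states, sc$recordings, k = 7)
  m <- train_classifier(fts[fts$cohort == "train", ], n_features = 2)
  p1 <- permutation_chance(m, fts[fts$cohort == "test", ], 10, seed = 5)
  p2 <- permutation_chance(m, fts[fts$cohort == "test", ], 10, seed = 5)
  expect_identical(p1$rates, p2$rates)

  # a feature constant in training triggers the degenerate-model warning
  degen <- data.frame(pattern1 = rep(0.5, 6),
                      pattern2 = c(0.9, 0.8, 0.85, 0.1, 0.2, 0.15),
                      conscious = rep(c(TRUE, FALSE), each = 3))
  expect_warning(train_classifier(degen, n_features = 2), "degenerate")
})

test_that("the feature sweep shows chance with pattern 7 alone and near-perfect with two", {
  sc <- sequence_cohort(seed = 12)
  feats <- feature_table(sc$states, sc$recordings, k = 7)
  train <- feats[feats$cohort == "train", ]
  test <- feats[feats$cohort == "test", ]

  # force the single SEVO/PROP-dominant feature: pattern 7 occupancy carries
  # little information about UWS vs control (low in both)
  only7 <- data.frame(pattern7 = train$pattern7, conscious = train$conscious)
  clf7 <- train_classifier(only7, n_features = 1)
  rate7 <- evaluate_classifier(clf7, test)
  rate2 <- evaluate_classifier(train_classifier(train, n_features = 2), test)
  expect_gte(rate2, 0.95)
  expect_lte(rate7, 0.7)  # near the chance band, far below the two-feature model
  expect_lt(rate7, rate2)
})
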