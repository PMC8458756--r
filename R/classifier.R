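#' Build the per-recording feature table for classification
#'
#' One row per recording: the k pattern-occupancy fractions as features, a
#' binary consciousness label (AWAKE = conscious; PROP, SEVO, UWS =
#' unconscious) and the cohort tag (train = anesthesia experiments,
#' test = UWS patients + controls).
#'
#' @param sequences named list of state sequences, one per recording.
#' @param recordings list of [time_course_table()]s aligned with `sequences`
#'   (provides group and cohort metadata).
#' @param k number of patterns.
#' @return data.frame with columns `pattern1..patternk`, `conscious`
#'   (logical), `group`, `cohort`.
#' @export
feature_table <- function(sequences, recordings, k = 7) {
  stop_if_not(length(sequences) == length(recordings),
              "sequences and recordings must align")
  occ <- occupancy(sequences, grouping = seq_along(sequences), k = k)$recording
  groups <- vapply(recordings, `[[`, "", "group")
  cohorts <- vapply(recordings, `[[`, "", "cohort")
  out <- as.data.frame(occ)
  out$conscious <- groups == "AWAKE"
  out$group <- groups
  out$cohort <- cohorts
  rownames(out) <- names(sequences)
  out
}

#' Fisher scores for two-class feature ranking
#'
#' For feature j with class means `mu1, mu0` and unbiased class variances
#' `s1^2, s0^2`: `F_j = (mu1 - mu0)^2 / (s1^2 + s0^2)`. A feature with zero
#' variance in both classes and equal means scores 0; with unequal means it
#' scores `Inf` (perfectly separating).
#'
#' @param features samples x features numeric matrix or data.frame.
#' @param labels logical or two-level vector of class labels.
#' @return named numeric vector of scores, one per feature.
#' @export
fisher_scores <- function(features, labels) {
  x <- as.matrix(features)
  y <- as.logical(labels)
  stop_if_not(!anyNA(y) && length(unique(y)) == 2, "both classes must be present")
  stop_if_not(sum(y) >= 2 && sum(!y) >= 2, "need >= 2 samples per class")
  mu1 <- colMeans(x[y, , drop = FALSE])
  mu0 <- colMeans(x[!y, , drop = FALSE])
  v1 <- apply(x[y, , drop = FALSE], 2, var)
  v0 <- apply(x[!y, , drop = FALSE], 2, var)
  num <- (mu1 - mu0)^2
  den <- v1 + v0
  score <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  stats::setNames(as.numeric(score), colnames(x))
}

#' Train the consciousness classifier
#'
#' Ranks the pattern-occupancy features by Fisher score on the training set
#' only, keeps the top `n_features`, standardizes them by training mean/SD,
#' and fits a linear-kernel support vector machine (cost C = 1).
#' A selected feature that is constant in training triggers a
#' degenerate-model warning and is scaled by SD 1.
#'
#' @param train feature table (see [feature_table()]) with both labels.
#' @param n_features number of top-ranked features to use, `1..k`.
#' @return `list(svm, features, center, scale, scores)`.
#' @export
train_classifier <- function(train, n_features = 2) {
  feat_cols <- grep("^pattern", colnames(train), value = TRUE)
  stop_if_not(n_features >= 1 && n_features <= length(feat_cols),
              "n_features must be in 1..%d", length(feat_cols))
  y <- train$conscious
  stop_if_not(length(unique(y)) == 2, "training set needs both classes")
  scores <- fisher_scores(train[, feat_cols, drop = FALSE], y)
  selected <- names(sort(scores, decreasing = TRUE))[seq_len(n_features)]
  x <- as.matrix(train[, selected, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) {
    warning(sprintf("degenerate model: feature(s) %s constant in training",
                    paste(selected[scl == 0], collapse = ", ")))
    scl[scl == 0] <- 1
  }
  xs <- scale(x, center = ctr, scale = scl)
  fit <- e1071::svm(xs, factor(y, levels = c(FALSE, TRUE)),
                    kernel = "linear", cost = 1, scale = FALSE)
  structure(list(svm = fit, features = selected, center = ctr, scale = scl,
                 scores = scores),
            class = "consciousness_classifier")
}

classifier_predict <- function(model, table) {
  stop_if_not(all(model$features %in% colnames(table)),
              "test set lacks the model's features")
  x <- as.matrix(table[, model$features, drop = FALSE])
  xs <- scale(x, center = model$center, scale = model$scale)
  as.logical(as.character(predict(model$svm, xs)))
}

#' Correct classification rate on a test set
#'
#' @param model a [train_classifier()] model.
#' @param test feature table of test recordings.
#' @return fraction of test recordings classified correctly.
#' @export
evaluate_classifier <- function(model, test) {
  stop_if_not(nrow(test) >= 1, "test set must be non-empty")
  mean(classifier_predict(model, test) == test$conscious)
}

#' Permutation chance level of the classifier
#'
#' Correct classification rate under random permutation of the test labels
#' (predictions fixed), repeated `n_permutations` times; returns the mean
#' rate and its standard error.
#'
#' @param model a [train_classifier()] model.
#' @param test feature table of test recordings.
#' @param n_permutations number of label permutations.
#' @param seed RNG seed.
#' @return `list(mean, se, rates)`.
#' @export
permutation_chance <- function(model, test, n_permutations = 100, seed = 1) {
  stop_if_not(nrow(test) >= 1, "test set must be non-empty")
  pred <- classifier_predict(model, test)
  set.seed(seed)
  rates <- vapply(seq_len(n_permutations), function(i) {
    mean(pred == sample(test$conscious))
  }, numeric(1))
  list(mean = mean(rates),
       se = if (n_permutations > 1) sd(rates) / sqrt(n_permutations) else 0,
       rates = rates)
}
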