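#' k-means clustering under the L1 (Manhattan) distance
#'
#' Lloyd-style iteration with L1 nearest-centroid assignment and
#' component-wise median centroid update (the exact minimizer of the
#' within-cluster L1 sum; even-sized clusters use the midpoint of the two
#' middle values). Each restart is initialized with k distinct rows sampled
#' uniformly; the best of `n_restarts` restarts by total within-cluster L1
#' objective is returned. Empty clusters are reseeded with the point farthest
#' from its centroid. Deterministic given `seed`.
#'
#' @param vectors pooled windows x d numeric matrix.
#' @param k number of patterns (default 7).
#' @param n_restarts number of random restarts (default 20).
#' @param max_iter iteration cap per restart; convergence is declared when
#'   assignments stop changing.
#' @param seed RNG seed for the initializations.
#' @return a `pattern_model`: `list(centroids, k, labels, objective,
#'   objective_trace, n_restarts, seed)`; `labels` are the training
#'   assignments of the pooled rows.
#' @export
kmeans_l1 <- function(vectors, k = 7, n_restarts = 20, max_iter = 100, seed = 1) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  stop_if_not(n >= k, "need at least k rows")
  stop_if_not(ncol(vectors) >= 1, "need at least one dimension")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- sample_distinct_rows(vectors, k)
    stop_if_not(length(init) == k,
                "k = %d exceeds the number of distinct rows", k)
    fit <- .kmeans_l1_restart(vectors, init - 1L, as.integer(max_iter))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(
    list(centroids = best$centroids, k = as.integer(k),
         labels = as.integer(best$labels), objective = best$objective,
         objective_trace = best$objective_trace,
         n_restarts = as.integer(n_restarts), seed = seed),
    class = "pattern_model")
}

# k row indices with pairwise-distinct rows (uniform sampling, rejecting
# duplicates of already-chosen rows)
sample_distinct_rows <- function(x, k) {
  perm <- sample.int(nrow(x))
  chosen <- integer(0)
  for (i in perm) {
    dup <- FALSE
    for (j in chosen) {
      if (all(x[i, ] == x[j, ])) { dup <- TRUE; break }
    }
    if (!dup) chosen <- c(chosen, i)
    if (length(chosen) == k) break
  }
  chosen
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("<pattern_model> k = %d patterns in %d dimensions, objective = %.4g (%d restarts)\n",
              x$k, ncol(x$centroids), x$objective, x$n_restarts))
  invisible(x)
}

#' Assign windows to their nearest pattern
#'
#' Each window vector gets the label of the L1-nearest centroid; ties break
#' to the lowest pattern id.
#'
#' @param vectors windows x d matrix (one recording's window vectors).
#' @param model a [kmeans_l1()] pattern model.
#' @return integer state sequence (one label in `1..k` per window).
#' @export
assign_patterns <- function(vectors, model) {
  D <- pattern_distances(vectors, model)
  apply(D, 1, which.min)
}

#' L1 distances of windows to every pattern centroid
#'
#' The per-window distance-to-pattern geometry underlying the pairwise
#' pattern-separation plots (21 pairs at k = 7).
#'
#' @param vectors windows x d matrix.
#' @param model a [kmeans_l1()] pattern model.
#' @return windows x k matrix of L1 distances.
#' @export
pattern_distances <- function(vectors, model) {
  vectors <- if (is.matrix(vectors)) vectors else matrix(vectors, nrow = 1)
  stop_if_not(ncol(vectors) == ncol(model$centroids),
              "vector dimension (%d) does not match the model (%d)",
              ncol(vectors), ncol(model$centroids))
  .l1_distances(vectors, model$centroids)
}

#' Match fitted patterns to reference templates
#'
#' Finds the bijection between model centroids and reference templates that
#' minimizes the total L1 centroid-template distance (exact optimal
#' assignment by permutation enumeration; k <= 8). Used to relabel a fitted
#' model into the generator's ground-truth pattern ids.
#'
#' @param model a [kmeans_l1()] pattern model.
#' @param reference_templates list of pattern templates (matrices are
#'   vectorized) or a k x d matrix of reference vectors.
#' @return integer permutation `perm` with `perm[j]` = reference id matched
#'   to model pattern `j`.
#' @export
relabel_to_reference <- function(model, reference_templates) {
  ref <- if (is.matrix(reference_templates)) {
    reference_templates
  } else {
    do.call(rbind, lapply(reference_templates, function(tp) vectorize_upper(tp$matrix)))
  }
  k <- model$k
  stop_if_not(nrow(ref) == k && ncol(ref) == ncol(model$centroids),
              "reference size does not match the model")
  stop_if_not(k <= 8, "permutation enumeration supports k <= 8")
  cost <- .l1_distances(model$centroids, ref)  # cost[j, ref]
  best_perm <- NULL
  best_cost <- Inf
  for (perm in all_permutations(k)) {
    total <- sum(cost[cbind(seq_len(k), perm)])
    if (total < best_cost) {
      best_cost <- total
      best_perm <- perm
    }
  }
  as.integer(best_perm)
}

#' Relabel state sequences with a pattern permutation
#'
#' @param states integer label vector (or list of them).
#' @param perm permutation from [relabel_to_reference()].
#' @return relabeled states, same shape.
#' @export
apply_relabeling <- function(states, perm) {
  if (is.list(states)) return(lapply(states, apply_relabeling, perm = perm))
  perm[states]
}

#' Majority frame state per sliding window
#'
#' Reference window labels from a frame-level ground-truth state sequence:
#' the modal state among the frames of each window (ties to the lowest id).
#'
#' @param states frame-level integer state sequence (length `T`).
#' @param window window length in frames.
#' @param step stride between window starts.
#' @return integer vector of length `T - window` (the [window_starts()] count).
#' @export
window_majority_states <- function(states, window = 30, step = 1) {
  starts <- window_starts(length(states), window, step)
  vapply(starts, function(s) {
    tab <- tabulate(states[s:(s + window - 1)])
    which.max(tab)
  }, integer(1))
}

#' Ground-truth window labels from the population window connectivity
#'
#' The generator-derived window-level ground truth used to score recovered
#' state sequences: each window's label is the pattern whose template is
#' L1-nearest to the window's *population* correlation matrix — the
#' correlation of the covariance mixture implied by the window's frame
#' states. For a window fully inside one state this is that state; for a
#' window straddling a transition it places the boundary where the mixture
#' itself crosses between templates, rather than at the 50% frame count of
#' [window_majority_states()]. Depends only on generator truth (frame states
#' and templates), never on a fitted model.
#'
#' @param states frame-level integer state sequence (length `T`).
#' @param templates list of pattern templates (as in `cohort_truth`).
#' @param window window length in frames.
#' @param step stride between window starts.
#' @return integer vector of length `T - window`.
#' @export
window_true_states <- function(states, templates, window = 30, step = 1) {
  starts <- window_starts(length(states), window, step)
  k <- length(templates)
  tvec <- do.call(rbind, lapply(templates, function(tp) vectorize_upper(tp$matrix)))
  # cumulative per-state frame counts for O(1) window composition
  counts <- vapply(seq_len(k), function(p) cumsum(states == p), numeric(length(states)))
  counts <- rbind(0, counts)
  out <- integer(length(starts))
  cache <- new.env()
  for (i in seq_along(starts)) {
    s <- starts[i]
    comp <- counts[s + window, ] - counts[s, ]
    key <- paste(comp, collapse = ",")
    lab <- cache[[key]]
    if (is.null(lab)) {
      present <- which(comp > 0)
      if (length(present) == 1) {
        lab <- present
      } else {
        mix <- Reduce(`+`, lapply(present, function(p) comp[p] * templates[[p]]$matrix)) / window
        v <- vectorize_upper(stats::cov2cor(mix))
        lab <- which.min(rowSums(abs(sweep(tvec, 2, v, "-"))))
      }
      cache[[key]] <- lab
    }
    out[i] <- lab
  }
  out
}
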