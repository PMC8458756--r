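#' Sliding-window start indices
#'
#' 1-based window starts under the `T - W` count convention forced by the
#' windowed-connectivity arithmetic: a 297-frame recording with a 30-frame
#' window at step 1 yields exactly 267 windows (the final frame is unused).
#'
#' @param n_frames number of frames `T`.
#' @param window window length `W` in frames.
#' @param step stride between starts.
#' @return integer vector of start indices.
#' @export
window_starts <- function(n_frames, window = 30, step = 1) {
  stop_if_not(step >= 1, "step must be >= 1")
  stop_if_not(n_frames > window,
              "n_frames (%d) must exceed the window length (%d)", n_frames, window)
  seq.int(1L, by = as.integer(step),
          length.out = (n_frames - window) %/% step)
}

#' Windowed connectivity matrix
#'
#' Pearson correlation of all network pairs over frames
#' `[start, start + window - 1]`, with the diagonal forced to exactly 1.
#' A network with zero variance inside the window yields 0 entries (with a
#' warning) rather than aborting the run.
#'
#' @param table a [time_course_table()] or numeric matrix.
#' @param start 1-based window start.
#' @param window window length in frames.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
windowed_connectivity <- function(table, start, window = 30) {
  x <- if (inherits(table, "time_course_table")) table$values else as.matrix(table)
  stop_if_not(start >= 1 && start + window - 1 <= nrow(x),
              "window [%d, %d] does not fit in %d frames", start, start + window - 1, nrow(x))
  seg <- x[start:(start + window - 1), , drop = FALSE]
  sds <- apply(seg, 2, sd)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance network(s) in window starting at %d; entries set to 0", start))
    cm <- suppressWarnings(cor(seg))
    cm[!is.finite(cm)] <- 0
  } else {
    cm <- cor(seg)
  }
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 1
  cm
}

#' Windowed-connectivity series of one recording
#'
#' Applies [windowed_connectivity()] at every window start and vectorizes
#' each matrix (strict upper triangle): a 297 x 57 recording yields 267
#' matrices of 57 x 57, i.e. a 267 x 1596 vector matrix.
#'
#' @param table a [time_course_table()] or numeric matrix.
#' @param window window length in frames.
#' @param step stride between window starts.
#' @param keep_matrices keep the full matrices alongside the vectorized form?
#'   Set `FALSE` for large cohorts where only the vectors are needed.
#' @return `list(matrices = <list or NULL>, vectors = <windows x n(n-1)/2
#'   matrix>, starts = <integer>, window = W, step = step)`.
#' @export
dfnc_series <- function(table, window = 30, step = 1, keep_matrices = TRUE) {
  x <- if (inherits(table, "time_course_table")) table$values else as.matrix(table)
  starts <- window_starts(nrow(x), window, step)
  d <- ncol(x) * (ncol(x) - 1) / 2
  vecs <- matrix(NA_real_, length(starts), d)
  mats <- if (keep_matrices) vector("list", length(starts))
  for (i in seq_along(starts)) {
    m <- windowed_connectivity(x, starts[i], window)
    vecs[i, ] <- vectorize_upper(m)
    if (keep_matrices) mats[[i]] <- m
  }
  list(matrices = mats, vectors = vecs, starts = starts,
       window = window, step = step)
}

#' Vectorize the strict upper triangle of a symmetric matrix
#'
#' Row-major order: `(1,2), (1,3), ..., (1,n), (2,3), ...`; length
#' `n(n-1)/2` (1596 for 57 networks). [devectorize_upper()] is the exact
#' inverse.
#'
#' @param matrix square symmetric numeric matrix.
#' @return numeric vector of the strict upper-triangle entries.
#' @export
vectorize_upper <- function(matrix) {
  stop_if_not(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
              "input must be a square matrix")
  t(matrix)[lower.tri(matrix)]
}

#' Rebuild a symmetric unit-diagonal matrix from its upper-triangle vector
#'
#' @param v vector of length `n(n-1)/2` in the order of [vectorize_upper()].
#' @param diag_value value for the diagonal (1 for correlation matrices).
#' @return n x n symmetric matrix.
#' @export
devectorize_upper <- function(v, diag_value = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  stop_if_not(n == round(n), "vector length is not n(n-1)/2 for integer n")
  n <- as.integer(n)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v  # column-major lower triangle = row-major upper of t(m)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Pool windowed-connectivity vectors across recordings
#'
#' Stacks every recording's window vectors into one matrix for clustering,
#' keeping track of which rows belong to which recording.
#'
#' @param series_list list of [dfnc_series()] results (named by recording).
#' @return `list(vectors = <pooled matrix>, recording = <factor>,
#'   window_index = <integer>)`.
#' @export
pool_windows <- function(series_list) {
  stop_if_not(length(series_list) >= 1, "no series to pool")
  counts <- vapply(series_list, function(s) nrow(s$vectors), integer(1))
  ids <- names(series_list) %||% as.character(seq_along(series_list))
  list(vectors = do.call(rbind, lapply(series_list, `[[`, "vectors")),
       recording = factor(rep(ids, counts), levels = ids),
       window_index = unlist(lapply(counts, seq_len), use.names = FALSE))
}
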