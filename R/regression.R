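#' Binary indicator of consciousness-specific pattern occurrence
#'
#' 1 where the window's state is one of the target patterns (default the
#' consciousness-specific patterns 1 and 3), else 0; aligned with the window
#' index of the state sequence.
#'
#' @param states integer state sequence.
#' @param target_patterns set of pattern ids coded as 1.
#' @return integer 0/1 vector of the same length.
#' @export
pattern_indicator <- function(states, target_patterns = c(1, 3)) {
  stop_if_not(length(target_patterns) >= 1, "target pattern set must be non-empty")
  as.integer(states %in% target_patterns)
}

#' Logistic regression of pattern occurrence on one network's activity
#'
#' Maximum-likelihood binomial logistic fit (logit link, iteratively
#' reweighted least squares via `stats::glm`) of the pooled binary pattern
#' indicator on the pooled, per-recording-standardized smoothed network
#' activity. Returns the slope B in log-odds per SD of network activity, its
#' Wald two-sided p-value, and a flag when the fit did not converge or the
#' response is perfectly separated.
#'
#' @param indicator 0/1 response vector (pooled windows).
#' @param predictor numeric predictor vector, same length.
#' @param network identifier carried into the result.
#' @return `list(network, slope, intercept, p_value, n, flag)`; `flag` is
#'   `"ok"`, `"non_convergence"` or `"separation"`.
#' @export
fit_pattern_regression <- function(indicator, predictor, network = NA) {
  stop_if_not(length(indicator) == length(predictor),
              "indicator and predictor must have equal length")
  stop_if_not(all(indicator %in% c(0, 1)), "indicator must be binary")
  stop_if_not(length(unique(indicator)) == 2,
              "both response classes must be present")
  fit <- suppressWarnings(glm(indicator ~ predictor, family = binomial()))
  sm <- summary(fit)$coefficients
  flag <- "ok"
  if (!fit$converged) flag <- "non_convergence"
  # perfect separation: fitted probabilities pinned at 0/1 with exploding slope
  if (abs(coef(fit)[2]) > 15 && sm["predictor", "Std. Error"] > 50) flag <- "separation"
  list(network = network,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       p_value = unname(sm["predictor", "Pr(>|z|)"]),
       n = length(indicator),
       flag = flag)
}

#' Per-network regression of conscious-pattern occurrence on activity
#'
#' For every network: smooth its conditioned time course with the 30-frame
#' sliding mean (the same window the connectivity matrices use, so smoothed
#' values align one-to-one with windows), standardize per recording, pool
#' windows across recordings, and fit the univariate logistic regression of
#' the pattern-1/3 indicator on that network's smoothed activity.
#' Per-network failures are recorded, not fatal.
#'
#' @param states_by_recording list of window-level state sequences.
#' @param tables list of conditioned [time_course_table()]s, aligned.
#' @param target_patterns pattern ids forming the response (default 1 and 3).
#' @param window smoothing window in frames.
#' @param alpha significance level for flagging (no multiple-testing
#'   correction by default, use `bonferroni = TRUE` to correct).
#' @param bonferroni apply a Bonferroni correction across networks?
#' @return data.frame: `network`, `slope`, `p_value`, `flag`,
#'   `significant_positive`.
#' @export
regress_all_networks <- function(states_by_recording, tables,
                                 target_patterns = c(1, 3), window = 30,
                                 alpha = 0.05, bonferroni = FALSE) {
  stop_if_not(length(states_by_recording) == length(tables),
              "states and tables must align")
  d <- ncol(tables[[1]]$values)
  indicator <- unlist(lapply(states_by_recording, pattern_indicator,
                             target_patterns = target_patterns),
                      use.names = FALSE)
  # smoothed, per-recording-standardized predictors, pooled across recordings
  predictors <- matrix(NA_real_, length(indicator), d)
  offset <- 0L
  for (i in seq_along(tables)) {
    x <- tables[[i]]$values
    sm <- apply(x, 2, sliding_mean, window = window)
    stop_if_not(nrow(sm) == length(states_by_recording[[i]]),
                "recording %d: smoothed length does not match its state sequence", i)
    predictors[offset + seq_len(nrow(sm)), ] <- scale_population(sm)
    offset <- offset + nrow(sm)
  }
  nets <- colnames(tables[[1]]$values) %||% paste0("N", seq_len(d))
  rows <- lapply(seq_len(d), function(j) {
    res <- tryCatch(
      fit_pattern_regression(indicator, predictors[, j], network = nets[j]),
      error = function(e) list(network = nets[j], slope = NA_real_,
                               intercept = NA_real_, p_value = NA_real_,
                               n = length(indicator), flag = paste("error:", conditionMessage(e))))
    data.frame(network = res$network, slope = res$slope, p_value = res$p_value,
               flag = res$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  thr <- if (bonferroni) alpha / d else alpha
  out$significant_positive <- !is.na(out$p_value) & out$p_value < thr &
    !is.na(out$slope) & out$slope > 0 & out$flag == "ok"
  out
}
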