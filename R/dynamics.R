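#' Pattern occupancy profiles
#'
#' Pooled window counts per pattern, per group (and per recording),
#' normalized within group: the "relative distribution of appearance" of the
#' k patterns in each condition.
#'
#' @param sequences list of integer state sequences (one per recording).
#' @param grouping factor or character vector of group labels, one per
#'   recording; a single value recycles.
#' @param k number of patterns.
#' @return `list(group = <groups x k probability matrix>,
#'   recording = <recordings x k probability matrix>,
#'   counts = <groups x k integer matrix>)`.
#' @export
occupancy <- function(sequences, grouping = "all", k = 7) {
  stop_if_not(length(sequences) >= 1, "need at least one sequence")
  if (!is.list(sequences)) sequences <- list(sequences)
  grouping <- rep_len(as.character(grouping), length(sequences))
  labs <- unlist(sequences, use.names = FALSE)
  stop_if_not(all(labs >= 1 & labs <= k), "state labels must lie in 1..k")

  per_rec <- t(vapply(sequences, function(s) tabulate(s, nbins = k), numeric(k)))
  rownames(per_rec) <- names(sequences)
  groups <- unique(grouping)
  counts <- t(vapply(groups, function(g) colSums(per_rec[grouping == g, , drop = FALSE]),
                     numeric(k)))
  rownames(counts) <- groups
  colnames(counts) <- colnames(per_rec) <- paste0("pattern", seq_len(k))
  list(group = counts / rowSums(counts),
       recording = per_rec / rowSums(per_rec),
       counts = counts)
}

#' Number of pattern transitions in a state sequence
#'
#' Adjacent-window label changes within one recording.
#'
#' @param sequence integer state sequence.
#' @return non-negative integer count.
#' @export
count_transitions <- function(sequence) {
  stop_if_not(length(sequence) >= 1, "sequence must be non-empty")
  if (length(sequence) == 1) return(0L)
  sum(sequence[-1] != sequence[-length(sequence)])
}

#' Symmetric pattern transition-probability matrix
#'
#' Unordered-pair transition probabilities pooled over recordings: for each
#' adjacent window pair within a recording, the unordered pattern pair
#' `{X, Y}` ("from X to Y or vice versa") is counted, self-transitions on the
#' diagonal; counts are divided by the total number of adjacent pairs, so the
#' diagonal plus the upper triangle sums to 1. Windows are adjacent only
#' within a recording (no cross-recording transitions).
#'
#' @param sequences list of integer state sequences.
#' @param k number of patterns.
#' @param per_recording if `TRUE`, average the per-recording probability
#'   matrices instead of pooling all pairs.
#' @return symmetric k x k probability matrix.
#' @export
transition_matrix <- function(sequences, k = 7, per_recording = FALSE) {
  if (!is.list(sequences)) sequences <- list(sequences)
  stop_if_not(length(sequences) >= 1, "need at least one sequence")
  one <- function(s) {
    m <- matrix(0, k, k)
    if (length(s) >= 2) {
      a <- s[-length(s)]
      b <- s[-1]
      lo <- pmin(a, b)
      hi <- pmax(a, b)
      for (t in seq_along(lo)) m[lo[t], hi[t]] <- m[lo[t], hi[t]] + 1
    }
    m
  }
  counts <- Reduce(`+`, lapply(sequences, one))
  dimnames(counts) <- list(paste0("pattern", 1:k), paste0("pattern", 1:k))
  if (per_recording) {
    mats <- lapply(sequences, function(s) {
      m <- one(s)
      tot <- sum(m)
      if (tot > 0) m / tot else m
    })
    probs <- Reduce(`+`, mats) / length(mats)
  } else {
    total <- sum(counts)
    stop_if_not(total > 0, "no adjacent window pairs in the input")
    probs <- counts / total
  }
  # symmetric representation of the unordered pairs
  probs <- probs + t(probs) - diag(diag(probs))
  dimnames(probs) <- dimnames(counts)
  probs
}

#' Pairwise group comparisons by rank-sum test, Bonferroni corrected
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test for every pair of groups on
#' a per-recording scalar (e.g. the transition count), with p-values
#' multiplied by the Bonferroni factor (default 6, the number of pairwise
#' comparisons among four groups) and capped at 1.
#'
#' @param values numeric vector of per-recording scalars.
#' @param grouping group label per value.
#' @param bonferroni_factor multiplication factor for the correction.
#' @return data.frame with columns `group1`, `group2`, `p_raw`, `p_corrected`.
#' @export
compare_groups_ranksum <- function(values, grouping, bonferroni_factor = 6) {
  grouping <- as.character(grouping)
  groups <- unique(grouping)
  stop_if_not(length(groups) >= 2, "need at least two groups")
  stop_if_not(all(table(grouping) >= 1), "every group needs at least one value")
  pairs <- utils::combn(groups, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p_raw = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- values[grouping == pairs[1, i]]
    b <- values[grouping == pairs[2, i]]
    if (all(c(a, b) == c(a, b)[1])) {
      out$p_raw[i] <- 1  # identical constant samples: no evidence either way
    } else {
      out$p_raw[i] <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided")$p.value)
    }
  }
  out$p_corrected <- pmin(out$p_raw * bonferroni_factor, 1)
  out
}

#' Chi-square test of pattern-distribution homogeneity between two groups
#'
#' Pearson chi-square on the 2 x k table of pooled window counts per pattern
#' (patterns unobserved in both groups are dropped, with the degrees of
#' freedom adjusted accordingly). Windows are treated as observations on the
#' nominal pattern scale; within-recording dependence is not modeled.
#'
#' @param seq_a,seq_b lists of state sequences for the two groups.
#' @param k number of patterns.
#' @return `list(statistic, df, p_value, table)`.
#' @export
pattern_distribution_chi2 <- function(seq_a, seq_b, k = 7) {
  if (!is.list(seq_a)) seq_a <- list(seq_a)
  if (!is.list(seq_b)) seq_b <- list(seq_b)
  stop_if_not(length(seq_a) >= 1 && length(seq_b) >= 1, "both groups must be non-empty")
  ca <- tabulate(unlist(seq_a), nbins = k)
  cb <- tabulate(unlist(seq_b), nbins = k)
  keep <- (ca + cb) > 0
  tab <- rbind(ca[keep], cb[keep])
  stop_if_not(ncol(tab) >= 2,
              "degenerate table: only one pattern observed across both groups")
  if (identical(tab[1, ] / sum(tab[1, ]), tab[2, ] / sum(tab[2, ]))) {
    return(list(statistic = 0, df = ncol(tab) - 1L, p_value = 1, table = tab))
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, table = tab)
}
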