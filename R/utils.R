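#' @useDynLib brainstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor fft glm mad median pchisq quantile rbinom rnorm runif
#'   sd var wilcox.test chisq.test binomial coef predict runmed
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Derive a stable child seed from a master seed and a string key
#'
#' Uses a polynomial string hash folded into the master seed so that every
#' recording (subject x condition) gets its own reproducible RNG stream while
#' staying inside the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param key character key, e.g. `"P03:PROP"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, key) {
  stop_if_not(is.numeric(master) && length(master) == 1, "master seed must be a single number")
  h <- 0
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((h + as.numeric(master)) %% 2147483647)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions (up to relabeling), 0 is the expected value
#' for independent labelings.
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stop_if_not(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# All permutations of 1..n as a list (n! entries); used for exact label
# matching at small k.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}
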