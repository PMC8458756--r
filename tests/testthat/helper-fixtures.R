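# Small fixtures built in code, shared across test files.

# two-pattern template set on 6 networks: pattern 1 = background noise only,
# pattern 2 = one 3-network block at r = 0.7
mini_templates <- function(base_noise = 0.05, seed = 42, r = 0.7) {
  build_pattern_templates(
    n_networks = 6, k = 2,
    block_spec = list(list(), list(list(networks = 1:3, r = r))),
    base_noise = base_noise, seed = seed)
}

# brute-force L1 k-means for k = 2: enumerate every bipartition into two
# non-empty clusters, use component-wise median centroids, return the
# minimal total within-cluster L1 objective. Independent of the package's
# iterative implementation.
brute_force_l1_k2 <- function(x) {
  n <- nrow(x)
  l1_obj <- function(rows) {
    ctr <- apply(x[rows, , drop = FALSE], 2, median)
    sum(abs(sweep(x[rows, , drop = FALSE], 2, ctr)))
  }
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix point n in cluster B to halve the space
    in_a <- which(bitwAnd(code, 2^(0:(n - 1))) > 0)
    best <- min(best, l1_obj(in_a) + l1_obj(setdiff(1:n, in_a)))
  }
  best
}

# a quick state-sequence cohort (no time courses) with the default group
# design: one window-level sequence per recording, drawn straight from the
# group specs. Mirrors the anesthesia/UWS split without any clustering.
sequence_cohort <- function(seed = 1, n_windows = 267,
                            config = default_cohort_config()) {
  gs <- config$group_specs
  plan <- list()
  add <- function(subject, condition, cohort)
    plan[[length(plan) + 1]] <<- list(subject = subject, condition = condition,
                                      cohort = cohort)
  for (i in seq_len(gs$PROP$n_subjects)) {
    add(sprintf("P%02d", i), "AWAKE", "train"); add(sprintf("P%02d", i), "PROP", "train")
  }
  for (i in seq_len(gs$SEVO$n_subjects)) {
    add(sprintf("S%02d", i), "AWAKE", "train"); add(sprintf("S%02d", i), "SEVO", "train")
  }
  for (i in seq_len(gs$AWAKE$n_subjects)) add(sprintf("C%02d", i), "AWAKE", "test")
  for (i in seq_len(gs$UWS$n_subjects)) add(sprintf("U%02d", i), "UWS", "test")
  states <- lapply(plan, function(p) {
    sample_state_sequence(gs[[p$condition]], n_windows,
                          seed = derive_seed(seed, paste0(p$subject, ":", p$condition)))
  })
  names(states) <- vapply(plan, function(p) paste0(p$subject, ":", p$condition), "")
  # minimal metadata-only recording stubs for feature_table()
  recs <- lapply(plan, function(p) {
    time_course_table(matrix(rnorm(4), 2, 2), tr = 2, subject = p$subject,
                      group = p$condition, cohort = p$cohort)
  })
  names(recs) <- names(states)
  list(states = states, recordings = recs,
       groups = vapply(plan, `[[`, "", "condition"))
}
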