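#' Build correlation-pattern templates
#'
#' Constructs k symmetric positive-definite correlation matrices ("pattern
#' templates") from a block specification: each pattern is unit-diagonal
#' background noise plus one or more network blocks raised to a requested
#' within-block correlation. An indefinite block request is repaired to the
#' nearest positive-definite correlation matrix (eigenvalue clipping with
#' re-normalization to unit diagonal); a request that the repair cannot honor
#' is an error naming the offending pattern.
#'
#' @param n_networks number of networks (matrix dimension).
#' @param k number of patterns.
#' @param block_spec list of length k; element `p` is a list of blocks, each
#'   `list(networks = <indices>, r = <within-block correlation>)` or, for a
#'   cross-block (e.g. anticorrelation between two systems),
#'   `list(networks = <indices>, networks2 = <indices>, r = <correlation>)`
#'   which sets only the entries between the two sets. An empty list gives a
#'   noise-only ("low overall correlation") pattern.
#' @param base_noise magnitude of the uniform background off-diagonal
#'   correlations.
#' @param seed RNG seed for the background noise.
#' @param descriptions optional character vector of pattern descriptions.
#' @return list of `pattern_template` objects (fields `id`, `matrix`,
#'   `description`).
#' @export
build_pattern_templates <- function(n_networks, k, block_spec,
                                    base_noise = 0.05, seed = 1,
                                    descriptions = NULL) {
  stop_if_not(k >= 2, "k must be >= 2")
  stop_if_not(n_networks >= 2, "n_networks must be >= 2")
  stop_if_not(length(block_spec) == k, "block_spec must have one entry per pattern")
  set.seed(seed)
  templates <- vector("list", k)
  for (pid in seq_len(k)) {
    noise <- matrix(runif(n_networks^2, -base_noise, base_noise), n_networks)
    m <- (noise + t(noise)) / 2
    diag(m) <- 1
    for (b in block_spec[[pid]]) {
      stop_if_not(abs(b$r) < 1, "requested correlation must be in (-1, 1)")
      if (is.null(b$networks2)) {
        idx <- b$networks
        m[idx, idx] <- b$r
      } else {
        m[b$networks, b$networks2] <- b$r
        m[b$networks2, b$networks] <- b$r
      }
      diag(m) <- 1
    }
    requested <- m
    m <- nearest_spd_correlation(m)
    if (max(abs(m - requested)) > 0.25) {
      stop(sprintf("pattern %d: requested block structure is not repairable to a valid correlation matrix", pid),
           call. = FALSE)
    }
    templates[[pid]] <- structure(
      list(id = pid, matrix = m,
           description = descriptions[pid] %||% sprintf("pattern %d", pid)),
      class = "pattern_template")
  }
  templates
}

# Nearest (in the eigenvalue-clipping sense) positive-definite correlation
# matrix: clip eigenvalues below eps, rescale to unit diagonal, iterate.
nearest_spd_correlation <- function(m, eps = 1e-6, max_iter = 50) {
  for (i in seq_len(max_iter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) > eps / 2) break
    vals <- pmax(e$values, eps)
    m <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  m
}

# Transition matrix of the reversible state chain. With nu_i = pi_i / w_i
# (w = relative dwell weights, default 1), off-diagonal P_ij = c nu_i nu_j /
# pi_i gives probability flow c nu_i nu_j between i and j - symmetric, so
# the stationary distribution is exactly the requested occupancy while state
# i's dwell time scales with w_i; c is calibrated so the occupancy-weighted
# mean dwell equals mean_dwell. Removing a forbidden pair symmetrically
# (mass onto the diagonal) preserves stationarity.
state_transition_matrix <- function(occupancy, mean_dwell, forbidden_pairs = list(),
                                    dwell_weights = NULL) {
  k <- length(occupancy)
  support <- which(occupancy > 0)
  P <- diag(1, k)
  if (length(support) == 1) return(P)
  w <- dwell_weights %||% rep(1, k)
  stop_if_not(length(w) == k && all(w > 0), "dwell_weights must be positive, one per pattern")
  nu <- occupancy / w
  cc <- 1 / (mean_dwell * (sum(nu)^2 - sum(nu^2)))
  for (i in support) {
    for (j in support) {
      if (i != j) P[i, j] <- cc * nu[i] * nu[j] / occupancy[i]
    }
  }
  for (pair in forbidden_pairs) {
    P[pair[1], pair[2]] <- 0
    P[pair[2], pair[1]] <- 0
  }
  diag(P) <- 0
  stop_if_not(max(rowSums(P)) <= 1 + 1e-12,
              "mean_dwell too short for this occupancy (leave probability > 1)")
  diag(P) <- 1 - rowSums(P)

  # every state with mass must be reachable within the allowed graph
  reached <- support[1]
  repeat {
    nxt <- unique(c(reached, support[colSums(P[reached, support, drop = FALSE] > 0) > 0]))
    if (length(nxt) == length(reached)) break
    reached <- nxt
  }
  if (!all(support %in% reached)) {
    stop("occupancy incompatible with forbidden-pair graph: some states with nonzero mass are unreachable",
         call. = FALSE)
  }
  P
}

#' Sample a frame-level state sequence for one recording
#'
#' First-order Markov chain whose stationary distribution equals the group's
#' occupancy exactly (reversible construction, see the methods vignette);
#' the self-transition probability is set by `mean_dwell` and forbidden
#' pattern pairs have transition probability zero.
#'
#' @param spec a [group_spec()].
#' @param n_frames number of frames to sample.
#' @param seed RNG seed.
#' @return integer vector of pattern labels, length `n_frames`.
#' @export
sample_state_sequence <- function(spec, n_frames, seed = 1) {
  stop_if_not(n_frames >= 1, "n_frames must be >= 1")
  k <- length(spec$occupancy)
  P <- state_transition_matrix(spec$occupancy, spec$mean_dwell, spec$forbidden_pairs,
                               spec$dwell_weights)
  set.seed(seed)
  states <- integer(n_frames)
  states[1] <- sample.int(k, 1, prob = spec$occupancy)
  for (t in seq_len(n_frames - 1)) {
    states[t + 1] <- sample.int(k, 1, prob = P[states[t], ])
  }
  states
}

#' Generate one recording's network time courses
#'
#' Each frame is drawn from a zero-mean multivariate normal distribution
#' whose covariance is the template of that frame's state; independent
#' Gaussian observation noise is added, optional state-coupled mean shifts
#' are applied (the "activation" model used by the regression analysis), and
#' columns are standardized (population convention). The default output shape
#' is 297 frames x 57 networks at TR = 2 s.
#'
#' @param templates list of pattern templates covering all labels in `states`.
#' @param states integer frame-state labels.
#' @param n_frames number of frames; must equal `length(states)`.
#' @param obs_noise_sd standard deviation of the added observation noise.
#' @param seed RNG seed.
#' @param tr repetition time in seconds.
#' @param activation optional `list(networks=, patterns=, shift=)`: the given
#'   networks have their mean raised by `shift` (in signal-SD units) during
#'   frames whose state is in `patterns`.
#' @param subject,group,cohort metadata passed to [time_course_table()].
#' @return a [time_course_table()]; columns z-scored unless `n_frames == 1`.
#' @export
generate_recording <- function(templates, states, n_frames = length(states),
                               obs_noise_sd = 0.1, seed = 1, tr = 2,
                               activation = NULL, subject = NA_character_,
                               group = NA_character_, cohort = NA_character_) {
  stop_if_not(n_frames >= 1, "n_frames must be >= 1")
  stop_if_not(length(states) == n_frames, "length(states) must equal n_frames")
  ids <- vapply(templates, function(tp) tp$id, integer(1))
  stop_if_not(all(states %in% ids), "templates must cover all state labels")
  d <- nrow(templates[[1]]$matrix)

  chol_by_id <- list()
  for (tp in templates) chol_by_id[[tp$id]] <- chol(tp$matrix)

  set.seed(seed)
  x <- matrix(0, n_frames, d)
  for (s in unique(states)) {
    rows <- which(states == s)
    z <- matrix(rnorm(length(rows) * d), length(rows), d)
    x[rows, ] <- z %*% chol_by_id[[s]]
  }
  if (obs_noise_sd > 0) {
    x <- x + matrix(rnorm(n_frames * d, sd = obs_noise_sd), n_frames, d)
  }
  if (!is.null(activation)) {
    on_frames <- states %in% activation$patterns
    x[on_frames, activation$networks] <- x[on_frames, activation$networks] + activation$shift
  }
  if (n_frames > 1) {
    x <- scale_population(x)
  }
  time_course_table(x, tr = tr, subject = subject, group = group, cohort = cohort)
}

# z-score columns with the population (1/N) standard deviation
scale_population <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- sqrt(colMeans(xc^2))
  stop_if_not(all(s > 0), "cannot standardize a constant column")
  sweep(xc, 2, s, "/")
}

#' Generate a full multi-group cohort with ground truth
#'
#' One recording per subject per condition: anesthesia subjects (PROP, SEVO
#' group specs with `paired_awake = TRUE`) contribute a paired AWAKE and an
#' anesthetized recording; control and UWS subjects contribute one recording
#' each. With the default design (11 propofol pairs, 14 sevoflurane pairs,
#' 20 controls, 18 UWS) this yields 88 recordings, 50 of them in the
#' anesthesia (training) cohort. Deterministic given `seed`: every recording
#' gets its own seed derived by stable hashing of subject and condition.
#'
#' @param group_specs named list of [group_spec()]s (must include `AWAKE`).
#' @param templates list of pattern templates.
#' @param n_frames frames per recording.
#' @param obs_noise_sd observation-noise standard deviation.
#' @param seed master seed.
#' @param tr repetition time (seconds).
#' @param activation optional activation model (see [generate_recording()]).
#' @return `list(recordings = <list of time_course_table>, truth = <cohort_truth>)`;
#'   `truth` holds the templates, group specs, per-recording frame states and
#'   the master seed.
#' @export
generate_cohort <- function(group_specs, templates, n_frames = 297,
                            obs_noise_sd = 0.1, seed = 1, tr = 2,
                            activation = NULL) {
  stop_if_not(length(group_specs) >= 1, "group_specs must be non-empty")
  if (is.null(names(group_specs))) {
    names(group_specs) <- vapply(group_specs, `[[`, "", "name")
  }

  plan <- list()  # one entry per recording: subject, condition, cohort
  prefixes <- c(AWAKE = "C", PROP = "P", SEVO = "S", UWS = "U")
  for (gs in group_specs) {
    pre <- prefixes[[gs$name]]
    for (i in seq_len(gs$n_subjects)) {
      subj <- sprintf("%s%02d", pre, i)
      if (gs$paired_awake) {
        stop_if_not(!is.null(group_specs$AWAKE),
                    "paired design needs an AWAKE group spec")
        plan[[length(plan) + 1]] <- list(subject = subj, condition = "AWAKE",
                                         cohort = gs$cohort)
      }
      plan[[length(plan) + 1]] <- list(subject = subj, condition = gs$name,
                                       cohort = gs$cohort)
    }
  }
  keys <- vapply(plan, function(p) paste0(p$subject, ":", p$condition), "")
  stop_if_not(!anyDuplicated(keys), "duplicate subject/condition keys in cohort design")

  recordings <- vector("list", length(plan))
  states_by_key <- vector("list", length(plan))
  names(recordings) <- names(states_by_key) <- keys
  for (i in seq_along(plan)) {
    p <- plan[[i]]
    cond_spec <- group_specs[[p$condition]]
    states <- sample_state_sequence(cond_spec, n_frames,
                                    seed = derive_seed(seed, paste0(keys[i], ":states")))
    recordings[[i]] <- generate_recording(
      templates, states, obs_noise_sd = obs_noise_sd,
      seed = derive_seed(seed, paste0(keys[i], ":signal")),
      tr = tr, activation = activation,
      subject = p$subject, group = p$condition, cohort = p$cohort)
    states_by_key[[i]] <- states
  }
  truth <- structure(
    list(templates = templates, group_specs = group_specs,
         states = states_by_key, seed = seed, activation = activation),
    class = "cohort_truth")
  list(recordings = recordings, truth = truth)
}

#' Generate the default synthetic cohort
#'
#' Convenience wrapper building templates and the full four-group cohort from
#' the packaged configuration (see [default_cohort_config()]).
#'
#' @param seed master seed.
#' @param config configuration list, by default the packaged one.
#' @return as [generate_cohort()].
#' @export
default_cohort <- function(seed = 1, config = default_cohort_config()) {
  templates <- build_pattern_templates(
    config$n_networks, config$k, config$block_spec,
    base_noise = config$base_noise,
    seed = derive_seed(seed, "templates"),
    descriptions = config$descriptions)
  generate_cohort(config$group_specs, templates,
                  n_frames = config$n_frames,
                  obs_noise_sd = config$obs_noise_sd,
                  seed = seed, tr = config$tr,
                  activation = config$activation)
}

#' Generate white-noise component time courses
#'
#' Standard-normal white-noise series emulating the flat-spectrum noise
#' components discarded by the signal screening stage.
#'
#' @param n_series number of noise components.
#' @param n_frames frames per series.
#' @param seed RNG seed.
#' @param tr repetition time (seconds).
#' @return a [time_course_table()] with z-scored columns.
#' @export
generate_noise_components <- function(n_series, n_frames = 297, seed = 1, tr = 2) {
  stop_if_not(n_series >= 1, "n_series must be >= 1")
  stop_if_not(n_frames >= 2, "need at least two frames to standardize")
  set.seed(seed)
  x <- matrix(rnorm(n_frames * n_series), n_frames, n_series)
  x <- scale_population(x)
  colnames(x) <- sprintf("noise%02d", seq_len(n_series))
  time_course_table(x, tr = tr)
}
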