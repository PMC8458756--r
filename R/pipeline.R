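#' Default pipeline run configuration
#'
#' Collects every tunable of the analysis in one validated list: synthetic
#' cohort settings, conditioning flags, window length and step, k and restart
#' count for clustering, classifier and regression settings, and the master
#' seed that every random stage derives its stream from.
#'
#' @param seed master seed.
#' @param cohort_config synthetic-cohort configuration ([default_cohort_config()]),
#'   or a directory path to load a written cohort from.
#' @return a named list of settings.
#' @export
default_run_config <- function(seed = 1, cohort_config = default_cohort_config()) {
  list(seed = seed, cohort = cohort_config,
       window = 30, step = 1, k = 7, n_restarts = 20, max_iter = 100,
       despike = TRUE, filter = "lowpass", cutoff_hz = 0.15,
       n_features = 2, n_permutations = 100,
       target_patterns = c(1, 3), bonferroni_factor = 6)
}

validate_run_config <- function(config) {
  req <- c("seed", "cohort", "window", "step", "k", "n_restarts",
           "n_features", "n_permutations", "target_patterns")
  missing <- setdiff(req, names(config))
  stop_if_not(length(missing) == 0, "config is missing fields: %s",
              paste(missing, collapse = ", "))
  stop_if_not(config$window >= 2 && config$step >= 1, "window/step out of range")
  if (is.list(config$cohort)) {
    stop_if_not(config$cohort$n_frames > config$window,
                "window (%d) must be smaller than the recording length (%d)",
                config$window, config$cohort$n_frames)
  }
  stop_if_not(config$k >= 2 && config$n_restarts >= 1, "k/n_restarts out of range")
  stop_if_not(config$n_features >= 1 && config$n_features <= config$k,
              "n_features must be in 1..k")
  invisible(TRUE)
}

#' Run the full dynamic-brain-state analysis
#'
#' Executes every stage on one cohort: simulate (or load) -> condition ->
#' windowed connectivity -> L1 k-means pattern clustering -> occupancy and
#' transition dynamics with group statistics -> Fisher + SVM consciousness
#' classification (train on the anesthesia cohort, test on UWS + controls)
#' -> per-network logistic regression of conscious-pattern occurrence.
#' With synthetic ground truth available, fitted patterns are relabeled to
#' the generator's pattern ids and the window-level adjusted Rand index is
#' reported. Deterministic given the config seed.
#'
#' @param config a [default_run_config()] list.
#' @param out_dir optional directory; when given, every stage's artifacts
#'   (occupancy, transition and regression CSVs, the summary JSON and a run
#'   log with seeds and a config hash) are written there.
#' @return invisibly, a list with elements `cohort`, `conditioned`, `windows`
#'   (the pooled window vectors with recording provenance), `model`, `perm`,
#'   `states`, `dynamics`, `classification`, `regression`, `summary`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  note("stage simulate: master seed %d", config$seed)
  if (is.character(config$cohort)) {
    recordings <- load_timecourses(config$cohort)
    truth <- NULL
  } else {
    cohort <- default_cohort(seed = config$seed, config = config$cohort)
    recordings <- cohort$recordings
    truth <- cohort$truth
  }
  keys <- names(recordings)
  note("  %d recordings", length(recordings))

  note("stage condition: despike=%s filter=%s", config$despike, config$filter)
  conditioned <- lapply(recordings, function(rec) {
    tryCatch(
      condition_recording(rec, despike_series = config$despike,
                          filter = config$filter,
                          cutoff_hz = config$cutoff_hz %||% 0.15),
      error = function(e) stop(sprintf("stage condition failed on recording %s:%s: %s",
                                       rec$subject, rec$group, conditionMessage(e)),
                               call. = FALSE))
  })

  note("stage dfnc: window %d, step %d", config$window, config$step)
  series <- lapply(conditioned, dfnc_series, window = config$window,
                   step = config$step, keep_matrices = FALSE)
  pooled <- pool_windows(series)
  rm(series)
  gc(FALSE)
  note("  pooled %d window vectors of dimension %d", nrow(pooled$vectors), ncol(pooled$vectors))

  note("stage cluster: k = %d, %d restarts", config$k, config$n_restarts)
  model <- kmeans_l1(pooled$vectors, k = config$k, n_restarts = config$n_restarts,
                     max_iter = config$max_iter %||% 100,
                     seed = derive_seed(config$seed, "kmeans"))
  states <- split(assign_patterns(pooled$vectors, model), pooled$recording)[keys]

  ari <- ari_all <- NA_real_
  perm <- seq_len(config$k)
  if (!is.null(truth)) {
    perm <- relabel_to_reference(model, truth$templates)
    states <- apply_relabeling(states, perm)
    ref <- unlist(lapply(keys, function(key) {
      window_true_states(truth$states[[key]], truth$templates,
                         config$window, config$step)
    }), use.names = FALSE)
    # unambiguous windows: all frames in one state, so the true label is
    # well defined; straddling windows have mixture labels and are scored
    # separately (ari_all)
    pure <- unlist(lapply(keys, function(key) {
      st <- truth$states[[key]]
      vapply(window_starts(length(st), config$window, config$step),
             function(s) length(unique(st[s:(s + config$window - 1)])) == 1,
             logical(1))
    }), use.names = FALSE)
    fitted <- unlist(states, use.names = FALSE)
    ari <- adjusted_rand_index(fitted[pure], ref[pure])
    ari_all <- adjusted_rand_index(fitted, ref)
    note("  relabeled to ground truth; ARI = %.3f on %d unambiguous windows (%.3f all windows)",
         ari, sum(pure), ari_all)
  }

  note("stage dynamics")
  groups <- vapply(recordings, `[[`, "", "group")
  occ <- occupancy(states, grouping = groups, k = config$k)
  transitions <- vapply(states, count_transitions, integer(1))
  tmat <- transition_matrix(states, k = config$k)
  ranksum <- compare_groups_ranksum(transitions, groups,
                                    bonferroni_factor = config$bonferroni_factor %||% 6)
  chi2 <- list()
  if ("AWAKE" %in% groups) {
    for (g in setdiff(unique(groups), "AWAKE")) {
      chi2[[paste0("AWAKE_vs_", g)]] <- pattern_distribution_chi2(
        states[groups == "AWAKE"], states[groups == g], k = config$k)
    }
  }

  note("stage classify: top %d Fisher-ranked features", config$n_features)
  feats <- feature_table(states, recordings, k = config$k)
  classification <- NULL
  if (all(c("train", "test") %in% feats$cohort) &&
      length(unique(feats$conscious[feats$cohort == "train"])) == 2) {
    train <- feats[feats$cohort == "train", ]
    test <- feats[feats$cohort == "test", ]
    clf <- train_classifier(train, n_features = config$n_features)
    rate <- evaluate_classifier(clf, test)
    chance <- permutation_chance(clf, test, n_permutations = config$n_permutations,
                                 seed = derive_seed(config$seed, "permutation"))
    classification <- list(model = clf, rate = rate, chance = chance,
                           n_train = nrow(train), n_test = nrow(test))
    note("  correct classification rate %.3f (chance %.3f +/- %.3f)",
         rate, chance$mean, chance$se)
  } else {
    note("  skipped: no train/test split with both classes in training")
  }

  note("stage regress: patterns %s", paste(config$target_patterns, collapse = ","))
  regression <- regress_all_networks(states, conditioned,
                                     target_patterns = config$target_patterns,
                                     window = config$window)
  note("  %d of %d networks significant positive",
       sum(regression$significant_positive), nrow(regression))

  summary <- list(
    seed = config$seed,
    n_recordings = length(recordings),
    k = config$k,
    window = config$window,
    ari = ari,
    ari_all_windows = ari_all,
    occupancy_by_group = occ$group,
    transition_counts = split(unname(transitions), groups),
    transition_matrix = tmat,
    ranksum = ranksum,
    chi2_p = lapply(chi2, `[[`, "p_value"),
    classification_rate = classification$rate,
    chance_mean = classification$chance$mean,
    chance_se = classification$chance$se,
    n_significant_networks = sum(regression$significant_positive),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(cohort = list(recordings = recordings, truth = truth),
                 conditioned = conditioned, windows = pooled, model = model,
                 perm = perm, states = states,
                 dynamics = list(occupancy = occ, transitions = transitions,
                                 transition_matrix = tmat, ranksum = ranksum,
                                 chi2 = chi2),
                 classification = classification, regression = regression,
                 summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(data.frame(group = rownames(occ$group), occ$group, row.names = NULL),
              file.path(out_dir, "occupancy_by_group.csv"), row.names = FALSE)
    write.csv(data.frame(recording = keys, group = groups, transitions = transitions,
                         row.names = NULL),
              file.path(out_dir, "transition_counts.csv"), row.names = FALSE)
    write.csv(as.data.frame(tmat), file.path(out_dir, "transition_matrix.csv"))
    write.csv(ranksum, file.path(out_dir, "ranksum_transitions.csv"), row.names = FALSE)
    write.csv(regression, file.path(out_dir, "regression_networks.csv"), row.names = FALSE)
    jsonlite::write_json(summary_to_json(summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_hash <- derive_seed(0, paste(deparse(config[setdiff(names(config), "cohort")]),
                                     collapse = ""))
    log_lines <- c(sprintf("R %s | brainstates %s | config hash %d",
                           getRversion(), as.character(utils::packageVersion("brainstates")),
                           cfg_hash),
                   log_lines)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

summary_to_json <- function(s) {
  s$occupancy_by_group <- as.data.frame(s$occupancy_by_group)
  s$transition_matrix <- as.data.frame(s$transition_matrix)
  s
}

#' Write a cohort to disk as plain-text artifacts
#'
#' One TSV per recording (frames x networks with a header of network names),
#' a JSON manifest (subject, group, cohort, TR, file), and - for synthetic
#' cohorts - a ground-truth JSON with the templates, frame-level states,
#' group specs and seed.
#'
#' @param cohort result of [generate_cohort()] / [default_cohort()], or a
#'   plain list of [time_course_table()]s.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  recordings <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  truth <- cohort$truth
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(names(recordings), function(key) {
    rec <- recordings[[key]]
    fname <- paste0(gsub(":", "_", key), ".tsv")
    df <- as.data.frame(rec$values)
    utils::write.table(df, file.path(dir, fname), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(key = key, file = fname, subject = rec$subject, group = rec$group,
         cohort = rec$cohort, tr = rec$tr)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    truth_json <- list(
      seed = truth$seed,
      templates = lapply(truth$templates, function(tp)
        list(id = tp$id, description = tp$description, matrix = tp$matrix)),
      states = truth$states,
      occupancy = lapply(truth$group_specs, `[[`, "occupancy"))
    jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a cohort of time-course tables from disk
#'
#' Reads the manifest written by [write_cohort()] (or an equivalent
#' hand-written one) and validates every recording: the referenced file must
#' exist, all recordings must have the same number of networks, values must
#' be finite and complete (a missing value is reported with its frame and
#' network coordinates), and every recording needs a group label.
#'
#' @param dir directory holding `manifest.json` and the recording TSVs.
#' @param manifest optional manifest path (default `dir/manifest.json`).
#' @return named list of [time_course_table()]s.
#' @export
load_timecourses <- function(dir, manifest = file.path(dir, "manifest.json")) {
  stop_if_not(file.exists(manifest), "manifest not found: %s", manifest)
  entries <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  stop_if_not(length(entries) >= 1, "empty manifest")
  out <- list()
  n_nets <- NULL
  for (e in entries) {
    path <- file.path(dir, e$file)
    stop_if_not(file.exists(path), "recording file missing: %s", path)
    stop_if_not(!is.null(e$group), "recording %s has no group label", e$key %||% e$file)
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    x <- as.matrix(df)
    bad <- which(!is.finite(x), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("recording %s: missing/non-finite value at frame %d, network %s",
                   e$key %||% e$file, bad[1, 1], colnames(x)[bad[1, 2]]), call. = FALSE)
    }
    if (is.null(n_nets)) n_nets <- ncol(x)
    stop_if_not(ncol(x) == n_nets,
                "recording %s has %d networks, expected %d", e$key %||% e$file,
                ncol(x), n_nets)
    key <- e$key %||% e$file
    out[[key]] <- time_course_table(x, tr = e$tr %||% 2,
                                    subject = e$subject %||% NA_character_,
                                    group = e$group,
                                    cohort = e$cohort %||% NA_character_)
  }
  out
}
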