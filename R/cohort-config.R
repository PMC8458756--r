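#' Default synthetic-cohort configuration
#'
#' Reads the editable JSON config shipped with the package
#' (`inst/extdata/cohort_defaults.json`). It defines the study conditions the
#' generator emulates: 57 networks in seven functional families, seven
#' connectivity pattern templates, the per-condition pattern occupancies
#' (AWAKE pattern 1 = 0.50 and pattern 3 = 0.22, SEVO pattern 7 = 0.99, ...),
#' the forbidden transition pairs, the cohort design (11 propofol pairs,
#' 14 sevoflurane pairs, 20 control and 18 UWS subjects) and the
#' activity-coupling of six networks to the consciousness-specific patterns.
#'
#' @param path path to a JSON config; defaults to the packaged file.
#' @return a list with elements `n_networks`, `k`, `n_frames`, `tr`,
#'   `obs_noise_sd`, `base_noise`, `block_spec`, `descriptions`,
#'   `group_specs`, `design`, `activation`, `forbidden_pairs`.
#' @export
default_cohort_config <- function(path = system.file("extdata", "cohort_defaults.json",
                                                     package = "brainstates")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- raw$k
  n_networks <- raw$n_networks

  fam <- lapply(raw$network_families, function(rng) seq.int(rng[1], rng[2]))
  tiles <- sort(as.integer(unlist(fam)))
  stop_if_not(length(tiles) == n_networks && all(tiles == seq_len(n_networks)),
              "network families must tile 1..n_networks exactly")

  block_spec <- vector("list", k)
  descriptions <- character(k)
  for (pid in seq_len(k)) {
    entry <- raw$pattern_blocks[[as.character(pid)]]
    stop_if_not(!is.null(entry), "missing pattern block spec for pattern %d", pid)
    descriptions[pid] <- entry$description
    blocks <- entry$blocks
    if (is.data.frame(blocks)) {
      blocks <- lapply(seq_len(nrow(blocks)), function(i) {
        b <- list(families = blocks$families[[i]], r = blocks$r[[i]])
        f2 <- blocks$families2[[i]]
        if (!is.null(f2) && length(f2) && !all(is.na(f2))) b$families2 <- f2
        b
      })
    }
    block_spec[[pid]] <- lapply(blocks, function(b) {
      out <- list(networks = sort(unlist(fam[b$families], use.names = FALSE)), r = b$r)
      if (!is.null(b$families2)) {
        out$networks2 <- sort(unlist(fam[b$families2], use.names = FALSE))
      }
      out
    })
  }

  forbidden <- raw$forbidden_pairs
  if (is.matrix(forbidden)) {
    forbidden <- lapply(seq_len(nrow(forbidden)), function(i) forbidden[i, ])
  }

  occ_vec <- function(named) {
    v <- numeric(k)
    v[as.integer(names(named))] <- unlist(named)
    v
  }
  weight_vec <- function(group) {
    w <- rep(1, k)
    named <- raw$dwell_weights[[group]]
    if (!is.null(named)) w[as.integer(names(named))] <- unlist(named)
    w
  }
  des <- raw$design
  dwell <- raw$mean_dwell
  if (length(dwell) == 1 && is.null(names(dwell))) {
    dwell <- list(AWAKE = dwell, PROP = dwell, SEVO = dwell, UWS = dwell)
  }
  group_specs <- list(
    AWAKE = group_spec("AWAKE", n_subjects = des$controls,
                       occupancy = occ_vec(raw$occupancy$AWAKE),
                       mean_dwell = dwell$AWAKE, forbidden_pairs = forbidden,
                       dwell_weights = weight_vec("AWAKE"),
                       cohort = "test"),
    PROP = group_spec("PROP", n_subjects = des$prop_pairs,
                      occupancy = occ_vec(raw$occupancy$PROP),
                      mean_dwell = dwell$PROP, forbidden_pairs = forbidden,
                      dwell_weights = weight_vec("PROP"),
                      paired_awake = TRUE, cohort = "train"),
    SEVO = group_spec("SEVO", n_subjects = des$sevo_pairs,
                      occupancy = occ_vec(raw$occupancy$SEVO),
                      mean_dwell = dwell$SEVO, forbidden_pairs = forbidden,
                      dwell_weights = weight_vec("SEVO"),
                      paired_awake = TRUE, cohort = "train"),
    UWS = group_spec("UWS", n_subjects = des$uws,
                     occupancy = occ_vec(raw$occupancy$UWS),
                     mean_dwell = dwell$UWS, forbidden_pairs = forbidden,
                      dwell_weights = weight_vec("UWS"),
                     cohort = "test")
  )

  activation <- NULL
  if (!is.null(raw$activation)) {
    activation <- list(networks = as.integer(raw$activation$networks),
                       patterns = as.integer(raw$activation$patterns),
                       shift = raw$activation$shift)
  }

  list(n_networks = n_networks, k = k, n_frames = raw$n_frames, tr = raw$tr,
       obs_noise_sd = raw$obs_noise_sd, base_noise = raw$base_noise,
       network_families = fam, block_spec = block_spec,
       descriptions = descriptions, group_specs = group_specs,
       design = des, activation = activation, forbidden_pairs = forbidden)
}

#' Specification of one subject group's state process
#'
#' @param name group label (`AWAKE`, `PROP`, `SEVO`, `UWS`).
#' @param n_subjects number of subjects in the group.
#' @param occupancy probability vector over the k patterns; the stationary
#'   distribution of the group's state chain. Must sum to 1.
#' @param mean_dwell expected consecutive frames spent in a state.
#' @param forbidden_pairs list of unordered pattern pairs whose transition
#'   probability is forced to zero.
#' @param paired_awake if `TRUE`, each subject also contributes a paired
#'   AWAKE recording (the anesthesia design).
#' @param cohort `"train"` or `"test"`.
#' @param dwell_weights optional per-pattern relative dwell multipliers
#'   (length k, default all 1): a pattern with weight 0.5 dwells half as
#'   long but is entered twice as often, leaving occupancy unchanged.
#' @return a `group_spec` list.
#' @export
group_spec <- function(name, n_subjects, occupancy, mean_dwell = 60,
                       forbidden_pairs = list(), paired_awake = FALSE,
                       cohort = NA_character_, dwell_weights = NULL) {
  stop_if_not(name %in% c("AWAKE", "PROP", "SEVO", "UWS"),
              "unknown group name '%s'", name)
  stop_if_not(n_subjects >= 1, "n_subjects must be >= 1")
  stop_if_not(abs(sum(occupancy) - 1) < 1e-9, "occupancy must sum to 1")
  stop_if_not(all(occupancy >= 0), "occupancy entries must be non-negative")
  stop_if_not(mean_dwell >= 1, "mean_dwell must be >= 1 frame")
  if (!is.null(dwell_weights)) {
    stop_if_not(length(dwell_weights) == length(occupancy) && all(dwell_weights > 0),
                "dwell_weights must be positive, one per pattern")
  }
  structure(
    list(name = name, n_subjects = as.integer(n_subjects),
         occupancy = occupancy, mean_dwell = mean_dwell,
         forbidden_pairs = forbidden_pairs, paired_awake = paired_awake,
         cohort = cohort, dwell_weights = dwell_weights),
    class = "group_spec"
  )
}
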