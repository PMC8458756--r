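test_that("pattern templates honor the block structure and are valid correlation matrices", {
  tpl <- mini_templates()
  expect_length(tpl, 2)
  m1 <- tpl[[1]]$matrix
  m2 <- tpl[[2]]$matrix
  expect_lte(mean(abs(m1[upper.tri(m1)])), 0.1)
  block <- m2[1:3, 1:3]
  expect_gte(mean(block[upper.tri(block)]), 0.6)
  for (tp in tpl) {
    expect_identical(tp$matrix, t(tp$matrix))
    expect_equal(unname(diag(tp$matrix)), rep(1, 6))
    expect_gt(min(eigen(tp$matrix, symmetric = TRUE, only.values = TRUE)$values), 0)
    off <- tp$matrix[upper.tri(tp$matrix)]
    expect_true(all(off >= -1 & off <= 1))
  }
})

test_that("default templates are symmetric positive definite with unit diagonal", {
  cfg <- default_cohort_config()
  tpl <- build_pattern_templates(cfg$n_networks, cfg$k, cfg$block_spec,
                                 cfg$base_noise, seed = 3)
  for (tp in tpl) {
    expect_identical(tp$matrix, t(tp$matrix))
    expect_equal(unname(diag(tp$matrix)), rep(1, cfg$n_networks))
    expect_gt(min(eigen(tp$matrix, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("sampling from a template reproduces its correlation matrix", {
  tpl <- mini_templates()
  set.seed(7)
  z <- matrix(rnorm(20000 * 6), 20000, 6) %*% chol(tpl[[2]]$matrix)
  expect_lt(max(abs(cor(z) - tpl[[2]]$matrix)), 0.05)
})

test_that("an unrepairable block request errors with the offending pattern", {
  spec <- list(list(),
               list(list(networks = 1:2, r = 0.95),
                    list(networks = 2:3, r = 0.95),
                    list(networks = c(1, 3), r = -0.95)))
  expect_error(build_pattern_templates(4, 2, spec, base_noise = 0.01, seed = 1),
               "pattern 2")
  expect_error(build_pattern_templates(4, 2, list(list(), list(list(networks = 1:2, r = 1.5)))),
               "in \\(-1, 1\\)")
})

test_that("state sequences follow the group occupancy and dwell structure", {
  cfg <- default_cohort_config()
  awake <- cfg$group_specs$AWAKE

  # degenerate chain: all mass on one pattern
  solo <- group_spec("AWAKE", 1, c(1, 0, 0, 0, 0, 0, 0))
  expect_identical(unique(sample_state_sequence(solo, 50, seed = 1)), 1L)

  # long-run frequencies match the printed AWAKE probabilities
  s <- sample_state_sequence(awake, 100000, seed = 5)
  freq <- tabulate(s, 7) / length(s)
  expect_lt(abs(freq[1] - 0.5), 0.02)
  expect_lt(abs(freq[3] - 0.22), 0.02)

  # total-variation convergence to the stationary occupancy
  s2 <- sample_state_sequence(awake, 200000, seed = 6)
  tv <- sum(abs(tabulate(s2, 7) / length(s2) - awake$occupancy)) / 2
  expect_lt(tv, 0.02)

  # forbidden pairs never occur adjacently
  forb <- group_spec("UWS", 1, c(0.3, 0.3, 0.4, rep(0, 4)),
                     mean_dwell = 3, forbidden_pairs = list(c(2, 3)))
  sf <- sample_state_sequence(forb, 20000, seed = 8)
  adj <- cbind(sf[-length(sf)], sf[-1])
  expect_identical(sum((adj[, 1] == 2 & adj[, 2] == 3) |
                       (adj[, 1] == 3 & adj[, 2] == 2)), 0L)

  # occupancy unreachable through the forbidden-pair graph errors
  bad <- group_spec("UWS", 1, c(0.5, 0.5, rep(0, 5)),
                    forbidden_pairs = list(c(1, 2)))
  expect_error(sample_state_sequence(bad, 10, seed = 1), "unreachable")
})

test_that("recordings carry the state-dependent covariance and default shape", {
  tpl <- mini_templates()

  # constant-state long recording recovers the template, noise-free
  states <- rep(2L, 20000)
  rec <- generate_recording(tpl, states, obs_noise_sd = 0, seed = 9)
  expect_lt(max(abs(cor(rec$values) - tpl[[2]]$matrix)), 0.05)

  # default shape: 297 retained frames x 57 networks
  cfg <- default_cohort_config()
  big <- build_pattern_templates(cfg$n_networks, cfg$k, cfg$block_spec,
                                 cfg$base_noise, seed = 2)
  st <- sample_state_sequence(cfg$group_specs$AWAKE, cfg$n_frames, seed = 3)
  out <- generate_recording(big, st, seed = 4)
  expect_identical(dim(out$values), c(297L, 57L))
  expect_equal(unname(colMeans(out$values)), rep(0, 57), tolerance = 1e-9)

  # degenerate single-frame recording stays finite
  one <- generate_recording(tpl, 1L, obs_noise_sd = 0, seed = 1)
  expect_identical(nrow(one$values), 1L)
  expect_true(all(is.finite(one$values)))

  expect_error(generate_recording(tpl, integer(0), n_frames = 0), "n_frames")
  expect_error(generate_recording(tpl, c(1L, 3L)), "cover")
})

test_that("activation shifts the mean of driven networks during target states", {
  tpl <- mini_templates()
  states <- rep(c(1L, 2L), each = 2000)
  rec <- generate_recording(tpl, states, obs_noise_sd = 0, seed = 11,
                            activation = list(networks = 1, patterns = 2, shift = 0.5))
  on_mean <- mean(rec$values[states == 2, 1])
  off_mean <- mean(rec$values[states == 1, 1])
  expect_gt(on_mean - off_mean, 0.3)
})

test_that("the default cohort design yields 88 recordings with a 50-recording training split", {
  cfg <- default_cohort_config()
  cfg$n_frames <- 40  # shape is design-driven, keep the fixture light
  cohort <- default_cohort(seed = 1, config = cfg)
  expect_length(cohort$recordings, 88)
  cohorts <- vapply(cohort$recordings, `[[`, "", "cohort")
  expect_identical(sum(cohorts == "train"), 50L)
  expect_identical(sum(cohorts == "test"), 38L)
  groups <- vapply(cohort$recordings, `[[`, "", "group")
  expect_identical(as.integer(table(groups)[c("AWAKE", "PROP", "SEVO", "UWS")]),
                   c(45L, 11L, 14L, 18L))

  # determinism: same master seed, bit-identical values
  again <- default_cohort(seed = 1, config = cfg)
  expect_identical(lapply(cohort$recordings, `[[`, "values"),
                   lapply(again$recordings, `[[`, "values"))
  expect_identical(cohort$truth$states, again$truth$states)

  # a different seed changes the data
  other <- default_cohort(seed = 2, config = cfg)
  expect_false(identical(cohort$recordings[[1]]$values, other$recordings[[1]]$values))
})

test_that("minimal cohorts and duplicate designs behave as contracted", {
  tpl <- mini_templates()
  solo <- group_spec("UWS", 1, c(0.5, 0.5), mean_dwell = 5)
  out <- generate_cohort(list(UWS = solo), tpl, n_frames = 40, seed = 1)
  expect_length(out$recordings, 1)
  expect_identical(out$recordings[[1]]$group, "UWS")

  dup <- list(UWS = solo, UWS2 = solo)  # same name -> same subject keys
  names(dup) <- NULL
  expect_error(generate_cohort(dup, tpl, n_frames = 40, seed = 1), "duplicate")
})

test_that("noise components are standardized and spectrally flat", {
  nc <- generate_noise_components(18, n_frames = 297, seed = 4)
  expect_identical(ncol(nc$values), 18L)
  expect_equal(unname(colMeans(nc$values)), rep(0, 18), tolerance = 1e-9)
  pop_sd <- sqrt(colMeans(nc$values^2))
  expect_equal(unname(pop_sd), rep(1, 18), tolerance = 1e-9)

  # flat spectrum: mean low-frequency power fraction ~ 0.1 / 0.25 of the band
  ratios <- apply(generate_noise_components(50, 2048, seed = 5)$values, 2, function(col) {
    pg <- periodogram(col, tr = 2)
    low_freq_ratio(pg$frequencies, pg$power)
  })
  expect_lt(abs(mean(ratios) - 0.4), 0.05)
})
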