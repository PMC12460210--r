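test_that("generators are bit-reproducible under a fixed seed", {
  sp <- list(coupling_spec(c("C3", "C4"), "alpha", pi / 2, 0.7))
  a <- gen_coupled_eeg(sp, duration = 6, seed = 11)
  b <- gen_coupled_eeg(sp, duration = 6, seed = 11)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, gen_coupled_eeg(sp, duration = 6,
                                                 seed = 12)$data))

  c1 <- gen_cohort(cohort_spec(n_subjects = 4, seed = 3))
  c2 <- gen_cohort(cohort_spec(n_subjects = 4, seed = 3))
  expect_identical(c1$pre[[2]]$values, c2$pre[[2]]$values)
  expect_identical(c1$behavior, c2$behavior)

  tr <- generate_track("easy", 10, seed = 1)
  expect_identical(gen_tracker(tr, 0.1, 0.3, seed = 5),
                   gen_tracker(tr, 0.1, 0.3, seed = 5))
})

test_that("coupling spec and cohort spec validate their invariants", {
  expect_error(coupling_spec(c("a", "a"), "alpha", 1, 0.5), "distinct")
  expect_error(coupling_spec(c("a", "b"), "delta", 1, 0.5), "unknown band")
  expect_error(coupling_spec(c("a", "b"), "alpha", 4, 0.5), "phase_lag")
  expect_error(coupling_spec(c("a", "b"), "alpha", 1, 1.5), "strength")
  expect_error(cohort_spec(n_subjects = 1), ">= 2")
  expect_error(cohort_spec(effect_edges = list(c("AF3", "XX"))), "unknown")
  expect_error(gen_coupled_eeg(duration = 2), "one analysis window")
  expect_error(gen_coupled_eeg(list(coupling_spec(c("C3", "C4"), "gamma",
                                                  1, 1)),
                               fs = 64, duration = 10), "twice the band")
})

test_that("uncoupled channels show only null-level ciPLV", {
  # mean ciPLV of independent channels across seeds stays within the
  # spread expected from the same estimator under explicit decoupling
  vals <- vapply(1:10, function(s) {
    rec <- gen_coupled_eeg(list(), n_channels = 2, duration = 20,
                           noise_sd = 1, seed = s,
                           channel_labels = c("a", "b"))
    ciplv(sliding_windows(rec), "alpha")$values["a", "b"]
  }, 0)
  # 9 windows of independent noise: mean resultant of ~9 random phases
  # has expectation ~ sqrt(pi)/(2 sqrt(9)) ~ 0.3; demand no systematic
  # coupling beyond that scale
  expect_lt(mean(vals), 0.35)

  # strength = 0 in a coupling spec behaves identically to no coupling
  r0 <- gen_coupled_eeg(list(coupling_spec(c("a", "b"), "alpha", pi / 2, 0)),
                        n_channels = 2, duration = 20, noise_sd = 1,
                        seed = 1, channel_labels = c("a", "b"))
  r1 <- gen_coupled_eeg(list(), n_channels = 2, duration = 20, noise_sd = 1,
                        seed = 1, channel_labels = c("a", "b"))
  expect_identical(r0$data, r1$data)
})

test_that("expected ciPLV grows monotonically with coupling strength", {
  grid <- c(0.2, 0.5, 0.8, 1)
  means <- vapply(grid, function(str) {
    mean(vapply(1:6, function(s) {
      rec <- gen_coupled_eeg(list(coupling_spec(c("a", "b"), "alpha",
                                                pi / 2, str)),
                             n_channels = 2, duration = 20, noise_sd = 0.3,
                             seed = s, channel_labels = c("a", "b"))
      ciplv(sliding_windows(rec), "alpha")$values["a", "b"]
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_gt(means[length(means)], 0.8)
})

test_that("zero-lag coupling saturates PLV but not ciPLV", {
  rec <- gen_coupled_eeg(list(coupling_spec(c("a", "b"), "alpha", 0, 1)),
                         n_channels = 2, duration = 30, noise_sd = 0,
                         seed = 4, channel_labels = c("a", "b"))
  ws <- sliding_windows(rec)
  expect_gte(plv(ws, "alpha")$values["a", "b"], 0.99)
  expect_lte(ciplv(ws, "alpha")$values["a", "b"], 0.05)
})

test_that("null cohorts are exchangeable between sessions", {
  tstats <- unlist(lapply(1:10, function(s) {
    ch <- gen_cohort(cohort_spec(n_subjects = 12, seed = s))
    st <- edge_stats(ch$pre, ch$post)
    st[upper.tri(st)]
  }))
  # paired t over exchangeable draws: mean ~ 0, unit-ish scale
  expect_lt(abs(mean(tstats)), 0.1)
})

test_that("effect edges and only effect edges shift in expectation", {
  eff <- planted_edges_rf()
  delta <- Reduce(`+`, lapply(1:12, function(s) {
    ch <- gen_cohort(cohort_spec(n_subjects = 10, effect_edges = eff,
                                 effect_size = -0.2, seed = s))
    Reduce(`+`, lapply(seq_along(ch$pre), function(i)
      ch$post[[i]]$values - ch$pre[[i]]$values)) / length(ch$pre)
  })) / 12
  lab <- eeg_montage_16()
  dimnames(delta) <- list(lab, lab)
  eff_mask <- matrix(FALSE, 16, 16, dimnames = list(lab, lab))
  for (e in eff) eff_mask[e[1], e[2]] <- eff_mask[e[2], e[1]] <- TRUE
  on_eff <- delta[eff_mask & upper.tri(delta)]
  off_eff <- delta[!eff_mask & upper.tri(delta)]
  expect_true(all(abs(on_eff + 0.2) < 0.03))
  expect_lt(max(abs(off_eff)), 0.03)
})

test_that("simulated tracker reproduces, lags and degrades with noise", {
  tr <- generate_track("moderate", 30, seed = 9)
  expect_identical(gen_tracker(tr, lag = 0, noise_sd = 0), tr$g)
  expect_equal(performance_r(gen_tracker(tr, 0, 0), tr$g), 1)

  # enormous noise drives the score to ~0 across seeds
  noisy <- mean(vapply(1:20, function(s)
    performance_r(gen_tracker(tr, 0, noise_sd = 1e4, seed = s), tr$g), 0))
  expect_lt(noisy, 0.1)

  # seed-averaged score is non-increasing over a noise grid
  sd_track <- sd(tr$g)
  grid <- sd_track * c(0, 0.5, 1, 2, 4, 8)
  means <- vapply(grid, function(nsd) {
    mean(vapply(1:15, function(s)
      performance_r(gen_tracker(tr, 0, nsd, seed = s), tr$g), 0))
  }, 0)
  expect_true(all(diff(means) <= 0))

  expect_error(gen_tracker(tr, lag = -1), "non-negative")
  expect_error(gen_tracker(tr, lag = 1e6), "exceeds track duration")
})
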