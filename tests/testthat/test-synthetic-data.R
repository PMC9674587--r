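test_that("a single-mode bank yields one unit-norm nonnegative vector", {
  bank <- make_ground_truth_bank(1, n_muscles = 8, seed = 1)
  expect_length(bank$mode_weights, 1)
  w <- bank$mode_weights[[1]]
  expect_true(all(w >= 0))
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-12)
})

test_that("bank modes are pairwise decorrelated below the ceiling", {
  for (s in c(7, 11, 23)) {
    bank <- make_ground_truth_bank(4, n_muscles = 8, seed = s)
    W <- do.call(cbind, bank$mode_weights)
    R <- cor(W)
    expect_true(all(R[upper.tri(R)] < 0.7))
    expect_true(all(W >= 0))
    expect_false(anyDuplicated(bank$burst_params$center) > 0)
  }
})

test_that("infeasible decorrelation requests error out", {
  expect_error(make_ground_truth_bank(20, n_muscles = 2, seed = 1))
})

test_that("trial synthesis is deterministic under a fixed seed", {
  bank <- make_ground_truth_bank(2, seed = 3)
  cfg <- cohort_config(n_subjects = 1, seed = 9)
  a <- synthesize_trial(bank, "early", 123, cfg)
  b <- synthesize_trial(bank, "early", 123, cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$events, b$events)
  c2 <- synthesize_trial(bank, "early", 124, cfg)
  expect_false(identical(a$signal, c2$signal))
})

test_that("noiseless single-mode trial demodulates to the planted envelope", {
  # rectifying the unit-variance Gaussian carrier scales the envelope by
  # E|N(0,1)| = sqrt(2/pi); shape must match the planted burst closely
  bank <- make_ground_truth_bank(1, seed = 5)
  cfg <- cohort_config(n_subjects = 1, noise_sd = 0, seed = 2)
  rec1 <- synthesize_trial(bank, "novel", 77, cfg)
  w <- bank$mode_weights[[1]]
  i0 <- rec1$events["LTD1"]; i1 <- rec1$events["LTD2"]
  tfrac <- (seq_len(ncol(rec1$signal)) - i0) / (i1 - i0)
  truth <- outer(w, exp(-0.5 * ((tfrac - bank$burst_params$center[1]) /
                                  bank$burst_params$width[1])^2))
  mid <- which.max(colSums(truth))
  win <- (mid - 30):(mid + 30)
  # average over carrier realizations: the per-trial envelope estimate is
  # itself noisy, the expectation is what the chain must reproduce
  envs <- lapply(1:8, function(s)
    condition_signal(synthesize_trial(bank, "novel", s, cfg)))
  env_mean <- Reduce(`+`, envs) / length(envs)
  ratio <- mean(env_mean[, win]) / mean(truth[, win])
  # the 35 Hz high-pass also removes that share of the white carrier's power
  expected <- sqrt(2 / pi) * sqrt(1 - 35 / 300)
  expect_lt(abs(ratio - expected), 0.1)
  expect_gt(cor(as.numeric(env_mean[, win]), as.numeric(truth[, win])), 0.95)
})

test_that("the pre-carrier envelope has the planted numerical rank", {
  recipes <- list(novel = list(recipe_mode(1), recipe_mode(2)))
  bank <- make_ground_truth_bank(2, seed = 8, stage_recipes = recipes)
  Mb <- true_binned_envelope(bank, "novel")
  sv <- svd(Mb)$d
  expect_gt(sv[2] / sv[1], 1e-6)           # genuinely rank 2
  expect_lt(sv[3] / sv[1], 1e-8)           # and no more
  expect_true(all(Mb >= 0))
})

test_that("cohort layout matches the protocol and jitter behaves", {
  bank <- make_ground_truth_bank(3, seed = 2)
  coh <- generate_cohort(bank, cohort_config(n_subjects = 3, seed = 4))
  expect_length(coh$recordings, 3 * (3 + 1 + 3 + 3))
  s1 <- cohort_trials(coh, "S01", "baseline")
  expect_length(s1, 3)
  expect_length(cohort_trials(coh, "S02", "novel"), 1)
  # jitter off -> identical weights across subjects
  coh0 <- generate_cohort(bank, cohort_config(n_subjects = 2,
                                              subject_jitter_sd = 0,
                                              seed = 4))
  expect_equal(coh0$truth$subjects$S01$weights,
               coh0$truth$subjects$S02$weights)
  # jitter on -> distinct but correlated
  w1 <- coh$truth$subjects$S01$weights[[1]]
  w2 <- coh$truth$subjects$S02$weights[[1]]
  expect_false(identical(w1, w2))
  expect_gt(cor(w1, w2), 0.8)
})

test_that("a fractionation recipe plants the intended stage structure", {
  recipes <- list(
    novel = list(recipe_merged(c(1, 4), c(0.6, 0.4)),
                 recipe_mode(2), recipe_mode(3)),
    early = list(recipe_mode(1), recipe_mode(2), recipe_mode(3),
                 recipe_mode(4)))
  bank <- make_ground_truth_bank(4, seed = 6, stage_recipes = recipes)
  novel <- emgsynergy:::resolve_stage(bank, "novel")
  early <- emgsynergy:::resolve_stage(bank, "early")
  expect_length(novel, 3)
  expect_length(early, 4)
  merged <- novel[[1]]$weights
  target <- 0.6 * bank$mode_weights[[1]] + 0.4 * bank$mode_weights[[4]]
  expect_equal(merged, target / sqrt(sum(target^2)), tolerance = 1e-12)
})

test_that("cohorts round-trip through the CSV/JSON dialect", {
  coh <- small_cohort(n_subjects = 1, n_modes = 2,
                      trials_per_stage = c(baseline = 3, novel = 1,
                                           early = 1, late = 1))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  rec <- coh$recordings[[1]]
  stem <- sprintf("%s_%s_t%02d", rec$subject_id, rec$stage_label,
                  rec$trial_index)
  back <- read_trial(file.path(dir, paste0(stem, ".csv")),
                     file.path(dir, paste0(stem, ".json")))
  expect_equal(back$signal, rec$signal, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(as.integer(back$events), as.integer(rec$events))
  expect_identical(back$stage_label, rec$stage_label)
})

test_that("recording invariants reject malformed event sequences", {
  sig <- matrix(rnorm(8 * 100), 8)
  expect_error(emg_recording(sig, 600,
                             c(LTD1 = 50, slip_onset = 20, LLO = 60,
                               LTD2 = 90), "S01", "novel"))
  expect_error(emg_recording(sig, 600,
                             c(LTD1 = 10, slip_onset = 20, LLO = 60,
                               LTD2 = 150), "S01", "novel"))
})
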