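test_that("an exactly rank-1 matrix factorizes to negligible error at k = 1", {
  set.seed(1)
  w <- abs(rnorm(8))
  c_t <- abs(rnorm(50))
  M <- outer(w, c_t)
  f <- run_nmf(M, 1, restarts = 5, seed = 2)
  expect_lt(f$sse, 1e-10 * sum(M^2))
  expect_equal(sqrt(colSums(f$W^2)), 1, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("run_nmf is deterministic given a seed and rejects bad input", {
  set.seed(2)
  M <- matrix(abs(rnorm(8 * 30)), 8)
  a <- run_nmf(M, 3, restarts = 4, seed = 7)
  b <- run_nmf(M, 3, restarts = 4, seed = 7)
  expect_identical(a$W, b$W)
  expect_identical(a$C, b$C)
  expect_error(run_nmf(matrix(c(NA, 1, 2, 3), 2), 1), "finite")
  expect_error(run_nmf(matrix(-1, 2, 2), 1), "nonnegative")
  expect_error(run_nmf(M, 9), "exceed")
})

test_that("best-of-restarts comes within 1% of a long-run restart oracle", {
  set.seed(5)
  M <- matrix(abs(rnorm(8 * 50)), 8)
  fast <- run_nmf(M, 3, restarts = 20, seed = 3)
  oracle <- run_nmf(M, 3, restarts = 1000, seed = 101)
  expect_lt(fast$sse, oracle$sse * 1.01)
})

test_that("VAF matches the brute-force oracle and hand-worked values", {
  set.seed(6)
  M <- matrix(abs(rnorm(8 * 20)), 8)
  f <- run_nmf(M, 3, restarts = 5, seed = 4)
  expect_equal(vaf_overall(M, f$W, f$C), vaf_oracle(M, f$W, f$C),
               tolerance = 1e-12)
  expect_equal(as.numeric(vaf_per_muscle(M, f$W, f$C)),
               vaf_per_muscle_oracle(M, f$W, f$C), tolerance = 1e-12)
  # perfect reconstruction and all-zero reconstruction
  W <- matrix(c(1, 2, 0, 1), 2)
  C <- matrix(abs(rnorm(8)), 2)
  P <- W %*% C
  expect_equal(vaf_overall(P, W, C), 1, tolerance = 1e-12)
  expect_equal(as.numeric(vaf_per_muscle(P, W, C)), c(1, 1),
               tolerance = 1e-12)
  expect_equal(vaf_overall(P, 0 * W, C), 0, tolerance = 1e-12)
  # hand-worked 2x4 case: M and a deliberately imperfect reconstruction
  M2 <- rbind(c(1, 2, 3, 4), c(2, 1, 2, 1))
  W2 <- rbind(1, 1)
  C2 <- matrix(c(1, 2, 2, 2), 1)
  # residuals: (0,0,1,2) and (1,-1,0,-1); ss_res = 5 + 3 = 8; ss_tot = 40
  expect_equal(vaf_overall(M2, W2, C2), 1 - 8 / 40, tolerance = 1e-12)
  expect_equal(as.numeric(vaf_per_muscle(M2, W2, C2)),
               c(1 - 5 / 30, 1 - 3 / 10), tolerance = 1e-12)
  expect_error(vaf_per_muscle(rbind(M2[1, ], 0), W2, C2), "zero energy")
})

test_that("VAF is non-decreasing in k under shared restarts", {
  set.seed(12)
  for (rep in 1:20) {
    M <- matrix(abs(rnorm(8 * 25)), 8)
    vafs <- sapply(1:3, function(k) {
      f <- run_nmf(M, k, restarts = 8, seed = 50 + rep)
      vaf_overall(M, f$W, f$C)
    })
    expect_true(all(diff(vafs) > -1e-6))
  }
})

test_that("dual-VAF selection recovers planted order on clean envelopes", {
  bank <- make_ground_truth_bank(4, seed = 1)
  Mb <- true_binned_envelope(bank, "novel")
  fit <- select_synergy_number(emg_matrix(Mb / apply(Mb, 1, sd)), seed = 3)
  expect_identical(fit$k, 4L)
  expect_true(fit$criteria_met)
  # rank oracle agrees
  expect_lt(svd(Mb)$d[5] / svd(Mb)$d[1], 1e-8)
})

test_that("degenerate selection cases behave per contract", {
  set.seed(3)
  M <- outer(abs(rnorm(8)), abs(rnorm(40)))
  f1 <- select_synergy_number(emg_matrix(M), restarts = 5, seed = 1)
  expect_identical(f1$k, 1L)
  f0 <- select_synergy_number(emg_matrix(M + abs(matrix(rnorm(320), 8))),
                              thresholds = c(per_muscle = 1e-9,
                                             overall = 1e-9),
                              restarts = 3, seed = 1)
  expect_identical(f0$k, 1L)
  # impossible thresholds -> k_max, flagged
  fx <- select_synergy_number(
    emg_matrix(M + abs(matrix(rnorm(320), 8))),
    thresholds = c(per_muscle = 0.999999, overall = 0.999999),
    k_max = 3, restarts = 3, seed = 1)
  expect_identical(fx$k, 3L)
  expect_false(fx$criteria_met)
})

test_that("selection is invariant to positive rescaling of the matrix", {
  bank <- make_ground_truth_bank(3, seed = 9)
  Mb <- true_binned_envelope(bank, "novel")
  m1 <- emg_matrix(Mb)
  m5 <- emg_matrix(5 * Mb)
  f1 <- select_synergy_number(m1, restarts = 10, seed = 21)
  f5 <- select_synergy_number(m5, restarts = 10, seed = 21)
  expect_identical(f1$k, f5$k)
  expect_equal(f1$W, f5$W, tolerance = 1e-6)
})

test_that("major contributors follow the 0.4 rule", {
  expect_identical(major_contributors(c(1, 0, 0, 0)), 1L)
  expect_identical(major_contributors(rep(1 / sqrt(8), 8)), integer(0))
  expect_identical(major_contributors(c(0.7, 0.7, 0, 0)), c(1L, 2L))
  W <- cbind(c(1, 0), c(0.3, 0.95))
  expect_identical(major_contributors(W), list(1L, 2L))
})

test_that("activation resampling interpolates onto the 100-point cycle", {
  const <- resample_activation(rep(3, 40), 40)
  expect_length(const$mean, 100)
  expect_true(all(abs(const$mean - 3) < 1e-12))
  ident <- resample_activation(seq(0, 1, length.out = 100), 100)
  expect_equal(ident$mean, seq(0, 1, length.out = 100), tolerance = 1e-12)
  # triangular peak location preserved within one grid point
  tri <- c(seq(0, 1, length.out = 21), seq(1, 0, length.out = 21)[-1])
  res <- resample_activation(tri, 41)
  expect_lt(abs(which.max(res$mean) - 51), 2)
  # multi-trial mean
  two <- resample_activation(c(rep(1, 10), rep(3, 10)), c(10, 20))
  expect_equal(two$mean, rep(2, 100), tolerance = 1e-12)
  expect_error(resample_activation(c(1), 1), "fewer than 2")
})

test_that("the fitted model exposes standard methods coherently", {
  coh <- small_cohort(n_subjects = 1)
  prep <- preprocess_stage(cohort_trials(coh, "S01", "early"),
                           cohort_trials(coh, "S01", "baseline"))
  fit <- select_synergy_number(prep$matrix, seed = 11,
                               norm_state = prep$state)
  expect_s3_class(fit, "synergy_fit")
  expect_identical(dim(coef(fit)), c(8L, fit$k))
  expect_equal(sqrt(colSums(coef(fit)^2)), rep(1, fit$k),
               tolerance = 1e-10, ignore_attr = TRUE)
  r <- residuals(fit)
  expect_identical(dim(r), dim(prep$matrix$values))
  expect_equal(fitted(fit) + r, prep$matrix$values, tolerance = 1e-12)
  # predicting the training data reproduces activations up to NNLS refit
  Chat <- predict(fit)
  expect_identical(dim(Chat), dim(fit$C))
  expect_true(all(Chat >= 0))
  Wraw <- synergy_weights(fit, "raw")
  expect_equal(sqrt(colSums(Wraw^2)), rep(1, fit$k), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_output(print(fit), "synergy_fit")
  expect_output(print(summary(fit)), "Major contributors")
})
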