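test_that("NNLS reconstruction solves the textbook cases", {
  set.seed(2)
  B <- apply(matrix(abs(rnorm(8 * 4)), 8), 2, emgsynergy:::unit_norm)
  # target equal to a basis column
  r <- nnls_reconstruct(B[, 3], B)
  expect_equal(r$coefficients[3], 1, tolerance = 1e-8)
  expect_lt(max(abs(r$coefficients[-3])), 1e-8)
  expect_equal(r$reconstruction_r, 1, tolerance = 1e-10)
  # orthogonal-support mixture with known coefficients
  w1 <- emgsynergy:::unit_norm(c(1, 2, 0, 0, 0, 0, 0, 0))
  w2 <- emgsynergy:::unit_norm(c(0, 0, 0, 3, 1, 0, 0, 0))
  target <- 0.6 * w1 + 0.4 * w2
  r2 <- nnls_reconstruct(target, cbind(w1, w2))
  expect_equal(r2$coefficients, c(0.6, 0.4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r2$reconstruction_r, 1, tolerance = 1e-10)
  # target orthogonal to the whole basis -> all coefficients zero
  r3 <- nnls_reconstruct(c(0, 0, 1, 0), diag(4)[, c(1, 2)])
  expect_equal(r3$coefficients, c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(nnls_reconstruct(w1, matrix(0, 8, 2)), "all-zero")
  expect_error(nnls_reconstruct(-w1, cbind(w1)), "nonnegative")
})

test_that("NNLS agrees with exhaustive active-set enumeration and KKT", {
  set.seed(6)
  for (i in 1:25) {
    A <- matrix(abs(rnorm(8 * 4)) * rbinom(32, 1, 0.7), 8)
    if (all(A == 0)) next
    b <- abs(rnorm(8))
    r <- nnls_reconstruct(b, A)
    o <- nnls_oracle(A, b)
    expect_equal(sum(r$residual^2), o$rss, tolerance = 1e-8)
    expect_equal(r$coefficients, o$x, tolerance = 1e-6, ignore_attr = TRUE)
    # KKT: residual orthogonal to active columns; gradient >= 0 elsewhere
    g <- -crossprod(A, r$residual)
    act <- r$coefficients > 1e-10
    if (any(act)) expect_lt(max(abs(g[act])), 1e-8)
    if (any(!act)) expect_gt(min(g[!act]), -1e-8)
  }
})

test_that("coefficients scale with the target and verdicts are unchanged", {
  set.seed(9)
  B <- apply(matrix(abs(rnorm(8 * 3)), 8), 2, emgsynergy:::unit_norm)
  t1 <- 0.5 * B[, 1] + 0.5 * B[, 2]
  r1 <- nnls_reconstruct(t1, B)
  r5 <- nnls_reconstruct(5 * t1, B)
  expect_equal(r5$coefficients, 5 * r1$coefficients, tolerance = 1e-8)
  expect_equal(r5$reconstruction_r, r1$reconstruction_r, tolerance = 1e-10)
  expect_identical(emgsynergy:::active_set(r1$coefficients),
                   emgsynergy:::active_set(r5$coefficients))
})

planted_merge_clusterings <- function(seed = 4, n_subjects = 8) {
  recipes <- list(
    novel = list(recipe_merged(c(1, 4), c(0.6, 0.4)),
                 recipe_mode(2), recipe_mode(3)),
    early = lapply(1:4, recipe_mode))
  bank <- make_ground_truth_bank(4, seed = seed, stage_recipes = recipes)
  list(bank = bank,
       novel = cluster_stage(weight_level_pool(bank, n_subjects, "novel",
                                               jitter_sd = 0.05, seed = 31)),
       early = cluster_stage(weight_level_pool(bank, n_subjects, "early",
                                               jitter_sd = 0.05, seed = 32)))
}

test_that("a planted merged synergy is detected with the right active set", {
  pm <- planted_merge_clusterings()
  res <- detect_merging(pm$novel, pm$early)
  merged <- res$table[res$table$verdict == "merged", ]
  expect_identical(nrow(merged), 1L)
  expect_gt(merged$reconstruction_r, 0.99)
  # the active basis clusters correspond to true modes 1 and 4
  act <- as.integer(strsplit(merged$active_basis, "\\+")[[1]])
  expect_length(act, 2)
  Wb <- emgsynergy:::cluster_weight_matrix(pm$early)
  truth <- do.call(cbind, pm$bank$mode_weights)
  matched_true <- apply(cor(Wb[, act], truth), 1, which.max)
  expect_setequal(matched_true, c(1, 4))
})

test_that("identical stages produce no merge or fractionation verdicts", {
  bank <- make_ground_truth_bank(4, seed = 13)
  cl <- cluster_stage(weight_level_pool(bank, 6, jitter_sd = 0.05, seed = 3))
  res <- detect_merging(cl, cl)
  expect_identical(nrow(res$table), 0L)   # every cluster matches one-to-one
})

test_that("unrelated random targets are mostly rejected", {
  bank <- make_ground_truth_bank(4, seed = 19)
  B <- do.call(cbind, bank$mode_weights)
  thr <- critical_r(6, 0.01)
  rejected <- 0L
  n <- 60L
  for (i in seq_len(n)) {
    tgt <- make_ground_truth_bank(1, seed = 700 + i)$mode_weights[[1]]
    r <- nnls_reconstruct(tgt, B)
    act <- emgsynergy:::active_set(r$coefficients)
    merged <- r$reconstruction_r > thr && length(act) >= 2 &&
      max(abs(cor(tgt, B))) <= thr   # a 1-to-1 match is not a merge either
    if (!merged) rejected <- rejected + 1L
  }
  expect_gt(rejected / n, 0.8)
})

test_that("weight modification is flagged with the changed muscle", {
  w <- emgsynergy:::unit_norm(c(0.8, 0.4, 0.3, 0.2, 0.1, 0.1, 0.1, 0.1))
  w_mod <- emgsynergy:::unit_norm(c(0.1, 0.4, 0.3, 0.2, 0.1, 0.1, 0.1, 0.1))
  act <- exp(-0.5 * ((seq(0, 1, length.out = 100) - 0.4) / 0.1)^2)
  mk <- function(W, A, stage) structure(lapply(seq_len(ncol(W)), function(j)
    list(cluster_id = j, members = data.frame(subject_id = "S01",
                                              synergy_index = j),
         mean_weights = W[, j], mean_activation = A[, j], n_subjects = 1L)),
    class = "mode_clustering", stage_label = stage)
  ca <- mk(cbind(w), cbind(act), "novel")
  cb <- mk(cbind(w_mod), cbind(act), "early")
  res <- detect_modification(ca, cb)
  expect_identical(nrow(res$table), 1L)
  expect_match(res$table$modified_muscles, "1")
  expect_gt(res$table$activation_r, 0.3)
  expect_lte(res$table$structure_r, critical_r(6, 0.01))
  # identical pair: structurally matched, not a candidate
  expect_identical(nrow(detect_modification(ca, ca)$table), 0L)
  # same structure, shifted activation: no candidate either
  act2 <- exp(-0.5 * ((seq(0, 1, length.out = 100) - 0.8) / 0.05)^2)
  cc <- mk(cbind(w), cbind(act2), "early")
  expect_identical(nrow(detect_modification(ca, cc)$table), 0L)
})
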