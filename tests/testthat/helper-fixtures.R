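# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no data files.

# The true (pre-carrier) envelope a bank emits for one stage, binned the same
# way the preprocessing would bin it: an oracle for rank/recovery checks.
true_binned_envelope <- function(bank, stage_label, n_samples = 900,
                                 bin_samples = 18) {
  modes <- emgsynergy:::resolve_stage(bank, stage_label)
  tfrac <- seq(0, 1, length.out = n_samples)
  W <- do.call(cbind, lapply(modes, `[[`, "weights"))
  C <- do.call(rbind, lapply(modes, function(m)
    m$amplitude * exp(-0.5 * ((tfrac - m$center) / m$width)^2)))
  M <- W %*% C
  starts <- seq(1, ncol(M) - bin_samples + 1, by = bin_samples)
  sapply(starts, function(j) rowMeans(M[, j:(j + bin_samples - 1)]))
}

# A synergy pool built directly from per-subject jittered bank weights (no
# EMG synthesis), for clustering/similarity/crossval tests that target the
# grouping logic itself.
weight_level_pool <- function(bank, n_subjects, stage_label = "novel",
                              jitter_sd = 0.1, seed = 1) {
  synthetic_synergy_pool(bank, n_subjects, stage_label, jitter_sd, seed)
}

# Minimal stand-ins for synergy fits where only k/subject/stage matter.
fake_fit <- function(subject_id, k, stage_label = "novel") {
  structure(list(k = k, subject_id = subject_id, stage_label = stage_label),
            class = "synergy_fit")
}

# One small end-to-end cohort reused by slower tests.
small_cohort <- function(n_subjects = 2, n_modes = 3, seed = 42, ...) {
  bank <- make_ground_truth_bank(n_modes, seed = seed)
  generate_cohort(bank, cohort_config(n_subjects = n_subjects,
                                      seed = seed + 1, ...))
}
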