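#' Subject-subsampling cross-validation of mode clusters
#'
#' Repeatedly removes \code{n_remove} subjects uniformly at random (without
#' replacement, a fresh independent draw per repetition), re-clusters each
#' stage's remaining pooled synergies under the subject-uniqueness rule, and
#' compares the subsample cluster means to the full-data cluster means by
#' greedy one-to-one best-match correlation. Stability of both the cluster
#' counts and the cluster structures across repetitions indicates robust
#' modes.
#'
#' @param stage_pools named list (stage -> \code{synergy_pool}) built from
#'   the full cohort.
#' @param n_remove subjects removed per repetition (0 <= n_remove <
#'   n_subjects).
#' @param reps repetitions (default 300).
#' @param seed master seed; per-repetition seeds derive from it.
#' @param recovery_r correlation level at which a full-data cluster counts as
#'   recovered (default 0.9).
#' @param linkage_method,distance passed to \code{\link{cluster_stage}}.
#' @return a \code{crossval_report}: per-rep data frame (\code{rep},
#'   \code{stage}, \code{n_clusters}, \code{mean_match_r},
#'   \code{frac_recovered}), per-stage summary (mean and sd of cluster
#'   counts, mean match r, mean fraction of full-data clusters recovered at
#'   \code{recovery_r}), and the settings.
#' @export
subsample_and_cluster <- function(stage_pools, n_remove, reps = 300L,
                                  seed = 1L, recovery_r = 0.9,
                                  linkage_method = "average",
                                  distance = "correlation") {
  stopifnot_scalar_count(reps, "reps", 1L)
  if (!is.numeric(n_remove) || n_remove < 0) stop("'n_remove' must be >= 0")
  subjects <- sort(unique(unlist(lapply(stage_pools, function(p)
    vapply(p, `[[`, "", "subject_id")))))
  if (n_remove >= length(subjects))
    stop(sprintf("cannot remove %d of %d subjects", n_remove,
                 length(subjects)))
  full <- lapply(stage_pools, cluster_stage, linkage_method = linkage_method,
                 distance = distance)
  rows <- list()
  for (r in seq_len(reps)) {
    keep <- with_seed(child_seed(seed, r), {
      if (n_remove == 0) subjects
      else setdiff(subjects, sample(subjects, n_remove))
    })
    for (st in names(stage_pools)) {
      sub <- Filter(function(it) it$subject_id %in% keep, stage_pools[[st]])
      sub <- structure(sub, class = "synergy_pool",
                       stage_label = attr(stage_pools[[st]], "stage_label"))
      cl <- cluster_stage(sub, linkage_method = linkage_method,
                          distance = distance)
      Wf <- cluster_weight_matrix(full[[st]])
      Ws <- cluster_weight_matrix(cl)
      mr <- match_pairs(cor(Wf, Ws), -1, "greedy")   # best match, no floor
      match_r <- vapply(seq_len(ncol(Wf)), function(i) {
        if (is.na(mr[i])) NA_real_ else cor(Wf[, i], Ws[, mr[i]])
      }, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, stage = st, n_clusters = length(cl),
        mean_match_r = mean(match_r, na.rm = TRUE),
        frac_recovered = mean(!is.na(match_r) & match_r >= recovery_r))
    }
  }
  per_rep <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(stage_pools), function(st) {
    d <- per_rep[per_rep$stage == st, ]
    data.frame(stage = st,
               full_n_clusters = length(full[[st]]),
               mean_n_clusters = mean(d$n_clusters),
               sd_n_clusters = sd(d$n_clusters),
               mean_match_r = mean(d$mean_match_r),
               mean_frac_recovered = mean(d$frac_recovered))
  }))
  structure(list(per_rep = per_rep, summary = summary, reps = reps,
                 n_remove = n_remove, recovery_r = recovery_r, seed = seed),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %d reps, %d subject(s) removed per rep\n",
              x$reps, x$n_remove))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf(
      "  %s: %.1f +/- %.1f clusters (full data %d); match r %.3f; %.0f%% recovered at r >= %.2f\n",
      x$summary$stage[i], x$summary$mean_n_clusters[i],
      x$summary$sd_n_clusters[i], x$summary$full_n_clusters[i],
      x$summary$mean_match_r[i], 100 * x$summary$mean_frac_recovered[i],
      x$recovery_r))
  invisible(x)
}
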