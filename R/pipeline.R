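#' Assemble a validated pipeline configuration
#'
#' Collects every stage's settings into one validated object. A pipeline
#' either simulates a cohort (\code{simulate} settings) or reads one from the
#' on-disk dialect of \code{\link{write_cohort}} (\code{input_dir}). When
#' trial-to-stage definitions are supplied for a read cohort they must not
#' overlap.
#'
#' @param simulate list of generator settings (\code{n_modes},
#'   \code{n_subjects}, optional \code{stage_recipes}, \code{noise_sd},
#'   \code{subject_jitter_sd}, \code{trials_per_stage}); \code{NULL} when
#'   reading from \code{input_dir}.
#' @param input_dir directory holding a written cohort (ignored when
#'   \code{simulate} is given).
#' @param stages optional named list mapping stage labels to trial indices
#'   for a read cohort; stages must be disjoint.
#' @param preprocessing list: \code{bin_ms}, \code{highpass_hz},
#'   \code{lowpass_hz}.
#' @param extraction list: \code{thresholds}, \code{k_max}, \code{restarts},
#'   \code{tol}, \code{max_iter}.
#' @param clustering list: \code{linkage_method}, \code{distance}.
#' @param similarity list: \code{alpha}, \code{activation_threshold}.
#' @param merge list: \code{floor_frac}, \code{delta_cutoff}.
#' @param crossval list: \code{n_remove}, \code{reps}, \code{recovery_r};
#'   \code{NULL} skips cross-validation.
#' @param seed master seed for every random stage.
#' @param out_dir output directory (\code{NULL}: no files written).
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL, stages = NULL,
                            preprocessing = list(), extraction = list(),
                            clustering = list(), similarity = list(),
                            merge = list(), crossval = NULL,
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either 'simulate' settings or an 'input_dir' is required")
  if (!is.null(input_dir) && is.null(simulate) && !dir.exists(input_dir))
    stop(sprintf("input_dir '%s' does not exist", input_dir))
  defaults <- list(
    preprocessing = list(bin_ms = 30, highpass_hz = 35, lowpass_hz = 40),
    extraction = list(thresholds = c(per_muscle = 0.75, overall = 0.90),
                      k_max = NULL, restarts = 20L, tol = 1e-6,
                      max_iter = 1000L),
    clustering = list(linkage_method = "average", distance = "correlation"),
    similarity = list(alpha = 0.01, activation_threshold = 0.3),
    merge = list(floor_frac = 0.2, delta_cutoff = 0.2))
  cfg <- list(simulate = simulate, input_dir = input_dir, stages = stages,
              preprocessing = utils::modifyList(defaults$preprocessing,
                                                preprocessing),
              extraction = utils::modifyList(defaults$extraction, extraction),
              clustering = utils::modifyList(defaults$clustering, clustering),
              similarity = utils::modifyList(defaults$similarity, similarity),
              merge = utils::modifyList(defaults$merge, merge),
              crossval = crossval, seed = as.integer(seed), out_dir = out_dir)
  th <- cfg$extraction$thresholds
  if (any(th <= 0 | th >= 1))
    stop("extraction thresholds must lie strictly in (0, 1)")
  if (cfg$similarity$alpha <= 0 || cfg$similarity$alpha >= 1)
    stop("similarity alpha must lie strictly in (0, 1)")
  if (!is.null(stages)) {
    all_idx <- unlist(stages)
    if (anyDuplicated(all_idx))
      stop("stage definitions overlap: a trial may belong to one stage only")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with top-level keys matching
#'   \code{\link{pipeline_config}} arguments.
#' @return a validated \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$extraction$thresholds))
    raw$extraction$thresholds <- unlist(raw$extraction$thresholds)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  stripped <- unclass(config)
  stripped$out_dir <- NULL
  jsonlite::write_json(stripped, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full synergy-adaptation analysis
#'
#' Executes, in order: cohort simulation (or loading), EMG conditioning and
#' binning, per-subject per-stage synergy extraction with dual-VAF order
#' selection, cross-subject clustering per stage, cross-stage mode matching,
#' merging/fractionation and weight-modification screening, and (optionally)
#' subject-subsampling cross-validation. Every random stage is seeded from
#' the config's master seed, so a rerun of the same config reproduces the
#' summary byte for byte. When \code{out_dir} is set, all module outputs are
#' written as CSV/JSON, each declaring the MD5 hash of the config that
#' produced it.
#'
#' @param config a \code{pipeline_config} or path to a YAML config.
#' @return a \code{synergy_pipeline}: the cohort, per-stage fits, clusterings,
#'   synergy-count comparison, mode registry, merge/fractionation and
#'   modification results, cross-validation report, and a plain-list
#'   \code{summary}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config or a YAML path")
  hash <- config_hash(config)
  stage_wrap <- function(stage_name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage_name,
                   conditionMessage(e)), call. = FALSE))
  }

  cohort <- stage_wrap("simulate", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      bank <- make_ground_truth_bank(
        n_modes = sim$n_modes %||% 4L,
        n_muscles = sim$n_muscles %||% 8L,
        seed = child_seed(config$seed, 11L),
        stage_recipes = sim$stage_recipes)
      cc <- cohort_config(
        n_subjects = sim$n_subjects,
        n_muscles = sim$n_muscles %||% 8L,
        trials_per_stage = sim$trials_per_stage %||%
          c(baseline = 3L, novel = 1L, early = 3L, late = 3L),
        sampling_rate = sim$sampling_rate %||% 600,
        gait_cycle_duration = sim$gait_cycle_duration %||% 1.5,
        subject_jitter_sd = sim$subject_jitter_sd %||% 0.1,
        noise_sd = sim$noise_sd %||% 0.05,
        seed = child_seed(config$seed, 12L))
      generate_cohort(bank, cc)
    } else {
      read_cohort(config$input_dir)
    }
  })

  stages <- setdiff(unique(vapply(cohort$recordings, `[[`, "", "stage_label")),
                    "baseline")
  subjects <- unique(vapply(cohort$recordings, `[[`, "", "subject_id"))

  fits_by_stage <- stage_wrap("extract", {
    pp <- config$preprocessing
    ex <- config$extraction
    out <- lapply(stats::setNames(nm = stages), function(st) {
      lapply(seq_along(subjects), function(si) {
        sid <- subjects[si]
        prep <- preprocess_stage(
          cohort_trials(cohort, sid, st),
          cohort_trials(cohort, sid, "baseline"),
          bin_ms = pp$bin_ms, highpass_hz = pp$highpass_hz,
          lowpass_hz = pp$lowpass_hz)
        select_synergy_number(
          prep$matrix, thresholds = ex$thresholds, k_max = ex$k_max,
          restarts = ex$restarts,
          seed = child_seed(config$seed, 100L + si),
          tol = ex$tol, max_iter = ex$max_iter, norm_state = prep$state)
      })
    })
    out
  })

  clusterings <- stage_wrap("cluster", {
    lapply(stats::setNames(nm = stages), function(st) {
      cluster_stage(pool_synergies(fits_by_stage[[st]]),
                    linkage_method = config$clustering$linkage_method,
                    distance = config$clustering$distance)
    })
  })

  counts <- stage_wrap("counts", count_synergy_numbers(fits_by_stage))

  n_muscles <- nrow(cluster_weight_matrix(clusterings[[1L]]))
  sthr <- critical_r(n_muscles - 2L, config$similarity$alpha)
  registry <- stage_wrap("similarity", {
    build_mode_registry(clusterings, structure_threshold = sthr,
                        activation_threshold =
                          config$similarity$activation_threshold)
  })

  merge_results <- stage_wrap("merge_fractionation", {
    res <- list()
    if (length(stages) > 1L) {
      for (a in stages) for (b in setdiff(stages, a)) {
        res[[paste(a, "from", b, sep = "_")]] <-
          detect_merging(clusterings[[a]], clusterings[[b]],
                         structure_threshold = sthr,
                         floor_frac = config$merge$floor_frac)
      }
    }
    res
  })
  modification_results <- stage_wrap("modification", {
    res <- list()
    if (length(stages) > 1L) {
      cmb <- utils::combn(stages, 2L)
      for (i in seq_len(ncol(cmb))) {
        res[[paste(cmb[1L, i], cmb[2L, i], sep = "_vs_")]] <-
          detect_modification(
            clusterings[[cmb[1L, i]]], clusterings[[cmb[2L, i]]],
            activation_threshold = config$similarity$activation_threshold,
            structure_threshold = sthr,
            delta_cutoff = config$merge$delta_cutoff)
      }
    }
    res
  })

  crossval <- NULL
  if (!is.null(config$crossval)) {
    crossval <- stage_wrap("crossval", {
      pools <- lapply(stats::setNames(nm = stages), function(st)
        pool_synergies(fits_by_stage[[st]]))
      subsample_and_cluster(
        pools, n_remove = config$crossval$n_remove %||% 5L,
        reps = config$crossval$reps %||% 300L,
        seed = child_seed(config$seed, 999L),
        recovery_r = config$crossval$recovery_r %||% 0.9,
        linkage_method = config$clustering$linkage_method,
        distance = config$clustering$distance)
    })
  }

  summary <- list(
    config_hash = hash,
    n_subjects = length(subjects),
    stages = as.list(stats::setNames(nm = stages)),
    synergy_counts = list(
      per_stage = lapply(seq_len(nrow(counts$summary)), function(i)
        list(stage = counts$summary$stage[i],
             mean = counts$summary$mean[i], sd = counts$summary$sd[i])),
      comparisons = if (is.null(counts$comparisons)) NULL else
        lapply(seq_len(nrow(counts$comparisons)), function(i)
          as.list(counts$comparisons[i, ]))),
    mode_counts = lapply(stats::setNames(nm = stages), function(st)
      length(clusterings[[st]])),
    n_modes_total = nrow(registry$registry),
    n_common_modes = sum(registry$registry$n_stages > 1L),
    n_unique_modes = sum(registry$registry$n_stages == 1L),
    merge_verdicts = lapply(merge_results, function(m)
      as.list(table(m$table$verdict))),
    n_modification_candidates = sum(vapply(modification_results,
                                           function(m) nrow(m$table), 0L)),
    crossval = if (is.null(crossval)) NULL else
      lapply(seq_len(nrow(crossval$summary)), function(i)
        as.list(crossval$summary[i, ])),
    structure_threshold = sthr,
    activation_threshold = config$similarity$activation_threshold)

  result <- structure(
    list(config = config, config_hash = hash, cohort = cohort,
         fits_by_stage = fits_by_stage, clusterings = clusterings,
         counts = counts, registry = registry,
         merge_results = merge_results,
         modification_results = modification_results,
         crossval = crossval, summary = summary),
    class = "synergy_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result)
  result
}

#' @export
print.synergy_pipeline <- function(x, ...) {
  cat("<synergy_pipeline>\n")
  print(x$counts)
  cat(sprintf("  modes: %d total (%d common, %d unique)\n",
              x$summary$n_modes_total, x$summary$n_common_modes,
              x$summary$n_unique_modes))
  if (!is.null(x$crossval)) print(x$crossval)
  invisible(x)
}

#' Read a cohort previously written with \code{\link{write_cohort}}
#' @param dir cohort directory containing \code{manifest.csv}.
#' @return an \code{emg_cohort} (truth sidecar attached when present).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(seq_len(nrow(manifest)), function(i)
    read_trial(file.path(dir, manifest$csv[i]),
               file.path(dir, manifest$sidecar[i])))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(recordings = recs, truth = truth, config = NULL),
            class = "emg_cohort")
}

# CSV with a leading provenance comment naming the config hash; read back
# with comment.char = "#".
write_hashed_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  write.csv(df, con, row.names = FALSE)
}

write_pipeline_outputs <- function(result) {
  dir.create(result$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- result$config$out_dir
  hash <- result$config_hash
  clusters <- do.call(rbind, lapply(names(result$clusterings), function(st) {
    do.call(rbind, lapply(result$clusterings[[st]], function(cl)
      data.frame(stage = st, cluster_id = cl$cluster_id, cl$members)))
  }))
  write_hashed_csv(clusters, file.path(out, "clusters.csv"), hash)
  means <- do.call(rbind, lapply(names(result$clusterings), function(st) {
    W <- cluster_weight_matrix(result$clusterings[[st]])
    data.frame(stage = st, cluster_id = seq_len(ncol(W)), t(W))
  }))
  write_hashed_csv(means, file.path(out, "cluster_means.csv"), hash)
  acts <- do.call(rbind, lapply(names(result$clusterings), function(st) {
    A <- cluster_activation_matrix(result$clusterings[[st]])
    data.frame(stage = st, cluster_id = seq_len(ncol(A)), t(A))
  }))
  write_hashed_csv(acts, file.path(out, "cluster_activations.csv"), hash)
  write_hashed_csv(result$registry$registry,
                   file.path(out, "mode_registry.csv"), hash)
  mf <- do.call(rbind, lapply(names(result$merge_results), function(nm) {
    t <- result$merge_results[[nm]]$table
    if (nrow(t)) cbind(comparison = nm, t) else NULL
  }))
  if (!is.null(mf))
    write_hashed_csv(mf, file.path(out, "merge_fractionation.csv"), hash)
  if (!is.null(result$crossval)) {
    write_hashed_csv(result$crossval$per_rep,
                     file.path(out, "crossval_per_rep.csv"), hash)
    jsonlite::write_json(
      c(list(config_hash = hash),
        result$crossval[c("summary", "reps", "n_remove", "recovery_r")]),
      file.path(out, "crossval_report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  jsonlite::write_json(result$summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
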