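#' Construct a ground-truth synergy bank
#'
#' Draws \code{n_modes} nonnegative, unit-norm muscle-weight vectors together
#' with burst-timing parameters, to serve as the generative truth behind a
#' synthetic EMG cohort. Each mode dominates its own signature muscle over a
#' sparse background — the modular weight structure of real motor modules,
#' where a dorsiflexor-, plantarflexor- or knee-extensor-dominant module each
#' has a muscle it chiefly drives — which makes the planted mode count
#' identifiable: a reconstruction lacking one mode starves that mode's
#' signature muscle. Weight vectors are additionally resampled until all
#' pairwise Pearson correlations fall below \code{max_r}, so the planted
#' modes are structurally distinct. Burst centers are spread across the gait
#' cycle (with slight jitter) and are always distinct. Requires
#' \code{n_modes <= n_muscles}.
#'
#' @param n_modes number of true synergy modes (>= 1).
#' @param n_muscles number of muscles (>= 2; default 8).
#' @param seed integer RNG seed; the bank is a deterministic function of it.
#' @param stage_recipes named list (one element per stage label) of recipe
#'   lists describing which modes a stage emits and how; see
#'   \code{\link{recipe_mode}}. Defaults to all modes, as-is, in the three
#'   standard stages \code{"novel"}, \code{"early"}, \code{"late"}.
#' @param max_r pairwise correlation ceiling between mode weight vectors.
#' @param max_attempts resampling budget before giving up.
#' @return an object of class \code{ground_truth_bank}: mode weight vectors
#'   (unit Euclidean norm, all entries >= 0), per-mode burst parameters
#'   (\code{center}, \code{width} as fractions of the gait cycle,
#'   \code{amplitude} in arbitrary envelope units) and the stage recipes.
#' @examples
#' bank <- make_ground_truth_bank(4, seed = 7)
#' sapply(bank$mode_weights, function(w) sqrt(sum(w^2)))
#' @export
make_ground_truth_bank <- function(n_modes, n_muscles = 8L, seed = 1L,
                                   stage_recipes = NULL, max_r = 0.7,
                                   max_attempts = 500L) {
  stopifnot_scalar_count(n_modes, "n_modes", 1L)
  stopifnot_scalar_count(n_muscles, "n_muscles", 2L)
  if (n_modes > n_muscles)
    stop(sprintf(
      "cannot plant %d identifiable modes on %d muscles (each mode needs its own signature muscle)",
      n_modes, n_muscles))
  weights <- with_seed(seed, {
    ws <- vector("list", n_modes)
    attempts <- 0L
    repeat {
      # Each mode gets a distinct signature muscle it dominates, over a
      # sparse gamma background: the modular structure of real synergy
      # vectors (1-3 dominant muscles, the rest near zero but positive).
      # The signature makes the planted mode count identifiable: dropping a
      # mode from a reconstruction starves its signature muscle.
      sig <- sample(n_muscles, n_modes)
      ok <- TRUE
      for (i in seq_len(n_modes)) {
        w <- rgamma(n_muscles, shape = 0.5, rate = 1) + 1e-3
        w[sig] <- w[sig] * 0.2                 # suppress other signatures
        w[sig[i]] <- max(w) * runif(1, 1.5, 2.5)
        ws[[i]] <- unit_norm(w)
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            if (cor(ws[[i]], ws[[j]]) >= max_r) { ok <- FALSE; break }
          }
        }
        if (!ok) break
      }
      if (ok) break
      attempts <- attempts + 1L
      if (attempts >= max_attempts)
        stop(sprintf(
          "could not draw %d weight vectors with pairwise r < %.2f in %d muscles after %d attempts",
          n_modes, max_r, n_muscles, max_attempts))
    }
    ws
  })
  # Burst centers evenly spread, jittered, strictly increasing -> distinct.
  centers <- with_seed(child_seed(seed, 1L), {
    base <- seq(0.12, 0.88, length.out = n_modes)
    jit <- if (n_modes > 1L) min(0.02, diff(base)[1] / 4) else 0.02
    base + runif(n_modes, -jit, jit)
  })
  burst <- data.frame(center = centers,
                      width = rep(0.10, n_modes),
                      amplitude = rep(1.0, n_modes))
  if (is.null(stage_recipes)) {
    all_modes <- lapply(seq_len(n_modes), recipe_mode)
    stage_recipes <- stats::setNames(
      rep(list(all_modes), length(DEFAULT_STAGES)), DEFAULT_STAGES)
  }
  bank <- structure(list(mode_weights = weights, burst_params = burst,
                         stage_recipes = stage_recipes,
                         n_muscles = as.integer(n_muscles),
                         n_modes = as.integer(n_modes), seed = as.integer(seed)),
                    class = "ground_truth_bank")
  validate_bank(bank)
  bank
}

validate_bank <- function(bank) {
  for (w in bank$mode_weights) {
    if (any(w < 0)) stop("bank weights must be nonnegative")
    if (abs(sqrt(sum(w^2)) - 1) > 1e-8) stop("bank weights must be unit norm")
  }
  if (any(bank$burst_params$center < 0 | bank$burst_params$center > 1))
    stop("burst centers must lie in [0, 1]")
  if (anyDuplicated(bank$burst_params$center))
    stop("burst centers must be distinct")
  invisible(bank)
}

#' Stage-recipe entries
#'
#' A stage recipe is a list of entries, each describing one synergy the stage
#' emits: a bank mode used as-is, a merged mode (nonnegative combination of
#' two or more bank modes, recruited by a single burst), or a modified mode
#' (per-muscle weight deltas applied to a bank mode, then clipped at zero and
#' renormalized). Merging/fractionation and weight modification planted this
#' way mirror the mechanisms a training study looks for between stages.
#'
#' @param mode bank mode index.
#' @param modes two or more bank mode indices being merged.
#' @param mix positive mixing weights, one per merged mode.
#' @param delta numeric vector of per-muscle weight changes (length
#'   \code{n_muscles}).
#' @return a recipe entry (a tagged list) for use in \code{stage_recipes}.
#' @export
recipe_mode <- function(mode) {
  list(type = "as_is", modes = as.integer(mode))
}

#' @rdname recipe_mode
#' @export
recipe_merged <- function(modes, mix) {
  if (length(modes) < 2L) stop("a merged mode needs >= 2 source modes")
  if (length(mix) != length(modes) || any(mix <= 0))
    stop("'mix' must be positive and match 'modes' in length")
  list(type = "merged", modes = as.integer(modes), mix = as.numeric(mix))
}

#' @rdname recipe_mode
#' @export
recipe_modified <- function(mode, delta) {
  list(type = "modified", modes = as.integer(mode), delta = as.numeric(delta))
}

# Resolve a stage recipe against (possibly jittered) mode weights into the
# emitted modes: weight vector + burst parameters + a human-readable label.
resolve_stage <- function(bank, stage_label) {
  recipe <- bank$stage_recipes[[stage_label]]
  if (is.null(recipe))
    stop(sprintf("stage '%s' is not present in the bank's stage_recipes",
                 stage_label))
  lapply(recipe, function(entry) {
    idx <- entry$modes
    bp <- bank$burst_params[idx[1L], ]
    w <- switch(entry$type,
      as_is = bank$mode_weights[[idx]],
      merged = {
        m <- Reduce(`+`, Map(function(i, a) a * bank$mode_weights[[i]],
                             idx, entry$mix))
        unit_norm(m)
      },
      modified = {
        if (length(entry$delta) != bank$n_muscles)
          stop("'delta' length must equal n_muscles")
        unit_norm(pmax(bank$mode_weights[[idx]] + entry$delta, 0))
      },
      stop(sprintf("unknown recipe type '%s'", entry$type)))
    label <- switch(entry$type,
      as_is = sprintf("mode%d", idx),
      merged = sprintf("merge_%s", paste(idx, collapse = "_")),
      modified = sprintf("mod%d", idx))
    list(weights = w, center = bp$center, width = bp$width,
         amplitude = bp$amplitude, label = label, type = entry$type,
         source_modes = idx)
  })
}

# Multiplicative log-normal jitter on the bank's base weight vectors,
# renormalized, so nonnegativity and unit norm are preserved. Applied once per
# subject; recipes then resolve against the jittered bases.
jitter_bank <- function(bank, sd, seed) {
  if (sd < 0) stop("'sd' must be >= 0")
  if (sd == 0) return(bank)
  bank$mode_weights <- with_seed(seed, lapply(bank$mode_weights, function(w) {
    unit_norm(w * exp(rnorm(length(w), 0, sd)))
  }))
  bank
}

#' Cohort generation settings
#'
#' Bundles the experiment-scale parameters of a synthetic cohort. Defaults
#' follow a slip-perturbation protocol: one novel trial, three early- and
#' three late-adaptation trials, with at least three unperturbed baseline
#' trials used only for normalization.
#'
#' @param n_subjects number of subjects.
#' @param n_muscles number of muscles (default 8).
#' @param trials_per_stage named counts for \code{baseline}, \code{novel},
#'   \code{early}, \code{late}.
#' @param sampling_rate EMG sampling rate in Hz (default 600).
#' @param gait_cycle_duration seconds from first to last touchdown (default 1.5).
#' @param subject_jitter_sd log-normal sd of per-subject multiplicative weight
#'   jitter (dimensionless; default 0.1).
#' @param noise_sd sd of the additive envelope noise term, in the same
#'   arbitrary units as the burst amplitudes (default 0.05).
#' @param seed master integer seed; every subject/trial seed derives from it.
#' @return a \code{cohort_config} list.
#' @export
cohort_config <- function(n_subjects, n_muscles = 8L,
                          trials_per_stage = c(baseline = 3L, novel = 1L,
                                               early = 3L, late = 3L),
                          sampling_rate = 600, gait_cycle_duration = 1.5,
                          subject_jitter_sd = 0.1, noise_sd = 0.05,
                          seed = 1L) {
  stopifnot_scalar_count(n_subjects, "n_subjects", 1L)
  stopifnot_scalar_count(n_muscles, "n_muscles", 2L)
  if (any(trials_per_stage < 1L)) stop("all trial counts must be >= 1")
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive")
  if (gait_cycle_duration <= 0) stop("'gait_cycle_duration' must be positive")
  if (subject_jitter_sd < 0 || noise_sd < 0) stop("sds must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_muscles = as.integer(n_muscles),
                 trials_per_stage = trials_per_stage,
                 sampling_rate = sampling_rate,
                 gait_cycle_duration = gait_cycle_duration,
                 subject_jitter_sd = subject_jitter_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' One trial of raw-like multi-channel EMG
#'
#' @param signal muscles x samples numeric matrix (zero-mean carrier scaled by
#'   the activation envelope).
#' @param sampling_rate Hz.
#' @param events named integer sample indices for \code{LTD1},
#'   \code{slip_onset}, \code{LLO}, \code{LTD2}.
#' @param subject_id,stage_label,trial_index provenance.
#' @return an \code{emg_recording}.
#' @export
emg_recording <- function(signal, sampling_rate, events, subject_id,
                          stage_label, trial_index = 1L) {
  signal <- as.matrix(signal)
  ev <- events[c("LTD1", "slip_onset", "LLO", "LTD2")]
  if (anyNA(ev)) stop("events must name LTD1, slip_onset, LLO, LTD2")
  if (!(ev["LTD1"] < ev["slip_onset"] && ev["slip_onset"] < ev["LLO"] &&
        ev["LLO"] < ev["LTD2"] && ev["LTD2"] <= ncol(signal)))
    stop("events must satisfy LTD1 < slip_onset < LLO < LTD2 <= n_samples")
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive")
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 events = ev, subject_id = subject_id,
                 stage_label = stage_label, trial_index = as.integer(trial_index)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, stage %s, trial %d\n",
              x$subject_id, x$stage_label, x$trial_index))
  cat(sprintf("  %d muscles x %d samples @ %g Hz; gait cycle %d..%d\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              x$events["LTD1"], x$events["LTD2"]))
  invisible(x)
}

# Baseline trials carry all modes at a reduced amplitude; they exist to give
# every muscle a positive normalization maximum, not to model quiet walking
# precisely.
BASELINE_AMPLITUDE_SCALE <- 0.3

#' Synthesize one EMG trial from a ground-truth bank
#'
#' Realizes the generative synergy model: each emitted mode contributes a
#' Gaussian activation burst (in normalized gait time between LTD1 and LTD2)
#' times its weight vector; the summed envelope plus additive Gaussian noise
#' (clipped at zero) multiplies a unit-variance zero-mean Gaussian carrier, so
#' the emitted signal looks like raw EMG and exercises the full conditioning
#' chain. The stage label \code{"baseline"} emits every bank mode at
#' a reduced amplitude.
#'
#' @param bank a \code{ground_truth_bank} (typically per-subject jittered).
#' @param stage_label a stage named in the bank's recipes, or
#'   \code{"baseline"}.
#' @param subject_seed integer seed; the trial is a deterministic function of
#'   (bank, stage_label, subject_seed, config).
#' @param config a \code{cohort_config}.
#' @return an \code{emg_recording}.
#' @export
synthesize_trial <- function(bank, stage_label, subject_seed, config) {
  fs <- config$sampling_rate
  pad_s <- 0.25
  cyc <- config$gait_cycle_duration
  n <- round((cyc + 2 * pad_s) * fs)
  ltd1 <- round(pad_s * fs) + 1L
  ltd2 <- ltd1 + round(cyc * fs)
  events <- c(LTD1 = ltd1,
              slip_onset = ltd1 + round(0.25 * cyc * fs),
              LLO = ltd1 + round(0.60 * cyc * fs),
              LTD2 = ltd2)
  if (identical(stage_label, "baseline")) {
    modes <- lapply(seq_len(bank$n_modes), function(i) {
      bp <- bank$burst_params[i, ]
      list(weights = bank$mode_weights[[i]], center = bp$center,
           width = bp$width,
           amplitude = bp$amplitude * BASELINE_AMPLITUDE_SCALE)
    })
  } else {
    modes <- resolve_stage(bank, stage_label)
  }
  tfrac <- (seq_len(n) - ltd1) / (ltd2 - ltd1)
  W <- do.call(cbind, lapply(modes, `[[`, "weights"))
  C <- do.call(rbind, lapply(modes, function(m)
    m$amplitude * exp(-0.5 * ((tfrac - m$center) / m$width)^2)))
  envelope <- W %*% C
  sig <- with_seed(subject_seed, {
    if (config$noise_sd > 0)
      envelope <- envelope +
        matrix(rnorm(length(envelope), 0, config$noise_sd),
               nrow = nrow(envelope))
    envelope <- pmax(envelope, 0)
    carrier <- matrix(rnorm(length(envelope)), nrow = nrow(envelope))
    envelope * carrier
  })
  rownames(sig) <- muscle_names(bank$n_muscles)
  emg_recording(sig, fs, events, subject_id = NA_character_,
                stage_label = stage_label)
}

muscle_names <- function(n_muscles) {
  if (n_muscles == 8L) DEFAULT_MUSCLES else sprintf("M%02d", seq_len(n_muscles))
}

#' Generate a multi-subject synthetic EMG cohort
#'
#' For every subject: the bank's weight vectors receive one multiplicative
#' log-normal jitter (shared across all of that subject's trials), then
#' baseline trials plus the per-stage perturbed trials are synthesized with
#' independent per-trial seeds derived from the master seed. A truth record
#' keeps each subject's jittered weights and emitted mode labels per stage so
#' downstream recovery can be scored.
#'
#' @param bank a \code{ground_truth_bank}.
#' @param config a \code{cohort_config}.
#' @return an \code{emg_cohort}: list of \code{recordings}, a \code{truth}
#'   sidecar list, and the \code{config}.
#' @examples
#' bank <- make_ground_truth_bank(3, seed = 2)
#' coh <- generate_cohort(bank, cohort_config(n_subjects = 2, seed = 5))
#' length(coh$recordings)
#' @export
generate_cohort <- function(bank, config) {
  stages <- intersect(names(config$trials_per_stage),
                      c("baseline", names(bank$stage_recipes)))
  recs <- list()
  truth_subjects <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    sbank <- jitter_bank(bank, config$subject_jitter_sd,
                         seed = child_seed(config$seed, s))
    trial_counter <- 0L
    for (st in stages) {
      for (tr in seq_len(config$trials_per_stage[[st]])) {
        trial_counter <- trial_counter + 1L
        rec <- synthesize_trial(
          sbank, st, child_seed(config$seed, s * 1000L + trial_counter),
          config)
        rec$subject_id <- sid
        rec$trial_index <- tr
        recs[[length(recs) + 1L]] <- rec
      }
    }
    truth_subjects[[sid]] <- list(
      weights = sbank$mode_weights,
      stage_modes = lapply(
        stats::setNames(nm = setdiff(stages, "baseline")),
        function(st) vapply(resolve_stage(sbank, st), `[[`, "", "label")))
  }
  structure(list(recordings = recs,
                 truth = list(bank = bank, subjects = truth_subjects),
                 config = config),
            class = "emg_cohort")
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort> %d subjects, %d recordings, %d true modes\n",
              x$config$n_subjects, length(x$recordings),
              x$truth$bank$n_modes))
  invisible(x)
}

#' Select a cohort's recordings by subject and stage
#' @param cohort an \code{emg_cohort}.
#' @param subject_id subject label.
#' @param stage_label stage label.
#' @return list of \code{emg_recording}s in trial order.
#' @export
cohort_trials <- function(cohort, subject_id, stage_label) {
  Filter(function(r) r$subject_id == subject_id &&
           r$stage_label == stage_label, cohort$recordings)
}

#' Build the pool of true per-subject synergies a stage would contribute
#'
#' Skips EMG synthesis and extraction entirely: applies each subject's weight
#' jitter to the bank, resolves the stage recipe, and returns the resulting
#' synergies as a pool ready for \code{\link{cluster_stage}}. Activation
#' curves are the modes' true burst shapes on the 100-point cycle. Useful for
#' exercising the grouping and matching stages against an exactly known
#' truth.
#'
#' @param bank a \code{ground_truth_bank}.
#' @param n_subjects number of subjects.
#' @param stage_label stage whose recipe to resolve (default \code{"novel"}).
#' @param jitter_sd per-subject log-normal weight jitter sd.
#' @param seed master seed for the subject jitters.
#' @param n_points activation grid length.
#' @return a \code{synergy_pool}.
#' @export
synthetic_synergy_pool <- function(bank, n_subjects, stage_label = "novel",
                                   jitter_sd = 0.1, seed = 1L,
                                   n_points = 100L) {
  grid <- seq(0, 1, length.out = n_points)
  pool <- list()
  for (s in seq_len(n_subjects)) {
    sbank <- jitter_bank(bank, jitter_sd, child_seed(seed, s))
    modes <- resolve_stage(sbank, stage_label)
    for (j in seq_along(modes)) {
      m <- modes[[j]]
      pool[[length(pool) + 1L]] <- list(
        subject_id = sprintf("S%02d", s), synergy_index = j,
        weights = m$weights,
        activation = m$amplitude *
          exp(-0.5 * ((grid - m$center) / m$width)^2))
    }
  }
  structure(pool, class = "synergy_pool", stage_label = stage_label)
}

#' Write / read a cohort in its on-disk dialect
#'
#' One CSV per trial (\code{sample_index} plus one column per muscle), a JSON
#' sidecar per trial (events, sampling rate, provenance), a cohort manifest
#' CSV, and a JSON truth sidecar holding the bank and per-subject truth.
#'
#' @param cohort an \code{emg_cohort}.
#' @param dir output directory (created if needed).
#' @return (invisibly) the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$recordings, function(rec) {
    stem <- sprintf("%s_%s_t%02d", rec$subject_id, rec$stage_label,
                    rec$trial_index)
    df <- data.frame(sample_index = seq_len(ncol(rec$signal)),
                     t(rec$signal), check.names = FALSE)
    write.csv(df, file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
    jsonlite::write_json(
      list(sampling_rate = rec$sampling_rate, events = as.list(rec$events),
           subject_id = rec$subject_id, stage_label = rec$stage_label,
           trial_index = rec$trial_index),
      file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA)
    data.frame(subject_id = rec$subject_id, stage_label = rec$stage_label,
               trial_index = rec$trial_index, csv = paste0(stem, ".csv"),
               sidecar = paste0(stem, ".json"))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$bank$mode_weights <- lapply(truth$bank$mode_weights, as.numeric)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @param csv_path,sidecar_path paths of one trial's CSV and JSON sidecar.
#' @export
read_trial <- function(csv_path, sidecar_path) {
  df <- read.csv(csv_path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  sig <- t(as.matrix(df[, setdiff(names(df), "sample_index"), drop = FALSE]))
  emg_recording(sig, meta$sampling_rate, unlist(meta$events),
                meta$subject_id, meta$stage_label, meta$trial_index)
}
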