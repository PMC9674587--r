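#' Condition a raw EMG trial into nonnegative envelopes
#'
#' Per channel: zero-phase Butterworth high-pass at \code{highpass_hz} (4th
#' order design, applied forward and backward), full-wave rectification, then
#' a 2nd-order zero-phase Butterworth low-pass at \code{lowpass_hz}. Small
#' negative excursions introduced by the smoothing filter are clipped to zero
#' so the output is a valid nonnegative envelope.
#'
#' @param rec an \code{emg_recording}.
#' @param highpass_hz high-pass cutoff (default 35).
#' @param lowpass_hz low-pass cutoff (default 40).
#' @return muscles x samples nonnegative envelope matrix (dimnames kept).
#' @export
condition_signal <- function(rec, highpass_hz = 35, lowpass_hz = 40) {
  fs <- rec$sampling_rate
  if (fs <= 2 * lowpass_hz)
    stop(sprintf("sampling rate %g Hz is too low for a %g Hz low-pass cutoff",
                 fs, lowpass_hz))
  if (fs <= 2 * highpass_hz)
    stop(sprintf("sampling rate %g Hz is too low for a %g Hz high-pass cutoff",
                 fs, highpass_hz))
  hp <- signal::butter(4, highpass_hz / (fs / 2), type = "high")
  lp <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  out <- t(apply(rec$signal, 1, function(x) {
    x <- signal::filtfilt(hp, x)
    x <- abs(x)
    signal::filtfilt(lp, x)
  }))
  pmax(out, 0)
}

#' Segment a conditioned envelope to the gait cycle and average into time bins
#'
#' Restricts the envelope to \code{[LTD1, LTD2)} and averages non-overlapping
#' windows of \code{bin_ms}. A final partial window is averaged over the
#' samples it actually contains (set \code{drop_partial = TRUE} to discard it
#' instead).
#'
#' @param envelope muscles x samples nonnegative matrix.
#' @param events named sample indices including \code{LTD1} and \code{LTD2}.
#' @param sampling_rate Hz.
#' @param bin_ms bin duration in milliseconds (default 30).
#' @param drop_partial drop a trailing partial bin rather than averaging it.
#' @return muscles x bins matrix of bin means, with attribute
#'   \code{bin_counts} giving the number of samples averaged per bin.
#' @export
segment_and_bin <- function(envelope, events, sampling_rate, bin_ms = 30,
                            drop_partial = FALSE) {
  i0 <- as.integer(events["LTD1"])
  i1 <- as.integer(events["LTD2"])
  if (is.na(i0) || is.na(i1) || i0 >= i1)
    stop("events must include LTD1 < LTD2 within the signal")
  seg <- envelope[, i0:(i1 - 1L), drop = FALSE]
  bw <- round(bin_ms / 1000 * sampling_rate)
  if (ncol(seg) < bw)
    stop(sprintf("segment of %d samples is shorter than one %g ms bin",
                 ncol(seg), bin_ms))
  n_full <- ncol(seg) %/% bw
  rem <- ncol(seg) %% bw
  starts <- (seq_len(n_full) - 1L) * bw + 1L
  counts <- rep(bw, n_full)
  if (rem > 0L && !drop_partial) {
    starts <- c(starts, n_full * bw + 1L)
    counts <- c(counts, rem)
  }
  out <- vapply(seq_along(starts), function(b) {
    rowMeans(seg[, starts[b]:(starts[b] + counts[b] - 1L), drop = FALSE])
  }, numeric(nrow(seg)))
  out <- matrix(out, nrow = nrow(seg),
                dimnames = list(rownames(envelope), NULL))
  attr(out, "bin_counts") <- counts
  out
}

#' Concatenate per-trial binned segments end-to-end
#'
#' @param segments list of muscles x bins matrices sharing muscle order.
#' @param muscle_labels optional muscle names (defaults to the first
#'   segment's rownames).
#' @param bin_ms bin duration carried as metadata.
#' @param stage_label,subject_id provenance.
#' @return an \code{emg_matrix}: the concatenated nonnegative matrix with
#'   \code{trial_boundaries} marking the last bin index of each trial.
#' @export
concatenate_trials <- function(segments, muscle_labels = NULL, bin_ms = 30,
                               stage_label = NA_character_,
                               subject_id = NA_character_) {
  if (length(segments) == 0L) stop("no segments to concatenate")
  nm <- nrow(segments[[1L]])
  labs <- muscle_labels %||% rownames(segments[[1L]])
  for (s in segments) {
    if (nrow(s) != nm) stop("segments disagree on muscle count")
    if (!is.null(labs) && !is.null(rownames(s)) &&
        !identical(rownames(s), labs))
      stop("segments disagree on muscle ordering")
  }
  values <- do.call(cbind, segments)
  boundaries <- cumsum(vapply(segments, ncol, integer(1)))
  emg_matrix(values, muscle_labels = labs, bin_ms = bin_ms,
             trial_boundaries = boundaries, stage_label = stage_label,
             subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The binned muscle-by-time activation matrix
#'
#' @param values muscles x bins nonnegative matrix.
#' @param muscle_labels optional muscle names.
#' @param bin_ms bin duration (ms).
#' @param trial_boundaries strictly increasing last-bin indices of the
#'   concatenated trials (defaults to a single trial).
#' @param stage_label,subject_id provenance.
#' @return an \code{emg_matrix}.
#' @export
emg_matrix <- function(values, muscle_labels = NULL, bin_ms = 30,
                       trial_boundaries = ncol(values),
                       stage_label = NA_character_,
                       subject_id = NA_character_) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("matrix entries must be finite")
  if (any(values < 0)) stop("matrix entries must be nonnegative")
  tb <- as.integer(trial_boundaries)
  if (any(diff(tb) <= 0) || tb[length(tb)] != ncol(values) || any(tb < 1L))
    stop("trial_boundaries must be strictly increasing and end at ncol(values)")
  if (!is.null(muscle_labels)) rownames(values) <- muscle_labels
  structure(list(values = values,
                 muscle_labels = rownames(values),
                 bin_ms = bin_ms, trial_boundaries = tb,
                 stage_label = stage_label, subject_id = subject_id),
            class = "emg_matrix")
}

#' @export
print.emg_matrix <- function(x, ...) {
  cat(sprintf("<emg_matrix> %d muscles x %d bins (%g ms), %d trial(s)%s\n",
              nrow(x$values), ncol(x$values), x$bin_ms,
              length(x$trial_boundaries),
              if (is.na(x$subject_id)) "" else
                sprintf(", subject %s stage %s", x$subject_id, x$stage_label)))
  invisible(x)
}

#' @export
dim.emg_matrix <- function(x) dim(x$values)

#' Normalize to baseline maxima and scale each muscle to unit variance
#'
#' Each muscle row is divided by that muscle's maximum activation across the
#' unperturbed baseline segments, then by its own (sample) standard deviation
#' so every muscle weighs equally in the factorization. Both divisors are
#' returned so the unit-variance scale can be removed from the extracted
#' weights afterwards.
#'
#' @param m an \code{emg_matrix}.
#' @param baseline_segments list of muscles x bins matrices from baseline
#'   (non-perturbed) trials, conditioned and binned with the same settings.
#' @return list with the scaled \code{emg_matrix} and a
#'   \code{normalization_state} (fields \code{baseline_max}, \code{row_sd}).
#' @export
normalize_and_scale <- function(m, baseline_segments) {
  if (length(baseline_segments) == 0L) stop("baseline segments must be nonempty")
  base <- do.call(cbind, baseline_segments)
  if (nrow(base) != nrow(m$values)) stop("baseline muscle count mismatch")
  bmax <- apply(base, 1, max)
  bad <- which(bmax <= 0)
  if (length(bad))
    stop(sprintf("muscle(s) %s have zero baseline maximum",
                 paste(rownames(m$values)[bad] %||% bad, collapse = ", ")))
  v <- m$values / bmax
  rsd <- apply(v, 1, sd)
  bad <- which(rsd <= 0)
  if (length(bad))
    stop(sprintf("muscle(s) %s have zero variance",
                 paste(rownames(m$values)[bad] %||% bad, collapse = ", ")))
  v <- v / rsd
  out <- m
  out$values <- v
  state <- structure(list(baseline_max = bmax, row_sd = rsd),
                     class = "normalization_state")
  list(matrix = out, state = state)
}

#' Undo baseline + unit-variance scaling
#' @param m a scaled \code{emg_matrix}.
#' @param state the \code{normalization_state} from
#'   \code{\link{normalize_and_scale}}.
#' @return the \code{emg_matrix} on its original scale.
#' @export
unscale_matrix <- function(m, state) {
  out <- m
  out$values <- m$values * state$row_sd * state$baseline_max
  out
}

#' Preprocess one subject-stage: condition, segment, bin, concatenate, scale
#'
#' Convenience wrapper running the full conditioning chain over a stage's
#' trials and its subject's baseline trials.
#'
#' @param stage_recs list of \code{emg_recording}s forming the stage.
#' @param baseline_recs list of baseline \code{emg_recording}s.
#' @param bin_ms bin duration (ms).
#' @param highpass_hz,lowpass_hz filter cutoffs.
#' @return list: scaled \code{matrix} (an \code{emg_matrix}), normalization
#'   \code{state}, and per-trial \code{events} (gait-landmark fractions used
#'   later for activation resampling).
#' @export
preprocess_stage <- function(stage_recs, baseline_recs, bin_ms = 30,
                             highpass_hz = 35, lowpass_hz = 40) {
  if (length(stage_recs) == 0L) stop("no stage recordings supplied")
  segs <- lapply(stage_recs, function(r) {
    env <- condition_signal(r, highpass_hz, lowpass_hz)
    segment_and_bin(env, r$events, r$sampling_rate, bin_ms)
  })
  base_segs <- lapply(baseline_recs, function(r) {
    env <- condition_signal(r, highpass_hz, lowpass_hz)
    segment_and_bin(env, r$events, r$sampling_rate, bin_ms)
  })
  m <- concatenate_trials(segs, bin_ms = bin_ms,
                          stage_label = stage_recs[[1L]]$stage_label,
                          subject_id = stage_recs[[1L]]$subject_id)
  scaled <- normalize_and_scale(m, base_segs)
  events <- lapply(stage_recs, function(r) {
    span <- as.numeric(r$events["LTD2"] - r$events["LTD1"])
    c(slip_onset = as.numeric(r$events["slip_onset"] - r$events["LTD1"]) / span,
      LLO = as.numeric(r$events["LLO"] - r$events["LTD1"]) / span)
  })
  list(matrix = scaled$matrix, state = scaled$state, events = events)
}
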