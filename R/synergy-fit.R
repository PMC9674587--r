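#' Fit a muscle-synergy decomposition with dual-VAF order selection
#'
#' The central estimator: scans candidate synergy numbers \code{k = 1, ...,
#' k_max}, factorizing the (unit-variance-scaled) activation matrix at each
#' \code{k} with \code{\link{run_nmf}}, and selects the smallest \code{k}
#' whose reconstruction exceeds 75\% variance accounted for in every muscle
#' AND 90\% overall. If no candidate satisfies both criteria the fit returns
#' \code{k_max} with \code{criteria_met = FALSE}. When a
#' \code{normalization_state} is supplied, the unit-variance scale is removed
#' from the returned weights (restoring the muscles' original relative
#' scaling) and the weight columns re-normalized to unit Euclidean norm, with
#' all compensating scale absorbed into the activations.
#'
#' @param m an \code{emg_matrix} (typically the unit-variance-scaled output of
#'   \code{\link{normalize_and_scale}}).
#' @param thresholds named fractions \code{per_muscle} and \code{overall}
#'   (defaults 0.75 and 0.90).
#' @param k_max largest synergy number scanned (default: number of muscles).
#' @param restarts,seed,tol,max_iter passed to \code{\link{run_nmf}}.
#' @param norm_state optional \code{normalization_state} whose \code{row_sd}
#'   is removed from the weights after extraction.
#' @param centered use centered VAF (default uncentered).
#' @return an object of class \code{synergy_fit} with components \code{W}
#'   (muscles x k, unit-norm columns, original muscle scaling), \code{C}
#'   (k x bins), \code{k}, \code{vaf_overall}, \code{vaf_per_muscle},
#'   \code{vaf_table} (the k-scan diagnostics), \code{criteria_met},
#'   and provenance (\code{subject_id}, \code{stage_label}, \code{seed},
#'   \code{restarts}, \code{trial_boundaries}).
#' @examples
#' W <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
#' C <- rbind(exp(-((1:40) - 10)^2 / 20), exp(-((1:40) - 30)^2 / 20))
#' m <- emg_matrix(W %*% C)
#' fit <- select_synergy_number(m, k_max = 4, seed = 1)
#' fit$k
#' @export
select_synergy_number <- function(m, thresholds = c(per_muscle = 0.75,
                                                    overall = 0.90),
                                  k_max = NULL, restarts = 20L, seed = 1L,
                                  tol = 1e-6, max_iter = 1000L,
                                  norm_state = NULL, centered = FALSE) {
  if (!inherits(m, "emg_matrix")) m <- emg_matrix(as.matrix(m))
  k_max <- k_max %||% nrow(m$values)
  stopifnot_scalar_count(k_max, "k_max", 1L)
  if (k_max > nrow(m$values)) stop("k_max cannot exceed the number of muscles")
  scan <- list()
  chosen <- NULL
  for (k in seq_len(k_max)) {
    nf <- run_nmf(m, k, restarts = restarts, seed = child_seed(seed, k),
                  tol = tol, max_iter = max_iter)
    vo <- vaf_overall(m$values, nf$W, nf$C, centered = centered)
    vm <- vaf_per_muscle(m$values, nf$W, nf$C, centered = centered)
    ok <- vo > thresholds[["overall"]] && all(vm > thresholds[["per_muscle"]])
    scan[[k]] <- data.frame(k = k, vaf_overall = vo,
                            vaf_min_muscle = min(vm), criteria_met = ok)
    if (ok) {
      chosen <- list(fit = nf, vo = vo, vm = vm, met = TRUE)
      break
    }
    if (k == k_max) chosen <- list(fit = nf, vo = vo, vm = vm, met = FALSE)
  }
  nf <- chosen$fit
  W <- nf$W
  C <- nf$C
  if (!is.null(norm_state)) {
    W <- W * norm_state$row_sd       # remove unit-variance scaling row-wise
    norms <- sqrt(colSums(W^2))
    W <- sweep(W, 2, norms, "/")
    C <- C * norms
  }
  structure(list(W = W, C = C, k = ncol(W),
                 vaf_overall = chosen$vo, vaf_per_muscle = chosen$vm,
                 vaf_table = do.call(rbind, scan),
                 criteria_met = chosen$met, thresholds = thresholds,
                 sse = nf$sse, restarts = restarts, seed = seed,
                 subject_id = m$subject_id, stage_label = m$stage_label,
                 trial_boundaries = m$trial_boundaries,
                 matrix = m, norm_state = norm_state,
                 W_scaled = nf$W, C_scaled = nf$C),
            class = "synergy_fit")
}

#' @export
print.synergy_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<synergy_fit> %s%s\n",
              if (is.na(x$subject_id)) "" else
                sprintf("subject %s, stage %s, ", x$subject_id, x$stage_label),
              sprintf("k = %d synerg%s", x$k, if (x$k == 1) "y" else "ies")))
  cat(sprintf("  overall VAF %.1f%%, min per-muscle VAF %.1f%%%s\n",
              100 * x$vaf_overall, 100 * min(x$vaf_per_muscle),
              if (x$criteria_met) "" else "  [VAF criteria NOT met at k_max]"))
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  mc <- major_contributors(object$W)
  out <- list(k = object$k, W = object$W,
              vaf_overall = object$vaf_overall,
              vaf_per_muscle = object$vaf_per_muscle,
              major_contributors = mc, vaf_table = object$vaf_table,
              criteria_met = object$criteria_met)
  class(out) <- "summary.synergy_fit"
  out
}

#' @export
print.summary.synergy_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Muscle synergy fit: k = %d (criteria %s)\n", x$k,
              if (x$criteria_met) "met" else "not met"))
  cat("\nWeights (unit-norm columns):\n")
  print(round(x$W, digits))
  cat("\nMajor contributors (weight > 0.4):\n")
  for (j in seq_along(x$major_contributors)) {
    idx <- x$major_contributors[[j]]
    nm <- if (length(idx)) paste(rownames(x$W)[idx] %||% idx, collapse = ", ")
          else "(none)"
    cat(sprintf("  synergy %d: %s\n", j, nm))
  }
  cat("\nVAF scan:\n")
  print(round(x$vaf_table, digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.synergy_fit <- function(object, ...) object$W

#' @export
fitted.synergy_fit <- function(object, ...) object$W_scaled %*% object$C_scaled

#' @export
residuals.synergy_fit <- function(object, ...)
  object$matrix$values - fitted(object)

#' Project new activation data onto fitted synergy weights
#'
#' Solves one nonnegative least-squares problem per time bin, recruiting the
#' fitted weight columns to reconstruct \code{newdata}.
#'
#' @param object a \code{synergy_fit}.
#' @param newdata an \code{emg_matrix} or matrix on the same muscle space and
#'   scaling as the training matrix; defaults to the training matrix.
#' @param ... ignored.
#' @return k x bins nonnegative activation matrix.
#' @export
predict.synergy_fit <- function(object, newdata = NULL, ...) {
  M <- if (is.null(newdata)) object$matrix$values
       else if (inherits(newdata, "emg_matrix")) newdata$values
       else as.matrix(newdata)
  if (nrow(M) != nrow(object$W_scaled))
    stop("newdata must have the same muscles as the fitted matrix")
  apply(M, 2, function(col) pracma::lsqnonneg(object$W_scaled, col)$x)
}

#' @export
plot.synergy_fit <- function(x, ...) {
  k <- x$k
  op <- par(mfrow = c(k, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(par(op))
  for (j in seq_len(k)) {
    barplot(x$W[, j], names.arg = rownames(x$W), las = 2,
            col = gray(0.4), ylim = c(0, 1),
            ylab = sprintf("w%d", j), ...)
    abline(h = 0.4, lty = 2)
  }
  invisible(x)
}

#' Fitted synergy weights on a chosen scale
#'
#' \code{"normalized"} returns the weights as fitted (unit-variance scale
#' removed, muscles in baseline-max-normalized units — the scale on which
#' synergies are conventionally reported). \code{"raw"} additionally undoes
#' the baseline-max normalization, returning weights proportional to the
#' muscles' physical envelope amplitudes; useful when comparing against a
#' generative ground truth expressed in raw units. Columns are unit-norm on
#' either scale.
#'
#' @param fit a \code{synergy_fit} fitted with a \code{norm_state}.
#' @param scale \code{"normalized"} (default) or \code{"raw"}.
#' @return muscles x k weight matrix with unit-norm columns.
#' @export
synergy_weights <- function(fit, scale = c("normalized", "raw")) {
  scale <- match.arg(scale)
  W <- fit$W
  if (scale == "raw") {
    if (is.null(fit$norm_state))
      stop("fit has no normalization state; raw scale unavailable")
    W <- W * fit$norm_state$baseline_max
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  }
  W
}

#' Muscles contributing more than a threshold weight to a synergy
#'
#' On a unit-norm weight vector, a muscle whose weight exceeds 0.4 is
#' conventionally read as a major contributor to that synergy.
#'
#' @param w a nonnegative unit-norm weight vector, or a weights matrix (one
#'   synergy per column).
#' @param threshold weight cutoff (default 0.4).
#' @return integer index vector, or a list of them for a matrix input.
#' @export
major_contributors <- function(w, threshold = 0.4) {
  if (is.matrix(w))
    return(lapply(seq_len(ncol(w)), function(j)
      major_contributors(w[, j], threshold)))
  which(w > threshold)
}

#' Resample a synergy's activation onto a common 100-point gait cycle
#'
#' Each trial's activation bins (one gait cycle, first to last touchdown) are
#' linearly interpolated onto \code{n_points} evenly spaced points of the
#' normalized cycle, and the across-trial mean curve is returned alongside
#' the per-trial curves.
#'
#' @param c_row numeric activation row (concatenated trials).
#' @param trial_boundaries last-bin indices of each trial.
#' @param events optional per-trial named landmark fractions (carried as
#'   metadata).
#' @param n_points grid length (default 100).
#' @return an \code{activation_curve}: list with \code{per_trial}
#'   (trials x n_points), \code{mean} (length n_points), \code{landmarks}.
#' @export
resample_activation <- function(c_row, trial_boundaries, events = NULL,
                                n_points = 100L) {
  tb <- as.integer(trial_boundaries)
  starts <- c(1L, head(tb, -1L) + 1L)
  grid <- seq(0, 1, length.out = n_points)
  per_trial <- t(vapply(seq_along(tb), function(i) {
    seg <- c_row[starts[i]:tb[i]]
    if (length(seg) < 2L)
      stop(sprintf("trial %d has fewer than 2 bins; cannot resample", i))
    approx(seq(0, 1, length.out = length(seg)), seg, xout = grid)$y
  }, numeric(n_points)))
  structure(list(per_trial = per_trial, mean = colMeans(per_trial),
                 landmarks = events, n_points = n_points),
            class = "activation_curve")
}

#' Mean 100-point activation curves for every synergy of a fit
#' @param fit a \code{synergy_fit}.
#' @param events optional per-trial landmark fractions.
#' @param n_points grid length.
#' @return k x n_points matrix of across-trial mean curves.
#' @export
activation_curves <- function(fit, events = NULL, n_points = 100L) {
  t(vapply(seq_len(fit$k), function(j) {
    resample_activation(fit$C[j, ], fit$trial_boundaries, events,
                        n_points)$mean
  }, numeric(n_points)))
}
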