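#' Nonnegative least-squares reconstruction of a synergy from another stage's
#' modes
#'
#' Models a target weight vector as a nonnegative linear combination of the
#' basis weight vectors (one column per candidate mode), solving
#' \code{min || target - basis coef ||^2, coef >= 0}, and reports the Pearson
#' correlation between the target and its fitted reconstruction.
#'
#' @param target_w nonnegative muscle-weight vector.
#' @param basis_w muscles x m nonnegative matrix of candidate mode weights.
#' @return list: \code{coefficients}, \code{reconstruction_r},
#'   \code{residual} (vector), \code{fitted}.
#' @export
nnls_reconstruct <- function(target_w, basis_w) {
  basis_w <- as.matrix(basis_w)
  if (ncol(basis_w) == 0L || all(basis_w == 0)) stop("basis is empty or all-zero")
  if (any(basis_w < 0) || any(target_w < 0))
    stop("target and basis must be nonnegative")
  if (length(target_w) != nrow(basis_w))
    stop("target and basis disagree on muscle count")
  sol <- pracma::lsqnonneg(basis_w, as.numeric(target_w))
  fitted <- as.numeric(basis_w %*% sol$x)
  r <- if (sd(fitted) == 0 || sd(target_w) == 0) 0 else cor(target_w, fitted)
  list(coefficients = sol$x, reconstruction_r = r,
       residual = as.numeric(target_w) - fitted, fitted = fitted)
}

# Basis elements with coefficient >= floor_frac of the largest are "active".
active_set <- function(coefficients, floor_frac = 0.2) {
  if (all(coefficients <= 0)) return(integer(0))
  which(coefficients >= floor_frac * max(coefficients))
}

#' Detect merged / fractionated synergies between two stages
#'
#' For every stage-A cluster without a one-to-one structural match in stage
#' B, its mean weight vector is reconstructed by nonnegative least squares
#' from all stage-B cluster means. If the reconstruction correlates with the
#' target above the structural threshold and at least two basis modes carry
#' non-trivial coefficients (>= \code{floor_frac} of the largest), the
#' stage-A synergy is read as a merging of those stage-B modes — equivalently
#' the stage-B modes are a fractionation of it. Running the function with the
#' stages swapped yields the fractionation direction.
#'
#' @param clusters_a,clusters_b \code{mode_clustering}s of the two stages.
#' @param structure_threshold critical r (default
#'   \code{critical_r(n_muscles - 2, 0.01)}).
#' @param floor_frac relative coefficient floor for counting a basis mode as
#'   active (default 0.2).
#' @return a \code{merge_fractionation_result}: data frame with one row per
#'   unmatched stage-A cluster (target cluster, verdict \code{"merged"} or
#'   \code{"unrelated"}, reconstruction_r, active basis clusters,
#'   coefficients).
#' @export
detect_merging <- function(clusters_a, clusters_b,
                           structure_threshold = NULL, floor_frac = 0.2) {
  Wa <- cluster_weight_matrix(clusters_a)
  Wb <- cluster_weight_matrix(clusters_b)
  structure_threshold <- structure_threshold %||%
    critical_r(nrow(Wa) - 2L, 0.01)
  match_ab <- match_pairs(cor(Wa, Wb), structure_threshold, "greedy")
  unmatched <- which(is.na(match_ab))
  rows <- lapply(unmatched, function(i) {
    rec <- nnls_reconstruct(Wa[, i], Wb)
    act <- active_set(rec$coefficients, floor_frac)
    merged <- rec$reconstruction_r > structure_threshold && length(act) >= 2L
    data.frame(target_cluster = i,
               verdict = if (merged) "merged" else "unrelated",
               reconstruction_r = rec$reconstruction_r,
               active_basis = paste(act, collapse = "+"),
               coefficients = paste(sprintf("%.4f", rec$coefficients),
                                    collapse = ","))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_cluster = integer(0), verdict = character(0),
               reconstruction_r = numeric(0), active_basis = character(0),
               coefficients = character(0))
  structure(list(table = out, direction = "A_from_B",
                 structure_threshold = structure_threshold,
                 stage_a = attr(clusters_a, "stage_label"),
                 stage_b = attr(clusters_b, "stage_label")),
            class = "merge_fractionation_result")
}

#' Detect weight-modified synergies between two stages
#'
#' A cross-stage pair whose mean activation curves are similar (r above the
#' activation screen) while the weight structures are not (r at or below the
#' structural threshold) is flagged as a candidate weight modification: the
#' same temporal drive recruiting an adjusted muscle balance. Reported
#' per-muscle deltas are differences of the unit-norm mean weight vectors;
#' muscles with |delta| above \code{delta_cutoff} are listed as modified.
#'
#' @param clusters_a,clusters_b \code{mode_clustering}s of the two stages.
#' @param activation_threshold activation-similarity screen (default 0.3).
#' @param structure_threshold critical r (default
#'   \code{critical_r(n_muscles - 2, 0.01)}).
#' @param delta_cutoff absolute weight change flagging a muscle as modified
#'   (default 0.2 on unit-norm vectors).
#' @return a \code{merge_fractionation_result} whose table has one row per
#'   candidate pair: clusters, activation_r, structure_r, modified muscles
#'   with signed deltas.
#' @export
detect_modification <- function(clusters_a, clusters_b,
                                activation_threshold = 0.3,
                                structure_threshold = NULL,
                                delta_cutoff = 0.2) {
  Wa <- cluster_weight_matrix(clusters_a)
  Wb <- cluster_weight_matrix(clusters_b)
  structure_threshold <- structure_threshold %||%
    critical_r(nrow(Wa) - 2L, 0.01)
  Aa <- cluster_activation_matrix(clusters_a)
  Ab <- cluster_activation_matrix(clusters_b)
  muscles <- rownames(Wa) %||% as.character(seq_len(nrow(Wa)))
  rows <- list()
  for (i in seq_len(ncol(Wa))) {
    for (j in seq_len(ncol(Wb))) {
      sr <- cor(Wa[, i], Wb[, j])
      if (sr > structure_threshold) next   # structurally the same mode
      ar <- cor(Aa[, i], Ab[, j])
      if (!is.finite(ar) || ar <= activation_threshold) next
      delta <- Wb[, j] - Wa[, i]
      mod <- which(abs(delta) > delta_cutoff)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_a = i, cluster_b = j, activation_r = ar, structure_r = sr,
        modified_muscles = paste(muscles[mod], collapse = "+"),
        deltas = paste(sprintf("%s%+.3f", muscles[mod], delta[mod]),
                       collapse = ","))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_a = integer(0), cluster_b = integer(0),
               activation_r = numeric(0), structure_r = numeric(0),
               modified_muscles = character(0), deltas = character(0))
  structure(list(table = out, direction = "modification",
                 structure_threshold = structure_threshold,
                 activation_threshold = activation_threshold,
                 stage_a = attr(clusters_a, "stage_label"),
                 stage_b = attr(clusters_b, "stage_label")),
            class = "merge_fractionation_result")
}

#' @export
print.merge_fractionation_result <- function(x, ...) {
  cat(sprintf("<merge_fractionation_result> %s vs %s (%s)\n",
              x$stage_a %||% "A", x$stage_b %||% "B", x$direction))
  if (nrow(x$table) == 0L) cat("  no candidates\n") else print(x$table)
  invisible(x)
}
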