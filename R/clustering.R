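#' Pool per-subject synergies within a stage
#'
#' Flattens a stage's fitted synergy sets into one list of
#' (subject, weight vector, mean activation curve) items, preserving
#' provenance so the clustering rule can forbid two synergies of the same
#' subject sharing a cluster.
#'
#' @param stage_fits list of \code{synergy_fit}s, one per subject, all from
#'   the same stage and muscle ordering.
#' @param n_points activation grid length (default 100).
#' @return a \code{synergy_pool}: list of items with \code{subject_id},
#'   \code{synergy_index}, \code{weights}, \code{activation}.
#' @export
pool_synergies <- function(stage_fits, n_points = 100L) {
  if (length(stage_fits) == 0L)
    return(structure(list(), class = "synergy_pool"))
  labs <- lapply(stage_fits, function(f) rownames(f$W))
  if (length(unique(vapply(labs, paste, "", collapse = "|"))) > 1L)
    stop("synergy fits disagree on muscle ordering")
  stage <- unique(vapply(stage_fits, function(f) f$stage_label, ""))
  if (length(stage) > 1L)
    stop(sprintf("synergy fits mix stages: %s", paste(stage, collapse = ", ")))
  pool <- list()
  for (f in stage_fits) {
    curves <- activation_curves(f, n_points = n_points)
    for (j in seq_len(f$k)) {
      pool[[length(pool) + 1L]] <- list(
        subject_id = f$subject_id, synergy_index = j,
        weights = f$W[, j], activation = curves[j, ])
    }
  }
  structure(pool, class = "synergy_pool", stage_label = stage)
}

#' Group pooled synergies into modes under the subject-uniqueness rule
#'
#' Builds a hierarchical tree on the pooled weight vectors (distance
#' \code{1 - Pearson r}, average linkage by default) and cuts it at the
#' smallest cluster count whose partition contains no two synergies from the
#' same subject in one cluster. Each resulting cluster is a "mode": a motor
#' module shared across subjects, summarized by the renormalized mean weight
#' vector and the mean activation curve of its members.
#'
#' @param pool a \code{synergy_pool} (or plain list of pool items).
#' @param linkage_method linkage passed to \code{\link[stats]{hclust}}
#'   (default \code{"average"}; \code{"ward.D2"} on Euclidean distance
#'   available via \code{distance = "euclidean"}).
#' @param distance \code{"correlation"} (1 - Pearson r) or
#'   \code{"euclidean"}.
#' @return a \code{mode_clustering}: list of clusters, each with
#'   \code{cluster_id}, \code{members} (data frame of subject_id,
#'   synergy_index), \code{mean_weights} (unit norm), \code{mean_activation},
#'   \code{n_subjects}; attribute \code{forced_singletons} flags the
#'   degenerate all-singleton fallback.
#' @export
cluster_stage <- function(pool, linkage_method = "average",
                          distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  if (length(pool) == 0L) stop("pool is empty")
  Wp <- do.call(rbind, lapply(pool, `[[`, "weights"))
  subjects <- vapply(pool, `[[`, "", "subject_id")
  n <- nrow(Wp)
  assignment <- seq_len(n)
  forced <- FALSE
  if (n > 1L) {
    d <- if (distance == "correlation") stats::as.dist(1 - cor(t(Wp)))
         else dist(Wp)
    tree <- hclust(d, method = linkage_method)
    assignment <- NULL
    for (kc in seq_len(n)) {
      cand <- cutree(tree, k = kc)
      if (!any_subject_duplicate(cand, subjects)) {
        assignment <- cand
        break
      }
    }
    if (is.null(assignment)) {   # unreachable in theory: singletons satisfy
      assignment <- seq_len(n)
      forced <- TRUE
    }
    forced <- forced || max(assignment) == n
  }
  clusters <- lapply(sort(unique(assignment)), function(cid) {
    idx <- which(assignment == cid)
    mw <- unit_norm(colMeans(Wp[idx, , drop = FALSE]))
    names(mw) <- colnames(Wp)
    act <- colMeans(do.call(rbind, lapply(pool[idx], `[[`, "activation")))
    list(cluster_id = cid,
         members = data.frame(
           subject_id = subjects[idx],
           synergy_index = vapply(pool[idx], function(p)
             as.integer(p$synergy_index), integer(1))),
         mean_weights = mw, mean_activation = act,
         n_subjects = length(unique(subjects[idx])))
  })
  structure(clusters, class = "mode_clustering",
            stage_label = attr(pool, "stage_label"),
            forced_singletons = forced)
}

any_subject_duplicate <- function(assignment, subjects) {
  any(vapply(split(subjects, assignment),
             function(s) anyDuplicated(s) > 0L, logical(1)))
}

#' @export
print.mode_clustering <- function(x, ...) {
  st <- attr(x, "stage_label")
  cat(sprintf("<mode_clustering>%s %d cluster(s)\n",
              if (is.null(st)) "" else sprintf(" stage %s:", st), length(x)))
  for (cl in x)
    cat(sprintf("  cluster %d: %d synergies from %d subject(s)\n",
                cl$cluster_id, nrow(cl$members), cl$n_subjects))
  if (isTRUE(attr(x, "forced_singletons")))
    cat("  note: no non-trivial cut satisfied the subject-uniqueness rule\n")
  invisible(x)
}

# Matrix of cluster mean weight vectors, one column per cluster.
cluster_weight_matrix <- function(clustering) {
  do.call(cbind, lapply(clustering, `[[`, "mean_weights"))
}

cluster_activation_matrix <- function(clustering) {
  do.call(cbind, lapply(clustering, `[[`, "mean_activation"))
}
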