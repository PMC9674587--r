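#' Critical Pearson correlation for a given degrees of freedom
#'
#' The smallest |r| significant at level \code{alpha} for \code{df} degrees
#' of freedom, from the t-distribution of \code{r sqrt(df) / sqrt(1 - r^2)}:
#' \code{r* = t* / sqrt(t*^2 + df)}. With 8 muscles (df = 6) at alpha = 0.01
#' two-tailed this gives the 0.834 structural-similarity threshold; with 100
#' activation points (df = 98) it gives 0.256, so a fixed 0.3 activation
#' screen is conservative.
#'
#' @param df degrees of freedom (n - 2 for a correlation of n points).
#' @param alpha significance level in (0, 1).
#' @param two_tailed two-tailed test (default TRUE).
#' @return the critical correlation in [0, 1).
#' @examples
#' critical_r(6, 0.01)    # 0.834
#' critical_r(98, 0.01)   # 0.256
#' @export
critical_r <- function(df, alpha = 0.01, two_tailed = TRUE) {
  stopifnot_scalar_count(df, "df", 1L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a probability strictly between 0 and 1")
  tq <- qt(1 - alpha / (1L + isTRUE(two_tailed)), df)
  tq / sqrt(tq^2 + df)
}

#' Pearson similarity between two equal-length vectors
#'
#' @param a,b numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return the Pearson correlation coefficient.
#' @export
pearson_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 points")
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero-variance input: correlation undefined")
  cor(a, b)
}

#' Match clustered modes across two stages
#'
#' Computes the Pearson correlation between every pair of cluster mean weight
#' vectors of two stages and forms one-to-one matches greedily in descending
#' r, accepting only pairs above the structural threshold (the critical r at
#' \code{n_muscles - 2} degrees of freedom by default). Matched pairs share a
#' mode; unmatched clusters are stage-unique modes. For matched pairs only,
#' the mean 100-point activation curves are additionally compared against the
#' fixed activation screen.
#'
#' @param clusters_a,clusters_b \code{mode_clustering}s from two different
#'   stages.
#' @param structure_threshold critical r for weight-vector similarity
#'   (default \code{critical_r(n_muscles - 2, 0.01)}).
#' @param activation_threshold fixed screen for activation similarity
#'   (default 0.3).
#' @param method \code{"greedy"} (descending r) or \code{"optimal"}
#'   (Hungarian assignment maximizing total matched r above threshold).
#' @return a \code{similarity_result}: data frame \code{pairs} (one row per
#'   cross-stage pair with structure_r, matched flag, activation_r,
#'   activation_similar), data frame \code{modes} (the pairwise mode
#'   registry: mode id, presence in each stage), thresholds used.
#' @export
classify_modes <- function(clusters_a, clusters_b,
                           structure_threshold = NULL,
                           activation_threshold = 0.3,
                           method = c("greedy", "optimal")) {
  method <- match.arg(method)
  Wa <- cluster_weight_matrix(clusters_a)
  Wb <- cluster_weight_matrix(clusters_b)
  if (nrow(Wa) != nrow(Wb)) stop("stages disagree on muscle count")
  structure_threshold <- structure_threshold %||%
    critical_r(nrow(Wa) - 2L, 0.01)
  R <- cor(Wa, Wb)
  match_ab <- match_pairs(R, structure_threshold, method)
  Aa <- cluster_activation_matrix(clusters_a)
  Ab <- cluster_activation_matrix(clusters_b)
  pairs <- do.call(rbind, lapply(seq_len(ncol(Wa)), function(i) {
    do.call(rbind, lapply(seq_len(ncol(Wb)), function(j) {
      matched <- !is.na(match_ab[i]) && match_ab[i] == j
      act_r <- if (matched) pearson_similarity(Aa[, i], Ab[, j]) else NA_real_
      data.frame(cluster_a = i, cluster_b = j, structure_r = R[i, j],
                 matched = matched, activation_r = act_r,
                 activation_similar = if (matched)
                   act_r > activation_threshold else NA)
    }))
  }))
  modes <- build_pairwise_registry(match_ab, ncol(Wa), ncol(Wb), R)
  structure(list(pairs = pairs, modes = modes,
                 structure_threshold = structure_threshold,
                 activation_threshold = activation_threshold,
                 stage_a = attr(clusters_a, "stage_label"),
                 stage_b = attr(clusters_b, "stage_label")),
            class = "similarity_result")
}

# Greedy or Hungarian-style one-to-one matching on a correlation matrix;
# returns for each row the matched column index or NA.
match_pairs <- function(R, threshold, method = "greedy") {
  na <- nrow(R)
  nb <- ncol(R)
  out <- rep(NA_integer_, na)
  if (method == "greedy") {
    cand <- which(R > threshold, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(R[cand], decreasing = TRUE)
      used_b <- logical(nb)
      for (idx in ord) {
        i <- cand[idx, 1]
        j <- cand[idx, 2]
        if (is.na(out[i]) && !used_b[j]) {
          out[i] <- j
          used_b[j] <- TRUE
        }
      }
    }
  } else {
    # exhaustive assignment on the (small) cluster counts seen here
    best <- -Inf
    best_assign <- out
    cols <- seq_len(nb)
    rec <- function(i, avail, cur, total) {
      if (i > na) {
        if (total > best) {
          best <<- total
          best_assign <<- cur
        }
        return()
      }
      rec(i + 1L, avail, { x <- cur; x[i] <- NA_integer_; x }, total)
      for (j in avail) {
        if (R[i, j] > threshold)
          rec(i + 1L, setdiff(avail, j),
              { x <- cur; x[i] <- j; x }, total + R[i, j])
      }
    }
    rec(1L, cols, out, 0)
    out <- best_assign
  }
  out
}

build_pairwise_registry <- function(match_ab, na, nb, R) {
  rows <- list()
  mid <- 0L
  for (i in seq_len(na)) {
    mid <- mid + 1L
    j <- match_ab[i]
    rows[[mid]] <- data.frame(
      mode_id = mid, cluster_a = i, cluster_b = ifelse(is.na(j), NA, j),
      common = !is.na(j),
      structure_r = ifelse(is.na(j), NA_real_, R[i, ifelse(is.na(j), 1L, j)]))
  }
  for (j in setdiff(seq_len(nb), match_ab[!is.na(match_ab)])) {
    mid <- mid + 1L
    rows[[mid]] <- data.frame(mode_id = mid, cluster_a = NA_integer_,
                              cluster_b = j, common = FALSE,
                              structure_r = NA_real_)
  }
  do.call(rbind, rows)
}

#' @export
print.similarity_result <- function(x, ...) {
  nmatch <- sum(x$modes$common)
  cat(sprintf("<similarity_result> %s vs %s: %d matched mode(s), %d unique\n",
              x$stage_a %||% "A", x$stage_b %||% "B", nmatch,
              nrow(x$modes) - nmatch))
  m <- x$pairs[x$pairs$matched, ]
  if (nrow(m)) {
    for (r in seq_len(nrow(m)))
      cat(sprintf("  A%d ~ B%d  structure r = %.3f, activation r = %.3f%s\n",
                  m$cluster_a[r], m$cluster_b[r], m$structure_r[r],
                  m$activation_r[r],
                  ifelse(m$activation_similar[r], "", " (activation differs)")))
  }
  invisible(x)
}

#' Per-subject synergy numbers across stages
#'
#' Tabulates each subject's selected synergy number per stage, the paired
#' differences between stages, and a paired Wilcoxon signed-rank test per
#' stage pair.
#'
#' @param fits_by_stage named list (stage -> list of \code{synergy_fit}s);
#'   every stage must cover the same subjects.
#' @return a \code{synergy_counts}: data frame \code{counts}
#'   (subject x stage), data frame \code{summary} (stage mean, sd), data
#'   frame \code{comparisons} (stage pair, mean paired difference, Wilcoxon
#'   p).
#' @export
count_synergy_numbers <- function(fits_by_stage) {
  stages <- names(fits_by_stage)
  if (is.null(stages) || length(stages) < 1L)
    stop("supply a named list of stages")
  per_stage <- lapply(fits_by_stage, function(fl) {
    stats::setNames(vapply(fl, function(f) as.integer(f$k), integer(1)),
                    vapply(fl, `[[`, "", "subject_id"))
  })
  subj <- sort(names(per_stage[[1L]]))
  for (st in stages)
    if (!identical(sort(names(per_stage[[st]])), subj))
      stop("stages cover different subjects")
  counts <- data.frame(subject_id = subj)
  for (st in stages) counts[[st]] <- per_stage[[st]][subj]
  summ <- data.frame(
    stage = stages,
    mean = vapply(stages, function(st) mean(counts[[st]]), 0),
    sd = vapply(stages, function(st) sd(counts[[st]]), 0))
  comps <- NULL
  if (length(stages) > 1L && length(subj) > 1L) {
    cmb <- utils::combn(stages, 2L)
    comps <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- counts[[cmb[1L, i]]]
      b <- counts[[cmb[2L, i]]]
      d <- b - a
      p <- if (all(d == 0)) 1 else
        suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
      data.frame(stage_a = cmb[1L, i], stage_b = cmb[2L, i],
                 mean_diff = mean(d), sd_diff = sd(d), p_wilcoxon = p)
    }))
  }
  structure(list(counts = counts, summary = summ, comparisons = comps),
            class = "synergy_counts")
}

#' @export
print.synergy_counts <- function(x, digits = 2, ...) {
  cat("<synergy_counts>\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: %.1f +/- %.1f synergies\n", x$summary$stage[i],
                x$summary$mean[i], x$summary$sd[i]))
  if (!is.null(x$comparisons))
    for (i in seq_len(nrow(x$comparisons)))
      cat(sprintf("  %s vs %s: mean diff %+.2f (Wilcoxon p = %.3g)\n",
                  x$comparisons$stage_a[i], x$comparisons$stage_b[i],
                  x$comparisons$mean_diff[i], x$comparisons$p_wilcoxon[i]))
  invisible(x)
}

#' Global mode registry across all stages
#'
#' Chains the pairwise matchings of every stage pair into connected
#' components: clusters linked (directly or transitively) by accepted matches
#' share one global mode id; modes present in a single stage are unique
#' modes.
#'
#' @param clusterings named list (stage -> \code{mode_clustering}).
#' @param structure_threshold,activation_threshold,method as in
#'   \code{\link{classify_modes}}.
#' @return list: data frame \code{registry} (mode_id, one presence column per
#'   stage holding the member cluster id or NA, n_stages), and the pairwise
#'   \code{similarity_result}s.
#' @export
build_mode_registry <- function(clusterings, structure_threshold = NULL,
                                activation_threshold = 0.3,
                                method = "greedy") {
  stages <- names(clusterings)
  nodes <- unlist(lapply(stages, function(st)
    paste0(st, ":", seq_along(clusterings[[st]]))), use.names = FALSE)
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  union_ <- function(a, b) parent[[find(a)]] <<- find(b)
  pairwise <- list()
  if (length(stages) > 1L) {
    cmb <- utils::combn(stages, 2L)
    for (i in seq_len(ncol(cmb))) {
      sa <- cmb[1L, i]; sb <- cmb[2L, i]
      res <- classify_modes(clusterings[[sa]], clusterings[[sb]],
                            structure_threshold, activation_threshold,
                            method)
      pairwise[[paste(sa, sb, sep = "_vs_")]] <- res
      m <- res$modes[res$modes$common, , drop = FALSE]
      for (r in seq_len(nrow(m)))
        union_(paste0(sa, ":", m$cluster_a[r]),
               paste0(sb, ":", m$cluster_b[r]))
    }
  }
  roots <- vapply(nodes, find, "")
  comp <- split(nodes, roots)
  # order: multi-stage (common) modes first, then unique
  comp <- comp[order(-vapply(comp, length, 0L))]
  registry <- do.call(rbind, lapply(seq_along(comp), function(mid) {
    members <- comp[[mid]]
    row <- data.frame(mode_id = mid)
    for (st in stages) {
      hit <- grep(paste0("^", st, ":"), members, value = TRUE)
      row[[st]] <- if (length(hit)) as.integer(sub(".*:", "", hit[1L]))
                   else NA_integer_
    }
    row$n_stages <- sum(!is.na(row[stages]))
    row
  }))
  list(registry = registry, pairwise = pairwise)
}
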