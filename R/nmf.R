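#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative muscles x bins matrix as \code{M ~ W C} with
#' \code{W, C >= 0}, minimizing the squared Frobenius reconstruction error by
#' Lee-Seung multiplicative updates. The factorization is restarted from
#' \code{restarts} random nonnegative initializations and the best (lowest
#' SSE) solution is kept; given the same seed the result is deterministic.
#' Columns of \code{W} are normalized to unit Euclidean norm with the scale
#' pushed into the rows of \code{C}.
#'
#' @param m an \code{emg_matrix} or nonnegative numeric matrix.
#' @param k number of synergies (1 <= k <= number of muscles).
#' @param restarts number of random restarts (default 20).
#' @param seed integer seed controlling all initializations.
#' @param tol relative SSE change (checked every 10 iterations) below which a
#'   run stops.
#' @param max_iter iteration cap per restart.
#' @return list with \code{W} (muscles x k, unit-norm columns), \code{C}
#'   (k x bins), \code{sse}, \code{restarts_used}, \code{iterations} of the
#'   winning run.
#' @export
run_nmf <- function(m, k, restarts = 20L, seed = 1L, tol = 1e-6,
                    max_iter = 1000L) {
  M <- if (inherits(m, "emg_matrix")) m$values else as.matrix(m)
  if (any(!is.finite(M))) stop("input matrix must be finite")
  if (any(M < 0)) stop("input matrix must be nonnegative")
  stopifnot_scalar_count(k, "k", 1L)
  if (k > nrow(M)) stop("k cannot exceed the number of muscles")
  stopifnot_scalar_count(restarts, "restarts", 1L)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- nmf_single_run(M, k, tol, max_iter)
      if (is.null(best) || fit$sse < best$sse) {
        best <- fit
        best$restarts_used <- r
      }
    }
  })
  # unit-norm columns of W; compensate in C
  norms <- sqrt(colSums(best$W^2))
  norms[norms == 0] <- 1
  best$W <- sweep(best$W, 2, norms, "/")
  best$C <- best$C * norms
  rownames(best$W) <- rownames(M)
  best$restarts_used <- restarts
  best
}

nmf_single_run <- function(M, k, tol, max_iter) {
  eps <- .Machine$double.eps
  nm <- nrow(M)
  nb <- ncol(M)
  scale0 <- sqrt(mean(M) / k + eps)
  W <- matrix(runif(nm * k, 0.2, 1), nm, k) * scale0
  C <- matrix(runif(k * nb, 0.2, 1), k, nb) * scale0
  sse_prev <- Inf
  it_done <- max_iter
  for (it in seq_len(max_iter)) {
    C <- C * crossprod(W, M) / (crossprod(W) %*% C + eps)
    W <- W * tcrossprod(M, C) / (W %*% tcrossprod(C) + eps)
    if (it %% 10L == 0L) {
      sse <- sum((M - W %*% C)^2)
      if (is.finite(sse_prev) &&
          abs(sse_prev - sse) <= tol * max(sse_prev, eps)) {
        it_done <- it
        break
      }
      sse_prev <- sse
    }
  }
  list(W = W, C = C, sse = sum((M - W %*% C)^2), iterations = it_done)
}

#' Variance accounted for by a factorization
#'
#' Uncentered by default: \code{1 - sum((M - WC)^2) / sum(M^2)}, the dominant
#' convention in the synergy literature; \code{centered = TRUE} subtracts row
#' means first. \code{vaf_per_muscle} restricts the same ratio to each muscle
#' row.
#'
#' @param m an \code{emg_matrix} or matrix.
#' @param W,C factor matrices.
#' @param centered use centered sums of squares.
#' @return \code{vaf_overall}: a single fraction. \code{vaf_per_muscle}: one
#'   fraction per muscle row.
#' @export
vaf_overall <- function(m, W, C, centered = FALSE) {
  M <- if (inherits(m, "emg_matrix")) m$values else as.matrix(m)
  R <- M - W %*% C
  if (centered) M <- M - rowMeans(M)
  denom <- sum(M^2)
  if (denom == 0) stop("matrix has zero energy; VAF undefined")
  1 - sum(R^2) / denom
}

#' @rdname vaf_overall
#' @export
vaf_per_muscle <- function(m, W, C, centered = FALSE) {
  M <- if (inherits(m, "emg_matrix")) m$values else as.matrix(m)
  R <- M - W %*% C
  Md <- if (centered) M - rowMeans(M) else M
  denom <- rowSums(Md^2)
  bad <- which(denom == 0)
  if (length(bad))
    stop(sprintf("muscle row(s) %s have zero energy; per-muscle VAF undefined",
                 paste(rownames(M)[bad] %||% bad, collapse = ", ")))
  stats::setNames(1 - rowSums(R^2) / denom, rownames(M))
}
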