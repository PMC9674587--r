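# Independent brute-force oracles, kept deliberately naive: elementwise loops
# and exhaustive enumeration, no shared code with the package internals.

# Uncentered variance accounted for, computed with explicit loops.
vaf_oracle <- function(M, W, C) {
  R <- M
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(ncol(M))) {
      pred <- 0
      for (k in seq_len(ncol(W))) pred <- pred + W[i, k] * C[k, j]
      R[i, j] <- M[i, j] - pred
    }
  }
  ss_res <- 0
  ss_tot <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    ss_res <- ss_res + R[i, j]^2
    ss_tot <- ss_tot + M[i, j]^2
  }
  1 - ss_res / ss_tot
}

vaf_per_muscle_oracle <- function(M, W, C) {
  sapply(seq_len(nrow(M)), function(i)
    vaf_oracle(M[i, , drop = FALSE], W[i, , drop = FALSE], C))
}

# NNLS by exhaustive active-set enumeration: solve the unconstrained LS on
# every support subset, keep the feasible (coef >= 0) solution with the
# smallest residual. Exact for small basis counts.
nnls_oracle <- function(A, b) {
  m <- ncol(A)
  best <- list(x = rep(0, m), rss = sum(b^2))
  for (mask in seq_len(2^m - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    xs <- tryCatch(solve(crossprod(As), crossprod(As, b)),
                   error = function(e) NULL)
    if (is.null(xs) || any(xs < 0)) next
    rss <- sum((b - As %*% xs)^2)
    if (rss < best$rss - 1e-12) {
      x <- rep(0, m)
      x[S] <- xs
      best <- list(x = x, rss = rss)
    }
  }
  best
}

# Partition equality up to cluster relabeling: compare as sets of member sets.
same_partition <- function(members_a, members_b) {
  key <- function(m) sort(vapply(m, function(df)
    paste(sort(paste(df$subject_id, df$synergy_index)), collapse = ";"), ""))
  identical(key(members_a), key(members_b))
}
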