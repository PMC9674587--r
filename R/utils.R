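#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded package internals never disturb a
#' user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Normalize a nonnegative vector to unit Euclidean norm
#' @param w numeric vector.
#' @return \code{w / sqrt(sum(w^2))}.
#' @keywords internal
unit_norm <- function(w) {
  n <- sqrt(sum(w^2))
  if (n == 0) stop("cannot normalize an all-zero vector")
  w / n
}

# Derive a bounded child seed from a master seed and an index; stays < 2^31.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1009) %% 2147483647L)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}
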