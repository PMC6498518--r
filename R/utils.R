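#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library functions never clobber the caller's
#' random stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed and a label path
#'
#' One global seed deterministically yields per-stage / per-subject sub-seeds,
#' so partial re-runs reproduce the full run's results. The fold is a simple
#' multiplicative hash kept below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed master integer seed
#' @param ... character or numeric labels identifying the stage/subject
#' @return an integer seed in [1, 2^31 - 2]
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.numeric(seed) %% m
  for (tok in list(...)) {
    for (v in utf8ToInt(paste0(as.character(tok), collapse = "|"))) {
      h <- (h * 69069 + v) %% m
    }
  }
  as.integer(h %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# index pairs (i < j) of the upper triangle of an n x n matrix, column-wise
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
sym_from_upper <- function(v, n, labels = NULL) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- v
  m + t(m)
}

stopifnot_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop(what, " must be a numeric matrix")
  if (any(!is.finite(x))) stop(what, " contains NaN/Inf values")
  invisible(x)
}
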