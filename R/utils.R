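## Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs \code{code} with the RNG seeded to \code{seed}, then restores the
#' caller's RNG state, so seeded operations never perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a parent seed and a counter
#'
#' Counter-based expansion of one pipeline seed into per-stage /
#' per-replicate seeds, so any stage can be re-run in isolation and still
#' reproduce. All arithmetic stays below 2^31 - 1.
#'
#' @param seed parent integer seed.
#' @param index non-negative counter (stage or replicate number).
#' @return an integer seed in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, index) {
  m <- 2147483647          # 2^31 - 1, prime (Lehmer modulus)
  s <- (as.numeric(seed) %% m) + 1
  x <- (s * 48271) %% m
  x <- (x + (as.numeric(index) %% m) * 69621) %% m
  as.integer((x %% (m - 1)) + 1)
}

## Symmetry check up to floating noise
isSymmetricZeroDiag <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    all(abs(m - t(m)) <= tol) && all(diag(m) == 0)
}

## Upper-triangle index helper: returns two-column matrix of (i, j), i < j,
## in column-major (lexicographic by j then i) order matching upper.tri().
upperPairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

## Trapezoidal integral of y over x
trapezoid <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
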