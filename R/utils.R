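# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded simulation helpers never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# trapezoidal integral of y sampled at (possibly non-uniform) x
trapz <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# symmetric eigen pseudo-inverse with relative truncation of small eigenvalues
pinv_sym <- function(A, rtol = 1e-12) {
  e <- eigen(A, symmetric = TRUE)
  lmax <- max(abs(e$values), 0)
  if (lmax == 0) return(matrix(0, nrow(A), ncol(A)))
  keep <- e$values > rtol * lmax
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}
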