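# Shared helpers: upper-triangle indexing, seed spawning, validation.

#' Upper-triangle index pairs of an n x n matrix
#'
#' Returns the (i, j) pairs with i < j in column-major order, i.e. the order
#' produced by `m[upper.tri(m)]`.
#'
#' @param n Number of nodes.
#' @return Two-column integer matrix with columns `i`, `j`.
#' @keywords internal
ut_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

#' Vectorize the upper triangle of a symmetric matrix
#' @param m Square matrix.
#' @return Numeric vector in `upper.tri` order.
#' @keywords internal
ut_vec <- function(m) m[upper.tri(m)]

#' Rebuild a symmetric matrix from its upper-triangle vector
#' @param v Upper-triangle vector in `upper.tri` order.
#' @param n Matrix dimension.
#' @return Symmetric matrix with zero diagonal.
#' @keywords internal
ut_unvec <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Deterministically spawn sub-seeds from one master seed
#'
#' One global seed drives every stochastic stage; each stage receives its own
#' sub-seed so stages stay reproducible independently of execution order.
#'
#' @param seed Master seed (integer).
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @export
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

stop_if_not_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  }
}

check_symmetric <- function(m, tol = 1e-10, what = "matrix") {
  stop_if_not_square(m, what)
  if (max(abs(m - t(m))) > tol) {
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
  }
}
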