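# Timepoint-consistency diagnostics of structural-connectivity signatures.
# Computed on the thresholded (post-mask) matrices, the same stage at which
# all downstream statistics operate.

#' Average correlations on the Fisher-Z scale
#'
#' Correlations are atanh-transformed, averaged, and transformed back with
#' tanh. Values with |r| = 1 are infinite on the z scale; they are clipped
#' to `1 - clip` (with a warning) when `clip` is positive, rejected
#' otherwise.
#'
#' @param rs Numeric vector of correlations in \[-1, 1\].
#' @param clip Clipping margin for |r| = 1 (default 1e-12); set to 0 to
#'   reject perfect correlations instead.
#' @return Single correlation on the r scale.
#' @export
fisher_z_mean <- function(rs, clip = 1e-12) {
  if (!length(rs)) stop("empty correlation list", call. = FALSE)
  if (any(abs(rs) > 1)) stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (any(abs(rs) == 1)) {
    if (clip <= 0) stop("|r| = 1 is infinite on the z scale", call. = FALSE)
    warning("perfect correlation clipped before Fisher-Z averaging")
    rs <- sign(rs) * pmin(abs(rs), 1 - clip)
  }
  tanh(mean(atanh(rs)))
}

# upper-triangle vectors of a list of matrices, as columns
ut_cols <- function(mats) {
  n <- nrow(mats[[1]])
  vapply(mats, ut_vec, numeric(n * (n - 1) / 2))
}

#' Within-timepoint consistency (subject vs timepoint mean)
#'
#' Pearson correlation between each subject's upper-triangle connectivity
#' vector and the element-wise timepoint mean, pooled across subjects on the
#' Fisher-Z scale.
#'
#' @param mats List of subject matrices at one timepoint.
#' @return List with `tc1` (pooled correlation) and `per_subject`
#'   (individual correlations).
#' @export
tc_within <- function(mats) {
  stopifnot(length(mats) >= 2)
  w <- ut_cols(mats)
  mu <- rowMeans(w)
  if (stats::sd(mu) == 0) stop("zero-variance mean vector", call. = FALSE)
  rs <- apply(w, 2, function(col) {
    if (stats::sd(col) == 0) stop("zero-variance subject vector",
                                  call. = FALSE)
    stats::cor(col, mu)
  })
  list(tc1 = fisher_z_mean(rs), per_subject = rs)
}

#' Pairwise inter-subject consistency
#'
#' All m(m-1)/2 Pearson correlations between subjects' upper-triangle
#' connectivity vectors. With `pool_timepoints = TRUE` the matrices of both
#' timepoints enter one pool, so pairs span timepoints (the inter-timepoint
#' variant).
#'
#' @param mats List of subject matrices, or (when pooling) a list with the
#'   matrices of both timepoints concatenated.
#' @param breaks Histogram breaks over \[0.5, 1\] (default 50 bins).
#' @return List with `correlations` (vector of pairwise r), `n_pairs`, and
#'   `histogram` (a `hist` object).
#' @export
tc_pairwise <- function(mats, breaks = seq(0.5, 1, length.out = 51)) {
  stopifnot(length(mats) >= 2)
  w <- ut_cols(mats)
  if (any(apply(w, 2, stats::sd) == 0)) {
    stop("zero-variance subject vector", call. = FALSE)
  }
  cm <- stats::cor(w)
  rs <- cm[upper.tri(cm)]
  brk <- breaks
  if (length(brk) > 1) {
    rng <- range(rs)
    if (rng[1] < min(brk) || rng[2] > max(brk)) {
      brk <- seq(min(rng[1], min(brk)), max(rng[2], max(brk)),
                 length.out = length(breaks))
    }
  }
  list(correlations = rs,
       n_pairs = length(rs),
       histogram = graphics::hist(rs, breaks = brk, plot = FALSE))
}

#' Full timepoint-consistency report
#'
#' @param built Built cohort from [build_connectomes()].
#' @return List with per-timepoint within-consistency, per-timepoint and
#'   pooled pairwise distributions, and pair counts; serializable to JSON.
#' @export
consistency_report <- function(built) {
  w1 <- tc_within(built$t1)
  w2 <- tc_within(built$t2)
  p1 <- tc_pairwise(built$t1)
  p2 <- tc_pairwise(built$t2)
  pool <- tc_pairwise(c(built$t1, built$t2))
  list(
    tc1 = c(t1 = w1$tc1, t2 = w2$tc1),
    tc1_per_subject = list(t1 = w1$per_subject, t2 = w2$per_subject),
    tc2 = list(t1 = p1, t2 = p2, pooled = pool),
    n_pairs = c(t1 = p1$n_pairs, t2 = p2$n_pairs, pooled = pool$n_pairs)
  )
}
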