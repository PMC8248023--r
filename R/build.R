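# Connectome construction: normalization, symmetrization, absolute weight
# threshold, group consistency-based thresholding, and the diagnostics that
# validate the mask. The fixed order of operations is:
#   waytotal-normalize -> individual-max normalize -> symmetrize ->
#   absolute weight threshold (fraction of strongest connection) ->
#   group consistency mask.

#' Construct a subject connectome from raw streamline counts
#'
#' Normalizes each row of the directed count matrix by the region's waytotal
#' (total streamlines generated from that seed and not rejected by masks),
#' divides by the individual's maximum value so entries lie in \[0, 1\], and
#' symmetrizes by averaging the two directed connection probabilities
#' P_ij and P_ji.
#'
#' @param raw n x n non-negative count matrix (rows = seed regions).
#' @param waytotals Positive n-vector of per-seed waytotals.
#' @return Symmetric n x n matrix with zero diagonal and entries in \[0, 1\].
#'   If the input is all zero, an all-zero matrix is returned with a warning
#'   and attribute `degenerate = TRUE`.
#' @export
normalize_sc <- function(raw, waytotals) {
  stop_if_not_square(raw, "raw count matrix")
  stopifnot(length(waytotals) == nrow(raw))
  if (any(raw < 0)) stop("raw counts must be non-negative", call. = FALSE)
  if (any(waytotals <= 0)) stop("waytotals must be positive", call. = FALSE)
  p <- raw / waytotals                 # divides each row i by waytotals[i]
  mx <- max(p)
  if (mx == 0) {
    warning("all-zero connectome: individual maximum is 0")
    out <- matrix(0, nrow(raw), ncol(raw))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p <- p / mx
  p <- (p + t(p)) / 2
  diag(p) <- 0
  dimnames(p) <- dimnames(raw)
  p
}

#' Remove connections weaker than a fraction of the strongest one
#'
#' @param connectome Symmetric weight matrix.
#' @param fraction Threshold as a fraction of the maximum weight
#'   (default 0.01, i.e. 1% of the strongest connection).
#' @return Matrix with entries below `fraction * max(weights)` zeroed.
#' @export
apply_weight_threshold <- function(connectome, fraction = 0.01) {
  stopifnot(fraction >= 0, fraction < 1)
  check_symmetric(connectome, what = "connectome")
  cut <- fraction * max(connectome)
  connectome[connectome < cut] <- 0
  connectome
}

#' Group consistency-based threshold mask
#'
#' Scores every edge by its consistency across subjects — the inverse
#' coefficient of variation (mean / SD) of its weight, counting the edge as
#' weight 0 in subjects where it is absent — and keeps the most consistent
#' edges up to the target density. Edges never observed (cross-subject mean
#' 0) are not eligible. Ties are broken by higher mean weight, then by
#' lexicographic (i, j) order, so the mask is deterministic.
#'
#' @param cohort List of symmetric weight matrices (one per subject, or per
#'   subject-timepoint when pooling timepoints).
#' @param target_density Fraction of the `n(n-1)/2` possible edges to keep
#'   (default 0.30).
#' @return List of class `consistency_mask` with elements `mask` (binary
#'   symmetric matrix), `target_density`, `achieved_density`, `n_edges`, and
#'   `consistency` (symmetric matrix of mean/SD scores, `Inf` where SD = 0
#'   and the mean is positive).
#' @export
consistency_mask <- function(cohort, target_density = 0.30) {
  stopifnot(length(cohort) >= 2, target_density > 0, target_density <= 1)
  n <- nrow(cohort[[1]])
  for (m in cohort) {
    stop_if_not_square(m)
    if (nrow(m) != n) stop("subjects must share one node set", call. = FALSE)
  }
  w <- vapply(cohort, ut_vec, numeric(n * (n - 1) / 2))
  mu <- rowMeans(w)
  sdv <- apply(w, 1, stats::sd)
  score <- ifelse(mu > 0, ifelse(sdv > 0, mu / sdv, Inf), -Inf)
  pairs <- ut_pairs(n)
  n_possible <- nrow(pairs)
  n_target <- round(target_density * n_possible)
  # rank: consistency desc, mean desc, then (i, j) asc
  ord <- order(-score, -mu, pairs[, 1], pairs[, 2])
  eligible <- which(mu[ord] > 0)
  keep_ord <- ord[eligible[seq_len(min(n_target, length(eligible)))]]
  if (length(keep_ord) < n_target) {
    warning(sprintf(
      "only %d edges ever observed; achieved density %.4f < target %.4f",
      length(keep_ord), length(keep_ord) / n_possible, target_density))
  }
  mv <- numeric(n_possible)
  mv[keep_ord] <- 1
  mask <- ut_unvec(mv, n)
  structure(list(
    mask = mask,
    consistency = ut_unvec(score, n),
    target_density = target_density,
    achieved_density = sum(mv) / n_possible,
    n_edges = as.integer(sum(mv))
  ), class = "consistency_mask")
}

#' Apply a binary mask to a connectome
#'
#' @param connectome Symmetric weight matrix.
#' @param mask A `consistency_mask` or a binary matrix of the same shape.
#' @return Elementwise product.
#' @export
apply_mask <- function(connectome, mask) {
  m <- if (inherits(mask, "consistency_mask")) mask$mask else mask
  if (!all(dim(connectome) == dim(m))) {
    stop("connectome and mask shapes differ", call. = FALSE)
  }
  connectome * m
}

#' Diagnostics for the consistency-based threshold
#'
#' For each subject: the fraction (and weight histogram) of its connections
#' removed by the mask, and the fraction (and weight histogram) of mask
#' edges absent from the subject — absences measured relative to the mask's
#' edge count.
#'
#' @param cohort List of subject matrices the mask was computed from.
#' @param mask `consistency_mask` (or binary matrix).
#' @param breaks Histogram breaks passed to [hist()] (default 30).
#' @return Data frame with one row per subject: `n_present`, `n_removed`,
#'   `removed_fraction`, `n_absent`, `absent_fraction`; histograms attached
#'   as attributes `removed_hist` and `absent_hist` (lists of `hist`
#'   objects).
#' @export
threshold_diagnostics <- function(cohort, mask, breaks = 30) {
  m <- if (inherits(mask, "consistency_mask")) mask$mask else mask
  mv <- ut_vec(m) > 0
  n_mask <- sum(mv)
  rows <- vector("list", length(cohort))
  rem_h <- abs_h <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    wv <- ut_vec(cohort[[s]])
    present <- wv > 0
    removed <- present & !mv
    absent <- mv & !present
    rows[[s]] <- data.frame(
      subject = s,
      n_present = sum(present),
      n_removed = sum(removed),
      removed_fraction = if (sum(present)) sum(removed) / sum(present) else 0,
      n_absent = sum(absent),
      absent_fraction = if (n_mask) sum(absent) / n_mask else 0
    )
    rem_h[[s]] <- if (any(removed)) {
      graphics::hist(wv[removed], breaks = breaks, plot = FALSE)
    }
    abs_h[[s]] <- if (any(absent)) {
      graphics::hist(wv[absent], breaks = breaks, plot = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "removed_hist") <- rem_h
  attr(out, "absent_hist") <- abs_h
  out
}

#' Classify an edge by hemisphere membership of its endpoints
#'
#' Uses the interleaved atlas convention: odd 1-based region index = left
#' hemisphere, even = right.
#'
#' @param i,j 1-based region indices (vectors allowed, recycled pairwise).
#' @param n_nodes Number of atlas regions (default 90).
#' @return Character vector with values `"intra-left"`, `"intra-right"` or
#'   `"inter-hemispheric"`.
#' @export
classify_edge_hemisphere <- function(i, j, n_nodes = 90L) {
  if (any(i < 1 | i > n_nodes | j < 1 | j > n_nodes)) {
    stop("region index out of range", call. = FALSE)
  }
  li <- i %% 2 == 1
  lj <- j %% 2 == 1
  ifelse(li & lj, "intra-left",
         ifelse(!li & !lj, "intra-right", "inter-hemispheric"))
}

#' Build all subject connectomes for a cohort and both timepoints
#'
#' Runs the full construction chain (normalize, weight-threshold,
#' consistency mask) over a raw cohort. The consistency mask is computed
#' either pooled over all subject-timepoints (default; guarantees a common
#' edge support for paired tests) or per timepoint.
#'
#' @param cohort Raw cohort as from [generate_cohort()] or [read_cohort()].
#' @param weight_fraction Absolute threshold fraction (default 0.01).
#' @param mask_density Consistency-mask target density (default 0.30).
#' @param mask_mode `"pooled"` (one mask across timepoints) or
#'   `"per-timepoint"`.
#' @return List with `t1`, `t2` (lists of masked subject matrices),
#'   `mask` (pooled) or `mask_t1`/`mask_t2`, and `subjects`.
#' @export
build_connectomes <- function(cohort, weight_fraction = 0.01,
                              mask_density = 0.30,
                              mask_mode = c("pooled", "per-timepoint")) {
  mask_mode <- match.arg(mask_mode)
  subjects <- names(cohort$counts)
  pre <- list(t1 = list(), t2 = list())
  for (s in subjects) {
    for (tp in 1:2) {
      sc <- normalize_sc(cohort$counts[[s]][[tp]],
                         cohort$waytotals[[s]][[tp]])
      sc <- apply_weight_threshold(sc, weight_fraction)
      pre[[tp]][[s]] <- sc
    }
  }
  if (mask_mode == "pooled") {
    # one mask for both timepoints, from cross-subject consistency of the
    # subject-mean matrices: averaging the two timepoints first keeps a
    # genuine longitudinal change from masquerading as inconsistency,
    # while still guaranteeing a common edge support for paired tests
    subj_mean <- Map(function(a, b) (a + b) / 2, pre$t1, pre$t2)
    msk <- consistency_mask(subj_mean, mask_density)
    out <- list(
      t1 = lapply(pre$t1, apply_mask, mask = msk),
      t2 = lapply(pre$t2, apply_mask, mask = msk),
      mask = msk, subjects = subjects)
  } else {
    m1 <- consistency_mask(pre$t1, mask_density)
    m2 <- consistency_mask(pre$t2, mask_density)
    out <- list(
      t1 = lapply(pre$t1, apply_mask, mask = m1),
      t2 = lapply(pre$t2, apply_mask, mask = m2),
      mask_t1 = m1, mask_t2 = m2, subjects = subjects)
  }
  out$unmasked <- pre
  out
}
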