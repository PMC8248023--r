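# Paired network-based statistics.
#
# Edges are tested with a paired t statistic over within-subject
# differences (F = t^2); supra-threshold edges are collected into connected
# components, and component extent (edge count) is referred to a null
# distribution of maximal component sizes obtained by random sign-flips of
# each subject's difference matrix — the exact permutation scheme for a
# paired exchangeable design. Component p-values carry the +1 correction,
# so they are never zero and the procedure is (slightly) conservative.

#' Pair a built cohort for longitudinal edge-wise testing
#'
#' Collects, for the edges present in the common group mask, the subject x
#' edge matrices of connectivity at each timepoint and their differences.
#'
#' @param built Built cohort from [build_connectomes()] (pooled mask mode,
#'   or per-timepoint masks whose intersection defines the tested edges).
#' @return List of class `cohort_pair`: `edges` (two-column index matrix),
#'   `sc1`, `sc2`, `d` (subjects x edges, `d = sc2 - sc1`), `n_nodes`,
#'   `subjects`.
#' @export
cohort_pair <- function(built) {
  if (!is.null(built$mask)) {
    maskm <- built$mask$mask
  } else {
    maskm <- built$mask_t1$mask * built$mask_t2$mask
  }
  n <- nrow(maskm)
  keep <- which(ut_vec(maskm) > 0)
  pairs <- ut_pairs(n)[keep, , drop = FALSE]
  grab <- function(mats) t(vapply(mats, function(m) ut_vec(m)[keep],
                                  numeric(length(keep))))
  sc1 <- grab(built$t1)
  sc2 <- grab(built$t2)
  structure(list(edges = pairs, sc1 = sc1, sc2 = sc2, d = sc2 - sc1,
                 n_nodes = n, subjects = built$subjects),
            class = "cohort_pair")
}

# column-wise paired t^2 for a difference matrix (subjects x edges);
# sumsq is invariant under sign flips, so it can be precomputed
paired_f_cols <- function(d, sumsq = colSums(d^2)) {
  ns <- nrow(d)
  m <- colMeans(d)
  v <- (sumsq - ns * m^2) / (ns - 1)
  f <- ifelse(v > 0, ns * m^2 / v, ifelse(m == 0, 0, Inf))
  f
}

#' Edge-wise paired F statistics
#'
#' Paired t over within-subject differences at every tested edge, returned
#' as F = t^2 in matrix form (zero outside the mask). Edges with
#' zero-variance nonzero differences get `Inf` with a warning.
#'
#' @param cp A [cohort_pair()].
#' @return Symmetric n x n matrix of F values.
#' @export
edgewise_paired_f <- function(cp) {
  stopifnot(inherits(cp, "cohort_pair"), nrow(cp$d) >= 3)
  f <- paired_f_cols(cp$d)
  if (any(is.infinite(f))) {
    warning("zero-variance nonzero differences: F set to Inf at ",
            sum(is.infinite(f)), " edge(s)")
  }
  fm <- matrix(0, cp$n_nodes, cp$n_nodes)
  fm[cp$edges] <- f
  fm[cp$edges[, c(2, 1), drop = FALSE]] <- f
  fm
}

# union-find on an edge index matrix; returns sizes (edge counts) and a
# component id per edge
edge_components <- function(edges, n) {
  storage.mode(edges) <- "integer"
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(edges[, 1], find, 0L)
  comp <- match(roots, unique(roots))
  list(comp = comp, sizes = tabulate(comp))
}

#' Connected components of supra-threshold edges
#'
#' @param f_matrix Symmetric matrix of edge statistics.
#' @param primary_threshold Edge-level cutoff (> 0); edges with
#'   `F > primary_threshold` enter the component graph.
#' @return List of components sorted by size (edge count) descending; each
#'   a list with `edges` (two-column index matrix), `f` (edge statistics)
#'   and `size`.
#' @export
extract_components <- function(f_matrix, primary_threshold) {
  stopifnot(primary_threshold > 0)
  stop_if_not_square(f_matrix, "F matrix")
  n <- nrow(f_matrix)
  supra <- which(upper.tri(f_matrix) & f_matrix > primary_threshold,
                 arr.ind = TRUE)
  if (!nrow(supra)) return(list())
  ec <- edge_components(supra, n)
  ord <- order(ec$sizes, decreasing = TRUE)
  lapply(ord, function(ci) {
    sel <- ec$comp == ci
    list(edges = supra[sel, , drop = FALSE],
         f = f_matrix[supra[sel, , drop = FALSE]],
         size = sum(sel))
  })
}

# max component size of supra-threshold edges (fast path for permutations)
max_component_size <- function(fv, edges, n, thr) {
  sel <- fv > thr
  if (!any(sel)) return(0L)
  e <- edges[sel, , drop = FALSE]
  if (nrow(e) == 1) return(1L)
  max(edge_components(e, n)$sizes)
}

#' Paired network-based statistics with permutation FWER control
#'
#' Observed components of supra-threshold paired-F edges are assigned
#' family-wise-error-corrected p-values by comparing their extent (edge
#' count) to the null distribution of the maximal component size under
#' random sign-flips of each subject's difference matrix:
#' `p = (1 + #\{null >= size\}) / (1 + n_perm)`.
#'
#' @param cp A [cohort_pair()].
#' @param primary_threshold Edge-level F cutoff.
#' @param n_perm Number of sign-flip permutations (default 5000).
#' @param alpha Corrected significance level (default 0.05).
#' @param seed Integer seed.
#' @return List of class `nbs_result`: `f_matrix`, `components` (each with
#'   `edges`, `size`, `p_fwer`, `significant`, per-edge mean differences and
#'   sign split), `null_max_size`, `primary_threshold`, `n_perm`, `alpha`,
#'   `seed`.
#' @export
nbs_paired <- function(cp, primary_threshold, n_perm = 5000, alpha = 0.05,
                       seed = 1L) {
  stopifnot(inherits(cp, "cohort_pair"), n_perm >= 100)
  if (n_perm < 1 / alpha - 1) {
    warning("n_perm too small to resolve alpha = ", alpha)
  }
  ns <- nrow(cp$d)
  sumsq <- colSums(cp$d^2)
  f_obs <- paired_f_cols(cp$d, sumsq)
  comps <- extract_components({
    fm <- matrix(0, cp$n_nodes, cp$n_nodes)
    fm[cp$edges] <- f_obs
    fm + t(fm)
  }, primary_threshold)

  set.seed(seed)
  # all sign patterns at once: permutation means are one matrix product,
  # and the per-edge sum of squares is invariant under sign flips
  s_mat <- matrix(sample(c(-1, 1), ns * n_perm, replace = TRUE), ns, n_perm)
  m_perm <- crossprod(cp$d, s_mat) / ns               # edges x perms
  v_perm <- (sumsq - ns * m_perm^2) / (ns - 1)
  f_perm <- ifelse(v_perm > 0, ns * m_perm^2 / v_perm,
                   ifelse(m_perm == 0, 0, Inf))
  supra <- f_perm > primary_threshold
  n_supra <- colSums(supra)
  null_max <- integer(n_perm)
  null_max[n_supra == 1L] <- 1L
  for (p in which(n_supra >= 2L)) {
    e <- cp$edges[supra[, p], , drop = FALSE]
    null_max[p] <- max(edge_components(e, cp$n_nodes)$sizes)
  }

  dbar <- colMeans(cp$d)
  comps <- lapply(comps, function(co) {
    idx <- match(paste(co$edges[, 1], co$edges[, 2]),
                 paste(cp$edges[, 1], cp$edges[, 2]))
    co$mean_diff <- dbar[idx]
    co$n_increase <- sum(co$mean_diff > 0)
    co$n_decrease <- sum(co$mean_diff < 0)
    co$p_fwer <- (1 + sum(null_max >= co$size)) / (1 + n_perm)
    co$significant <- co$p_fwer < alpha
    co
  })
  structure(list(
    f_matrix = {
      fm <- matrix(0, cp$n_nodes, cp$n_nodes)
      fm[cp$edges] <- f_obs
      fm + t(fm)
    },
    components = comps, null_max_size = null_max,
    primary_threshold = primary_threshold, n_perm = n_perm,
    alpha = alpha, seed = seed
  ), class = "nbs_result")
}

#' Census of components across a range of primary thresholds
#'
#' Also exposes the threshold-selection rule used downstream: the maximal
#' threshold at which exactly one component with more than two connections
#' is detected.
#'
#' @param cp A [cohort_pair()].
#' @param thresholds Ascending vector of primary thresholds.
#' @return Data frame (`threshold`, `n_components`, `largest_size`,
#'   `n_nodes`), with the selected threshold as attribute
#'   `selected_threshold` (NA when the rule never fires).
#' @export
threshold_sweep <- function(cp, thresholds) {
  stopifnot(!is.unsorted(thresholds))
  fm <- edgewise_paired_f(cp)
  rows <- lapply(thresholds, function(th) {
    comps <- extract_components(fm, th)
    big <- vapply(comps, `[[`, 0L, "size")
    data.frame(threshold = th,
               n_components = length(comps),
               largest_size = if (length(big)) max(big) else 0L,
               n_nodes = if (length(comps)) {
                 length(unique(unlist(lapply(comps, function(co)
                   as.vector(co$edges)))))
               } else 0L)
  })
  out <- do.call(rbind, rows)
  rule <- out$threshold[out$n_components == 1 & out$largest_size > 2]
  attr(out, "selected_threshold") <- if (length(rule)) max(rule) else NA_real_
  out
}

#' Sub-network mean-connectivity summaries for a component
#'
#' Per subject and timepoint, the mean connectivity of the component's
#' edges, stratified by the sign of the group-mean longitudinal difference
#' (all / increases / decreases) crossed with hemisphere class (all /
#' intra-left / intra-right / inter-hemispheric), plus the percent change of
#' the group means. Empty strata are omitted and flagged.
#'
#' @param cp A [cohort_pair()].
#' @param component One component from [nbs_paired()] (needs `edges` and
#'   `mean_diff`).
#' @return List with `subject_means` (data frame: subject, timepoint,
#'   network, hemisphere_class, mean_sc), `percent_change` (data frame:
#'   network, hemisphere_class, pct_change), and `empty_strata`.
#' @export
component_summaries <- function(cp, component) {
  stopifnot(nrow(component$edges) >= 1)
  ek <- paste(component$edges[, 1], component$edges[, 2])
  idx <- match(ek, paste(cp$edges[, 1], cp$edges[, 2]))
  if (any(is.na(idx))) stop("component edge outside tested set",
                            call. = FALSE)
  hemi <- classify_edge_hemisphere(component$edges[, 1],
                                   component$edges[, 2], cp$n_nodes)
  sign_grp <- ifelse(component$mean_diff > 0, "increases", "decreases")
  nets <- list(all = rep(TRUE, length(idx)),
               increases = sign_grp == "increases",
               decreases = sign_grp == "decreases")
  hemis <- list(all = rep(TRUE, length(idx)),
                `intra-left` = hemi == "intra-left",
                `intra-right` = hemi == "intra-right",
                `inter-hemispheric` = hemi == "inter-hemispheric")
  subj_rows <- list()
  pct_rows <- list()
  empty <- character()
  for (nn in names(nets)) {
    for (hh in names(hemis)) {
      sel <- idx[nets[[nn]] & hemis[[hh]]]
      stratum <- paste(nn, hh, sep = " / ")
      if (!length(sel)) {
        empty <- c(empty, stratum)
        next
      }
      m1 <- rowMeans(cp$sc1[, sel, drop = FALSE])
      m2 <- rowMeans(cp$sc2[, sel, drop = FALSE])
      subj_rows[[stratum]] <- data.frame(
        subject = rep(cp$subjects, 2),
        timepoint = rep(1:2, each = length(m1)),
        network = nn, hemisphere_class = hh,
        mean_sc = c(m1, m2))
      pct_rows[[stratum]] <- data.frame(
        network = nn, hemisphere_class = hh,
        pct_change = 100 * (mean(m2) - mean(m1)) / mean(m1))
    }
  }
  list(subject_means = do.call(rbind, c(subj_rows, make.row.names = FALSE)),
       percent_change = do.call(rbind, c(pct_rows,
                                         make.row.names = FALSE)),
       empty_strata = empty)
}
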