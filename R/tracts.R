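# White-matter tract attribution: which tract is responsible for each
# altered connection, from region x tract streamline-overlap matrices at
# the two timepoints.

#' Region x tract overlap from streamline density arrays
#'
#' Each region's streamline density array is thresholded at `max_fraction`
#' of its own maximum (removing spurious streamlines) and the mean value
#' over each tract mask's support is recorded. This is the fixture-scale
#' analogue of computing mean streamline counts inside atlas tract masks.
#'
#' @param densities List (one per region) of numeric arrays on a common
#'   grid.
#' @param tract_masks Named list of logical arrays on the same grid.
#' @param max_fraction Per-region threshold fraction (default 0.01).
#' @return Region x tract matrix of mean thresholded densities.
#' @export
density_to_overlap <- function(densities, tract_masks, max_fraction = 0.01) {
  stopifnot(length(densities) >= 1, length(tract_masks) >= 1)
  grid <- length(densities[[1]])
  for (d in densities) stopifnot(length(d) == grid)
  for (m in tract_masks) {
    stopifnot(length(m) == grid)
    if (!any(m)) stop("empty tract mask", call. = FALSE)
  }
  out <- matrix(0, length(densities), length(tract_masks),
                dimnames = list(names(densities), names(tract_masks)))
  for (r in seq_along(densities)) {
    d <- as.numeric(densities[[r]])
    d[d < max_fraction * max(d)] <- 0
    for (t in seq_along(tract_masks)) {
      out[r, t] <- mean(d[as.logical(tract_masks[[t]])])
    }
  }
  out
}

#' Threshold an overlap matrix at a fraction of its global maximum
#'
#' @param overlap Region x tract matrix.
#' @param fraction Fraction of the matrix maximum (default 0.05).
#' @return Matrix with sub-threshold entries zeroed.
#' @export
threshold_overlap <- function(overlap, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction < 1)
  overlap[overlap < fraction * max(overlap)] <- 0
  overlap
}

#' Proportion of change between two overlap matrices
#'
#' `(M2 - M1) / M1` elementwise; entries with `M1 = 0` are undefined and
#' returned as `NA` (masked).
#'
#' @param overlap_t1,overlap_t2 Same-shape matrices.
#' @return Change matrix with `NA` at masked entries.
#' @export
proportion_change <- function(overlap_t1, overlap_t2) {
  stopifnot(all(dim(overlap_t1) == dim(overlap_t2)))
  out <- (overlap_t2 - overlap_t1) / overlap_t1
  out[overlap_t1 == 0] <- NA_real_
  out
}

#' Attribute component edges to white-matter tracts
#'
#' For each edge, candidate tracts are those whose proportion of change has
#' the edge's sign (negative for a decrease, positive for an increase) in
#' both endpoint rows. Among several candidates, the tract with the highest
#' mean intensity — averaged over the two timepoints and both endpoints —
#' is selected. When no tract matches the sign at both endpoints, the
#' fallback picks the highest-mean-intensity tract regardless of sign and
#' flags the edge.
#'
#' @param edges Data frame with columns `i`, `j`, `sign` (+1 increase,
#'   -1 decrease); row names of the overlap matrices must cover `i`, `j`.
#' @param change Proportion-of-change matrix (after the 5% threshold, i.e.
#'   from [proportion_change()] on thresholded overlaps).
#' @param overlap_t1,overlap_t2 Thresholded overlap matrices.
#' @return Data frame, one row per edge x candidate tract: `i`, `j`,
#'   `sign`, `tract`, `mean_intensity`, `change_i`, `change_j`, `rule`
#'   (`"common-sign"` or `"highest-mean fallback"`), `selected`.
#' @export
attribute_tracts <- function(edges, change, overlap_t1, overlap_t2) {
  stopifnot(all(c("i", "j", "sign") %in% names(edges)))
  rn <- rownames(overlap_t1)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(overlap_t1)))
  rows <- list()
  for (k in seq_len(nrow(edges))) {
    ri <- match(as.character(edges$i[k]), rn)
    rj <- match(as.character(edges$j[k]), rn)
    if (is.na(ri) || is.na(rj)) {
      stop("edge endpoint missing from overlap matrices", call. = FALSE)
    }
    sgn <- edges$sign[k]
    ci <- change[ri, ]
    cj <- change[rj, ]
    meanint <- (overlap_t1[ri, ] + overlap_t1[rj, ] +
                overlap_t2[ri, ] + overlap_t2[rj, ]) / 4
    matches <- !is.na(ci) & !is.na(cj) & sign(ci) == sgn & sign(cj) == sgn
    if (any(matches)) {
      cand <- which(matches)
      rule <- "common-sign"
    } else {
      cand <- which.max(meanint)
      rule <- "highest-mean fallback"
    }
    ord <- cand[order(-meanint[cand])]
    rows[[k]] <- data.frame(
      i = edges$i[k], j = edges$j[k], sign = sgn,
      tract = colnames(change)[ord],
      mean_intensity = meanint[ord],
      change_i = ci[ord], change_j = cj[ord],
      rule = rule,
      selected = seq_along(ord) == 1L)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  rownames(out) <- NULL
  out
}
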