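# Synthetic two-timepoint cohort generator.
#
# The generator emulates the statistical structure of probabilistic
# tractography streamline-count connectomes: 90 nodes laid out with mirror
# symmetry across the midline (odd index = left, even = right), expected
# counts decaying with Euclidean distance, a subject-level multiplier shared
# across timepoints (the source of within-subject correlation), log-normal
# edge noise, Poisson counting, directional jitter so the symmetrization
# step is exercised, and per-seed waytotals that differ from plain row sums.
# A planted sub-network of edges changes its expectation by a factor (1 +
# delta) between timepoints; everything else is stationary in expectation.

#' Configuration for a synthetic two-timepoint cohort
#'
#' @param n_subjects Number of subjects (each observed at both timepoints).
#' @param n_nodes Number of regions; must be even so left/right mirror pairs
#'   exist. Default 90.
#' @param base_density Fraction of the `n(n-1)/2` node pairs given a nonzero
#'   expected count. The retained pairs are the shortest-distance ones, a
#'   deterministic, mirror-symmetric support. Default 0.5 (raw probabilistic
#'   tractography matrices are dense before thresholding).
#' @param weight_decay Length constant of the exponential distance decay of
#'   expected counts, in units of the unit-cube coordinates. Default 0.25.
#' @param count_scale Expected streamline count of a zero-length connection;
#'   sets the overall count magnitude. Default 5000 (streamlines sampled per
#'   seed voxel in typical tractography runs).
#' @param noise_cv Baseline coefficient of variation of the multiplicative
#'   log-normal edge x subject x timepoint noise. Default 0.1.
#' @param noise_dispersion Weight-dependent noise component: the effective
#'   squared CV of edge (i, j) is `noise_cv^2 + noise_dispersion / mu_ij`,
#'   so weak connections are reconstructed less consistently across
#'   subjects than strong ones — the regime that motivates group
#'   consistency-based thresholding. Default 50 (in expected-count units).
#' @param subject_cv Coefficient of variation of the subject-level log-normal
#'   multiplier shared by both timepoints. Default 0.15.
#' @param planted_increase,planted_decrease Data frames (or NULL) with
#'   columns `i`, `j`, `delta` giving edges whose timepoint-2 expectation is
#'   scaled by `1 + delta`; `delta > 0` for increases, `-1 < delta < 0` for
#'   decreases. The two lists must be disjoint.
#' @param cognition List with elements `slope`, `subject_sd`, `residual_sd`
#'   controlling the linear coupling of cognitive scores to sub-network mean
#'   connectivity (see [generate_cognition()]).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration including this seed.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_subjects,
                          n_nodes = 90L,
                          base_density = 0.5,
                          weight_decay = 0.25,
                          count_scale = 5000,
                          noise_cv = 0.1,
                          noise_dispersion = 50,
                          subject_cv = 0.15,
                          planted_increase = NULL,
                          planted_decrease = NULL,
                          cognition = list(slope = -1, subject_sd = 1,
                                           residual_sd = 0.1),
                          seed = 1L) {
  stopifnot(n_subjects >= 1, n_nodes >= 4, n_nodes %% 2 == 0,
            base_density > 0, base_density <= 1,
            weight_decay > 0, count_scale > 0,
            noise_cv >= 0, noise_dispersion >= 0, subject_cv >= 0)
  check_planted <- function(p, sign) {
    if (is.null(p) || nrow(p) == 0) return(NULL)
    p <- as.data.frame(p)
    stopifnot(all(c("i", "j", "delta") %in% names(p)))
    if (any(p$i < 1 | p$i > n_nodes | p$j < 1 | p$j > n_nodes | p$i == p$j)) {
      stop("planted edge outside node range", call. = FALSE)
    }
    if (any(p$delta <= -1)) stop("planted delta must be > -1", call. = FALSE)
    if (sign > 0 && any(p$delta <= 0)) {
      stop("planted_increase requires delta > 0", call. = FALSE)
    }
    if (sign < 0 && any(p$delta >= 0)) {
      stop("planted_decrease requires delta < 0", call. = FALSE)
    }
    # canonical i < j
    swap <- p$i > p$j
    tmp <- p$i[swap]; p$i[swap] <- p$j[swap]; p$j[swap] <- tmp
    p
  }
  inc <- check_planted(planted_increase, +1)
  dec <- check_planted(planted_decrease, -1)
  if (!is.null(inc) && !is.null(dec)) {
    key <- function(p) paste(p$i, p$j)
    if (length(intersect(key(inc), key(dec)))) {
      stop("planted edge lists must be disjoint", call. = FALSE)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    base_density = base_density, weight_decay = weight_decay,
    count_scale = count_scale, noise_cv = noise_cv,
    noise_dispersion = noise_dispersion, subject_cv = subject_cv,
    planted_increase = inc, planted_decrease = dec,
    cognition = cognition, seed = as.integer(seed)
  ), class = "cohort_config")
}

# log-normal draws with mean 1 and given coefficient(s) of variation
rlnorm_cv <- function(n, cv) {
  if (all(cv == 0)) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Mirror-symmetric node coordinates: left nodes (odd index) uniform in
# [0, 0.45] x [0,1]^2, right nodes (even) mirrored across the x = 0.5 plane.
mirror_coordinates <- function(n_nodes) {
  n_pairs <- n_nodes / 2
  left <- cbind(stats::runif(n_pairs, 0, 0.45),
                stats::runif(n_pairs), stats::runif(n_pairs))
  coords <- matrix(NA_real_, n_nodes, 3)
  coords[seq(1, n_nodes, by = 2), ] <- left
  right <- left
  right[, 1] <- 1 - right[, 1]
  coords[seq(2, n_nodes, by = 2), ] <- right
  coords
}

# Expected-count matrix at timepoint 1: distance-decaying on a deterministic
# support formed by the shortest base_density fraction of pairs, with planted
# edges always included.
expected_counts <- function(coords, config) {
  n <- config$n_nodes
  d <- as.matrix(stats::dist(coords))
  pairs <- ut_pairs(n)
  dv <- d[upper.tri(d)]
  n_keep <- max(1L, round(config$base_density * nrow(pairs)))
  keep <- rank(dv, ties.method = "first") <= n_keep
  # mirror distances are tied, so a cutoff can split a pair from its mirror
  # image; close the support under mirroring to keep expectations symmetric
  mirror_node <- ifelse(seq_len(n) %% 2 == 1, seq_len(n) + 1L,
                        seq_len(n) - 1L)
  mi <- pmin(mirror_node[pairs[, 1]], mirror_node[pairs[, 2]])
  mj <- pmax(mirror_node[pairs[, 1]], mirror_node[pairs[, 2]])
  mirror_idx <- match(paste(mi, mj), paste(pairs[, 1], pairs[, 2]))
  keep <- keep | keep[mirror_idx]
  planted <- rbind(config$planted_increase[, c("i", "j")],
                   config$planted_decrease[, c("i", "j")])
  if (!is.null(planted) && nrow(planted)) {
    pk <- paste(planted$i, planted$j)
    keep <- keep | paste(pairs[, 1], pairs[, 2]) %in% pk
  }
  mu_v <- ifelse(keep, config$count_scale * exp(-dv / config$weight_decay), 0)
  # planted edges are modeled as strong connections (baseline at least at
  # the support's 90th weight percentile): a planted effect on a weak,
  # inconsistently reconstructed edge would be discarded by any
  # consistency-thresholded analysis and is not the regime being emulated
  if (!is.null(planted) && nrow(planted)) {
    pidx <- match(paste(planted$i, planted$j), paste(pairs[, 1], pairs[, 2]))
    q90 <- stats::quantile(mu_v[keep & mu_v > 0], 0.9, names = FALSE)
    mu_v[pidx] <- pmax(mu_v[pidx], q90)
  }
  ut_unvec(mu_v, n)
}

#' Generate a synthetic two-timepoint cohort of streamline-count connectomes
#'
#' Draws, for every subject and timepoint, a directed raw streamline-count
#' matrix (integer Poisson counts around a log-normally perturbed expected
#' matrix) plus a per-seed waytotal vector. Timepoint 2 expectations of
#' planted edges are scaled by `1 + delta`; all other edges are stationary.
#' The same configuration (including its seed) always reproduces the same
#' cohort bitwise.
#'
#' @param config A [cohort_config()].
#' @return List with elements
#'   `counts` (per subject: list of two n x n integer matrices),
#'   `waytotals` (per subject: list of two n-vectors),
#'   `truth` (planted edges with deltas, cognition slope, subject latent
#'   intercepts and multipliers), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  coords <- mirror_coordinates(n)
  mu1 <- expected_counts(coords, config)

  effect <- matrix(1, n, n)
  planted <- rbind(config$planted_increase, config$planted_decrease)
  if (!is.null(planted) && nrow(planted)) {
    for (k in seq_len(nrow(planted))) {
      effect[planted$i[k], planted$j[k]] <- 1 + planted$delta[k]
      effect[planted$j[k], planted$i[k]] <- 1 + planted$delta[k]
    }
  }
  mu2 <- mu1 * effect

  subjects <- sprintf("sub%03d", seq_len(config$n_subjects))
  subj_mult <- rlnorm_cv(config$n_subjects, config$subject_cv)
  subj_intercept <- stats::rnorm(config$n_subjects, 0,
                                 config$cognition$subject_sd)

  # weight-dependent between-subject noise: weak connections are less
  # consistently reconstructed than strong ones
  cv_v <- sqrt(config$noise_cv^2 +
                 config$noise_dispersion / pmax(ut_vec(mu1), 1))

  counts <- vector("list", config$n_subjects)
  waytotals <- vector("list", config$n_subjects)
  names(counts) <- names(waytotals) <- subjects
  for (s in seq_len(config$n_subjects)) {
    counts[[s]] <- vector("list", 2L)
    waytotals[[s]] <- vector("list", 2L)
    for (tp in 1:2) {
      mu <- if (tp == 1) mu1 else mu2
      # shared edge-level noise for both directions, independent +-5%
      # directional jitter so P_ij != P_ji in the raw data
      noise <- ut_unvec(rlnorm_cv(length(cv_v), cv_v), n)
      noise[noise == 0] <- 1
      jitter <- matrix(stats::runif(n * n, 0.95, 1.05), n, n)
      lambda <- subj_mult[s] * mu * noise * jitter
      diag(lambda) <- 0
      cts <- matrix(stats::rpois(n * n, lambda), n, n)
      storage.mode(cts) <- "integer"
      rownames(cts) <- colnames(cts) <- paste0("V", seq_len(n))
      counts[[s]][[tp]] <- cts
      waytotals[[s]][[tp]] <- unname(rowSums(cts)) * stats::runif(n, 1, 2) + 1
    }
  }

  truth <- list(
    planted_increase = config$planted_increase,
    planted_decrease = config$planted_decrease,
    cognition_slope = config$cognition$slope,
    subject_multiplier = stats::setNames(subj_mult, subjects),
    subject_intercept = stats::setNames(subj_intercept, subjects),
    expected_t1 = mu1, expected_t2 = mu2
  )
  list(counts = counts, waytotals = waytotals, truth = truth, config = config)
}

#' Generate cognitive scores coupled to sub-network mean connectivity
#'
#' Scores follow a linear mixed model: for subject s at timepoint t,
#' `score = intercept_s + slope * subnet_mean_st + residual`, where the
#' subject intercepts are the latent ones drawn by [generate_cohort()] and
#' residuals are i.i.d. Gaussian. With a negative slope this reproduces the
#' situation where higher sub-network connectivity goes with lower scores.
#'
#' @param subnet_means Numeric matrix, subjects x 2 timepoints, of mean
#'   connectivity over the designated edge set (computed by the caller from
#'   the built connectomes).
#' @param cohort Cohort from [generate_cohort()] (provides intercepts,
#'   coupling parameters and the score-generation seed).
#' @return Data frame with columns `subject`, `timepoint`, `score`.
#' @export
generate_cognition <- function(subnet_means, cohort) {
  cfg <- cohort$config
  if (is.null(subnet_means) || !length(subnet_means)) {
    stop("designated edge set produced no sub-network means", call. = FALSE)
  }
  stopifnot(is.matrix(subnet_means), ncol(subnet_means) == 2,
            nrow(subnet_means) == cfg$n_subjects,
            is.finite(cfg$cognition$slope))
  set.seed(cfg$seed + 1L)
  subjects <- names(cohort$counts)
  icpt <- cohort$truth$subject_intercept
  out <- expand.grid(subject = subjects, timepoint = 1:2,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$subject, out$timepoint), ]
  x <- as.vector(t(subnet_means))          # subject-major, tp within
  resid <- stats::rnorm(nrow(out), 0, cfg$cognition$residual_sd)
  out$subnet_mean <- x
  out$score <- icpt[out$subject] + cfg$cognition$slope * x + resid
  rownames(out) <- NULL
  out
}

#' Generate region x tract overlap fixtures with a known edge-to-tract map
#'
#' Builds a pair of region-by-tract mean-streamline matrices (one per
#' timepoint) in which each planted edge has a unique "true" tract whose
#' overlap with both endpoint regions changes with the sign of the planted
#' effect, while distractor tracts carry identical values at both timepoints
#' (zero change). Construction therefore guarantees a unique sign-matching
#' candidate per edge, so attribution has an exact right answer.
#'
#' @param config A [cohort_config()] with planted edges.
#' @param n_tracts Number of tracts (columns); must be at least the number
#'   of planted edges so the true map is unique.
#' @param seed Seed for the baseline intensities.
#' @return List with `overlap_t1`, `overlap_t2` (region x tract matrices,
#'   rows named by region index, columns `tract01..`), and `true_map`
#'   (data frame `i`, `j`, `delta`, `tract`).
#' @export
generate_tract_fixtures <- function(config, n_tracts, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"), n_tracts >= 1)
  planted <- rbind(config$planted_increase, config$planted_decrease)
  if (is.null(planted) || !nrow(planted)) {
    stop("config has no planted edges to attribute", call. = FALSE)
  }
  if (n_tracts < nrow(planted)) {
    stop("need at least one tract per planted edge", call. = FALSE)
  }
  set.seed(seed)
  n <- config$n_nodes
  tracts <- sprintf("tract%02d", seq_len(n_tracts))
  # baseline overlaps: moderate positive values everywhere so the 5% max
  # threshold keeps genuine entries
  base <- matrix(stats::runif(n * n_tracts, 50, 150), n, n_tracts,
                 dimnames = list(seq_len(n), tracts))
  m1 <- base
  m2 <- base
  true_map <- planted
  true_map$tract <- tracts[seq_len(nrow(planted))]
  for (k in seq_len(nrow(planted))) {
    tr <- true_map$tract[k]
    for (node in c(planted$i[k], planted$j[k])) {
      m1[node, tr] <- 400 + stats::runif(1, 0, 100)
      m2[node, tr] <- m1[node, tr] * (1 + planted$delta[k])
    }
  }
  list(overlap_t1 = m1, overlap_t2 = m2, true_map = true_map)
}
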