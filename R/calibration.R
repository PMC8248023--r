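# Monte-Carlo calibration of the paired NBS procedure: empirical
# family-wise error rate on null cohorts and planted-component recovery on
# effect cohorts. Both drive the whole pipeline (cohort generation ->
# construction -> masking -> NBS), so they exercise the procedure exactly
# as it is used.

#' Default primary threshold for a paired design
#'
#' The squared two-sided t quantile at the given edge-level p for n - 1
#' degrees of freedom; the FWER of the component test is controlled for
#' any choice, this only fixes sensitivity.
#'
#' @param n_subjects Number of subjects.
#' @param edge_p Edge-level two-sided p defining the cutoff
#'   (default 0.001).
#' @return Scalar F threshold.
#' @export
default_primary_threshold <- function(n_subjects, edge_p = 0.001) {
  stats::qt(1 - edge_p / 2, df = n_subjects - 1)^2
}

#' Empirical FWER of paired NBS on null cohorts
#'
#' Generates `n_datasets` cohorts with no planted effect, runs the full
#' construction chain and the paired NBS on each, and reports the fraction
#' of datasets yielding any component significant at `alpha`. With the +1
#' permutation correction this fraction should stay at or below the
#' nominal level (up to Monte-Carlo error).
#'
#' @param n_datasets Number of null cohorts (default 200).
#' @param n_subjects Subjects per cohort (default 30).
#' @param n_perm Sign-flip permutations per cohort (default 500).
#' @param alpha Corrected level (default 0.05).
#' @param primary_threshold Edge-level F cutoff; default from
#'   [default_primary_threshold()].
#' @param seed Master seed; cohort c uses seed `seed + c - 1` for
#'   generation and a spawned seed for its permutations.
#' @param n_nodes Nodes per connectome (default 90).
#' @return List: `fwer` (fraction of datasets with a significant
#'   component), `n_datasets`, `any_significant` (logical vector),
#'   `mc_se` (binomial Monte-Carlo standard error at the nominal level).
#' @export
simulate_null_fwer <- function(n_datasets = 200, n_subjects = 30,
                               n_perm = 500, alpha = 0.05,
                               primary_threshold = NULL, seed = 1L,
                               n_nodes = 90L) {
  if (is.null(primary_threshold)) {
    primary_threshold <- default_primary_threshold(n_subjects)
  }
  perm_seeds <- spawn_seeds(seed, n_datasets)
  hit <- logical(n_datasets)
  for (c in seq_len(n_datasets)) {
    cfg <- cohort_config(n_subjects = n_subjects, n_nodes = n_nodes,
                         seed = seed + c - 1L)
    built <- build_connectomes(generate_cohort(cfg))
    res <- nbs_paired(cohort_pair(built), primary_threshold,
                      n_perm = n_perm, alpha = alpha,
                      seed = perm_seeds[c])
    hit[c] <- any(vapply(res$components, `[[`, TRUE, "significant"))
  }
  list(fwer = mean(hit), n_datasets = n_datasets, any_significant = hit,
       mc_se = sqrt(alpha * (1 - alpha) / n_datasets))
}

#' Planted-component recovery of paired NBS
#'
#' Runs the pipeline on demo cohorts carrying the reference 16-edge planted
#' component and measures, per replicate, the fraction of planted edges
#' contained in the detected significant component and the fraction of
#' detected edges that are spurious.
#'
#' @param n_replicates Number of cohorts (default 20).
#' @param n_subjects Subjects per cohort (default 51).
#' @param delta Planted absolute effect size (default 0.4).
#' @param n_perm Permutations (default 500).
#' @param alpha Corrected level (default 0.05).
#' @param primary_threshold Edge-level F cutoff; default from
#'   [default_primary_threshold()].
#' @param seed Master seed.
#' @return Data frame per replicate: `detected` (any significant
#'   component), `recovered_fraction`, `spurious_fraction`, `p_fwer`.
#' @export
simulate_component_recovery <- function(n_replicates = 20, n_subjects = 51,
                                        delta = 0.4, n_perm = 500,
                                        alpha = 0.05,
                                        primary_threshold = NULL,
                                        seed = 1L) {
  if (is.null(primary_threshold)) {
    primary_threshold <- default_primary_threshold(n_subjects)
  }
  comp <- reference_component()
  planted_key <- paste(pmin(comp$index1, comp$index2),
                       pmax(comp$index1, comp$index2))
  perm_seeds <- spawn_seeds(seed, n_replicates)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cohort <- make_demo(seed = seed + r - 1L, n_subjects = n_subjects,
                        delta = delta)
    built <- build_connectomes(cohort)
    res <- nbs_paired(cohort_pair(built), primary_threshold,
                      n_perm = n_perm, alpha = alpha,
                      seed = perm_seeds[r])
    sig <- Filter(function(co) co$significant, res$components)
    if (!length(sig)) {
      return(data.frame(detected = FALSE, recovered_fraction = 0,
                        spurious_fraction = NA_real_, p_fwer = NA_real_))
    }
    # union of significant components (a strong plant should land in one)
    got <- do.call(rbind, lapply(sig, `[[`, "edges"))
    got_key <- paste(pmin(got[, 1], got[, 2]), pmax(got[, 1], got[, 2]))
    data.frame(
      detected = TRUE,
      recovered_fraction = mean(planted_key %in% got_key),
      spurious_fraction = mean(!(got_key %in% planted_key)),
      p_fwer = min(vapply(sig, `[[`, 0, "p_fwer")))
  })
  do.call(rbind, rows)
}
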