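# End-to-end orchestration: build -> consistency -> NBS -> topology ->
# tract attribution -> brain-cognition statistics, from one configuration
# with one master seed, writing every stage's outputs as plain-text tables.

#' Reference 16-edge longitudinal component
#'
#' The bundled edge list of a connected component of 16 region pairs with
#' significant longitudinal connectivity differences in an aging cohort
#' (7 increases, 9 decreases), used as a realistic planted sub-network for
#' the demo cohort and as a fixture for hemisphere-census checks.
#'
#' @return Data frame: `index1`, `name1`, `index2`, `name2`, `difference`.
#' @export
reference_component <- function() {
  path <- system.file("extdata", "significant_component.tsv",
                      package = "longconn")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Demo cohort configuration with the reference component planted
#'
#' Plants the reference 16-edge component (increases and decreases at
#' `+delta` / `-delta`) in a synthetic cohort, so the full pipeline can
#' recover a sub-network whose hemisphere-class census matches the plant:
#' decreases 3 intra-left / 5 intra-right / 1 inter-hemispheric, increases
#' 2 intra-left / 5 inter-hemispheric.
#'
#' @param seed Integer seed.
#' @param n_subjects Cohort size (default 51).
#' @param delta Absolute fractional effect size on planted edges
#'   (default 0.4).
#' @return A [cohort_config()].
#' @export
make_demo_config <- function(seed = 1L, n_subjects = 51L, delta = 0.4) {
  comp <- reference_component()
  inc <- comp[comp$difference > 0, ]
  dec <- comp[comp$difference < 0, ]
  cohort_config(
    n_subjects = n_subjects,
    planted_increase = data.frame(i = inc$index1, j = inc$index2,
                                  delta = delta),
    planted_decrease = data.frame(i = dec$index1, j = dec$index2,
                                  delta = -delta),
    seed = seed)
}

#' Generate and write the bundled demo cohort
#'
#' @param seed Integer seed.
#' @param dir Output directory for the cohort files (optional; when NULL
#'   nothing is written).
#' @param ... Passed to [make_demo_config()].
#' @return The generated cohort (invisibly includes its config).
#' @export
make_demo <- function(seed = 1L, dir = NULL, ...) {
  cohort <- generate_cohort(make_demo_config(seed = seed, ...))
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Pipeline run configuration
#'
#' @param cohort_dir Directory with a cohort manifest (or NULL when a
#'   cohort object is passed to [run_pipeline()] directly).
#' @param out_dir Output directory.
#' @param weight_fraction Absolute weight threshold (default 0.01, i.e. 1%
#'   of the strongest connection).
#' @param mask_density Consistency-mask density (default 0.30).
#' @param nbs_threshold Primary F threshold, or NULL to select it by the
#'   sweep rule over `sweep_thresholds`.
#' @param sweep_thresholds Candidate thresholds for the sweep.
#' @param n_perm Sign-flip permutations (default 5000).
#' @param alpha Corrected significance level (default 0.05).
#' @param louvain_runs Louvain consensus runs (default 10000).
#' @param n_rand Randomized-ensemble size for sigma (default 100).
#' @param bootstrap_draws Bootstrap draws (default 10000).
#' @param seed Master seed; all stage seeds are spawned from it.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_dir = NULL, out_dir = "results",
                       weight_fraction = 0.01, mask_density = 0.30,
                       nbs_threshold = NULL,
                       sweep_thresholds = seq(5, 30, by = 1),
                       n_perm = 5000, alpha = 0.05,
                       louvain_runs = 10000, n_rand = 100,
                       bootstrap_draws = 10000, seed = 1L) {
  stopifnot(weight_fraction >= 0, weight_fraction < 1,
            mask_density > 0, mask_density <= 1,
            n_perm >= 100, alpha > 0, alpha < 1,
            louvain_runs >= 1, n_rand >= 0, bootstrap_draws >= 1000)
  structure(as.list(environment()), class = "run_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

#' Run the full longitudinal connectome pipeline
#'
#' Stages: connectome construction, timepoint consistency, paired NBS (with
#' threshold sweep when no primary threshold is fixed), graph metrics and
#' paired tests, community structure and hubs with modular fingerprints,
#' tract attribution (when overlaps are supplied), and brain-cognition
#' repeated-measures correlation (when scores are supplied). All tabular
#' outputs are TSV; a provenance record (config, seeds) is written as JSON.
#'
#' @param config A [run_config()].
#' @param cohort Optional cohort object (otherwise read from
#'   `config$cohort_dir`).
#' @param cognition Optional data frame `subject`, `timepoint`, `score`.
#' @param tract_overlaps Optional list with `overlap_t1`, `overlap_t2`.
#' @return List with every stage's results (also written under
#'   `config$out_dir`).
#' @export
run_pipeline <- function(config, cohort = NULL, cognition = NULL,
                         tract_overlaps = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- spawn_seeds(config$seed, 6)

  if (is.null(cohort)) {
    if (is.null(config$cohort_dir)) stop("no cohort given", call. = FALSE)
    log_stage("load", "reading cohort from ", config$cohort_dir)
    cohort <- read_cohort(config$cohort_dir)
  }
  # drop subjects missing a timepoint
  complete <- vapply(cohort$counts, function(x) {
    length(x) == 2 && !is.null(x[[1]]) && !is.null(x[[2]])
  }, TRUE)
  if (any(!complete)) {
    warning("excluding ", sum(!complete), " subject(s) missing a timepoint")
    cohort$counts <- cohort$counts[complete]
    cohort$waytotals <- cohort$waytotals[complete]
  }

  log_stage("build", length(cohort$counts), " subjects")
  built <- build_connectomes(cohort, config$weight_fraction,
                             config$mask_density)

  log_stage("consistency")
  tc <- consistency_report(built)
  jsonlite::write_json(
    list(tc1 = as.list(tc$tc1), n_pairs = as.list(tc$n_pairs)),
    file.path(config$out_dir, "timepoint_consistency.json"),
    auto_unbox = TRUE, digits = NA)

  log_stage("nbs")
  cp <- cohort_pair(built)
  thr <- config$nbs_threshold
  sweep <- NULL
  if (is.null(thr)) {
    sweep <- threshold_sweep(cp, config$sweep_thresholds)
    thr <- attr(sweep, "selected_threshold")
    if (is.na(thr)) thr <- max(config$sweep_thresholds)
    utils::write.table(sweep, file.path(config$out_dir,
                                        "threshold_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  nbs <- nbs_paired(cp, thr, config$n_perm, config$alpha, seeds[1])
  sig <- Filter(function(co) co$significant, nbs$components)
  comp_table <- do.call(rbind, lapply(seq_along(nbs$components),
                                      function(k) {
    co <- nbs$components[[k]]
    data.frame(component = k, i = co$edges[, 1], j = co$edges[, 2],
               mean_diff = co$mean_diff,
               hemisphere = classify_edge_hemisphere(co$edges[, 1],
                                                     co$edges[, 2],
                                                     cp$n_nodes),
               p_fwer = co$p_fwer, significant = co$significant)
  }))
  if (!is.null(comp_table)) {
    labels <- aal90_labels()
    if (cp$n_nodes == nrow(labels)) {
      comp_table$name_i <- labels$name[comp_table$i]
      comp_table$name_j <- labels$name[comp_table$j]
    }
    utils::write.table(comp_table,
                       file.path(config$out_dir, "nbs_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summaries <- if (length(sig)) component_summaries(cp, sig[[1]]) else NULL
  if (!is.null(summaries)) {
    utils::write.table(summaries$percent_change,
                       file.path(config$out_dir,
                                 "component_percent_change.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_stage("metrics")
  metrics <- cohort_metrics(built, n_rand = config$n_rand, seed = seeds[2])
  utils::write.table(metrics, file.path(config$out_dir, "graph_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  metric_tests <- do.call(rbind, lapply(
    setdiff(names(metrics), c("subject", "timepoint")), function(mm) {
      v1 <- metrics[[mm]][metrics$timepoint == 1]
      v2 <- metrics[[mm]][metrics$timepoint == 2]
      cbind(data.frame(metric = mm), paired_t_with_d(v1, v2))
    }))
  metric_tests$q <- fdr_bh(metric_tests$p)
  utils::write.table(metric_tests,
                     file.path(config$out_dir, "graph_metric_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("community")
  gmean <- list(t1 = Reduce(`+`, built$t1) / length(built$t1),
                t2 = Reduce(`+`, built$t2) / length(built$t2))
  part <- lapply(gmean, louvain_consensus, n_runs = config$louvain_runs,
                 seed = seeds[3])
  roles <- Map(node_roles, gmean, part)
  ghubs <- lapply(gmean, function(m) {
    classify_global_hubs(efficiencies(shortest_path_lengths(m))$e_nodal)
  })
  ref <- select_reference_partition(
    c(built$t1, built$t2), list(part$t1$assignment, part$t2$assignment))
  fingerprints <- Map(function(m, rl) {
    modular_fingerprints(m, ref, rl$node[rl$role == "connector hub"])
  }, gmean, roles)
  hub_change <- if (fingerprints$t1$overall_hub_driven > 0) {
    100 * (fingerprints$t2$overall_hub_driven -
             fingerprints$t1$overall_hub_driven) /
      fingerprints$t1$overall_hub_driven
  } else NA_real_
  for (tp in c("t1", "t2")) {
    utils::write.table(
      data.frame(node = seq_along(part[[tp]]$assignment),
                 module = part[[tp]]$assignment),
      file.path(config$out_dir, sprintf("partition_%s.tsv", tp)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(roles[[tp]],
                       file.path(config$out_dir,
                                 sprintf("node_roles_%s.tsv", tp)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  topology <- list(partitions = part,
                   similarity = partition_similarity(part$t1, part$t2),
                   roles = roles, global_hubs = ghubs,
                   reference = ref, fingerprints = fingerprints,
                   hub_driven_pct_change = hub_change)

  tracts <- NULL
  if (!is.null(tract_overlaps) && length(sig)) {
    log_stage("tracts")
    o1 <- threshold_overlap(tract_overlaps$overlap_t1)
    o2 <- threshold_overlap(tract_overlaps$overlap_t2)
    ch <- proportion_change(o1, o2)
    co <- sig[[1]]
    tracts <- attribute_tracts(
      data.frame(i = co$edges[, 1], j = co$edges[, 2],
                 sign = sign(co$mean_diff)),
      ch, o1, o2)
    utils::write.table(tracts,
                       file.path(config$out_dir, "tract_attribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cognition_stats <- NULL
  if (!is.null(cognition) && length(sig)) {
    log_stage("cognition")
    sm <- component_summaries(cp, sig[[1]])$subject_means
    nets <- unique(sm$network)
    rows <- list()
    for (nn in nets) {
      sub <- sm[sm$network == nn & sm$hemisphere_class == "all", ]
      mrg <- merge(sub, cognition, by = c("subject", "timepoint"))
      rr <- rmcorr(mrg$subject, mrg$mean_sc, mrg$score)
      recs <- split(mrg, mrg$subject)
      ci <- bootstrap_ci(recs, function(rs) {
        dd <- do.call(rbind, rs)
        dd$subject <- rep(seq_along(rs), vapply(rs, nrow, 0L))
        suppressWarnings(rmcorr(dd$subject, dd$mean_sc, dd$score)$r_rm)
      }, n_draws = config$bootstrap_draws, seed = seeds[4])
      rows[[nn]] <- cbind(data.frame(network = nn), rr,
                          ci_lower = ci$lower, ci_upper = ci$upper)
    }
    cognition_stats <- do.call(rbind, rows)
    cognition_stats$q <- fdr_bh(cognition_stats$p)
    utils::write.table(cognition_stats,
                       file.path(config$out_dir, "cognition_rmcorr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  provenance <- list(
    config = config[setdiff(names(config), "sweep_thresholds")],
    sweep_thresholds = config$sweep_thresholds,
    stage_seeds = seeds,
    n_subjects = length(cohort$counts),
    nbs_threshold_used = thr,
    package_version = as.character(utils::packageVersion("longconn")),
    r_version = R.version.string)
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  invisible(list(built = built, consistency = tc, pair = cp, sweep = sweep,
                 nbs = nbs, summaries = summaries, metrics = metrics,
                 metric_tests = metric_tests, topology = topology,
                 tracts = tracts, cognition = cognition_stats,
                 provenance = provenance))
}
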