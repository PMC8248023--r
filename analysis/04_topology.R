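#!/usr/bin/env Rscript
# Stage 4 -- graph topology and its longitudinal change.
#
# Per-subject graph metrics (degree, density, efficiencies, characteristic
# path length, clustering, small-world sigma against 100 degree-preserving
# rewirings) with paired t-tests and FDR correction; group-level community
# structure (Louvain consensus over 10000 runs), global / provincial /
# connector hubs, and modular-connectivity fingerprints on the reference
# partition.

suppressPackageStartupMessages(library(longconn))

cohort <- read_cohort("scratch/cohort")
built <- build_connectomes(cohort)

message("computing per-subject metrics (this is the slow stage)")
metrics <- cohort_metrics(built, n_rand = 100, seed = 21L)
utils::write.table(metrics, "results/graph_metrics.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

tests <- do.call(rbind, lapply(
  setdiff(names(metrics), c("subject", "timepoint")), function(mm) {
    cbind(data.frame(metric = mm),
          paired_t_with_d(metrics[[mm]][metrics$timepoint == 1],
                          metrics[[mm]][metrics$timepoint == 2]))
  }))
tests$q <- fdr_bh(tests$p)
utils::write.table(tests, "results/graph_metric_tests.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("paired metric tests (q = BH-adjusted):")
print(tests, digits = 3)

gmean <- list(t1 = Reduce(`+`, built$t1) / length(built$t1),
              t2 = Reduce(`+`, built$t2) / length(built$t2))
part <- lapply(gmean, louvain_consensus, n_runs = 10000, seed = 31L)
message(sprintf("modules: t1 = %d (Q = %.3f, mode %.2f), t2 = %d (Q = %.3f, mode %.2f); similarity %.3f",
                max(part$t1$assignment), part$t1$q, part$t1$mode_frequency,
                max(part$t2$assignment), part$t2$q, part$t2$mode_frequency,
                partition_similarity(part$t1, part$t2)))

labels <- aal90_labels()
for (tp in c("t1", "t2")) {
  roles <- node_roles(gmean[[tp]], part[[tp]])
  roles$name <- labels$name
  ghub <- classify_global_hubs(
    efficiencies(shortest_path_lengths(gmean[[tp]]))$e_nodal)
  ghub$name <- labels$name[ghub$node]
  utils::write.table(roles, sprintf("results/node_roles_%s.tsv", tp),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ghub, sprintf("results/global_hubs_%s.tsv", tp),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(tp, ": ", nrow(ghub), " global hubs, ",
          sum(roles$role == "provincial hub"), " provincial, ",
          sum(roles$role == "connector hub"), " connector")
}

ref <- select_reference_partition(c(built$t1, built$t2),
                                  list(part$t1$assignment,
                                       part$t2$assignment))
message("reference partition: timepoint ", attr(ref, "index"))
fp <- lapply(c("t1", "t2"), function(tp) {
  rl <- node_roles(gmean[[tp]], part[[tp]])
  modular_fingerprints(gmean[[tp]], ref,
                       rl$node[rl$role == "connector hub"])
})
names(fp) <- c("t1", "t2")
for (tp in c("t1", "t2")) {
  write_matrix_tsv(fp[[tp]]$inter,
                   sprintf("results/fingerprint_inter_%s.tsv", tp),
                   labels = colnames(fp[[tp]]$inter))
  write_matrix_tsv(fp[[tp]]$hub_driven,
                   sprintf("results/fingerprint_hub_driven_%s.tsv", tp),
                   labels = colnames(fp[[tp]]$hub_driven))
}
if (fp$t1$overall_hub_driven > 0) {
  message(sprintf("connector-hub inter-modular connectivity: %d -> %d (%.1f%% change)",
                  fp$t1$overall_hub_driven, fp$t2$overall_hub_driven,
                  100 * (fp$t2$overall_hub_driven - fp$t1$overall_hub_driven) /
                    fp$t1$overall_hub_driven))
}
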