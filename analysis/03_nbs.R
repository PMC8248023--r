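#!/usr/bin/env Rscript
# Stage 3 -- paired network-based statistics.
#
# Sweeps the primary F threshold, applies the selection rule (maximal
# threshold with a unique component of more than two connections), runs
# the sign-flip permutation test at 5000 permutations, and summarizes the
# significant component: edge list with hemisphere classes, and mean
# sub-network connectivity with percent changes per stratum.

suppressPackageStartupMessages(library(longconn))

cohort <- read_cohort("scratch/cohort")
built <- build_connectomes(cohort)
cp <- cohort_pair(built)

sweep <- threshold_sweep(cp, seq(5, 60, by = 1))
utils::write.table(sweep, "results/threshold_sweep.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
thr <- attr(sweep, "selected_threshold")
if (is.na(thr)) thr <- default_primary_threshold(nrow(cp$d))
message("primary threshold: F = ", round(thr, 2))

res <- nbs_paired(cp, thr, n_perm = 5000, alpha = 0.05, seed = 11L)
sig <- Filter(function(co) co$significant, res$components)
message(length(res$components), " component(s); ", length(sig),
        " significant at p < 0.05 FWER")

labels <- aal90_labels()
tabs <- lapply(seq_along(res$components), function(k) {
  co <- res$components[[k]]
  data.frame(component = k,
             index1 = co$edges[, 1], name1 = labels$name[co$edges[, 1]],
             index2 = co$edges[, 2], name2 = labels$name[co$edges[, 2]],
             mean_diff = co$mean_diff,
             hemisphere = classify_edge_hemisphere(co$edges[, 1],
                                                   co$edges[, 2]),
             p_fwer = co$p_fwer, significant = co$significant)
})
utils::write.table(do.call(rbind, tabs), "results/nbs_components.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

if (length(sig)) {
  co <- sig[[1]]
  message(sprintf("largest significant component: %d edges (%d increases, %d decreases), p = %.4g",
                  co$size, co$n_increase, co$n_decrease, co$p_fwer))
  sm <- component_summaries(cp, co)
  utils::write.table(sm$subject_means, "results/component_subject_means.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sm$percent_change, "results/component_percent_change.tsv",
                     sep = "\t", quote = FALSE, row.names = FALSE)
  print(sm$percent_change)
}
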