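#!/usr/bin/env Rscript
# Stage 6 -- brain-cognition association.
#
# Generates cognitive scores coupled to the planted sub-network (negative
# slope: higher connectivity goes with lower scores), then estimates the
# repeated-measures correlation between each component sub-network's mean
# connectivity and the scores, with BH-FDR across sub-networks and a
# cluster bootstrap confidence interval for the correlation coefficient.

suppressPackageStartupMessages(library(longconn))

cohort <- read_cohort("scratch/cohort")
# rebuild the generator state so the latent subject intercepts match
cohort_obj <- make_demo(seed = cohort$seed, n_subjects = 51L, delta = 0.4)
built <- build_connectomes(cohort_obj)
cp <- cohort_pair(built)

comps <- utils::read.table("results/nbs_components.tsv", sep = "\t",
                           header = TRUE)
sig <- comps[comps$significant & comps$component ==
               min(comps$component[comps$significant]), ]
co <- list(edges = cbind(sig$index1, sig$index2), mean_diff = sig$mean_diff)
sm_tab <- component_summaries(cp, co)$subject_means

# scores coupled to the full planted component's mean connectivity
planted <- rbind(cohort_obj$config$planted_increase,
                 cohort_obj$config$planted_decrease)
edges <- as.matrix(planted[, c("i", "j")])
subnet <- sapply(1:2, function(tp) sapply(built[[tp]], function(m) {
  mean(m[edges])
}))
scores <- generate_cognition(subnet, cohort_obj)
utils::write.table(scores, "results/cognition_scores.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

rows <- list()
for (nn in unique(sm_tab$network)) {
  sub <- sm_tab[sm_tab$network == nn & sm_tab$hemisphere_class == "all", ]
  mrg <- merge(sub, scores, by = c("subject", "timepoint"))
  rr <- rmcorr(mrg$subject, mrg$mean_sc, mrg$score)
  recs <- split(mrg, mrg$subject)
  ci <- bootstrap_ci(recs, function(rs) {
    dd <- do.call(rbind, rs)
    dd$subject <- rep(seq_along(rs), vapply(rs, nrow, 0L))
    suppressWarnings(rmcorr(dd$subject, dd$mean_sc, dd$score)$r_rm)
  }, n_draws = 10000, seed = 41L)
  rows[[nn]] <- cbind(data.frame(network = nn), rr,
                      ci_lower = ci$lower, ci_upper = ci$upper)
}
out <- do.call(rbind, rows)
out$q <- fdr_bh(out$p)
utils::write.table(out, "results/cognition_rmcorr.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("repeated-measures correlations (FDR-adjusted q):")
print(out, digits = 3, row.names = FALSE)
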