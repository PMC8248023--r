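#!/usr/bin/env Rscript
# Stage 1 -- simulate the demo cohort.
#
# Generates a two-timepoint cohort of 51 subjects with the bundled 16-edge
# reference component planted (7 increases, 9 decreases at |delta| = 0.4 of
# the baseline expectation), plus region-by-tract overlap fixtures carrying
# a known edge-to-tract map. Everything downstream reads these files.

suppressPackageStartupMessages(library(longconn))

seed <- 1L
cohort_dir <- "scratch/cohort"
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("simulating demo cohort (51 subjects, 90 nodes, seed ", seed, ")")
cohort <- make_demo(seed = seed, n_subjects = 51L, delta = 0.4,
                    dir = cohort_dir)

fx <- generate_tract_fixtures(cohort$config, n_tracts = 20, seed = seed + 1L)
write_matrix <- function(m, path) {
  utils::write.table(data.frame(region = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
write_matrix(fx$overlap_t1, "results/tract_overlap_t1.tsv")
write_matrix(fx$overlap_t2, "results/tract_overlap_t2.tsv")
utils::write.table(fx$true_map, "results/tract_true_map.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

planted <- rbind(cohort$config$planted_increase,
                 cohort$config$planted_decrease)
message("planted component: ", nrow(planted), " edges (",
        nrow(cohort$config$planted_increase), " increases, ",
        nrow(cohort$config$planted_decrease), " decreases)")
message("cohort written to ", cohort_dir)
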