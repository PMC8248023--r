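# Synthetic cohort generator: determinism, null behaviour, planted-effect
# recovery, mirror symmetry, cognition coupling, tract fixtures.

test_that("same seed reproduces the cohort bitwise; configs validate", {
  cfg <- tiny_config(n_subjects = 3)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$waytotals, c2$waytotals)

  expect_error(cohort_config(5, planted_increase =
    data.frame(i = 1, j = 99, delta = 0.5)), "node range")
  expect_error(cohort_config(5, planted_decrease =
    data.frame(i = 1, j = 2, delta = -1.5)), "> -1")
  expect_error(cohort_config(5,
    planted_increase = data.frame(i = 1, j = 2, delta = 0.5),
    planted_decrease = data.frame(i = 2, j = 1, delta = -0.5)),
    "disjoint")
})

test_that("counts are non-negative integers and mirror pairs share expectations", {
  coh <- generate_cohort(tiny_config(n_subjects = 2))
  for (s in coh$counts) {
    for (m in s) {
      expect_true(all(m >= 0))
      expect_type(m[1], "integer")
    }
  }
  mu <- coh$truth$expected_t1
  n <- nrow(mu)
  odd <- seq(1, n, 2)
  # mirrored pair of edge (2i-1, 2j-1) is (2i, 2j)
  expect_equal(mu[odd, odd], mu[odd + 1, odd + 1],
               ignore_attr = TRUE)
})

test_that("null config gives equal timepoint expectations; group mean difference shrinks", {
  mean_rel_diff <- function(n_subjects) {
    coh <- generate_cohort(tiny_config(n_subjects = n_subjects, seed = 7))
    d <- Reduce(`+`, lapply(names(coh$counts), function(s) {
      coh$counts[[s]][[2]] - coh$counts[[s]][[1]]
    })) / length(coh$counts)
    on <- coh$truth$expected_t1 > 0
    mean(abs(d[on]) / coh$truth$expected_t1[on])
  }
  coh <- generate_cohort(tiny_config(n_subjects = 4, seed = 7))
  expect_identical(coh$truth$expected_t1, coh$truth$expected_t2)
  # the group-mean relative difference shrinks as 1/sqrt(n): quadrupling
  # the cohort roughly halves it, and at n = 40 it is a few percent
  r10 <- mean_rel_diff(10)
  r40 <- mean_rel_diff(40)
  expect_lt(r40, 0.1)
  expect_lt(r40, 0.75 * r10)
})

test_that("planted edges scale timepoint-2 expectation by 1 + delta", {
  edges <- cbind(c(1, 3, 5, 2, 4), c(7, 9, 11, 8, 10))
  cfg <- tiny_config(n_subjects = 40, noise_cv = 0.1,
                     planted_increase = planted_df(edges, 0.5))
  coh <- generate_cohort(cfg)
  expect_equal(coh$truth$expected_t2[edges],
               1.5 * coh$truth$expected_t1[edges])
  # Monte-Carlo: edge-wise ratio of group means within [1.3, 1.7]
  m1 <- Reduce(`+`, lapply(coh$counts, `[[`, 1)) / length(coh$counts)
  m2 <- Reduce(`+`, lapply(coh$counts, `[[`, 2)) / length(coh$counts)
  ratio <- (m2[edges] + t(m2)[edges]) / (m1[edges] + t(m1)[edges])
  expect_true(all(ratio > 1.3 & ratio < 1.7))
})

test_that("cognition scores follow the linear within-subject model", {
  edges <- cbind(c(1, 3), c(5, 7))
  cfg <- tiny_config(n_subjects = 10,
                     planted_increase = planted_df(edges, 0.4),
                     cognition = list(slope = -1, subject_sd = 1,
                                      residual_sd = 0))
  coh <- generate_cohort(cfg)
  sm <- matrix(runif(20, 0.2, 0.8), 10, 2)
  sc <- generate_cognition(sm, coh)
  # residual_sd 0, slope -1: within-subject score change = -1 x SC change
  ch <- tapply(sc$score, sc$subject, diff)[unique(sc$subject)]
  expect_equal(as.numeric(ch), -(sm[, 2] - sm[, 1]), tolerance = 1e-12)

  # slope 0, residual 0 -> constant within subject
  cfg0 <- tiny_config(n_subjects = 4,
                      cognition = list(slope = 0, subject_sd = 1,
                                       residual_sd = 0))
  coh0 <- generate_cohort(cfg0)
  sc0 <- generate_cognition(matrix(runif(8), 4, 2), coh0)
  expect_equal(as.numeric(unlist(tapply(sc0$score, sc0$subject, diff))),
               rep(0, 4))
  expect_error(generate_cognition(NULL, coh0), "no sub-network")
})

test_that("tract fixtures change with the planted sign and are reproducible", {
  edges <- cbind(c(1, 3, 5), c(7, 9, 11))
  cfg <- tiny_config(planted_decrease = planted_df(edges, -0.5))
  fx1 <- generate_tract_fixtures(cfg, n_tracts = 8, seed = 5)
  fx2 <- generate_tract_fixtures(cfg, n_tracts = 8, seed = 5)
  expect_identical(fx1, fx2)
  for (k in 1:3) {
    tr <- fx1$true_map$tract[k]
    for (node in edges[k, ]) {
      expect_lt(fx1$overlap_t2[node, tr], fx1$overlap_t1[node, tr])
    }
  }
  # distractor tracts carry zero change
  distract <- setdiff(colnames(fx1$overlap_t1), fx1$true_map$tract)
  expect_identical(fx1$overlap_t1[, distract], fx1$overlap_t2[, distract])
  expect_error(generate_tract_fixtures(cfg, n_tracts = 2), "at least one")
})

test_that("cohorts round-trip through the on-disk manifest format", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(tiny_config(n_subjects = 2, n_nodes = 10))
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects, names(coh$counts))
  for (s in back$subjects) {
    for (tp in 1:2) {
      expect_equal(unname(back$counts[[s]][[tp]]),
                   unname(coh$counts[[s]][[tp]]),
                   ignore_attr = TRUE)
      expect_equal(back$waytotals[[s]][[tp]], coh$waytotals[[s]][[tp]])
    }
  }
})
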