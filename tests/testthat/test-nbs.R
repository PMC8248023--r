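# Paired network-based statistics: edge-wise F, component extraction,
# permutation null, threshold sweep, component summaries.

# minimal cohort_pair built directly from difference structures
toy_pair <- function(sc1, sc2, edges, n_nodes) {
  structure(list(edges = edges, sc1 = sc1, sc2 = sc2, d = sc2 - sc1,
                 n_nodes = n_nodes,
                 subjects = paste0("s", seq_len(nrow(sc1)))),
            class = "cohort_pair")
}

test_that("edge-wise paired F matches the closed-form paired t", {
  edges <- cbind(1:2, 3:4)
  sc1 <- matrix(0, 3, 2)
  sc2 <- cbind(c(0.1, 0.2, 0.3), c(0, 0, 0))
  fm <- edgewise_paired_f(toy_pair(sc1, sc2, edges, 5))
  t_hand <- 0.2 / (sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(fm[1, 3], t_hand^2, tolerance = 1e-12)
  expect_equal(fm[2, 4], 0)
  expect_true(isSymmetric(fm))

  # identical timepoints: all-zero F
  fz <- edgewise_paired_f(toy_pair(sc2, sc2, edges, 5))
  expect_true(all(fz == 0))

  # constant nonzero differences: infinite t, flagged
  sc2c <- cbind(c(1, 1, 1, 1), rep(0, 4))
  expect_warning(
    fi <- edgewise_paired_f(toy_pair(matrix(0, 4, 2), sc2c, edges, 5)),
    "zero-variance")
  expect_true(is.infinite(fi[1, 3]))
})

test_that("component extraction returns connected supra-threshold sets by size", {
  f <- matrix(0, 9, 9)
  set_edge <- function(i, j, v) f[i, j] <<- f[j, i] <<- v
  set_edge(1, 2, 5); set_edge(2, 3, 5); set_edge(7, 8, 5)
  comps <- extract_components(f, 1)
  expect_length(comps, 2)
  expect_equal(comps[[1]]$size, 2L)
  expect_equal(comps[[2]]$size, 1L)
  expect_length(extract_components(f, 10), 0)

  full <- matrix(3, 5, 5); diag(full) <- 0
  all_in <- extract_components(full, 1)
  expect_length(all_in, 1)
  expect_equal(all_in[[1]]$size, 10L)
})

test_that("largest component size is non-increasing along the threshold sweep", {
  coh <- generate_cohort(tiny_config(n_subjects = 10, n_nodes = 24,
    planted_increase = planted_df(cbind(c(1, 3, 5), c(3, 5, 7)), 0.6)))
  cp <- cohort_pair(build_connectomes(coh))
  sweep <- threshold_sweep(cp, seq(2, 40, by = 2))
  expect_true(all(diff(sweep$largest_size) <= 0))
  tail_zero <- sweep[sweep$threshold > max(edgewise_paired_f(cp)), ]
  expect_true(all(tail_zero$n_components == 0))
})

test_that("nbs p-values carry the +1 correction and respect the identity bound", {
  coh <- generate_cohort(tiny_config(n_subjects = 8, n_nodes = 20, seed = 3))
  cp <- cohort_pair(build_connectomes(coh))
  res <- nbs_paired(cp, default_primary_threshold(8), n_perm = 200,
                    seed = 5)
  expect_length(res$null_max_size, 200)
  for (co in res$components) {
    expect_gt(co$p_fwer, 0)
    expect_lte(co$p_fwer, 1)
    expect_equal(co$p_fwer,
                 (1 + sum(res$null_max_size >= co$size)) / 201)
  }
  # identity sign pattern is one of the possible permutations: its max
  # component size is >= every observed component size by construction
  fm <- edgewise_paired_f(cp)
  obs_max <- if (length(res$components)) res$components[[1]]$size else 0L
  id_max <- length(extract_components(fm, res$primary_threshold))
  if (obs_max > 0) {
    sizes <- vapply(extract_components(fm, res$primary_threshold),
                    `[[`, 0L, "size")
    expect_equal(max(sizes), obs_max)
  }
  # determinism under seed
  res2 <- nbs_paired(cp, default_primary_threshold(8), n_perm = 200,
                     seed = 5)
  expect_identical(res$null_max_size, res2$null_max_size)
})

test_that("permutation null matches full sign-flip enumeration on small n", {
  set.seed(9)
  ns <- 6
  edges <- cbind(c(1, 1, 2, 4), c(2, 3, 3, 5))
  d <- matrix(rnorm(ns * 4), ns, 4)
  cp <- toy_pair(matrix(0, ns, 4), d, edges, 6)
  thr <- 4
  # exact: all 2^6 sign patterns
  exact <- integer(2^ns)
  for (k in seq_len(2^ns)) {
    s <- 2 * as.integer(intToBits(k - 1)[1:ns]) - 1
    sd_ <- s * d
    m <- colMeans(sd_)
    v <- apply(sd_, 2, var)
    f <- ifelse(v > 0, ns * m^2 / v, 0)
    sel <- f > thr
    exact[k] <- if (!any(sel)) 0L else {
      e <- edges[sel, , drop = FALSE]
      max(longconn:::edge_components(e, 6)$sizes)
    }
  }
  res <- nbs_paired(cp, thr, n_perm = 4000, seed = 1)
  # Monte-Carlo distribution approximates the exact enumeration (KS-style
  # max CDF gap over observed sizes)
  sizes <- 0:4
  cdf_exact <- sapply(sizes, function(s) mean(exact <= s))
  cdf_mc <- sapply(sizes, function(s) mean(res$null_max_size <= s))
  expect_lt(max(abs(cdf_exact - cdf_mc)), 0.05)
})

test_that("planted components are recovered with the correct sign split", {
  inc <- cbind(c(1, 3), c(3, 5))
  dec <- cbind(c(10, 12), c(12, 14))
  coh <- generate_cohort(tiny_config(n_subjects = 25, n_nodes = 26,
    seed = 77,
    planted_increase = planted_df(inc, 0.6),
    planted_decrease = planted_df(dec, -0.4)))
  cp <- cohort_pair(build_connectomes(coh))
  res <- nbs_paired(cp, default_primary_threshold(25), n_perm = 300,
                    seed = 2)
  sig <- Filter(function(co) co$significant, res$components)
  expect_gte(length(sig), 1)
  got <- do.call(rbind, lapply(sig, `[[`, "edges"))
  key <- paste(got[, 1], got[, 2])
  expect_true(all(paste(inc[, 1], inc[, 2]) %in% key) ||
                all(paste(dec[, 1], dec[, 2]) %in% key))
  for (co in sig) {
    expect_equal(co$n_increase + co$n_decrease, co$size)
  }
})

test_that("component summaries stratify by sign and hemisphere with percent change", {
  # one-edge component halving everywhere: percent change -50
  edges <- cbind(1L, 3L)
  sc1 <- matrix(0.2, 5, 1)
  sc2 <- matrix(0.1, 5, 1)
  cp <- toy_pair(sc1, sc2, edges, 4)
  co <- list(edges = edges, mean_diff = -0.1)
  sm <- component_summaries(cp, co)
  all_all <- sm$percent_change[
    sm$percent_change$network == "all" &
      sm$percent_change$hemisphere_class == "all", ]
  expect_equal(all_all$pct_change, -50)
  expect_true("increases / all" %in% sm$empty_strata)

  # reference component: published hemisphere census
  comp <- reference_component()
  hemi <- classify_edge_hemisphere(comp$index1, comp$index2)
  inc <- comp$difference > 0
  expect_equal(sum(inc & hemi == "intra-left"), 2)
  expect_equal(sum(inc & hemi == "intra-right"), 0)
  expect_equal(sum(inc & hemi == "inter-hemispheric"), 5)
  expect_equal(sum(!inc & hemi == "intra-left"), 3)
  expect_equal(sum(!inc & hemi == "intra-right"), 5)
  expect_equal(sum(!inc & hemi == "inter-hemispheric"), 1)
})

test_that("stratum means equal brute-force averages on synthetic data", {
  coh <- generate_cohort(tiny_config(n_subjects = 6, n_nodes = 16, seed = 4))
  built <- build_connectomes(coh)
  cp <- cohort_pair(built)
  ne <- min(5, nrow(cp$edges))
  co <- list(edges = cp$edges[seq_len(ne), , drop = FALSE],
             mean_diff = colMeans(cp$d)[seq_len(ne)])
  sm <- component_summaries(cp, co)$subject_means
  row1 <- sm[sm$network == "all" & sm$hemisphere_class == "all" &
               sm$timepoint == 1 & sm$subject == cp$subjects[1], ]
  brute <- mean(sapply(seq_len(ne), function(k) {
    built$t1[[1]][co$edges[k, 1], co$edges[k, 2]]
  }))
  expect_equal(row1$mean_sc, brute, tolerance = 1e-12)
})
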