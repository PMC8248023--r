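# Community structure, hubs, fingerprints.

test_that("Louvain consensus recovers unambiguous two-clique structure", {
  w <- two_cliques(4)
  p <- louvain_consensus(w, n_runs = 50, seed = 1)
  expect_equal(p$mode_frequency, 1)
  expect_equal(p$assignment[1:4], rep(p$assignment[1], 4))
  expect_equal(p$assignment[5:8], rep(p$assignment[5], 4))
  expect_false(p$assignment[1] == p$assignment[5])
  # same seed -> identical partition
  expect_identical(p, louvain_consensus(w, n_runs = 50, seed = 1))
  expect_error(louvain_consensus(matrix(0, 3, 3), 10, 1), "empty graph")
})

test_that("modularity Q matches closed forms and vanishes under trivial structure", {
  w <- two_cliques(4)
  truth <- rep(1:2, each = 4)
  # two equal disconnected cliques, true split: Q = 1/2
  expect_equal(modularity_q(w, truth), 0.5, tolerance = 1e-12)
  expect_equal(modularity_q(w, rep(1, 8)), 0)
  # agrees with igraph on weighted random graphs
  set.seed(6)
  for (rep in 1:5) {
    m <- random_weight_matrix(12, 0.5)
    if (sum(m) == 0) next
    a <- sample(1:3, 12, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(m, "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_q(m, a),
                 igraph::modularity(g, a, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
  # random assignments on a random graph: the expectation over uniform
  # 3-group assignments has the closed form -(2/3) sum(s^2) / (2m)^2
  # (only the diagonal null terms survive in expectation)
  m <- random_weight_matrix(14, 0.5)
  qs <- replicate(400, modularity_q(m, sample(1:3, 14, replace = TRUE)))
  s <- rowSums(m)
  expected_q <- -(2 / 3) * sum(s^2) / sum(m)^2
  expect_equal(mean(qs), expected_q, tolerance = 0.02)
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "zero total")
})

test_that("consensus Q on planted blocks equals Q of the true assignment", {
  set.seed(44)
  n <- 24
  truth <- rep(1:4, each = 6)
  w <- matrix(runif(n * n, 0, 0.05), n, n)
  for (b in 1:4) {
    sel <- which(truth == b)
    w[sel, sel] <- runif(36, 0.8, 1)
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  p <- louvain_consensus(w, n_runs = 30, seed = 9)
  expect_equal(p$assignment, canon <- match(truth, unique(truth)))
  expect_equal(p$q, modularity_q(w, truth), tolerance = 1e-12)
})

test_that("partition similarity follows the best-Jaccard-match rule", {
  expect_equal(partition_similarity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(partition_similarity(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0.5)
  expect_equal(partition_similarity(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  # symmetrized variant is symmetric; plain direction need not be
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 1, 1, 1, 2, 2)
  expect_equal(partition_similarity(a, b, symmetrize = TRUE),
               partition_similarity(b, a, symmetrize = TRUE))
  expect_equal(partition_similarity(a, a), 1)
})

test_that("global hub rule: normalized efficiency above 1 + SD", {
  expect_equal(nrow(classify_global_hubs(rep(2, 6))), 0)
  hubs <- classify_global_hubs(c(1, 1, 1, 1, 2))
  expect_equal(hubs$node, 5)
  expect_equal(hubs$e_normalized, 2 / 1.2, tolerance = 1e-12)
  # hub-and-spoke: center has highest nodal efficiency
  star <- matrix(0, 7, 7)
  star[1, 2:7] <- star[2:7, 1] <- 1
  en <- efficiencies(shortest_path_lengths(star))$e_nodal
  expect_true(1 %in% classify_global_hubs(en)$node)
})

test_that("node roles: PC arithmetic and connector classification", {
  # node with 2 edges in-module and 2 in one other module: PC = 0.5
  w <- matrix(0, 7, 7)
  w[1, 2] <- w[1, 3] <- w[1, 4] <- w[1, 5] <- 1
  w <- pmax(w, t(w))
  a <- c(1, 1, 1, 2, 2, 2, 2)
  roles <- node_roles(w, a)
  expect_equal(roles$pc[1], 0.5)
  expect_equal(roles$pc[6], 0)          # no edges -> PC 0
  # all edges inside own module -> PC 0
  w2 <- two_cliques(4)
  r2 <- node_roles(w2, rep(1:2, each = 4))
  expect_true(all(r2$pc == 0))

  # a 5-cycle module plus a hub node wired to all of it and into the
  # opposite clique: high within-module degree and mixed participation
  k <- 5
  n <- 2 * k + 1
  w3 <- matrix(0, n, n)
  for (v in 1:k) {                         # 5-cycle, within-degree 2
    w3[v, v %% k + 1] <- 1
  }
  w3[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1  # K5 on the other side
  bridge <- n
  w3[bridge, 1:k] <- 1                      # hub covers its whole module
  w3[bridge, k + 1:3] <- 1                  # plus edges across
  w3 <- pmax(w3, t(w3))
  diag(w3) <- 0
  a3 <- c(rep(1, k), rep(2, k), 1)
  r3 <- node_roles(w3, a3)
  expect_equal(r3$role[bridge], "connector hub")
  # role labels are invariant to module relabeling
  r3b <- node_roles(w3, 3 - a3)
  expect_equal(r3$role, r3b$role)
})

test_that("RSN overlap columns sum to 100 and isolate matched modules", {
  set.seed(12)
  vols <- matrix(runif(8 * 3), 8, 3)
  a <- c(1, 1, 2, 2, 2, 3, 3, 3)
  ov <- rsn_overlap(a, vols)
  expect_equal(colSums(ov), rep(100, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # single module holding all regions -> 100 everywhere
  expect_true(all(rsn_overlap(rep(1, 8), vols) == 100))
  # module exactly covering the only regions intersecting an RSN
  vols2 <- vols
  vols2[3:8, 1] <- 0
  ov2 <- rsn_overlap(c(1, 1, 2, 2, 2, 3, 3, 3), vols2)
  expect_equal(as.numeric(ov2["module1", 1]), 100)
  expect_equal(as.numeric(ov2["module2", 1]), 0)
  expect_error(rsn_overlap(a, vols * 0), "zero total")
})

test_that("fingerprints count edges by module with the degree convention", {
  w <- two_cliques(4)
  a <- rep(1:2, each = 4)
  fp <- modular_fingerprints(w, a)
  expect_equal(fp$inter["module1", "module2"], 0)
  expect_equal(fp$intra, c(module1 = 12, module2 = 12))  # 2 x 6 edges
  expect_true(fp$no_connector_hubs)
  expect_equal(fp$overall_hub_driven, 0)

  # single bridge edge whose endpoint is a connector hub
  wb <- two_cliques(4, bridge = TRUE)
  fpb <- modular_fingerprints(wb, a, connector_hubs = 4L)
  expect_equal(fpb$hub_driven["module1", "module2"], 1)
  expect_equal(fpb$overall_hub_driven, 1)

  # doubling a hub's inter-module edges doubles the overall value
  wb2 <- wb
  wb2[4, 6] <- wb2[6, 4] <- 1
  fpb2 <- modular_fingerprints(wb2, a, connector_hubs = 4L)
  expect_equal(fpb2$overall_hub_driven, 2)
})

test_that("reference partition selection maximizes mean Q; first wins ties", {
  set.seed(2)
  n <- 12
  truth <- rep(1:2, each = 6)
  mats <- replicate(4, {
    m <- matrix(runif(n * n, 0, 0.1), n, n)
    m[1:6, 1:6] <- m[1:6, 1:6] + 0.8
    m[7:12, 7:12] <- m[7:12, 7:12] + 0.8
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
  }, simplify = FALSE)
  rand <- sample(1:2, n, replace = TRUE)
  chosen <- select_reference_partition(mats, list(rand, truth))
  expect_equal(attr(chosen, "index"), 2L)
  same <- select_reference_partition(mats, list(truth, truth))
  expect_equal(attr(same, "index"), 1L)
  single <- select_reference_partition(mats, list(truth))
  expect_equal(attr(single, "index"), 1L)
})
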