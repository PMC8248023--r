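# Graph metrics against hand calculations and independent brute-force
# oracles (Floyd-Warshall, exhaustive triangle census).

unit_triangle <- function() {
  m <- matrix(1, 3, 3); diag(m) <- 0; m
}

unit_path3 <- function() {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- m[2, 3] <- m[3, 2] <- 1
  m
}

test_that("degree and density on canonical toy graphs", {
  tri <- degree_and_density(unit_triangle())
  expect_equal(tri$k, c(2, 2, 2))
  expect_equal(tri$kappa, 1)
  pa <- degree_and_density(unit_path3())
  expect_equal(pa$k, c(1, 2, 1))
  expect_equal(pa$kappa, 2 / 3)
  expect_equal(degree_and_density(matrix(0, 4, 4))$kappa, 0)
})

test_that("shortest paths use inverse-weight costs", {
  l <- shortest_path_lengths(unit_triangle())
  expect_equal(l[upper.tri(l)], rep(1, 3))
  expect_equal(shortest_path_lengths(unit_path3())[1, 3], 2)
  half <- matrix(0, 2, 2); half[1, 2] <- half[2, 1] <- 0.5
  expect_equal(shortest_path_lengths(half)[1, 2], 2)
})

test_that("efficiencies and characteristic path length on hand-worked graphs", {
  eff_tri <- efficiencies(shortest_path_lengths(unit_triangle()))
  expect_equal(eff_tri$e_glob, 1)
  expect_equal(eff_tri$e_local, 1)

  eff_pa <- efficiencies(shortest_path_lengths(unit_path3()))
  expect_equal(eff_pa$e_glob, 5 / 6)
  expect_equal(eff_pa$e_nodal, c(0.75, 1, 0.75), ignore_attr = TRUE)

  expect_equal(characteristic_path_length(
    shortest_path_lengths(unit_path3())), 4 / 3)
  expect_equal(characteristic_path_length(
    shortest_path_lengths(unit_triangle())), 1)
  two <- matrix(0, 2, 2); two[1, 2] <- two[2, 1] <- 1
  expect_equal(characteristic_path_length(shortest_path_lengths(two)), 1)

  # isolated node: nodal efficiency 0, L on the largest component, flagged
  iso <- matrix(0, 4, 4)
  iso[1:3, 1:3] <- unit_triangle()
  l_iso <- shortest_path_lengths(iso)
  expect_equal(efficiencies(l_iso)$e_nodal[4], 0, ignore_attr = TRUE)
  cpl <- characteristic_path_length(l_iso)
  expect_true(isTRUE(attr(cpl, "disconnected")))
  expect_equal(as.numeric(cpl), 1)
})

test_that("clustering coefficient matches the triangle census", {
  expect_equal(clustering_coefficient(unit_triangle())$cl, 1)
  expect_equal(clustering_coefficient(unit_path3())$cl, 0)
  # 4-clique minus one edge
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  k4[1, 2] <- k4[2, 1] <- 0
  expect_equal(clustering_coefficient(k4)$cl_nodal,
               c(1, 1, 2 / 3, 2 / 3), ignore_attr = TRUE)
  expect_equal(clustering_coefficient(k4)$cl, oracle_clustering(k4))
})

test_that("all metrics agree with brute-force oracles on 50 random small graphs", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    w <- random_weight_matrix(n, runif(1, 0.3, 0.8))
    if (sum(w) == 0) next
    l <- shortest_path_lengths(w)
    l_oracle <- oracle_floyd_warshall(w)
    expect_equal(l, l_oracle, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(clustering_coefficient(w)$cl, oracle_clustering(w),
                 tolerance = 1e-10)
    # degree by explicit counting
    expect_equal(degree_and_density(w)$k,
                 apply(w > 0, 1, sum), ignore_attr = TRUE)
    # efficiency consistency: E_glob >= 1/L on connected graphs
    if (!any(is.infinite(l))) {
      expect_gte(efficiencies(l)$e_glob,
                 1 / as.numeric(characteristic_path_length(l)) - 1e-12)
    }
  }
})

test_that("global efficiency is monotone under edge addition", {
  set.seed(23)
  for (rep in 1:10) {
    w <- random_weight_matrix(10, 0.3)
    absent <- which(upper.tri(w) & w == 0)
    if (!length(absent)) next
    e0 <- efficiencies(shortest_path_lengths(w))$e_glob
    pick <- sample(absent, 1)
    w2 <- w
    w2[pick] <- 0.5
    w2 <- pmax(w2, t(w2))
    e1 <- efficiencies(shortest_path_lengths(w2))$e_glob
    expect_gte(e1, e0 - 1e-12)
  }
})

test_that("rewired ensembles preserve the degree sequence and are reproducible", {
  set.seed(31)
  w <- random_weight_matrix(15, 0.3)
  ens <- randomized_ensemble(w, n_nets = 5, seed = 7)
  k0 <- degree_and_density(w)$k
  for (m in ens) {
    expect_equal(degree_and_density(m)$k, k0)
    expect_true(isSymmetric(m))
    # weights are carried with edges: multiset of weights preserved
    expect_equal(sort(m[upper.tri(m) & m > 0]),
                 sort(w[upper.tri(w) & w > 0]))
  }
  expect_identical(ens, randomized_ensemble(w, n_nets = 5, seed = 7))
  expect_warning(randomized_ensemble(two_cliques(2) * 0, 2, 1), "too few")
})

test_that("sigma is 1 against the graph itself and > 1 for small-world graphs", {
  w <- random_weight_matrix(12, 0.5)
  expect_equal(small_world_sigma(w, list(w))$sigma, 1)

  # Watts-Strogatz ring lattice with a few rewired shortcuts
  set.seed(41)
  ws <- igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 60, 4, 0.05), sparse = FALSE) * 1
  ws <- pmax(ws, t(ws))
  ens <- randomized_ensemble(ws, n_nets = 20, seed = 2)
  expect_gt(small_world_sigma(ws, ens)$sigma, 1)

  # Erdos-Renyi graphs are their own null: sigma near 1
  er <- igraph::as_adjacency_matrix(
    igraph::sample_gnp(60, 0.15), sparse = FALSE) * 1
  er <- pmax(er, t(er))
  ens_er <- randomized_ensemble(er, n_nets = 20, seed = 3)
  expect_equal(small_world_sigma(er, ens_er)$sigma, 1, tolerance = 0.1)
})
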