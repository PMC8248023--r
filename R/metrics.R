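# Graph-theory characterization of weighted connectomes.
#
# Convention: degree, density, clustering and the degree-preserving rewiring
# operate on the binary support of the weight matrix; path-based metrics
# (shortest paths, efficiencies, characteristic path length) use weighted
# costs with edge cost = 1 / weight. Disconnected node pairs contribute
# 1/infinity = 0 to efficiencies; the characteristic path length of a
# disconnected graph is computed on the largest connected component and
# flagged.

#' Binary node degrees and connection density
#'
#' @param connectome Symmetric non-negative weight matrix, zero diagonal.
#' @return List with `k` (per-node binary degree), `mean_k`, and `kappa`
#'   (density, 2E / (N (N - 1))).
#' @export
degree_and_density <- function(connectome) {
  check_symmetric(connectome, what = "connectome")
  a <- connectome > 0
  diag(a) <- FALSE
  k <- rowSums(a)
  n <- nrow(a)
  list(k = k, mean_k = mean(k), kappa = sum(a) / (n * (n - 1)))
}

#' All-pairs shortest weighted path lengths
#'
#' Edge cost is the inverse of the connection weight; path length is the
#' minimal summed cost. Disconnected pairs get `Inf`, the diagonal 0.
#'
#' @param connectome Symmetric non-negative weight matrix.
#' @return n x n matrix of shortest path lengths.
#' @export
shortest_path_lengths <- function(connectome) {
  check_symmetric(connectome, what = "connectome")
  g <- igraph::graph_from_adjacency_matrix(connectome, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    n <- nrow(connectome)
    l <- matrix(Inf, n, n)
    diag(l) <- 0
    return(l)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

#' Global, nodal, and local efficiency
#'
#' Global efficiency is the mean inverse shortest path length over ordered
#' node pairs; nodal efficiency of node j averages 1 / l_ij over the other
#' nodes; local efficiency is the mean nodal efficiency. `1 / Inf` counts
#' as 0, so isolated nodes have nodal efficiency 0.
#'
#' @param l Shortest-path-length matrix from [shortest_path_lengths()].
#' @return List with `e_glob`, `e_nodal` (vector), `e_local`.
#' @export
efficiencies <- function(l) {
  stop_if_not_square(l, "path-length matrix")
  n <- nrow(l)
  inv <- 1 / l
  diag(inv) <- 0
  inv[is.infinite(l)] <- 0
  e_nodal <- colSums(inv) / (n - 1)
  list(e_glob = sum(inv) / (n * (n - 1)),
       e_nodal = e_nodal,
       e_local = mean(e_nodal))
}

#' Characteristic path length
#'
#' Mean shortest path length over all ordered node pairs. On a disconnected
#' graph the mean is taken over the largest connected component and the
#' result carries attribute `disconnected = TRUE`.
#'
#' @param l Shortest-path-length matrix.
#' @return Scalar L, possibly with a `disconnected` attribute.
#' @export
characteristic_path_length <- function(l) {
  stop_if_not_square(l, "path-length matrix")
  n <- nrow(l)
  if (!any(is.infinite(l))) {
    return(sum(l) / (n * (n - 1)))
  }
  # largest component: nodes mutually reachable
  reach <- is.finite(l)
  comp_of <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp_of[v] == 0L) {
      cid <- cid + 1L
      comp_of[reach[v, ]] <- cid
    }
  }
  big <- which(comp_of == which.max(tabulate(comp_of)))
  if (length(big) < 2) {
    out <- NA_real_
  } else {
    sub <- l[big, big, drop = FALSE]
    out <- sum(sub) / (length(big) * (length(big) - 1))
  }
  attr(out, "disconnected") <- TRUE
  out
}

#' Binary clustering coefficient
#'
#' Per node, the fraction of closed triangles among its neighbors,
#' 2 t_i / (k_i (k_i - 1)); nodes of degree < 2 contribute 0. Returns the
#' network mean and the per-node values.
#'
#' @param connectome Symmetric weight matrix (binary support is used).
#' @return List with `cl` (mean) and `cl_nodal`.
#' @export
clustering_coefficient <- function(connectome) {
  check_symmetric(connectome, what = "connectome")
  a <- (connectome > 0) * 1
  diag(a) <- 0
  k <- rowSums(a)
  t_i <- diag(a %*% a %*% a) / 2
  cl_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  list(cl = mean(cl_i), cl_nodal = cl_i)
}

#' Degree-preserving randomized ensemble
#'
#' Generates rewired copies of the connectome by attempted double-edge
#' swaps: two edges (a, b), (c, d) are replaced by (a, d), (c, b) when the
#' move creates neither self-loops nor multi-edges. Weights travel with the
#' surviving half-edges, the binary degree sequence is preserved exactly.
#' Each network receives `10 * E` attempted swaps.
#'
#' @param connectome Symmetric weight matrix.
#' @param n_nets Ensemble size (default 100).
#' @param seed Integer seed.
#' @return List of `n_nets` rewired weight matrices.
#' @export
randomized_ensemble <- function(connectome, n_nets = 100, seed = 1L) {
  check_symmetric(connectome, what = "connectome")
  stopifnot(n_nets >= 1)
  n <- nrow(connectome)
  pairs <- which(upper.tri(connectome) & connectome > 0, arr.ind = TRUE)
  ne <- nrow(pairs)
  if (ne < 2) {
    warning("too few edges to rewire; returning copies")
    return(replicate(n_nets, connectome, simplify = FALSE))
  }
  set.seed(seed)
  out <- vector("list", n_nets)
  for (r in seq_len(n_nets)) {
    ei <- pairs[, 1]
    ej <- pairs[, 2]
    w <- connectome[pairs]
    adj <- connectome > 0
    n_try <- 10L * ne
    c1 <- sample.int(ne, n_try, replace = TRUE)
    c2 <- sample.int(ne, n_try, replace = TRUE)
    flip <- stats::runif(n_try) < 0.5
    for (t in seq_len(n_try)) {
      e1 <- c1[t]; e2 <- c2[t]
      if (e1 == e2) next
      a <- ei[e1]; b <- ej[e1]
      # random orientation: either endpoint of the second edge may pair
      # with a; a fixed pairing rule over sorted endpoints biases the null
      if (flip[t]) {
        c <- ej[e2]; d <- ei[e2]
      } else {
        c <- ei[e2]; d <- ej[e2]
      }
      if (length(unique(c(a, b, c, d))) < 4) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c, b] <- adj[b, c] <- TRUE
      ei[e1] <- min(a, d); ej[e1] <- max(a, d)
      ei[e2] <- min(c, b); ej[e2] <- max(c, b)
    }
    m <- matrix(0, n, n)
    m[cbind(ei, ej)] <- w
    m[cbind(ej, ei)] <- w
    out[[r]] <- m
  }
  out
}

#' Small-world index
#'
#' sigma = (Cl / Cl_rand) / (L / L_rand), where Cl_rand and L_rand are the
#' ensemble means of the clustering coefficient and characteristic path
#' length of degree-preserving randomized networks. sigma > 1 indicates
#' small-world organization.
#'
#' @param connectome Symmetric weight matrix.
#' @param ensemble List of rewired networks from [randomized_ensemble()].
#' @return List with `sigma`, `cl`, `l`, `cl_rand`, `l_rand`.
#' @export
small_world_sigma <- function(connectome, ensemble) {
  stopifnot(length(ensemble) >= 1)
  cl <- clustering_coefficient(connectome)$cl
  l <- as.numeric(characteristic_path_length(
    shortest_path_lengths(connectome)))
  cl_rand <- mean(vapply(ensemble, function(m) {
    clustering_coefficient(m)$cl
  }, 0))
  l_rand <- mean(vapply(ensemble, function(m) {
    as.numeric(characteristic_path_length(shortest_path_lengths(m)))
  }, 0))
  if (cl_rand == 0 || l_rand == 0) {
    stop("ensemble clustering or path length is zero", call. = FALSE)
  }
  list(sigma = (cl / cl_rand) / (l / l_rand),
       cl = cl, l = l, cl_rand = cl_rand, l_rand = l_rand)
}

#' Full metric set for one connectome
#'
#' @param connectome Symmetric weight matrix.
#' @param n_rand Randomized-ensemble size for the small-world index
#'   (default 100); 0 skips sigma.
#' @param seed Seed for the ensemble.
#' @return One-row data frame: `mean_k`, `kappa`, `e_glob`, `e_local`, `L`,
#'   `cl`, and (when computed) `sigma`.
#' @export
metric_set <- function(connectome, n_rand = 100, seed = 1L) {
  dd <- degree_and_density(connectome)
  l <- shortest_path_lengths(connectome)
  eff <- efficiencies(l)
  cpl <- characteristic_path_length(l)
  cl <- clustering_coefficient(connectome)
  out <- data.frame(mean_k = dd$mean_k, kappa = dd$kappa,
                    e_glob = eff$e_glob, e_local = eff$e_local,
                    L = as.numeric(cpl), cl = cl$cl)
  if (n_rand > 0) {
    ens <- randomized_ensemble(connectome, n_rand, seed)
    out$sigma <- small_world_sigma(connectome, ens)$sigma
  }
  out
}

#' Metric table for a built cohort
#'
#' @param built Built cohort from [build_connectomes()].
#' @param n_rand Ensemble size per subject for sigma (default 100).
#' @param seed Master seed; per-subject ensemble seeds are spawned from it.
#' @return Tidy data frame, one row per subject x timepoint.
#' @export
cohort_metrics <- function(built, n_rand = 100, seed = 1L) {
  subjects <- built$subjects
  seeds <- spawn_seeds(seed, 2 * length(subjects))
  rows <- list()
  k <- 0L
  for (tp in 1:2) {
    for (s in seq_along(subjects)) {
      k <- k + 1L
      ms <- metric_set(built[[tp]][[s]], n_rand = n_rand, seed = seeds[k])
      rows[[k]] <- cbind(data.frame(subject = subjects[s], timepoint = tp),
                         ms)
    }
  }
  do.call(rbind, rows)
}
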