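# Modularity, hubs and modular-connectivity fingerprints.
#
# Community detection uses weighted Louvain run many times; the modal
# canonical partition is the consensus. Hub classification follows two
# complementary definitions: global hubs by normalized nodal efficiency,
# and provincial/connector hubs by within-module degree z-score crossed
# with participation coefficient. Degree quantities entering z, PC and the
# fingerprints are binary connection counts.

canonical_partition <- function(assignment) {
  # relabel modules by order of first appearance -> canonical form
  match(assignment, unique(assignment))
}

#' Consensus community structure via repeated Louvain runs
#'
#' Runs weighted Louvain `n_runs` times with distinct sub-seeds, maps every
#' partition to its canonical labeling (modules numbered by first node
#' occurrence), and returns the partition occurring most often. Ties are
#' broken by higher modularity, then lexicographically on the canonical
#' label string.
#'
#' @param connectome Symmetric non-negative weight matrix.
#' @param n_runs Number of Louvain runs (default 1000; analysis-scale runs
#'   use 10000).
#' @param seed Integer seed.
#' @return List of class `partition`: `assignment` (integer vector, module
#'   ids contiguous from 1), `q` (weighted modularity), `n_runs`,
#'   `mode_frequency`.
#' @export
louvain_consensus <- function(connectome, n_runs = 1000, seed = 1L) {
  check_symmetric(connectome, what = "connectome")
  stopifnot(n_runs >= 1)
  if (max(connectome) == 0) stop("empty graph", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(connectome, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wts <- igraph::E(g)$weight
  seeds <- spawn_seeds(seed, n_runs)
  keys <- character(n_runs)
  parts <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    cl <- igraph::cluster_louvain(g, weights = wts)
    parts[[r]] <- canonical_partition(igraph::membership(cl))
    keys[r] <- paste(parts[[r]], collapse = ",")
  }
  tab <- table(keys)
  top <- max(tab)
  cand <- names(tab)[tab == top]
  if (length(cand) > 1) {
    qs <- vapply(cand, function(k) {
      modularity_q(connectome, parts[[match(k, keys)]])
    }, 0)
    cand <- cand[qs == max(qs)]
    cand <- sort(cand)[1]
  }
  assignment <- parts[[match(cand, keys)]]
  structure(list(assignment = assignment,
                 q = modularity_q(connectome, assignment),
                 n_runs = n_runs,
                 mode_frequency = top / n_runs),
            class = "partition")
}

#' Weighted Newman modularity of a given assignment
#'
#' Q = sum_ij (w_ij - s_i s_j / (2m)) delta(c_i, c_j) / (2m), with s the
#' node strengths and 2m the total weight.
#'
#' @param connectome Symmetric non-negative weight matrix.
#' @param assignment Integer module id per node (or a `partition`).
#' @return Scalar Q.
#' @export
modularity_q <- function(connectome, assignment) {
  if (inherits(assignment, "partition")) assignment <- assignment$assignment
  check_symmetric(connectome, what = "connectome")
  stopifnot(length(assignment) == nrow(connectome))
  w <- connectome
  diag(w) <- 0
  two_m <- sum(w)
  if (two_m == 0) stop("zero total weight", call. = FALSE)
  s <- rowSums(w)
  same <- outer(assignment, assignment, "==")
  sum((w - outer(s, s) / two_m)[same]) / two_m
}

#' Similarity between two partitions of the same node set
#'
#' For each module of the first partition, the best Jaccard overlap (shared
#' regions over the union of regions) with any module of the second; the
#' similarity is the mean of these best matches. The symmetrized variant
#' averages both directions.
#'
#' @param p1,p2 `partition` objects or assignment vectors.
#' @param symmetrize Average both directions (default FALSE).
#' @return Value in (0, 1]; 1 for identical partitions.
#' @export
partition_similarity <- function(p1, p2, symmetrize = FALSE) {
  a1 <- if (inherits(p1, "partition")) p1$assignment else p1
  a2 <- if (inherits(p2, "partition")) p2$assignment else p2
  stopifnot(length(a1) == length(a2), length(a1) > 0)
  one_way <- function(x, y) {
    mean(vapply(unique(x), function(m) {
      mx <- x == m
      max(vapply(unique(y), function(k) {
        my <- y == k
        sum(mx & my) / sum(mx | my)
      }, 0))
    }, 0))
  }
  if (symmetrize) (one_way(a1, a2) + one_way(a2, a1)) / 2 else one_way(a1, a2)
}

#' Global hubs by normalized nodal efficiency
#'
#' Nodal efficiencies are normalized by their mean; a node is a hub when
#' its normalized efficiency exceeds 1 + SD of the normalized values
#' (strict inequality, so a flat profile yields no hubs).
#'
#' @param e_nodal Non-negative nodal-efficiency vector.
#' @return Data frame of hubs sorted by normalized efficiency descending:
#'   `node`, `e_nodal`, `e_normalized`; full normalized vector attached as
#'   attribute `e_normalized`.
#' @export
classify_global_hubs <- function(e_nodal) {
  stopifnot(length(e_nodal) >= 2, all(e_nodal >= 0), any(e_nodal > 0))
  e_norm <- e_nodal / mean(e_nodal)
  cut <- 1 + stats::sd(e_norm)
  hubs <- which(e_norm > cut)
  out <- data.frame(node = hubs, e_nodal = e_nodal[hubs],
                    e_normalized = e_norm[hubs])
  out <- out[order(-out$e_normalized), ]
  rownames(out) <- NULL
  attr(out, "e_normalized") <- e_norm
  out
}

#' Node roles: within-module degree z-score and participation coefficient
#'
#' z is computed on binary within-module degree, standardized within each
#' module (0 for singleton or zero-variance modules); PC is
#' 1 - sum_m (k_im / k_i)^2 on binary degrees. A node is a hub candidate
#' when z exceeds mean(z) + SD(z) over all nodes; candidates split into
#' provincial (PC <= 0.3) and connector (PC > 0.3) hubs.
#'
#' @param connectome Symmetric weight matrix (binary support used).
#' @param partition `partition` or assignment vector.
#' @return Data frame per node: `node`, `module`, `degree`, `within_degree`,
#'   `z`, `pc`, `role`.
#' @export
node_roles <- function(connectome, partition) {
  a <- if (inherits(partition, "partition")) partition$assignment else
    partition
  check_symmetric(connectome, what = "connectome")
  stopifnot(length(a) == nrow(connectome))
  adj <- (connectome > 0) * 1
  diag(adj) <- 0
  n <- nrow(adj)
  k <- rowSums(adj)
  mods <- sort(unique(a))
  # per-node degree into each module
  k_im <- vapply(mods, function(m) rowSums(adj[, a == m, drop = FALSE]),
                 numeric(n))
  within <- k_im[cbind(seq_len(n), match(a, mods))]
  z <- numeric(n)
  for (m in mods) {
    sel <- a == m
    if (sum(sel) < 2) next
    sdm <- stats::sd(within[sel])
    if (sdm > 0) z[sel] <- (within[sel] - mean(within[sel])) / sdm
  }
  pc <- ifelse(k > 0, 1 - rowSums((k_im / pmax(k, 1))^2), 0)
  cut <- mean(z) + stats::sd(z)
  role <- rep("none", n)
  role[z > cut & pc <= 0.3] <- "provincial hub"
  role[z > cut & pc > 0.3] <- "connector hub"
  data.frame(node = seq_len(n), module = a, degree = k,
             within_degree = within, z = z, pc = pc, role = role)
}

#' Module-by-RSN percentage overlap
#'
#' Entry (m, r) is 100 times the intersected volume between the regions of
#' module m and RSN r, normalized by the total intersected volume between
#' all atlas regions and that RSN; columns sum to 100 when every region is
#' assigned to a module.
#'
#' @param partition `partition` or assignment vector.
#' @param region_rsn_volumes Region x RSN matrix of intersection volumes.
#' @return Module x RSN percentage matrix.
#' @export
rsn_overlap <- function(partition, region_rsn_volumes) {
  a <- if (inherits(partition, "partition")) partition$assignment else
    partition
  v <- as.matrix(region_rsn_volumes)
  stopifnot(nrow(v) == length(a), all(v >= 0))
  tot <- colSums(v)
  if (any(tot == 0)) stop("RSN with zero total intersection", call. = FALSE)
  mods <- sort(unique(a))
  out <- t(vapply(mods, function(m) {
    100 * colSums(v[a == m, , drop = FALSE]) / tot
  }, numeric(ncol(v))))
  rownames(out) <- paste0("module", mods)
  out
}

#' Inter-/intra-modular connectivity fingerprints
#'
#' Modular connectivity strength is the binary degree (total connection
#' count) of the nodes forming a module. The module-by-module matrix
#' `inter` has, off the diagonal, the number of edges between two modules
#' and, on the diagonal, twice the number of within-module edges (the
#' degree convention). The connector-hub-driven matrix counts edges from
#' connector hubs (rows = the hub's module) toward each target module; its
#' overall value is the sum of its off-diagonal (inter-modular) entries.
#'
#' @param connectome Symmetric weight matrix (binary support used).
#' @param reference_partition `partition` or assignment vector, held fixed
#'   across timepoints.
#' @param connector_hubs Integer vector of connector-hub nodes (possibly
#'   empty).
#' @return List: `inter` (module x module), `intra` (vector, = diag of
#'   `inter`), `hub_driven` (module x module), `overall_hub_driven`,
#'   `no_connector_hubs` flag.
#' @export
modular_fingerprints <- function(connectome, reference_partition,
                                 connector_hubs = integer()) {
  a <- if (inherits(reference_partition, "partition")) {
    reference_partition$assignment
  } else reference_partition
  adj <- (connectome > 0) * 1
  diag(adj) <- 0
  mods <- sort(unique(a))
  b <- vapply(mods, function(m) as.numeric(a == m), numeric(length(a)))
  inter <- t(b) %*% adj %*% b
  dimnames(inter) <- list(paste0("module", mods), paste0("module", mods))
  hub_driven <- matrix(0, length(mods), length(mods),
                       dimnames = dimnames(inter))
  if (length(connector_hubs)) {
    for (h in connector_hubs) {
      hm <- match(a[h], mods)
      tgt <- vapply(mods, function(m) sum(adj[h, a == m]), 0)
      hub_driven[hm, ] <- hub_driven[hm, ] + tgt
    }
  }
  off <- hub_driven
  diag(off) <- 0
  list(inter = inter,
       intra = diag(inter),
       hub_driven = hub_driven,
       overall_hub_driven = sum(off),
       no_connector_hubs = length(connector_hubs) == 0)
}

#' Choose a reference partition by mean goodness-of-fit
#'
#' Scores every candidate partition by the mean, over subject matrices, of
#' its modularity Q; the candidate with the highest mean wins (first wins
#' ties).
#'
#' @param mats List of subject weight matrices.
#' @param candidates List of `partition` objects or assignment vectors.
#' @return The chosen candidate, with attributes `scores` and `index`.
#' @export
select_reference_partition <- function(mats, candidates) {
  stopifnot(length(candidates) >= 1)
  scores <- vapply(candidates, function(p) {
    mean(vapply(mats, modularity_q, 0, assignment = p))
  }, 0)
  best <- which.max(scores)   # which.max takes the first on ties
  out <- candidates[[best]]
  attr(out, "scores") <- scores
  attr(out, "index") <- best
  out
}
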