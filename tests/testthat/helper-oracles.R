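# Independent brute-force oracles used to check the fast implementations.
# These deliberately share no code with the package internals.

# Floyd-Warshall all-pairs shortest paths on costs 1/w
oracle_floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# exhaustive triangle census -> mean binary clustering coefficient
oracle_clustering <- function(w) {
  a <- w > 0
  diag(a) <- FALSE
  n <- nrow(a)
  cl <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ])
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (p in seq_len(k - 1)) {
      for (q in seq(p + 1, k)) {
        if (a[nb[p], nb[q]]) t_i <- t_i + 1
      }
    }
    cl[i] <- 2 * t_i / (k * (k - 1))
  }
  mean(cl)
}

# ANCOVA sums-of-squares oracle for the repeated-measures correlation:
# residualize y on subject dummies with and without x, by explicit
# projection matrices
oracle_rmcorr <- function(subject, x, y) {
  subj <- factor(subject)
  z <- stats::model.matrix(~ subj)
  proj <- function(m) m %*% solve(crossprod(m)) %*% t(m)
  p0 <- proj(z)
  r_y <- y - p0 %*% y
  r_x <- x - p0 %*% x
  slope <- sum(r_x * r_y) / sum(r_x^2)
  ss_x <- slope^2 * sum(r_x^2)
  ss_err <- sum((r_y - slope * r_x)^2)
  sign(slope) * sqrt(ss_x / (ss_x + ss_err))
}

# random symmetric weight matrix on n nodes with given edge probability
random_weight_matrix <- function(n, p = 0.4) {
  v <- ifelse(stats::runif(n * (n - 1) / 2) < p, stats::runif(n * (n - 1) / 2), 0)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

# small two-clique weight matrix (cliques of size k, optional bridge)
two_cliques <- function(k = 4, bridge = FALSE) {
  n <- 2 * k
  m <- matrix(0, n, n)
  m[1:k, 1:k] <- 1
  m[(k + 1):n, (k + 1):n] <- 1
  diag(m) <- 0
  if (bridge) m[k, k + 1] <- m[k + 1, k] <- 1
  m
}

# tiny cohort config used across tests (small n_nodes keeps tests quick)
tiny_config <- function(n_subjects = 8, n_nodes = 20, seed = 42, ...) {
  cohort_config(n_subjects = n_subjects, n_nodes = n_nodes, seed = seed, ...)
}

# planted edges helper
planted_df <- function(edges, delta) {
  data.frame(i = edges[, 1], j = edges[, 2], delta = delta)
}
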