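# Independent brute-force oracles, deliberately written with different
# algorithms from the package internals (Floyd-Warshall / explicit
# enumeration instead of bitset BFS).

# all-pairs shortest paths by Floyd-Warshall
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

bf_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- fw_distances(adj)
  sum(1 / d[row(d) != col(d)]) / (n * (n - 1))
}

bf_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  vapply(seq_len(n), function(i) sum(1 / d[i, -i]) / (n - 1), numeric(1))
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    bf_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

# random symmetric 0/1 adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.integer(stats::runif(sum(ut)) < p)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

path_graph <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1L
  a
}

complete_graph <- function(n) {
  a <- matrix(1L, n, n)
  diag(a) <- 0L
  a
}

star_graph <- function(n) {
  a <- matrix(0L, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1L
  a
}

# tiny cohort spec for fast end-to-end tests
tiny_cohort_spec <- function(seed = 1, n_per_group = c(6, 4, 3, 3),
                             deltas = c(0, 0.2, 0.4, 0.6),
                             n_timepoints = 100) {
  g <- smallworldfc:::default_groups()
  g$n_subjects <- as.integer(n_per_group)
  g$disruption <- deltas
  cohort_spec(n_timepoints = n_timepoints, groups = g, seed = seed)
}
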