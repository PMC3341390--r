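#' Binary network objects
#'
#' A `binary_network` wraps an undirected, unweighted adjacency matrix
#' together with its wiring cost (edge density) and, when it was produced
#' by thresholding a correlation matrix, the threshold that generated it.
#'
#' @param adjacency square 0/1 matrix, symmetric with zero diagonal.
#' @param threshold_kind `"correlation"`, `"cost"` or `NA` for benchmark
#'   graphs.
#' @param threshold_value the generating threshold, if any.
#' @return an object of class `binary_network` with elements `adjacency`,
#'   `n_nodes`, `n_edges`, `cost` (exactly `2 * n_edges / (n * (n - 1))`),
#'   and `threshold`.
#' @export
binary_network <- function(adjacency, threshold_kind = NA_character_,
                           threshold_value = NA_real_) {
  adjacency <- validate_adjacency(adjacency)
  n <- nrow(adjacency)
  k <- sum(adjacency) / 2L
  structure(
    list(adjacency = adjacency,
         n_nodes = n,
         n_edges = as.integer(k),
         cost = if (n > 1) 2 * k / (n * (n - 1)) else 0,
         threshold = list(kind = threshold_kind, value = threshold_value)),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("binary network: %d nodes, %d edges (cost %.4f)\n",
              x$n_nodes, x$n_edges, x$cost))
  if (!is.na(x$threshold$kind))
    cat(sprintf("  thresholded by %s at %.4f\n",
                x$threshold$kind, x$threshold$value))
  invisible(x)
}

validate_adjacency <- function(adjacency) {
  if (inherits(adjacency, "binary_network")) return(adjacency$adjacency)
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be a square matrix")
  a <- adjacency
  storage.mode(a) <- "integer"
  if (anyNA(a) || any(a != 0L & a != 1L))
    stop("adjacency entries must be 0 or 1")
  if (any(a != t(a))) stop("adjacency must be symmetric")
  if (any(diag(a) != 0L)) stop("adjacency must have a zero diagonal")
  a
}

#' Extract an adjacency matrix
#'
#' Accepts either a `binary_network` or a bare 0/1 matrix, validating the
#' latter.
#'
#' @param x a `binary_network` or symmetric 0/1 matrix with zero diagonal.
#' @return integer adjacency matrix.
#' @export
as_adjacency <- function(x) validate_adjacency(x)

#' Ring-lattice benchmark graph
#'
#' Regular ring lattice in which every node is joined to its `k / 2`
#' nearest neighbours on each side; the degree-matched regular baseline of
#' the small-world comparison.
#'
#' @param n number of nodes.
#' @param k even degree per node, `k < n`.
#' @return a [binary_network()].
#' @export
ring_lattice <- function(n, k) {
  if (k %% 2 != 0) stop("k must be even")
  if (k < 0 || k >= n) stop("k must satisfy 0 <= k < n")
  a <- matrix(0L, n, n)
  if (k > 0) {
    for (off in seq_len(k / 2)) {
      i <- seq_len(n)
      j <- ((i - 1 + off) %% n) + 1
      a[cbind(i, j)] <- 1L
      a[cbind(j, i)] <- 1L
    }
  }
  binary_network(a)
}

#' Uniform random graph with a fixed edge count
#'
#' Draws exactly `m` distinct undirected edges uniformly at random (an
#' Erdos-Renyi G(n, m) graph); the cost-matched random baseline used for
#' efficiency-curve comparisons.
#'
#' @param n number of nodes.
#' @param m number of edges, at most `n * (n - 1) / 2`.
#' @param seed optional integer seed.
#' @return a [binary_network()].
#' @export
random_gnm <- function(n, m, seed = NULL) {
  m_max <- n * (n - 1) / 2
  if (m > m_max) stop("m exceeds the maximum number of edges")
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0L, n, n)
  if (m > 0) {
    picked <- sample.int(m_max, m)
    ut <- which(upper.tri(a))
    a[ut[picked]] <- 1L
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
  }
  binary_network(a)
}

#' Watts-Strogatz small-world graph
#'
#' Starts from a ring lattice and rewires each edge independently with
#' probability `p` (the far endpoint is redirected to a uniformly chosen
#' node, avoiding self-loops and duplicate edges), preserving the total
#' edge count.
#'
#' @param n number of nodes.
#' @param k even lattice degree.
#' @param p rewiring probability in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a [binary_network()].
#' @export
watts_strogatz <- function(n, k, p, seed = NULL) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  net <- ring_lattice(n, k)
  a <- net$adjacency
  if (p == 0 || k == 0) return(net)
  for (off in seq_len(k / 2)) {
    for (i in seq_len(n)) {
      j <- ((i - 1 + off) %% n) + 1
      if (a[i, j] == 0L) next  # already rewired away
      if (stats::runif(1) >= p) next
      free <- which(a[i, ] == 0L)
      free <- free[free != i]
      if (length(free) == 0) next
      j_new <- free[sample.int(length(free), 1)]
      a[i, j] <- a[j, i] <- 0L
      a[i, j_new] <- a[j_new, i] <- 1L
    }
  }
  binary_network(a)
}
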