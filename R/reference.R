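#' Degree-preserving randomization
#'
#' Randomizes a binary network by repeated double-edge swaps: two edges
#' `(a, b)` and `(c, d)` are replaced by `(a, d)` and `(c, b)` unless a
#' self-loop or duplicate edge would result. The degree of every node —
#' and hence the edge count — is conserved exactly. Swap proposals that
#' would be invalid are rejected; if the swap quota cannot be met within
#' the attempt budget the best effort is returned, with the attempt count
#' recorded in the `"rewiring"` attribute.
#'
#' @param net a [binary_network()] or adjacency matrix.
#' @param n_swaps number of successful swaps to perform; default 10 times
#'   the edge count.
#' @param seed optional integer seed.
#' @param max_attempts proposal budget; default `100 * n_swaps`.
#' @return a rewired [binary_network()].
#' @export
rewire_degree_preserving <- function(net, n_swaps = NULL, seed = NULL,
                                     max_attempts = NULL) {
  a <- as_adjacency(net)
  k <- sum(a) / 2
  if (is.null(n_swaps)) n_swaps <- 10 * k
  if (is.null(max_attempts)) max_attempts <- 100 * max(1, n_swaps)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_rewire(a, as.integer(n_swaps), as.integer(max_attempts))
  adj <- res$adjacency
  dimnames(adj) <- dimnames(a)
  out <- binary_network(adj)
  attr(out, "rewiring") <- list(n_swaps_requested = n_swaps,
                                n_swaps_done = res$n_swaps_done,
                                n_attempts = res$n_attempts)
  out
}

#' Degree-matched regular (lattice) network
#'
#' Deterministic ring lattice on the same number of nodes with exactly the
#' same edge count as the input: complete neighbour rings (offset 1, 2,
#' ...) are laid down while a full ring fits, then the remaining edges are
#' placed at the next ring offset in ascending node order. The regular
#' baseline of the small-world comparison.
#'
#' @param net a [binary_network()] or adjacency matrix.
#' @return a [binary_network()] with identical node and edge counts.
#' @export
matched_regular <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes")
  k_target <- sum(a) / 2
  if (k_target > n * (n - 1) / 2) stop("edge count exceeds maximum")
  out <- matrix(0L, n, n, dimnames = dimnames(a))
  remaining <- k_target
  off <- 1
  while (remaining > 0 && off <= floor(n / 2)) {
    ring_size <- if (n %% 2 == 0 && off == n / 2) n / 2 else n
    i <- seq_len(min(ring_size, remaining))
    j <- ((i - 1 + off) %% n) + 1
    out[cbind(i, j)] <- 1L
    out[cbind(j, i)] <- 1L
    remaining <- remaining - length(i)
    off <- off + 1
  }
  binary_network(out)
}

#' Small-world decision for a binary network
#'
#' Compares the network's global and local efficiency against
#' degree-matched baselines: the mean over `n_random` degree-preserving
#' rewired surrogates, and the deterministic matched regular lattice. The
#' network is called small-world when
#' `E_glob(regular) < E_glob(G) < E_glob(random)` and
#' `E_loc(random) < E_loc(G) < E_loc(regular)` — more integrated than a
#' lattice while more locally clustered than a random graph.
#'
#' @param net a [binary_network()] or adjacency matrix.
#' @param n_random number of rewired surrogates (default 20).
#' @param seed optional integer seed for the surrogate draws.
#' @param n_swaps swaps per surrogate; default 10 times the edge count.
#' @return object of class `small_world_report`: real, random (mean and
#'   SD) and regular efficiencies, `criteria_passed`, and a `reason` when
#'   the decision is degenerate.
#' @export
small_world_check <- function(net, n_random = 20, seed = NULL,
                              n_swaps = NULL) {
  if (n_random < 1) stop("n_random must be at least 1")
  a <- as_adjacency(net)
  n <- nrow(a)
  k <- sum(a) / 2
  report <- list(n_nodes = n, n_edges = k, n_random_replicates = n_random,
                 seed = seed)
  if (k == 0 || k == n * (n - 1) / 2) {
    report <- c(report, list(
      e_glob_real = cpp_global_efficiency(a),
      e_loc_real = cpp_local_efficiency(a),
      e_glob_random = NA_real_, e_loc_random = NA_real_,
      e_glob_random_sd = NA_real_, e_loc_random_sd = NA_real_,
      e_glob_regular = NA_real_, e_loc_regular = NA_real_,
      criteria_passed = FALSE,
      reason = if (k == 0) "empty graph" else "complete graph"))
    class(report) <- "small_world_report"
    return(report)
  }
  if (!is.null(seed)) set.seed(seed)
  e_glob_real <- cpp_global_efficiency(a)
  e_loc_real <- cpp_local_efficiency(a)
  rand_glob <- rand_loc <- numeric(n_random)
  for (i in seq_len(n_random)) {
    sur <- rewire_degree_preserving(a, n_swaps = n_swaps)
    rand_glob[i] <- cpp_global_efficiency(sur$adjacency)
    rand_loc[i] <- cpp_local_efficiency(sur$adjacency)
  }
  reg <- matched_regular(a)
  e_glob_reg <- cpp_global_efficiency(reg$adjacency)
  e_loc_reg <- cpp_local_efficiency(reg$adjacency)
  passed <- e_glob_reg < e_glob_real && e_glob_real < mean(rand_glob) &&
    mean(rand_loc) < e_loc_real && e_loc_real < e_loc_reg
  report <- c(report, list(
    e_glob_real = e_glob_real, e_loc_real = e_loc_real,
    e_glob_random = mean(rand_glob), e_loc_random = mean(rand_loc),
    e_glob_random_sd = stats::sd(rand_glob),
    e_loc_random_sd = stats::sd(rand_loc),
    e_glob_regular = e_glob_reg, e_loc_regular = e_loc_reg,
    criteria_passed = passed, reason = NA_character_))
  class(report) <- "small_world_report"
  report
}

#' @export
print.small_world_report <- function(x, ...) {
  cat(sprintf("small-world check: %d nodes, %d edges\n",
              x$n_nodes, x$n_edges))
  if (!is.na(x$reason)) {
    cat(sprintf("  degenerate (%s): criteria not applicable\n", x$reason))
    return(invisible(x))
  }
  cat(sprintf("  E_glob: regular %.4f < real %.4f < random %.4f ?\n",
              x$e_glob_regular, x$e_glob_real, x$e_glob_random))
  cat(sprintf("  E_loc:  random %.4f < real %.4f < regular %.4f ?\n",
              x$e_loc_random, x$e_loc_real, x$e_loc_regular))
  cat(sprintf("  small-world criteria %s (%d surrogates)\n",
              if (x$criteria_passed) "PASSED" else "failed",
              x$n_random_replicates))
  invisible(x)
}
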