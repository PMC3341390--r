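#' Shortest path lengths of a binary network
#'
#' Breadth-first-search hop counts between every pair of nodes.
#' Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param net a [binary_network()] or 0/1 adjacency matrix.
#' @return numeric N x N matrix of path lengths.
#' @export
shortest_path_lengths <- function(net) {
  a <- as_adjacency(net)
  d <- cpp_shortest_paths(a)
  dimnames(d) <- dimnames(a)
  d
}

#' Global efficiency
#'
#' Mean inverse shortest path length over all ordered node pairs,
#' `E_glob = (1 / (N (N - 1))) * sum_{i != j} 1 / L_ij`, with
#' `1 / Inf = 0` for disconnected pairs. An index of network integration:
#' 1 for a complete graph, 0 for an empty one.
#'
#' @inheritParams shortest_path_lengths
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) cpp_global_efficiency(as_adjacency(net))

#' Local efficiency
#'
#' Mean, over nodes, of the global efficiency of the subgraph induced on
#' each node's neighbours (the node itself excluded). Nodes with fewer
#' than two neighbours contribute zero. An index of segregation and fault
#' tolerance.
#'
#' @inheritParams shortest_path_lengths
#' @return scalar in `[0, 1]`.
#' @export
local_efficiency <- function(net) cpp_local_efficiency(as_adjacency(net))

#' Nodal efficiency
#'
#' Per-node efficiency `E_nod(i) = (1 / (N - 1)) * sum_{j != i} 1 / L_ij`,
#' the inverse of the harmonic-mean shortest path length from node `i` to
#' every other node. High values mark hub roles; the mean over nodes
#' equals the global efficiency.
#'
#' @inheritParams shortest_path_lengths
#' @return numeric vector of length N.
#' @export
nodal_efficiency <- function(net) {
  a <- as_adjacency(net)
  e <- cpp_nodal_efficiency(a)
  names(e) <- rownames(a)
  e
}

#' Nodal connectivity strength
#'
#' Mean correlation of each region with the `N - 1` other regions,
#' `S_i = (1 / (N - 1)) * sum_{j != i} r_ij`.
#'
#' @param mat N x N correlation matrix (unit diagonal).
#' @return numeric vector of length N.
#' @export
nodal_strength <- function(mat) {
  n <- nrow(mat)
  if (n < 2) stop("need at least two regions")
  s <- (rowSums(mat) - diag(mat)) / (n - 1)
  names(s) <- rownames(mat)
  s
}

#' Efficiency as a function of threshold
#'
#' Binarizes a correlation matrix over an ascending grid of correlation or
#' cost thresholds and records global, local and nodal efficiency at each
#' point. Thresholds at which the network has no edges are recorded as
#' zeros and flagged.
#'
#' @param mat correlation matrix.
#' @param thresholds strictly increasing thresholds in (0, 1).
#' @param kind `"cost"` (relative efficiency: equal edge counts) or
#'   `"correlation"` (absolute efficiency).
#' @return an `efficiency_curve`: list with `kind`, `thresholds`, `e_glob`,
#'   `e_loc`, `nodal` (N x length(thresholds) matrix) and `empty` flags.
#' @export
efficiency_sweep <- function(mat, thresholds,
                             kind = c("cost", "correlation")) {
  kind <- match.arg(kind)
  if (any(diff(thresholds) <= 0)) stop("thresholds must be strictly increasing")
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  k <- length(thresholds)
  n <- nrow(mat)
  e_glob <- e_loc <- numeric(k)
  nodal <- matrix(0, n, k, dimnames = list(rownames(mat), NULL))
  empty <- logical(k)
  for (i in seq_len(k)) {
    net <- if (kind == "cost") threshold_cost(mat, thresholds[i])
           else threshold_correlation(mat, thresholds[i])
    if (net$n_edges == 0L) { empty[i] <- TRUE; next }
    a <- net$adjacency
    e_glob[i] <- cpp_global_efficiency(a)
    e_loc[i] <- cpp_local_efficiency(a)
    nodal[, i] <- cpp_nodal_efficiency(a)
  }
  structure(list(kind = kind, thresholds = thresholds, e_glob = e_glob,
                 e_loc = e_loc, nodal = nodal, empty = empty),
            class = "efficiency_curve")
}

#' @export
print.efficiency_curve <- function(x, ...) {
  cat(sprintf("efficiency curve over %d %s thresholds in [%.3f, %.3f]\n",
              length(x$thresholds), x$kind,
              min(x$thresholds), max(x$thresholds)))
  cat(sprintf("  E_glob range %.4f-%.4f, E_loc range %.4f-%.4f\n",
              min(x$e_glob), max(x$e_glob), min(x$e_loc), max(x$e_loc)))
  invisible(x)
}

#' Integrated (threshold-averaged) efficiency
#'
#' Trapezoidal integral of an efficiency curve over `[range_lo, range_hi]`
#' divided by the range width, i.e. a threshold-averaged efficiency on the
#' same `[0, 1]` scale as the pointwise values. This removes the
#' dependence of group comparisons on any single threshold choice.
#'
#' @param curve an `efficiency_curve` from [efficiency_sweep()].
#' @param range_lo,range_hi integration bounds; both must lie within the
#'   sampled thresholds. Default: the full sampled range.
#' @param what `"e_glob"`, `"e_loc"`, or `"nodal"` (per-region integral).
#' @return scalar (or, for `"nodal"`, a vector of length N).
#' @export
integrate_curve <- function(curve, range_lo = NULL, range_hi = NULL,
                            what = c("e_glob", "e_loc", "nodal")) {
  what <- match.arg(what)
  thr <- curve$thresholds
  if (is.null(range_lo)) range_lo <- min(thr)
  if (is.null(range_hi)) range_hi <- max(thr)
  if (range_lo < min(thr) - 1e-9 || range_hi > max(thr) + 1e-9)
    stop("integration range must lie within the sampled thresholds")
  sel <- which(thr >= range_lo - 1e-9 & thr <= range_hi + 1e-9)
  if (length(sel) < 2) stop("fewer than 2 sampled points in range")
  x <- thr[sel]
  width <- x[length(x)] - x[1]
  if (what == "nodal") {
    v <- apply(curve$nodal[, sel, drop = FALSE], 1,
               function(y) pracma::trapz(x, y))
    return(v / width)
  }
  y <- curve[[what]][sel]
  pracma::trapz(x, y) / width
}

#' Per-subject integrated network efficiencies
#'
#' Convenience wrapper running the full single-subject network analysis:
#' Pearson correlation matrix, absolute (correlation-threshold) and
#' relative (cost-threshold) efficiency sweeps, and their integrated
#' global, local and nodal values, plus nodal strength.
#'
#' @param ts T x N regional time-series matrix (or a precomputed
#'   correlation matrix with `is_matrix = TRUE`).
#' @param corr_thresholds,cost_thresholds ascending sweep grids; defaults
#'   0.05-0.60 and 0.05-0.50.
#' @param step grid step, default 0.01.
#' @param is_matrix set `TRUE` when `ts` is already a correlation matrix.
#' @return list with scalars `e_glob_abs`, `e_loc_abs`, `e_glob_rel`,
#'   `e_loc_rel` (integrated values) and vectors `strength`, `nodal_abs`,
#'   `nodal_rel`.
#' @export
subject_efficiency <- function(ts,
                               corr_thresholds = NULL,
                               cost_thresholds = NULL,
                               step = 0.01,
                               is_matrix = FALSE) {
  if (is.null(corr_thresholds)) corr_thresholds <- seq(0.05, 0.60, by = step)
  if (is.null(cost_thresholds)) cost_thresholds <- seq(0.05, 0.50, by = step)
  mat <- if (is_matrix) ts else correlation_matrix(ts)
  abs_curve <- efficiency_sweep(mat, corr_thresholds, "correlation")
  rel_curve <- efficiency_sweep(mat, cost_thresholds, "cost")
  list(e_glob_abs = integrate_curve(abs_curve, what = "e_glob"),
       e_loc_abs = integrate_curve(abs_curve, what = "e_loc"),
       e_glob_rel = integrate_curve(rel_curve, what = "e_glob"),
       e_loc_rel = integrate_curve(rel_curve, what = "e_loc"),
       strength = nodal_strength(mat),
       nodal_abs = integrate_curve(abs_curve, what = "nodal"),
       nodal_rel = integrate_curve(rel_curve, what = "nodal"))
}

#' Integrated efficiencies for every subject of a cohort
#'
#' @param cohort a cohort from [generate_cohort()] (list with `subjects`
#'   data frame and `timeseries` list), or a named list of correlation
#'   matrices with `is_matrix = TRUE`.
#' @inheritParams subject_efficiency
#' @return list with `summary` (one row per subject: integrated absolute /
#'   relative global and local efficiency joined to the subject table) and
#'   matrices `strength`, `nodal_abs`, `nodal_rel` (subject x region).
#' @export
cohort_efficiency <- function(cohort, corr_thresholds = NULL,
                              cost_thresholds = NULL, step = 0.01,
                              is_matrix = FALSE) {
  series <- if (is_matrix) cohort else cohort$timeseries
  ids <- names(series)
  res <- lapply(series, subject_efficiency,
                corr_thresholds = corr_thresholds,
                cost_thresholds = cost_thresholds,
                step = step, is_matrix = is_matrix)
  summary <- data.frame(
    subject_id = ids,
    e_glob_abs = vapply(res, `[[`, numeric(1), "e_glob_abs"),
    e_loc_abs = vapply(res, `[[`, numeric(1), "e_loc_abs"),
    e_glob_rel = vapply(res, `[[`, numeric(1), "e_glob_rel"),
    e_loc_rel = vapply(res, `[[`, numeric(1), "e_loc_rel"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is_matrix && !is.null(cohort$subjects))
    summary <- merge(cohort$subjects, summary, by = "subject_id",
                     sort = FALSE)
  list(summary = summary,
       strength = do.call(rbind, lapply(res, `[[`, "strength")),
       nodal_abs = do.call(rbind, lapply(res, `[[`, "nodal_abs")),
       nodal_rel = do.call(rbind, lapply(res, `[[`, "nodal_rel")))
}
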