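#' Interregional Pearson correlation matrix
#'
#' Pearson correlation between every pair of regional time series; the
#' weighted functional-connectivity network. Zero-variance regions yield
#' zero entries (flagged in the `"flagged_regions"` attribute) rather than
#' `NA`.
#'
#' @param ts T x N matrix, one column per region.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  sds <- apply(ts, 2, stats::sd)
  flat <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(ts))
  if (length(flat) > 0) {
    warning(sprintf("%d zero-variance region(s); correlations set to 0",
                    length(flat)))
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  attr(r, "flagged_regions") <- flat
  r
}

#' Group-level correlation matrix
#'
#' Entrywise average of subject correlation matrices through Fisher's
#' z-transform (variance-stabilized pooling): `tanh(mean(atanh(r)))`.
#' Entries at exactly `|r| = 1` are clipped to `1 - 1e-7` before the
#' transform.
#'
#' @param mats list of N x N correlation matrices with identical dimnames.
#' @return pooled N x N correlation matrix, unit diagonal.
#' @export
group_matrix <- function(mats) {
  if (length(mats) < 1) stop("need at least one matrix")
  dims <- dim(mats[[1]])
  clip <- 1 - 1e-7
  z <- 0
  n_clipped <- 0L
  for (m in mats) {
    if (!identical(dim(m), dims)) stop("matrices must share dimensions")
    m <- pmin(pmax(unclass(m), -clip), clip)
    n_clipped <- n_clipped + sum(abs(m) >= clip & row(m) != col(m))
    z <- z + atanh(m)
  }
  r <- tanh(z / length(mats))
  diag(r) <- 1
  dimnames(r) <- dimnames(mats[[1]])
  attr(r, "n_clipped") <- n_clipped
  r
}

#' Binarize at a correlation threshold
#'
#' Keeps an edge wherever `r_ij > r_thr` (strict, positive correlations
#' only). Networks built this way across groups share the threshold but
#' not the edge count, and measure "absolute" network efficiency.
#'
#' @param mat correlation matrix.
#' @param r_thr threshold in (0, 1).
#' @return a [binary_network()].
#' @export
threshold_correlation <- function(mat, r_thr) {
  if (r_thr <= 0 || r_thr >= 1) stop("r_thr must be in (0, 1)")
  a <- (unclass(mat) > r_thr) * 1L
  diag(a) <- 0L
  storage.mode(a) <- "integer"
  binary_network(a, "correlation", r_thr)
}

#' Binarize at a wiring-cost threshold
#'
#' Keeps the `m = floor(cost * N * (N - 1) / 2)` strongest correlations,
#' so every network binarized at the same cost has exactly the same number
#' of nodes and edges ("relative" efficiency). Ties are broken
#' deterministically by ascending `(i, j)` order.
#'
#' @param mat correlation matrix.
#' @param cost target edge density in (0, 1).
#' @return a [binary_network()]; its realized cost `2m / (N (N - 1))`
#'   never exceeds `cost`.
#' @export
threshold_cost <- function(mat, cost) {
  if (cost <= 0 || cost >= 1) stop("cost must be in (0, 1)")
  n <- nrow(mat)
  m_max <- n * (n - 1) / 2
  m <- floor(cost * m_max)
  if (m == 0) warning("requested cost keeps no edges")
  a <- matrix(0L, n, n, dimnames = dimnames(mat))
  if (m > 0) {
    ut <- which(upper.tri(mat))
    r <- unclass(mat)[ut]
    ij <- arrayInd(ut, dim(mat))
    keep <- ut[order(-r, ij[, 1], ij[, 2])[seq_len(m)]]
    a[keep] <- 1L
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
  }
  binary_network(a, "cost", cost)
}
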