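test_that("analytic efficiency values hold exactly", {
  expect_identical(global_efficiency(complete_graph(4)), 1)
  expect_identical(global_efficiency(complete_graph(7)), 1)
  expect_identical(global_efficiency(matrix(0L, 5, 5)), 0)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  # two disjoint edges on 4 nodes: 4 of 12 ordered pairs at distance 1
  two_edges <- matrix(0L, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- 1L
  two_edges[3, 4] <- two_edges[4, 3] <- 1L
  expect_equal(global_efficiency(two_edges), 1 / 3)
  expect_identical(local_efficiency(complete_graph(4)), 1)
  expect_identical(local_efficiency(star_graph(6)), 0)
  expect_identical(nodal_efficiency(star_graph(8))[1], 1)
  isolated <- matrix(0L, 4, 4)
  isolated[2, 3] <- isolated[3, 2] <- 1L
  expect_identical(nodal_efficiency(isolated)[1], 0)
})

test_that("shortest path lengths match Floyd-Warshall on random graphs", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    a <- random_adjacency(n, stats::runif(1, 0.1, 0.7))
    expect_identical(shortest_path_lengths(a), fw_distances(a))
  }
})

test_that("disconnected pairs are Inf and contribute zero efficiency", {
  a <- path_graph(3)
  a <- rbind(cbind(a, matrix(0L, 3, 2)), matrix(0L, 2, 5))
  d <- shortest_path_lengths(a)
  expect_identical(d[1, 4], Inf)
  expect_identical(d[1, 3], 2)
  expect_equal(global_efficiency(a), (5 / 6) * (3 * 2) / (5 * 4))
})

test_that("efficiencies agree with brute-force enumeration", {
  set.seed(7)
  for (i in 1:60) {
    n <- sample(4:16, 1)
    a <- random_adjacency(n, stats::runif(1, 0.1, 0.8))
    expect_equal(global_efficiency(a), bf_global_efficiency(a),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(a), bf_local_efficiency(a),
                 tolerance = 1e-12)
    expect_equal(unname(nodal_efficiency(a)), bf_nodal_efficiency(a),
                 tolerance = 1e-12)
  }
})

test_that("mean nodal efficiency equals global efficiency", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    a <- random_adjacency(n, stats::runif(1, 0.05, 0.9))
    expect_equal(mean(nodal_efficiency(a)), global_efficiency(a),
                 tolerance = 1e-12)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:15, 1)
    a <- random_adjacency(n, 0.3)
    e0 <- global_efficiency(a)
    free <- which(a == 0 & upper.tri(a))
    if (length(free) == 0) next
    pick <- sample(free, 1)
    ij <- arrayInd(pick, dim(a))
    a[ij[1], ij[2]] <- a[ij[2], ij[1]] <- 1L
    expect_gte(global_efficiency(a), e0)
  }
})

test_that("metrics are permutation equivariant", {
  set.seed(13)
  a <- random_adjacency(12, 0.35)
  p <- sample(12)
  ap <- a[p, p]
  expect_equal(global_efficiency(ap), global_efficiency(a))
  expect_equal(local_efficiency(ap), local_efficiency(a))
  expect_equal(unname(nodal_efficiency(ap)),
               unname(nodal_efficiency(a))[p])
})

test_that("nodal strength averages correlations over N - 1 regions", {
  m <- matrix(0.5, 6, 6); diag(m) <- 1
  expect_equal(unname(nodal_strength(m)), rep(0.5, 6))
  m3 <- diag(3)
  m3[1, 2] <- m3[2, 1] <- 0.2
  m3[1, 3] <- m3[3, 1] <- 0.4
  m3[2, 3] <- m3[3, 2] <- 0.6
  expect_equal(unname(nodal_strength(m3)), c(0.3, 0.4, 0.5))
})

test_that("efficiency values always lie in [0, 1]", {
  set.seed(17)
  for (i in 1:30) {
    a <- random_adjacency(sample(3:25, 1), stats::runif(1, 0, 1))
    expect_true(global_efficiency(a) >= 0 && global_efficiency(a) <= 1)
    expect_true(local_efficiency(a) >= 0 && local_efficiency(a) <= 1)
    ne <- nodal_efficiency(a)
    expect_true(all(ne >= 0 & ne <= 1))
  }
})

test_that("efficiency sweep matches direct metric calls", {
  set.seed(3)
  ts <- matrix(rnorm(60 * 8), 60, 8)
  mat <- correlation_matrix(ts)
  sweep1 <- efficiency_sweep(mat, c(0.2, 0.3), "cost")
  net <- threshold_cost(mat, 0.2)
  expect_equal(sweep1$e_glob[1], global_efficiency(net))
  expect_equal(sweep1$e_loc[1], local_efficiency(net))
  expect_equal(unname(sweep1$nodal[, 1]), unname(nodal_efficiency(net)))
  # cost sweep of E_glob is non-decreasing (edge-addition property)
  sw <- efficiency_sweep(mat, seq(0.1, 0.9, 0.1), "cost")
  expect_true(all(diff(sw$e_glob) >= -1e-12))
})

test_that("all-0.8 matrix gives constant curves until the threshold", {
  m <- matrix(0.8, 5, 5); diag(m) <- 1
  sw <- efficiency_sweep(m, c(0.3, 0.5, 0.7, 0.85), "correlation")
  expect_equal(sw$e_glob, c(1, 1, 1, 0))
  expect_true(sw$empty[4])
})

test_that("integrated efficiency is a threshold average", {
  thr <- seq(0.1, 0.5, 0.1)
  const_curve <- structure(list(kind = "cost", thresholds = thr,
                                e_glob = rep(0.7, 5),
                                e_loc = rep(0.4, 5),
                                nodal = matrix(0.3, 2, 5),
                                empty = rep(FALSE, 5)),
                           class = "efficiency_curve")
  expect_equal(integrate_curve(const_curve, what = "e_glob"), 0.7)
  expect_equal(integrate_curve(const_curve, what = "e_loc"), 0.4)
  expect_equal(unname(integrate_curve(const_curve, what = "nodal")),
               c(0.3, 0.3))
  ramp <- structure(list(kind = "cost", thresholds = c(0, 1) * 0.4 + 0.1,
                         e_glob = c(0, 1), e_loc = c(0, 1),
                         nodal = matrix(c(0, 1), 1, 2),
                         empty = c(FALSE, FALSE)),
                    class = "efficiency_curve")
  expect_equal(integrate_curve(ramp, what = "e_glob"), 0.5)
})

test_that("trapezoid integral matches a fine Riemann refinement", {
  thr <- seq(0.05, 0.6, 0.01)
  vals <- 0.5 + 0.3 * sin(8 * thr)
  curve <- structure(list(kind = "correlation", thresholds = thr,
                          e_glob = vals, e_loc = vals,
                          nodal = matrix(vals, 1, length(thr),
                                         byrow = TRUE),
                          empty = rep(FALSE, length(thr))),
                     class = "efficiency_curve")
  got <- integrate_curve(curve, 0.05, 0.6, "e_glob")
  # midpoint Riemann sum over each sampled interval of the piecewise
  # linear interpolant, at 1000x refinement
  f <- stats::approxfun(thr, vals)
  xs <- seq(0.05, 0.6, length.out = 55001)
  mid <- (xs[-1] + xs[-length(xs)]) / 2
  ref <- sum(f(mid) * diff(xs)) / (0.6 - 0.05)
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("integration range must be sampled and contain 2+ points", {
  thr <- seq(0.1, 0.5, 0.1)
  curve <- structure(list(kind = "cost", thresholds = thr,
                          e_glob = thr, e_loc = thr,
                          nodal = matrix(thr, 1), empty = rep(FALSE, 5)),
                     class = "efficiency_curve")
  expect_error(integrate_curve(curve, 0.05, 0.5), "within the sampled")
  expect_error(integrate_curve(curve, 0.1, 0.12), "fewer than 2")
})
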