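test_that("target correlation interpolates linearly in the disruption", {
  # two modules of 2 regions, uniform vulnerability, no boost
  spec <- cohort_spec(n_regions = 4, n_timepoints = 50,
                      module_assignment = c(1, 1, 2, 2),
                      homotopic_pairs = matrix(integer(0), 0, 2),
                      base_within_module_r = 0.6,
                      base_background_r = 0.1,
                      category_boost = numeric(0), vulnerability = numeric(0))
  r0 <- target_correlation(spec, 0)
  expect_equal(r0[1, 2], 0.6)
  expect_equal(r0[3, 4], 0.6)
  expect_equal(r0[1, 3], 0.1)
  expect_equal(diag(r0), rep(1, 4))
  r1 <- target_correlation(spec, 1)
  expect_equal(r1[1, 2], 0.1)
  expect_equal(r1[1, 4], 0.1)
  r05 <- target_correlation(spec, 0.5)
  expect_equal(r05[1, 2], 0.1 + 0.5 * (0.6 - 0.1))
  expect_error(target_correlation(spec, 1.2), "delta")
})

test_that("target correlation is symmetric PSD with unit diagonal", {
  spec <- cohort_spec(seed = 1)
  for (d in c(0, 0.3, 0.7, 1)) {
    r <- target_correlation(spec, d)
    expect_equal(r, t(r))
    expect_equal(diag(r), setNames(rep(1, 90), rownames(r)))
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_true(all(abs(r[row(r) != col(r)]) < 1))
  }
})

test_that("homotopic pairs carry the strongest off-diagonal correlation", {
  spec <- cohort_spec(seed = 1)
  r <- target_correlation(spec, 0)
  hp <- spec$homotopic_pairs
  homotopic <- r[hp]
  other <- r[upper.tri(r)]
  expect_gt(min(homotopic), stats::quantile(other, 0.9))
})

test_that("sampled series recover the target correlation", {
  # identity covariance: off-diagonals within 3/sqrt(T) of zero
  ts <- sample_timeseries(diag(10), 4000, seed = 1)
  r <- correlation_matrix(ts)
  expect_lt(max(abs(r[row(r) != col(r)])), 3 / sqrt(4000) * 1.5)
  # correlated block recovered within 0.05 at T = 5000
  spec <- cohort_spec(n_regions = 6, n_timepoints = 50,
                      module_assignment = c(1, 1, 1, 2, 2, 2),
                      homotopic_pairs = matrix(integer(0), 0, 2),
                      base_within_module_r = 0.6, base_background_r = 0.1,
                      category_boost = numeric(0), vulnerability = numeric(0))
  target <- target_correlation(spec, 0)
  ts2 <- sample_timeseries(target, 5000, seed = 2)
  expect_lt(max(abs(correlation_matrix(ts2) - target)), 0.05)
})

test_that("sampling is reproducible and guards short scans", {
  expect_identical(sample_timeseries(diag(5), 30, seed = 9),
                   sample_timeseries(diag(5), 30, seed = 9))
  expect_error(sample_timeseries(diag(5), 6), "n_timepoints")
})

test_that("generated cohort matches the group table", {
  coh <- generate_cohort(tiny_cohort_spec(seed = 5))
  expect_equal(nrow(coh$subjects), 16)
  expect_equal(as.vector(table(coh$subjects$group)), c(6, 4, 3, 3))
  expect_equal(length(coh$timeseries), 16)
  expect_equal(dim(coh$timeseries[[1]]), c(100, 90))
  # grade maps one-to-one onto group
  expect_equal(unique(coh$subjects$grade[coh$subjects$group == "MHE"]), 2)
  # controls carry no ammonia assay; patients do
  expect_true(all(is.na(coh$subjects$ammonia[coh$subjects$group == "control"])))
  expect_true(all(coh$subjects$ammonia[coh$subjects$grade > 0] > 0,
                  na.rm = TRUE))
})

test_that("study-sized cohort emits 70 subjects with sizes 35/17/9/9", {
  spec <- cohort_spec(seed = 3, n_timepoints = 92)
  coh <- generate_cohort(spec)
  expect_equal(nrow(coh$subjects), 70)
  expect_equal(as.vector(table(coh$subjects$group)), c(35, 17, 9, 9))
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  s1 <- generate_cohort(tiny_cohort_spec(seed = 7))
  s2 <- generate_cohort(tiny_cohort_spec(seed = 7))
  expect_identical(s1$subjects, s2$subjects)
  expect_identical(s1$timeseries, s2$timeseries)
})

test_that("ammonia means rise with grade over replicate cohorts", {
  means <- matrix(NA_real_, 10, 3)
  for (s in 1:10) {
    g <- smallworldfc:::default_groups()
    g$n_subjects <- c(2L, 30L, 30L, 30L)
    coh <- generate_cohort(cohort_spec(n_regions = 4, n_timepoints = 20,
                                       module_assignment = rep(1, 4),
                                       groups = g, seed = s))
    m <- tapply(coh$subjects$ammonia, coh$subjects$grade, mean,
                na.rm = TRUE)
    means[s, ] <- m[as.character(1:3)]
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) > 0))
})

test_that("disruption degrades integrated local efficiency of group-mean networks", {
  spec <- cohort_spec(seed = 2)
  deltas <- seq(0, 1, 0.25)
  eloc <- matrix(NA_real_, 4, length(deltas))
  for (r in 1:4) {
    for (di in seq_along(deltas)) {
      target <- target_correlation(spec, deltas[di])
      mats <- lapply(1:5, function(s)
        correlation_matrix(sample_timeseries(target, 290, noise_sd = 0.3,
                                             seed = 1000 * r + 10 * di + s)))
      gm <- group_matrix(mats)
      sw <- efficiency_sweep(gm, seq(0.1, 0.5, 0.1), "correlation")
      eloc[r, di] <- integrate_curve(sw, what = "e_loc")
    }
  }
  rho <- stats::cor(deltas, colMeans(eloc), method = "spearman")
  expect_lt(rho, 0)
  expect_true(all(diff(colMeans(eloc)) <= 0))
})

test_that("within-module correlation decreases with disruption", {
  spec <- cohort_spec(seed = 1)
  same_mod <- outer(spec$module_assignment, spec$module_assignment, "==") &
    upper.tri(diag(90))
  deltas <- c(0, 0.25, 0.5, 0.75, 1)
  mean_r <- vapply(deltas, function(d) {
    reps <- vapply(1:3, function(s) {
      ts <- sample_timeseries(target_correlation(spec, d), 290,
                              noise_sd = 0.3, seed = 100 * d + s)
      mean(correlation_matrix(ts)[same_mod])
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(mean_r) < 0))
})
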