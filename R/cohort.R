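#' The 90-region AAL taxonomy
#'
#' The 45 bilateral region pairs of the Automated Anatomical Labeling
#' template, each classified as Association, Primary, Paralimbic or
#' Subcortical cortex and tagged with its lobe. Regions 1-45 are the left
#' hemisphere, 46-90 the right, so region `i` and `i + 45` are
#' bilaterally homologous (homotopic).
#'
#' @return data frame with 90 rows: `index`, `name`, `abbreviation`,
#'   `category`, `lobe`, `hemisphere`.
#' @export
aal90_regions <- function() {
  path <- system.file("extdata", "aal90_regions.tsv",
                      package = "smallworldfc", mustWork = TRUE)
  pairs <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- rbind(
    data.frame(name = paste("Left", pairs$name),
               abbreviation = paste0(pairs$abbreviation, ".L"),
               category = pairs$category, lobe = pairs$lobe,
               hemisphere = "L", stringsAsFactors = FALSE),
    data.frame(name = paste("Right", pairs$name),
               abbreviation = paste0(pairs$abbreviation, ".R"),
               category = pairs$category, lobe = pairs$lobe,
               hemisphere = "R", stringsAsFactors = FALSE))
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Study-emulating group table: sizes from the cohort the analysis targets,
# age means/SDs and sex ratios matching its demographics, a monotone
# disruption gradient, and venous ammonia distributions (mg/dL) rising
# with grade; controls have no ammonia assay.
default_groups <- function() {
  data.frame(
    label = c("control", "noHE", "MHE", "OHE"),
    grade = 0:3,
    n_subjects = c(35L, 17L, 9L, 9L),
    disruption = c(0, 0.15, 0.30, 0.45),
    age_mean = c(50.06, 49.95, 57.00, 60.56),
    age_sd = c(10.23, 7.85, 5.70, 7.09),
    prop_male = c(22 / 35, 12 / 17, 8 / 9, 5 / 9),
    ammonia_mean = c(NA, 113.64, 139.10, 194.22),
    ammonia_sd = c(NA, 47.75, 67.63, 81.93),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic resting-state cohort
#'
#' Collects every parameter of the cohort generator: network size, scan
#' length, the group table (label, size, disruption), the modular (lobe)
#' and homotopic structure of the target correlation matrix, baseline
#' correlation levels, and per-category disruption vulnerability.
#'
#' The emulated correlation structure has four ingredients observed in
#' resting-state data: a smooth distance-dependent decay of correlation
#' along the cortical sheet (regions laid out on a ring within each
#' hemisphere), elevated correlation within a lobe, strong correlation
#' between bilaterally homologous regions, and a weak positive background.
#' This graded geometry is what makes the thresholded networks
#' small-world: distance decay supplies lattice-like local clustering
#' while homotopic and inter-lobe links supply shortcuts. The disruption
#' parameter `delta` in `[0, 1]` shrinks all structured correlation
#' linearly toward the background level, weighted per region pair by a
#' category-specific vulnerability, which degrades global and local
#' efficiency monotonically and shifts hubs away from the primary
#' cortices.
#'
#' @param n_regions number of regions (default 90; must be even when the
#'   default homotopic pairing is used).
#' @param n_timepoints scan length after discarding equilibration volumes
#'   (default 290 = 300 volumes minus 10).
#' @param tr_seconds repetition time, default 2.
#' @param groups data frame with columns `label`, `grade`, `n_subjects`,
#'   `disruption` and optionally `age_mean`, `age_sd`, `prop_male`,
#'   `ammonia_mean`, `ammonia_sd`.
#' @param module_assignment integer/character vector of length `n_regions`
#'   assigning each region to a module (lobe). Default: AAL lobes.
#' @param homotopic_pairs 2-column matrix of region index pairs; default
#'   `(i, i + n/2)`.
#' @param base_within_module_r,base_homotopic_r,base_background_r baseline
#'   correlation levels. With the graded distance model (default for the
#'   90-region layout) `base_within_module_r` is the additive within-lobe
#'   elevation at distance zero; with the flat model (no positions) it is
#'   the absolute within-module correlation level.
#' @param base_distance_r peak of the distance-decaying correlation
#'   component; set to 0 (or leave `positions` unset on custom layouts)
#'   for a flat block model.
#' @param distance_lambda e-folding length (in region positions) of the
#'   distance decay; `within_module_lambda` likewise for the within-lobe
#'   elevation.
#' @param cross_hemisphere_attenuation multiplier on structured
#'   correlation between non-homotopic regions of opposite hemispheres.
#' @param positions within-hemisphere position of each region on the ring
#'   (default `1..n/2` repeated for the two hemispheres when `n_regions`
#'   is 90); `hemisphere` the 0/1 hemisphere indicator.
#' @param category_boost named per-category additive baseline-connectivity
#'   increment (applied as the pairwise mean), differentiating mean
#'   connectivity strength between cortical classes so that the
#'   undisrupted hub set is association-dominated with over-represented
#'   primary (sensory-motor) regions.
#' @param vulnerability named vector of per-category disruption weights.
#' @param noise_sd white-noise standard deviation added on top of the
#'   unit-variance structured signal.
#' @param delta_sd between-subject SD of the disruption parameter.
#' @param seed integer seed controlling the whole cohort draw.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 90,
                        n_timepoints = 290,
                        tr_seconds = 2,
                        groups = default_groups(),
                        module_assignment = NULL,
                        homotopic_pairs = NULL,
                        base_within_module_r = NULL,
                        base_homotopic_r = 0.60,
                        base_background_r = NULL,
                        base_distance_r = 0.45,
                        distance_lambda = 6,
                        within_module_lambda = 8,
                        cross_hemisphere_attenuation = 0.75,
                        positions = NULL,
                        hemisphere = NULL,
                        category_boost = c(Association = 0,
                                           Primary = 0.01,
                                           Paralimbic = -0.005,
                                           Subcortical = -0.005),
                        vulnerability = c(Association = 0.5, Primary = 1.0,
                                          Paralimbic = 1.0,
                                          Subcortical = 0.8),
                        noise_sd = 0.3,
                        delta_sd = 0.03,
                        seed = 1L) {
  if (nrow(groups) < 1) stop("group list must not be empty")
  if (any(groups$disruption < 0 | groups$disruption > 1))
    stop("disruption must lie in [0, 1]")
  regions <- NULL
  if (n_regions == 90) {
    regions <- aal90_regions()
    if (is.null(module_assignment)) module_assignment <- regions$lobe
    if (is.null(positions)) {
      positions <- rep(seq_len(45), 2)
      hemisphere <- rep(0:1, each = 45)
    }
  }
  if (is.null(module_assignment))
    module_assignment <- rep(1L, n_regions)
  if (length(module_assignment) != n_regions)
    stop("module_assignment must have one entry per region")
  graded <- !is.null(positions) && base_distance_r > 0
  if (graded && (length(positions) != n_regions ||
                 length(hemisphere) != n_regions))
    stop("positions and hemisphere must have one entry per region")
  # graded model: within-module level is an additive elevation over a
  # lower background; flat block model: absolute levels
  if (is.null(base_within_module_r))
    base_within_module_r <- if (graded) 0.08 else 0.40
  if (is.null(base_background_r))
    base_background_r <- if (graded) 0.05 else 0.10
  levels_ok <- c(base_within_module_r, base_homotopic_r,
                 base_background_r, base_distance_r)
  if (any(levels_ok <= -1 | levels_ok >= 1))
    stop("correlation levels must lie in (-1, 1)")
  if (is.null(homotopic_pairs)) {
    if (n_regions %% 2 == 0) {
      h <- n_regions / 2
      homotopic_pairs <- cbind(seq_len(h), seq_len(h) + h)
    } else homotopic_pairs <- matrix(integer(0), 0, 2)
  }
  category <- if (!is.null(regions)) regions$category
              else rep(NA_character_, n_regions)
  structure(
    list(n_regions = n_regions, n_timepoints = n_timepoints,
         tr_seconds = tr_seconds, groups = groups, regions = regions,
         module_assignment = module_assignment,
         homotopic_pairs = homotopic_pairs, category = category,
         graded = graded, positions = positions, hemisphere = hemisphere,
         base_within_module_r = base_within_module_r,
         base_homotopic_r = base_homotopic_r,
         base_background_r = base_background_r,
         base_distance_r = base_distance_r,
         distance_lambda = distance_lambda,
         within_module_lambda = within_module_lambda,
         cross_hemisphere_attenuation = cross_hemisphere_attenuation,
         category_boost = category_boost, vulnerability = vulnerability,
         noise_sd = noise_sd, delta_sd = delta_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort spec: %d regions, %d timepoints (TR %gs), seed %d\n",
              x$n_regions, x$n_timepoints, x$tr_seconds, x$seed))
  print(x$groups[, c("label", "n_subjects", "disruption")])
  invisible(x)
}

#' Target correlation matrix at a given disruption level
#'
#' Builds the structured correlation matrix the generator samples from:
#' background level everywhere, elevated within modules, highest between
#' homotopic pairs, plus the primary-cortex boost; all structure above
#' background is shrunk by `delta` times the pairwise vulnerability and
#' the matrix is projected to the nearest unit-diagonal positive
#' semi-definite matrix (eigenvalue clipping at zero, then diagonal
#' renormalization).
#'
#' @param spec a [cohort_spec()].
#' @param delta disruption in `[0, 1]`; `delta = 0` is the undisrupted
#'   structure, `delta = 1` (at vulnerability 1) pure background.
#' @return N x N PSD correlation matrix.
#' @export
target_correlation <- function(spec, delta) {
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  n <- spec$n_regions
  bg <- spec$base_background_r
  mod <- spec$module_assignment
  same_mod <- outer(mod, mod, "==")
  if (isTRUE(spec$graded)) {
    # ring distance within hemisphere, attenuated across hemispheres
    pos <- spec$positions
    half <- max(pos)
    d <- abs(outer(pos, pos, "-"))
    d <- pmin(d, half - d)
    att <- ifelse(outer(spec$hemisphere, spec$hemisphere, "=="), 1,
                  spec$cross_hemisphere_attenuation)
    s <- bg + (spec$base_distance_r - bg) * att *
      exp(-d / spec$distance_lambda)
    s <- s + spec$base_within_module_r * att * same_mod *
      exp(-d / spec$within_module_lambda)
  } else {
    s <- matrix(bg, n, n)
    s[same_mod] <- spec$base_within_module_r
  }
  hp <- spec$homotopic_pairs
  if (nrow(hp) > 0) {
    s[hp] <- spec$base_homotopic_r
    s[hp[, 2:1, drop = FALSE]] <- spec$base_homotopic_r
  }
  if (!all(is.na(spec$category)) && length(spec$category_boost) > 0) {
    b <- unname(spec$category_boost[spec$category])
    b[is.na(b)] <- 0
    s <- s + outer(b, b, function(x, y) (x + y) / 2)
  }
  # per-pair effective disruption: mean of the two regions' vulnerability
  v <- rep(1, n)
  if (!all(is.na(spec$category)) && length(spec$vulnerability) > 0) {
    v <- unname(spec$vulnerability[spec$category])
    v[is.na(v)] <- 1
  }
  vmat <- outer(v, v, "+") / 2
  r <- bg + (1 - delta * vmat) * (s - bg)
  r[r > 0.95] <- 0.95
  r[r < -0.95] <- -0.95
  diag(r) <- 1
  r <- nearest_psd_correlation(r)
  if (!is.null(spec$regions))
    dimnames(r) <- list(spec$regions$abbreviation,
                        spec$regions$abbreviation)
  r
}

# Eigenvalue clipping at zero followed by renormalization to unit
# diagonal; errors if the projection fails to produce a PSD matrix.
nearest_psd_correlation <- function(r, tol = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) < -tol) {
    vals <- pmax(e$values, 0)
    r <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(r))
    if (any(d <= 0)) stop("PSD projection produced a degenerate diagonal")
    r <- r / outer(d, d)
    e2 <- eigen(r, symmetric = TRUE, only.values = TRUE)
    if (min(e2$values) < -1e-6)
      stop("correlation construction failed: matrix not PSD after projection")
  }
  (r + t(r)) / 2
}

#' Sample regional time series from a target correlation matrix
#'
#' Rows are independent draws from a zero-mean multivariate Gaussian with
#' the given correlation matrix, plus white measurement noise of standard
#' deviation `noise_sd`.
#'
#' @param cov N x N PSD covariance/correlation matrix.
#' @param n_timepoints number of rows; must be at least `N + 2` so the
#'   downstream sample correlation is stable.
#' @param noise_sd white-noise SD.
#' @param seed optional integer seed.
#' @return T x N matrix.
#' @export
sample_timeseries <- function(cov, n_timepoints, noise_sd = 0,
                              seed = NULL) {
  n <- nrow(cov)
  if (n_timepoints < n + 2)
    stop("n_timepoints must be at least n_regions + 2")
  if (!is.null(seed)) set.seed(seed)
  e <- eigen(cov, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("covariance must be PSD")
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(stats::rnorm(n_timepoints * n), n_timepoints, n)
  out <- z %*% sq
  if (noise_sd > 0)
    out <- out + noise_sd * matrix(stats::rnorm(n_timepoints * n),
                                   n_timepoints, n)
  colnames(out) <- colnames(cov)
  out
}

# mean/sd on the natural scale -> lognormal meanlog/sdlog
lognormal_params <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a full synthetic cohort
#'
#' Draws every subject of the group table: a subject record (group, grade,
#' age, sex, venous ammonia) and a regional time-series matrix sampled
#' from the group's disrupted correlation structure (with a small
#' between-subject jitter on the disruption parameter). Ammonia is
#' lognormal with group-specific means that rise with grade; controls get
#' `NA` (no assay).
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (data frame: `subject_id`, `group`,
#'   `grade`, `age`, `sex`, `ammonia`, `disruption`) and `timeseries`
#'   (named list of T x N matrices), plus the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  if (nrow(g) == 0) stop("group list must not be empty")
  set.seed(spec$seed)
  records <- list()
  series <- list()
  idx <- 0L
  for (gi in seq_len(nrow(g))) {
    n_sub <- g$n_subjects[gi]
    has_ammonia <- !is.null(g$ammonia_mean) && !is.na(g$ammonia_mean[gi])
    lp <- if (has_ammonia) lognormal_params(g$ammonia_mean[gi],
                                            g$ammonia_sd[gi])
    base_delta <- g$disruption[gi]
    base_cov <- if (spec$delta_sd == 0) target_correlation(spec, base_delta)
    for (si in seq_len(n_sub)) {
      idx <- idx + 1L
      id <- sprintf("S%03d", idx)
      delta <- if (spec$delta_sd > 0)
        min(1, max(0, base_delta + stats::rnorm(1, 0, spec$delta_sd)))
      else base_delta
      covm <- if (is.null(base_cov)) target_correlation(spec, delta)
              else base_cov
      ts <- sample_timeseries(covm, spec$n_timepoints, spec$noise_sd)
      age_mean <- if (!is.null(g$age_mean)) g$age_mean[gi] else 50
      age_sd <- if (!is.null(g$age_sd)) g$age_sd[gi] else 10
      p_male <- if (!is.null(g$prop_male)) g$prop_male[gi] else 0.5
      records[[idx]] <- data.frame(
        subject_id = id, group = g$label[gi], grade = g$grade[gi],
        age = round(min(80, max(18, stats::rnorm(1, age_mean, age_sd))), 1),
        sex = if (stats::rbinom(1, 1, p_male) == 1) "M" else "F",
        ammonia = if (has_ammonia)
          stats::rlnorm(1, lp$meanlog, lp$sdlog) else NA_real_,
        disruption = delta, stringsAsFactors = FALSE)
      series[[id]] <- ts
    }
  }
  subjects <- do.call(rbind, records)
  subjects$group <- factor(subjects$group, levels = g$label)
  rownames(subjects) <- NULL
  list(subjects = subjects, timeseries = series, spec = spec)
}
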