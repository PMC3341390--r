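#' Severity-trend linear regression
#'
#' Ordinary least squares of a network outcome on the encephalopathy grade
#' (0 = control, 1 = no HE, 2 = minimal HE, 3 = overt HE) treated as a
#' linear severity score, adjusting for age and sex. Reports the grade
#' coefficient's t statistic and two-sided p value — the monotone-trend
#' test applied to every integrated efficiency and nodal metric.
#'
#' @param outcome per-subject values.
#' @param grade integer severity 0-3 (or any numeric score).
#' @param age,sex covariates; `sex` may be a factor/character (coded 0/1)
#'   or numeric.
#' @return object of class `trend_result`: `t_statistic`, `p_value`,
#'   `estimate`, `df`, `covariates`.
#' @export
severity_trend <- function(outcome, grade, age = NULL, sex = NULL) {
  n <- length(outcome)
  if (n < 5) stop("need at least 5 subjects")
  if (length(unique(grade)) < 2) stop("grade must span at least 2 levels")
  dat <- data.frame(outcome = outcome, grade = as.numeric(grade))
  if (!is.null(age)) dat$age <- as.numeric(age)
  if (!is.null(sex))
    dat$sex <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  fit <- stats::lm(outcome ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("design matrix is collinear; drop or recode covariates")
  s <- summary(fit)$coefficients
  structure(list(estimate = s["grade", 1], t_statistic = s["grade", 3],
                 p_value = s["grade", 4], df = fit$df.residual,
                 covariates = setdiff(names(dat), c("outcome", "grade"))),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("severity trend: b = %.4g, t(%d) = %.3f, p = %.3g\n",
              x$estimate, x$df, x$t_statistic, x$p_value))
  if (length(x$covariates) > 0)
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Covariate-adjusted univariate ANOVA with Bonferroni post hoc
#'
#' F test for the group factor after adjusting for age and sex (nested
#' model comparison: covariates-only versus covariates plus group),
#' followed by all pairwise group comparisons, each a covariate-adjusted
#' two-group fit with Bonferroni-corrected p value
#' (`min(1, p * n_pairs)`).
#'
#' @param outcome per-subject values.
#' @param group factor of group labels (at least 2 groups with 2+
#'   subjects).
#' @param age,sex optional covariates.
#' @return object of class `anova_result`: `F_statistic`, `df`,
#'   `p_value`, and `posthoc` data frame (pair, raw and adjusted p).
#' @export
group_anova <- function(outcome, group, age = NULL, sex = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 subjects")
  covs <- data.frame(row.names = seq_along(outcome))
  if (!is.null(age)) covs$age <- as.numeric(age)
  if (!is.null(sex))
    covs$sex <- if (is.numeric(sex)) sex else as.numeric(factor(sex)) - 1
  dat <- cbind(data.frame(outcome = outcome, group = group), covs)
  rhs0 <- if (ncol(covs) > 0) paste(names(covs), collapse = " + ") else "1"
  fit0 <- stats::lm(stats::as.formula(paste("outcome ~", rhs0)), data = dat)
  fit1 <- stats::lm(stats::as.formula(paste("outcome ~", rhs0, "+ group")),
                    data = dat)
  an <- stats::anova(fit0, fit1)
  f_stat <- an$F[2]
  df <- c(an$Df[2], an$Res.Df[2])
  p <- an$`Pr(>F)`[2]
  # all-pairs post hoc: covariate-adjusted two-group refits
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  posthoc <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        estimate = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    sub <- dat[dat$group %in% pairs[, i], , drop = FALSE]
    sub$group <- droplevels(sub$group)
    fit <- stats::lm(stats::as.formula(paste("outcome ~", rhs0, "+ group")),
                     data = sub)
    s <- summary(fit)$coefficients
    row <- grep("^group", rownames(s))
    posthoc$estimate[i] <- s[row, 1]
    posthoc$p_raw[i] <- s[row, 4]
    posthoc$p_bonferroni[i] <- min(1, s[row, 4] * n_pairs)
  }
  structure(list(F_statistic = f_stat, df = df, p_value = p,
                 posthoc = posthoc),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("group ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F_statistic, x$p_value))
  print(x$posthoc, digits = 3)
  invisible(x)
}

#' Ammonia-efficiency association
#'
#' Simple linear regression of a network efficiency measure on venous
#' ammonia concentration (mg/dL), reporting the coefficient of
#' determination and the slope's two-sided p value. Pairs with missing
#' ammonia (healthy controls carry no assay) are dropped.
#'
#' @param efficiency per-subject efficiency values.
#' @param ammonia per-subject ammonia (mg/dL); may contain `NA`.
#' @return list with `r_squared`, `p_value`, `slope`, `n`.
#' @export
ammonia_association <- function(efficiency, ammonia) {
  ok <- is.finite(efficiency) & is.finite(ammonia)
  efficiency <- efficiency[ok]
  ammonia <- ammonia[ok]
  if (length(ammonia) < 4) stop("need at least 4 paired observations")
  if (stats::sd(ammonia) == 0) stop("ammonia values are constant")
  fit <- stats::lm(efficiency ~ ammonia)
  s <- summary(fit)
  list(r_squared = s$r.squared,
       p_value = s$coefficients["ammonia", 4],
       slope = s$coefficients["ammonia", 1],
       n = length(ammonia))
}

#' Per-region severity-trend table
#'
#' Runs [severity_trend()] for every region of a subject-by-region nodal
#' metric matrix, producing the region-wise t and p table (one row per
#' region). P values are reported unadjusted; set `fdr = TRUE` to append
#' Benjamini-Hochberg adjusted values.
#'
#' @param nodal subject x region matrix (strength or integrated nodal
#'   efficiency).
#' @param grade,age,sex per-subject covariates as in [severity_trend()].
#' @param regions optional region table to join.
#' @param fdr append an FDR-adjusted column.
#' @return data frame, one row per region, descending `|t|`.
#' @export
regional_trend_table <- function(nodal, grade, age = NULL, sex = NULL,
                                 regions = NULL, fdr = FALSE) {
  res <- apply(nodal, 2, function(v) {
    tr <- severity_trend(v, grade, age, sex)
    c(t = tr$t_statistic, p = tr$p_value)
  })
  out <- data.frame(region = colnames(nodal), t = res["t", ],
                    p = res["p", ], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (fdr) out$p_fdr <- stats::p.adjust(out$p, "BH")
  if (!is.null(regions)) {
    out$category <- regions$category[match(out$region,
                                           regions$abbreviation)]
  }
  out[order(-abs(out$t)), , drop = FALSE]
}
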