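#' Identify hub regions
#'
#' Hubs are the nodes whose metric value lies strictly more than one
#' sample standard deviation above the mean over all nodes. With zero
#' variance the hub set is empty and flagged.
#'
#' @param values per-node metric (nodal strength or integrated nodal
#'   efficiency), optionally named.
#' @param metric label recorded in the report.
#' @return object of class `hub_report`: `values`, `mean`, `sd`,
#'   `threshold`, integer `hubs` (indices), and `degenerate` flag.
#' @export
identify_hubs <- function(values, metric = "nodal metric") {
  if (length(values) < 2) stop("need at least 2 nodes")
  if (any(!is.finite(values))) stop("values must be finite")
  m <- mean(values)
  s <- stats::sd(values)
  degenerate <- s == 0
  hubs <- if (degenerate) integer(0) else which(values > m + s)
  structure(list(metric = metric, values = values, mean = m, sd = s,
                 threshold = m + s, hubs = hubs,
                 degenerate = degenerate),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("hub report (%s): %d/%d hubs above %.4f (mean %.4f + SD %.4f)\n",
              x$metric, length(x$hubs), length(x$values), x$threshold,
              x$mean, x$sd))
  if (length(x$hubs) > 0 && !is.null(names(x$values)))
    cat(" ", paste(names(x$values)[x$hubs], collapse = ", "), "\n")
  invisible(x)
}

#' Category distribution of a hub set
#'
#' Percentage of hub nodes falling in each cortical category of the region
#' taxonomy (Association, Primary, Paralimbic — the limbic/paralimbic
#' class — and Subcortical). Percentages are unrounded and sum to 100; an
#' empty hub set yields all zeros with a flag.
#'
#' @param hubs integer region indices (e.g. `identify_hubs(...)$hubs`).
#' @param regions region table as from [aal90_regions()].
#' @return named numeric vector of percentages over the four categories,
#'   with attribute `"empty"` when the hub set was empty.
#' @export
category_distribution <- function(hubs, regions = aal90_regions()) {
  cats <- c("Association", "Primary", "Paralimbic", "Subcortical")
  if (length(hubs) == 0) {
    out <- stats::setNames(rep(0, length(cats)), cats)
    attr(out, "empty") <- TRUE
    return(out)
  }
  if (any(hubs < 1 | hubs > nrow(regions)))
    stop("hub indices outside the region table")
  counts <- table(factor(regions$category[hubs], levels = cats))
  out <- 100 * as.numeric(counts) / length(hubs)
  names(out) <- cats
  attr(out, "empty") <- FALSE
  out
}

#' Rank regions by a nodal metric
#'
#' Stable descending sort of the regions by metric value, ties broken by
#' region index (table order).
#'
#' @param values per-node metric vector.
#' @param regions region table aligned with `values`.
#' @return the region table reordered, with a `value` column and `rank`.
#' @export
rank_regions <- function(values, regions = aal90_regions()) {
  if (length(values) != nrow(regions))
    stop("values and region table lengths differ")
  if (any(!is.finite(values))) stop("values must be finite")
  ord <- order(-values, seq_along(values))
  out <- regions[ord, , drop = FALSE]
  out$value <- values[ord]
  out$rank <- seq_along(ord)
  rownames(out) <- NULL
  out
}

#' Hub category distributions per group
#'
#' Runs the group-level hub analysis: pools subject correlation matrices
#' per group through [group_matrix()], extracts the chosen nodal metric,
#' identifies hubs (mean + 1 SD rule) and reports the category
#' distribution of each group's hub set.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param metric `"strength"` (nodal connectivity strength of the group
#'   matrix) or `"nodal_efficiency"` (integrated relative nodal efficiency
#'   of the group matrix).
#' @param cost_thresholds sweep grid for the nodal-efficiency metric.
#' @return list per group: `hub_report` and `distribution`.
#' @export
group_hub_analysis <- function(cohort, metric = c("strength",
                                                  "nodal_efficiency"),
                               cost_thresholds = seq(0.05, 0.50, 0.01)) {
  metric <- match.arg(metric)
  regions <- cohort$spec$regions
  if (is.null(regions)) stop("cohort has no region table")
  groups <- levels(cohort$subjects$group)
  out <- list()
  for (g in groups) {
    ids <- cohort$subjects$subject_id[cohort$subjects$group == g]
    mats <- lapply(cohort$timeseries[ids], correlation_matrix)
    gm <- group_matrix(mats)
    values <- if (metric == "strength") nodal_strength(gm)
    else integrate_curve(efficiency_sweep(gm, cost_thresholds, "cost"),
                         what = "nodal")
    hr <- identify_hubs(values, metric = paste(g, metric))
    out[[g]] <- list(hub_report = hr,
                     distribution = category_distribution(hr$hubs, regions))
  }
  out
}
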