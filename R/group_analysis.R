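#' Stack significance maps into a matrix
#'
#' @param maps List of data.frames (region, hemisphere, signed_log10p) as
#'   produced by \code{\link{significance_map}}.
#' @return Numeric matrix, rows = scans, columns = region:hemisphere keys.
#' @export
stack_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  key <- paste(maps[[1]]$hemisphere, maps[[1]]$region, sep = ".")
  out <- t(vapply(maps, function(m) {
    stopifnot(identical(paste(m$hemisphere, m$region, sep = "."), key))
    m$signed_log10p
  }, numeric(length(key))))
  colnames(out) <- key
  out
}

#' Per-region percentage of anomalous scans
#'
#' Fraction (in %) of maps whose signed log10(p) exceeds the detection
#' boundary in the requested direction: above -log10(q) for increases,
#' below +log10(q) (i.e. below -2 at q = 0.01) for decreases.  Increases
#' and decreases are tallied separately.
#'
#' @param maps List of significance maps or a matrix from
#'   \code{\link{stack_maps}}.
#' @param direction \code{"increase"} or \code{"decrease"}.
#' @param q Significance threshold (default 0.01).
#' @return Named numeric vector of percentages per region.
#' @export
anomaly_percentage_map <- function(maps, direction = c("decrease", "increase"),
                                   q = 0.01) {
  direction <- match.arg(direction)
  m <- if (is.matrix(maps)) maps else stack_maps(maps)
  thr <- -log10(q)
  hit <- if (direction == "increase") m > thr else m < -thr
  100 * colMeans(hit, na.rm = TRUE)
}

#' Element-wise mean of significance maps (template map)
#' @param maps List of maps or matrix from \code{\link{stack_maps}}.
#' @return Named numeric vector (the average map).
#' @export
average_map <- function(maps) {
  m <- if (is.matrix(maps)) maps else stack_maps(maps)
  colMeans(m, na.rm = TRUE)
}

#' Per-region Cohen's d between two groups
#'
#' d = (meanA - meanB) / pooled SD, pooled over both groups with n - 1
#' weights.  Regions with zero pooled SD are reported as NA and listed.
#'
#' @param values_a,values_b Numeric matrices (scans x regions) with
#'   matching columns.
#' @return List of class \code{som_contrast}: \code{d} (named vector),
#'   \code{n_a}, \code{n_b}, \code{undefined} (region names).
#' @export
cohens_d_map <- function(values_a, values_b) {
  stopifnot(identical(colnames(values_a), colnames(values_b)),
            nrow(values_a) >= 2, nrow(values_b) >= 2)
  na <- nrow(values_a); nb <- nrow(values_b)
  ma <- colMeans(values_a); mb <- colMeans(values_b)
  sa <- apply(values_a, 2, stats::sd)
  sb <- apply(values_b, 2, stats::sd)
  pooled <- sqrt(((na - 1) * sa^2 + (nb - 1) * sb^2) / (na + nb - 2))
  d <- (ma - mb) / pooled
  d[pooled == 0] <- NA_real_
  structure(list(d = d, n_a = na, n_b = nb,
                 undefined = names(d)[pooled == 0]),
            class = "som_contrast")
}

#' Normalized L2-distance between two maps
#'
#' Euclidean distance between the unit-normalized maps:
#' || a/||a|| - b/||b|| ||.  Ranges from 0 for identical maps to 2 for
#' antisymmetric maps, with sqrt(2) indicating orthogonal maps.  Unlike a
#' Pearson correlation it is not invariant to shift and scale, which
#' matters when ranking individual maps against a template.
#'
#' @param map_a,map_b Numeric vectors over the same region set.
#' @return Distance in [0, 2].
#' @export
normalized_l2 <- function(map_a, map_b) {
  stopifnot(length(map_a) == length(map_b))
  na <- sqrt(sum(map_a^2)); nb <- sqrt(sum(map_b^2))
  if (na == 0 || nb == 0) stop("normalized L2 undefined for a zero map")
  sqrt(sum((map_a / na - map_b / nb)^2))
}

#' ROC curve and AUC from per-scan scores
#'
#' Sweeps thresholds over the unique scores (rule: score >= threshold is
#' called a case), computes sensitivity / 1-specificity pairs and the
#' trapezoid AUC, which on this sweep equals the Mann-Whitney statistic
#' with the mid-rank tie convention.  The operating point closest to the
#' top-left corner (0, 1) is reported.
#'
#' @param scores Numeric vector, higher = more case-like.
#' @param labels Logical (TRUE = case) or factor/character with cases
#'   identified by \code{case_label}.
#' @param case_label Level treated as case when labels are not logical.
#' @return List of class \code{som_roc}: \code{thresholds}, \code{tpr},
#'   \code{fpr}, \code{auc}, \code{best_point} (threshold, tpr, fpr).
#' @export
roc_from_scores <- function(scores, labels, case_label = "case") {
  if (!is.logical(labels)) labels <- labels == case_label
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  dist <- sqrt(fpr^2 + (1 - tpr)^2)
  b <- which.min(dist)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 best_point = c(threshold = thr[b], tpr = tpr[b],
                                fpr = fpr[b])),
            class = "som_roc")
}

#' @export
print.som_roc <- function(x, ...) {
  cat(sprintf("<som_roc> AUC %.3f; best point thr %.4g (TPR %.2f, FPR %.2f)\n",
              x$auc, x$best_point["threshold"], x$best_point["tpr"],
              x$best_point["fpr"]))
  invisible(x)
}

#' Partition evaluations (or any records) by a covariate
#'
#' @param x data.frame.
#' @param by Column name to stratify on (e.g. \code{cdr}).
#' @param drop_na Drop records with a missing stratum value?
#' @return Named list of data.frames; strata sizes sum to the input size
#'   when \code{drop_na} is FALSE (missing values form an \code{"NA"}
#'   stratum).
#' @export
stratify <- function(x, by, drop_na = FALSE) {
  stopifnot(by %in% names(x))
  g <- as.character(x[[by]])
  if (drop_na) {
    keep <- !is.na(x[[by]])
    x <- x[keep, , drop = FALSE]; g <- g[keep]
  } else g[is.na(g)] <- "NA"
  split(x, g)
}

#' Mean regional change between baseline and follow-up scans
#'
#' Later minus baseline, always: per region, the mean over subject pairs
#' of the follow-up value minus the baseline value, so cortical thinning
#' yields negative entries.
#'
#' @param baseline,followup \code{som_cohort}s with the same subjects in
#'   the same order, one scan each; follow-up ages must exceed baseline
#'   ages.
#' @param catalog A \code{som_catalog}.
#' @param kind Metric kind (default \code{mean_cth}).
#' @param normalized Use brain-size-normalized variants?
#' @return data.frame (region, hemisphere, mean_change) in metric units.
#' @export
longitudinal_change_map <- function(baseline, followup, catalog,
                                    kind = "mean_cth", normalized = TRUE) {
  if (!identical(baseline$demo$subject_id, followup$demo$subject_id))
    stop("baseline and follow-up cohorts list different subjects")
  if (any(followup$demo$age <= baseline$demo$age))
    stop("follow-up ages must exceed baseline ages")
  nm <- catalog_dk_names(catalog, kind, normalized)
  nm <- intersect(nm, colnames(baseline$metrics))
  delta <- followup$metrics[, nm, drop = FALSE] -
    baseline$metrics[, nm, drop = FALSE]
  sel <- match(nm, if (normalized) paste0(catalog$name, ".norm") else catalog$name)
  data.frame(region = catalog$region[sel], hemisphere = catalog$hemisphere[sel],
             mean_change = colMeans(delta, na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent change of a metric over a scan interval
#'
#' 100 * (baseline - followup) / baseline: positive for shrinkage
#' (atrophy), negative for growth.  The interval length is attached so
#' rates are always reported with their time base.
#'
#' @param v_baseline,v_followup Metric values (baseline > 0).
#' @param years Interval in years (> 0).
#' @return Percent change with attribute \code{years}.
#' @export
interval_change_rate <- function(v_baseline, v_followup, years) {
  if (any(v_baseline <= 0)) stop("baseline value must be positive")
  if (years <= 0) stop("interval must be positive")
  out <- 100 * (v_baseline - v_followup) / v_baseline
  attr(out, "years") <- years
  out
}

#' Rank-sum comparison of two distance samples
#'
#' Thin wrapper over the Wilcoxon rank-sum test (exact null for small,
#' tie-free samples; normal approximation otherwise), used e.g. to compare
#' rescan map distances between groups.
#'
#' @param x,y Numeric samples.
#' @param ... Passed to \code{stats::wilcox.test}.
#' @return The \code{htest} object.
#' @export
rank_sum_test <- function(x, y, ...) stats::wilcox.test(x, y, ...)
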