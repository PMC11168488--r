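#' Subject-wise leave-one-out cross-validation of a normative cohort
#'
#' For every subject, all normative models are refit on the cohort with
#' that subject's scans (all sessions and rescans) excluded, and each of
#' the subject's scans is evaluated against those models.  Per-subject RNG
#' seeds are derived deterministically from the master seed and the
#' subject id, so the result does not depend on subject ordering.
#'
#' @param cohort The normative \code{som_cohort}.
#' @param metrics Metric names to model and evaluate (default: all raw
#'   catalog metrics present, excluding ICV).
#' @param rcfg A \code{som_resampling_config}; its seed is the master
#'   seed.
#' @param fcfg A \code{som_fit_config}.
#' @param ecfg A \code{som_eval_config}.
#' @param catalog Catalog used for metric defaults.
#' @return An object of class \code{som_loocv}: \code{per_scan}
#'   data.frame (scan_id, subject_id, n_evaluated, n_abnormal, threshold,
#'   flagged), long \code{evaluations} data.frame, \code{total_tests},
#'   \code{total_detections}, \code{detection_fraction}, \code{q},
#'   \code{metrics}, \code{seed}.
#' @export
run_loocv <- function(cohort, metrics = NULL, rcfg = resampling_config(),
                      fcfg = fit_config(), ecfg = evaluation_config(),
                      catalog = build_metric_catalog()) {
  subjects <- unique(cohort$demo$subject_id)
  if (length(subjects) < 2L) stop("LOOCV needs at least 2 subjects")
  if (is.null(metrics))
    metrics <- setdiff(intersect(catalog_raw_names(catalog),
                                 colnames(cohort$metrics)), "icv")
  ids <- scan_ids(cohort)
  per_scan <- list()
  ev_all <- list()
  for (s in subjects) {
    in_s <- cohort$demo$subject_id == s
    train <- cohort_subset(cohort, !in_s)
    rc <- rcfg
    rc$seed <- if (is.null(rcfg$seed)) NULL else .derive_seed(rcfg$seed, s)
    models <- tryCatch(
      fit_models(train, metrics, rc, fcfg, catalog),
      error = function(e)
        stop("LOOCV aborted: refit without subject ", s, " failed: ",
             conditionMessage(e)))
    for (i in which(in_s)) {
      evals <- evaluate_scan(cohort$demo[i, , drop = FALSE],
                             cohort$metrics[i, ], models, train, ecfg,
                             fcfg$age_window_frac)
      fl <- flag_anomalous_scan(evals, ecfg)
      per_scan[[length(per_scan) + 1L]] <- data.frame(
        scan_id = ids[i], subject_id = s, n_evaluated = fl$n_evaluated,
        n_abnormal = fl$n_abnormal, threshold = fl$threshold,
        flagged = fl$is_anomalous, stringsAsFactors = FALSE)
      evals$scan_id <- ids[i]
      ev_all[[length(ev_all) + 1L]] <- evals
    }
  }
  per_scan <- do.call(rbind, per_scan)
  ev_all <- do.call(rbind, ev_all)
  total_tests <- sum(per_scan$n_evaluated)
  total_detections <- sum(per_scan$n_abnormal)
  structure(list(per_scan = per_scan, evaluations = ev_all,
                 total_tests = total_tests,
                 total_detections = total_detections,
                 detection_fraction = total_detections / total_tests,
                 q = ecfg$q, metrics = metrics, seed = rcfg$seed),
            class = "som_loocv")
}

#' @export
print.som_loocv <- function(x, ...) {
  cat(sprintf(
    "<som_loocv> %d scans, %d metrics: %d / %d detections (%.3g%%), %d scan(s) flagged\n",
    nrow(x$per_scan), length(x$metrics), x$total_detections, x$total_tests,
    100 * x$detection_fraction, sum(x$per_scan$flagged)))
  invisible(x)
}

#' Remove LOOCV-flagged scans from the normative cohort
#'
#' Strict filter: the cleaned cohort plus the removed scans partition the
#' original.  The normalization context and all normative models must be
#' refit on the cleaned cohort afterwards.  Removing more than half of
#' the cohort aborts as a pathological configuration.
#'
#' @param cohort The cohort the LOOCV was run on.
#' @param loocv A \code{som_loocv}.
#' @param ecfg A \code{som_eval_config} (unused fields reserved).
#' @return List with \code{cohort} (cleaned) and \code{removed} (scan
#'   ids).
#' @export
clean_cohort <- function(cohort, loocv, ecfg = evaluation_config()) {
  ids <- scan_ids(cohort)
  removed <- loocv$per_scan$scan_id[loocv$per_scan$flagged]
  if (length(removed) > 0.5 * n_scans(cohort))
    stop("cleaning would remove more than 50% of scans; aborting")
  keep <- !(ids %in% removed)
  list(cohort = cohort_subset(cohort, keep), removed = removed)
}

#' One-sided binomial excess test
#'
#' P(X >= k) for X ~ Binomial(n, q): is the number of anomaly detections
#' larger than expected from the significance threshold alone?
#'
#' @param k Number of detections.
#' @param n Number of tests.
#' @param q Expected detection rate.
#' @return One-sided p-value.
#' @export
binomial_excess_test <- function(k, n, q) {
  stopifnot(k >= 0, k <= n)
  stats::pbinom(k - 1, n, q, lower.tail = FALSE)
}

#' Shapiro-Wilk summary of model fit residues
#'
#' Tests, per metric, the retained fit residues for normality; metrics
#' with fewer than 3 residues (or degenerate, all-identical residues) are
#' skipped and reported.  Residue sets beyond the test's 5000-sample limit
#' are thinned deterministically.
#'
#' @param models Named list of \code{som_model}.
#' @param alpha Rejection level (default 0.05).
#' @return List with \code{n_tested}, \code{n_rejected}, \code{fraction},
#'   \code{skipped} (metric names) and per-metric \code{p_values}.
#' @export
residue_normality_summary <- function(models, alpha = 0.05) {
  pv <- stats::setNames(rep(NA_real_, length(models)), names(models))
  skipped <- character()
  for (nm in names(models)) {
    r <- models[[nm]]$residues
    if (length(r) > 5000L)
      r <- r[seq(1L, length(r), length.out = 5000L)]
    if (length(r) < 3L || diff(range(r)) == 0) {
      skipped <- c(skipped, nm)
      next
    }
    pv[nm] <- stats::shapiro.test(r)$p.value
  }
  tested <- !is.na(pv)
  list(n_tested = sum(tested), n_rejected = sum(pv[tested] < alpha),
       fraction = if (any(tested)) mean(pv[tested] < alpha) else NA_real_,
       skipped = skipped, p_values = pv)
}

#' Union of removed-scan lists from two processing pipelines
#' @param removed_a,removed_b Character vectors of scan ids.
#' @return Sorted union.
#' @export
union_removed_scans <- function(removed_a, removed_b)
  sort(union(removed_a, removed_b))
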