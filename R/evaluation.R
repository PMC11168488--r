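#' Evaluation configuration
#'
#' @param q Per-metric significance threshold (default 0.01, i.e. a
#'   detection boundary at |signed log10 p| = 2).
#' @param scan_flag_fraction Fraction of abnormal metrics above which a
#'   whole scan is flagged (default 0.05, i.e. 18 of 358 raw metrics).
#' @param min_match_size Minimum covariate-matched reference size before
#'   matching keys are relaxed (default 20).
#' @param matching_keys Covariates matched exactly, relaxed from the end
#'   (default sex, scanner, protocol: protocol is dropped first, sex never).
#' @return A list of class \code{som_eval_config}.
#' @export
evaluation_config <- function(q = 0.01, scan_flag_fraction = 0.05,
                              min_match_size = 20L,
                              matching_keys = c("sex", "scanner", "protocol")) {
  stopifnot(q > 0, q < 1, scan_flag_fraction > 0, scan_flag_fraction < 1)
  structure(list(q = q, scan_flag_fraction = scan_flag_fraction,
                 min_match_size = as.integer(min_match_size),
                 matching_keys = matching_keys),
            class = "som_eval_config")
}

.matching_levels <- c("exact", "relaxed-protocol", "relaxed-scanner", "all")

#' Select a covariate-matched reference subset
#'
#' Matches the scan exactly on all matching keys; while the subset holds
#' fewer than \code{min_match_size} distinct participants, keys are
#' dropped one at a time from the end of the key list (protocol, then
#' scanner; sex is never dropped with the default keys).  The floor
#' counts participants rather than scans because rescans of one subject
#' are not independent evidence for the reference statistics.  Outlier
#' exclusion is per metric and happens in \code{\link{evaluate_metric}}
#' via \code{retained_ids}.
#'
#' @param scan_demo One-row data.frame (or list) with the scan's
#'   covariates.
#' @param cohort The normative \code{som_cohort}.
#' @param cfg A \code{som_eval_config}.
#' @param retained_ids Optional scan ids counted towards the subset size
#'   (e.g. a model's non-outlier scans).
#' @return List with \code{scan_ids} and \code{level} (one of exact,
#'   relaxed-protocol, relaxed-scanner, all).
#' @export
match_reference <- function(scan_demo, cohort, cfg = evaluation_config(),
                            retained_ids = NULL) {
  if (n_scans(cohort) == 0) stop("empty normative cohort")
  ids <- scan_ids(cohort)
  avail <- if (is.null(retained_ids)) rep(TRUE, length(ids))
           else ids %in% retained_ids
  keys <- cfg$matching_keys
  for (k_drop in seq(length(keys), 0)) {
    use <- keys[seq_len(k_drop)]
    sel <- avail
    for (kk in use)
      sel <- sel & cohort$demo[[kk]] == as.character(scan_demo[[kk]])
    n_subj <- length(unique(cohort$demo$subject_id[sel]))
    if (n_subj >= cfg$min_match_size || k_drop == 0L) {
      level <- if (k_drop == length(keys)) "exact"
               else if (k_drop == 0L) "all"
               else paste0("relaxed-", keys[k_drop + 1L])
      if (sum(sel) < 3L)
        stop("fewer than 3 reference scans even after full relaxation")
      return(list(scan_ids = ids[sel], level = level))
    }
  }
}

# two-sided Gaussian tail on the log scale; returns c(p, log10p)
.z_to_p <- function(z) {
  lp <- log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  c(p = exp(lp), log10p = lp / log(10))
}

#' Evaluate one metric of a scan against its normative model
#'
#' The scan's value is positioned with respect to the covariate-matched,
#' age-local reference residues: the reported residual is the value minus
#' the normative expectation (trajectory at the scan's age plus the
#' matched subset's mean residue, which absorbs covariate mean shifts the
#' age trajectory cannot), and the z-score divides it by the combined
#' standard deviation sqrt(sigma_pop^2 + sigma_meas^2), where sigma_pop
#' is the age-local SD of the matched reference residues and sigma_meas
#' the scan-rescan measurement uncertainty.  The z-score is converted to
#' a two-sided Gaussian p-value and reported as signed log10(p), negative
#' when the value lies below expectation (e.g. atrophy).  The artifact
#' probability 2(1 - Phi(|residual| / sigma_meas)) gauges whether the
#' deviation could arise from measurement noise alone.
#'
#' @param value Metric value of the scan.
#' @param age Scan age in years.
#' @param model A \code{som_model}.
#' @param ref_ids Scan ids of the covariate-matched reference subset.
#' @param cfg A \code{som_eval_config}.
#' @param age_window_frac Age-local window fraction.
#' @param matching_level Matching level label carried into the output.
#' @return One-row data.frame: metric, residual, z, p, signed_log10p,
#'   matched_n, matching_level, artifact_p.
#' @export
evaluate_metric <- function(value, age, model, ref_ids,
                            cfg = evaluation_config(),
                            age_window_frac = 0.10,
                            matching_level = "exact") {
  loc <- local_population_sd(model, age, age_window_frac,
                             subset_ids = ref_ids)
  res <- value - predict_trajectory(model, age) -
    if (is.finite(loc$mean)) loc$mean else 0
  s <- sqrt(loc$sd^2 + model$sigma_meas^2)
  if (!is.finite(s) || s == 0) {
    return(data.frame(metric = model$metric, residual = res, z = NA_real_,
                      p = NA_real_, signed_log10p = NA_real_,
                      matched_n = loc$n, matching_level = matching_level,
                      artifact_p = NA_real_, stringsAsFactors = FALSE))
  }
  z <- res / s
  zp <- .z_to_p(z)
  artifact_p <- if (model$sigma_meas > 0)
    .z_to_p(res / model$sigma_meas)[["p"]] else 1
  data.frame(metric = model$metric, residual = res, z = z, p = zp[["p"]],
             signed_log10p = -sign(res) * zp[["log10p"]],
             matched_n = loc$n, matching_level = matching_level,
             artifact_p = artifact_p, stringsAsFactors = FALSE)
}

#' Evaluate a scan against a set of normative models
#'
#' Runs \code{\link{evaluate_metric}} for every model whose metric the
#' scan carries, with a covariate-matched, outlier-excluded reference
#' subset per metric.  Per-metric failures are collected as NA rows and
#' never abort the scan.
#'
#' @param scan_demo One-row data.frame with the scan's covariates
#'   (subject_id, session_id, age, sex, scanner, protocol).
#' @param values Named numeric vector of the scan's metric values.
#' @param models Named list of \code{som_model}.
#' @param cohort The normative cohort the models were fitted on.
#' @param cfg A \code{som_eval_config}.
#' @param age_window_frac Age-local window fraction.
#' @return data.frame of per-metric evaluations.
#' @export
evaluate_scan <- function(scan_demo, values, models, cohort,
                          cfg = evaluation_config(), age_window_frac = 0.10) {
  stopifnot(length(models) >= 1)
  rows <- vector("list", length(models))
  for (i in seq_along(models)) {
    mod <- models[[i]]
    if (!mod$metric %in% names(values) || !is.finite(values[[mod$metric]]))
      next
    rows[[i]] <- tryCatch({
      ref <- match_reference(scan_demo, cohort, cfg,
                             retained_ids = names(mod$residues))
      evaluate_metric(values[[mod$metric]], scan_demo$age, mod,
                      ref$scan_ids, cfg, age_window_frac, ref$level)
    }, error = function(e)
      data.frame(metric = mod$metric, residual = NA_real_, z = NA_real_,
                 p = NA_real_, signed_log10p = NA_real_, matched_n = 0L,
                 matching_level = "error", artifact_p = NA_real_,
                 stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(metric = character(), residual = numeric(),
                      z = numeric(), p = numeric(), signed_log10p = numeric(),
                      matched_n = integer(), matching_level = character(),
                      artifact_p = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a regional significance map from scan evaluations
#'
#' @param evals data.frame from \code{\link{evaluate_scan}}.
#' @param catalog A \code{som_catalog}.
#' @param kind Metric kind (\code{mean_cth}, \code{sd_cth} or
#'   \code{volume}).
#' @param normalized Use the brain-size-normalized variants?
#' @return data.frame (region, hemisphere, signed_log10p) over the 68 DK
#'   cortical regions.
#' @export
significance_map <- function(evals, catalog, kind = "mean_cth",
                             normalized = TRUE) {
  nm <- catalog_dk_names(catalog, kind, normalized)
  sel <- catalog$kind == kind & catalog$region %in% dk_regions() &
    catalog$hemisphere %in% c("lh", "rh")
  out <- data.frame(region = catalog$region[sel],
                    hemisphere = catalog$hemisphere[sel],
                    stringsAsFactors = FALSE)
  out$signed_log10p <- evals$signed_log10p[match(nm, evals$metric)]
  out
}

#' Flag a scan as anomalous from its raw-metric evaluations
#'
#' A scan is anomalous when at least ceil(scan_flag_fraction * n) of its n
#' evaluated raw metrics have p below q; with the defaults and the full
#' 358-metric catalog the threshold is 18.
#'
#' @param evals data.frame of evaluations covering raw metrics only.
#' @param cfg A \code{som_eval_config}.
#' @return List with \code{is_anomalous}, \code{n_abnormal},
#'   \code{threshold} and \code{n_evaluated}.
#' @export
flag_anomalous_scan <- function(evals, cfg = evaluation_config()) {
  if (nrow(evals) == 0) stop("no evaluations supplied")
  ok <- !is.na(evals$p)
  n_eval <- sum(ok)
  if (n_eval == 0) stop("all evaluations are NA")
  n_ab <- sum(evals$p[ok] < cfg$q)
  thr <- as.integer(ceiling(cfg$scan_flag_fraction * n_eval))
  list(is_anomalous = n_ab >= thr, n_abnormal = n_ab, threshold = thr,
       n_evaluated = n_eval)
}
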