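#' Persist normative models as JSON
#'
#' One JSON document holding, per metric: averaged coefficients (both the
#' centered/scaled basis used for prediction and the raw-age basis),
#' degree histogram, outlier flags, retained residues with ages,
#' measurement uncertainty and the fit seed.
#'
#' @param models Named list of \code{som_model}.
#' @param path Output .json path.
#' @param cohort_hash Optional provenance hash recorded alongside.
#' @return The path, invisibly.
#' @export
write_models <- function(models, path, cohort_hash = NULL) {
  doc <- list(
    package = "normascan",
    cohort_hash = cohort_hash,
    models = lapply(models, function(m) {
      m$degree_counts <- as.list(stats::setNames(as.integer(m$degree_counts),
                                                 names(m$degree_counts)))
      unclass(m)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read normative models written by \code{\link{write_models}}
#' @param path Path to the .json document.
#' @return Named list of \code{som_model}.
#' @export
read_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(doc$models, function(m) {
    m$degree_counts <- unlist(m$degree_counts)
    m$outlier_flags <- unlist(m$outlier_flags)
    m$residues <- unlist(m$residues)
    m$residue_ages <- unlist(m$residue_ages)
    m$coef <- as.numeric(m$coef)
    m$coef_age <- as.numeric(m$coef_age)
    class(m) <- "som_model"
    m
  })
}

# md5 of the cohort's on-disk representation
.cohort_hash <- function(cohort) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(c(tmp, sub("\\.csv$", "_demo.csv", tmp))))
  write_cohort(cohort, tmp, sub("\\.csv$", "_demo.csv", tmp))
  unname(tools::md5sum(tmp))
}

#' Run the full normative-modeling workflow
#'
#' fit -> LOOCV -> clean -> refit (normalization context and models on
#' the cleaned cohort) -> optional patient evaluation -> group summaries.
#' All intermediates are persisted under \code{out_dir} together with a
#' manifest (seed, configuration echo, cohort hashes, package version)
#' sufficient to reproduce the run.
#'
#' @param hc_cohort Normative (healthy-control) \code{som_cohort} with
#'   raw metrics.
#' @param patients Optional patient \code{som_cohort} to evaluate against
#'   the cleaned models.
#' @param metrics Metric names to model (default: all raw catalog metrics
#'   present, excluding ICV).
#' @param rcfg,fcfg,ecfg Configurations; \code{rcfg$seed} seeds the whole
#'   run.
#' @param out_dir Output directory (created if missing); NULL disables
#'   persistence.
#' @param post_loocv Re-run the LOOCV on the cleaned cohort as a check?
#' @param catalog A \code{som_catalog}.
#' @return List of class \code{som_run}: \code{loocv}, \code{removed},
#'   \code{clean_cohort}, \code{models}, \code{norm_ctx},
#'   \code{post_loocv}, \code{patient_eval} (per-scan flags and long
#'   evaluations or NULL), \code{roc}, \code{summary} (named numbers),
#'   \code{manifest}.
#' @export
run_full_pipeline <- function(hc_cohort, patients = NULL, metrics = NULL,
                              rcfg = resampling_config(),
                              fcfg = fit_config(),
                              ecfg = evaluation_config(),
                              out_dir = NULL, post_loocv = FALSE,
                              catalog = build_metric_catalog()) {
  if (is.null(metrics))
    metrics <- setdiff(intersect(catalog_raw_names(catalog),
                                 colnames(hc_cohort$metrics)), "icv")
  loocv <- run_loocv(hc_cohort, metrics, rcfg, fcfg, ecfg, catalog)
  cl <- clean_cohort(hc_cohort, loocv, ecfg)
  ctx <- if ("icv" %in% colnames(cl$cohort$metrics))
    normalization_context(cl$cohort) else NULL
  models <- fit_models(cl$cohort, metrics, rcfg, fcfg, catalog)
  post <- if (post_loocv)
    run_loocv(cl$cohort, metrics, rcfg, fcfg, ecfg, catalog) else NULL
  patient_eval <- NULL
  roc <- NULL
  if (!is.null(patients)) {
    per_scan <- list(); ev_all <- list()
    pids <- scan_ids(patients)
    for (i in seq_len(n_scans(patients))) {
      evals <- evaluate_scan(patients$demo[i, , drop = FALSE],
                             patients$metrics[i, ], models, cl$cohort,
                             ecfg, fcfg$age_window_frac)
      fl <- flag_anomalous_scan(evals, ecfg)
      per_scan[[i]] <- data.frame(
        scan_id = pids[i], subject_id = patients$demo$subject_id[i],
        n_evaluated = fl$n_evaluated, n_abnormal = fl$n_abnormal,
        threshold = fl$threshold, flagged = fl$is_anomalous,
        stringsAsFactors = FALSE)
      evals$scan_id <- pids[i]
      ev_all[[i]] <- evals
    }
    patient_eval <- list(per_scan = do.call(rbind, per_scan),
                         evaluations = do.call(rbind, ev_all))
    hc_ref <- if (!is.null(post)) post else loocv
    hc_scores <- 100 * hc_ref$per_scan$n_abnormal / hc_ref$per_scan$n_evaluated
    pt_scores <- 100 * patient_eval$per_scan$n_abnormal /
      patient_eval$per_scan$n_evaluated
    roc <- roc_from_scores(c(pt_scores, hc_scores),
                           rep(c(TRUE, FALSE),
                               c(length(pt_scores), length(hc_scores))))
  }
  summary <- list(
    n_hc_scans = n_scans(hc_cohort),
    n_metrics = length(metrics),
    loocv_detection_fraction = loocv$detection_fraction,
    n_removed = length(cl$removed),
    post_loocv_detection_fraction =
      if (!is.null(post)) post$detection_fraction else NA,
    patient_flag_rate = if (!is.null(patient_eval))
      mean(patient_eval$per_scan$flagged) else NA,
    hc_flag_rate = mean(loocv$per_scan$flagged),
    auc = if (!is.null(roc)) roc$auc else NA)
  manifest <- list(
    package = "normascan",
    version = as.character(utils::packageVersion("normascan")),
    seed = rcfg$seed,
    n_resamples = rcfg$n_resamples, n_bins = rcfg$n_bins,
    f_test_alpha = fcfg$f_test_alpha, iqr_factor = fcfg$iqr_factor,
    q = ecfg$q, scan_flag_fraction = ecfg$scan_flag_fraction,
    min_match_size = ecfg$min_match_size,
    metrics = metrics,
    hc_cohort_hash = .cohort_hash(hc_cohort),
    clean_cohort_hash = .cohort_hash(cl$cohort),
    patient_cohort_hash = if (!is.null(patients)) .cohort_hash(patients)
                          else NULL)
  out <- structure(list(loocv = loocv, removed = cl$removed,
                        clean_cohort = cl$cohort, models = models,
                        norm_ctx = ctx, post_loocv = post,
                        patient_eval = patient_eval, roc = roc,
                        summary = summary, manifest = manifest),
                   class = "som_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_models(models, file.path(out_dir, "models.json"),
                 cohort_hash = manifest$clean_cohort_hash)
    data.table::fwrite(loocv$per_scan, file.path(out_dir, "loocv_scans.csv"))
    writeLines(cl$removed, file.path(out_dir, "removed_scans.txt"))
    write_cohort(cl$cohort, file.path(out_dir, "clean_metrics.csv"),
                 file.path(out_dir, "clean_demographics.csv"))
    if (!is.null(patient_eval)) {
      data.table::fwrite(patient_eval$per_scan,
                         file.path(out_dir, "patient_scans.csv"))
      data.table::fwrite(patient_eval$evaluations,
                         file.path(out_dir, "patient_evaluations.csv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.som_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<som_run> %d HC scans, %d metrics\n",
           "  LOOCV detection fraction: %.4f (flag rate %.4f)\n",
           "  scans removed by cleaning: %d\n"),
    s$n_hc_scans, s$n_metrics, s$loocv_detection_fraction, s$hc_flag_rate,
    s$n_removed))
  if (!is.na(s$patient_flag_rate))
    cat(sprintf("  patient flag rate: %.4f, AUC: %.3f\n",
                s$patient_flag_rate, s$auc))
  invisible(x)
}
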