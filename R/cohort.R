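#' Construct a cohort of scans
#'
#' A cohort couples a demographics table (one row per scan) with a numeric
#' metric matrix (one row per scan, one column per catalog metric).  The
#' pair (subject_id, session_id) must be unique; ages must be finite and
#' positive.
#'
#' @param demo data.frame with columns subject_id, session_id, age, sex,
#'   scanner, protocol and optionally cdr (numeric, NA when missing).
#' @param metrics Numeric matrix, rows aligned with \code{demo}, columns
#'   named by catalog metric names (may be a subset).
#' @param provenance Free-text source tag.
#' @return An object of class \code{som_cohort}.
#' @export
som_cohort <- function(demo, metrics, provenance = "unspecified") {
  stopifnot(is.data.frame(demo), nrow(demo) == nrow(metrics))
  need <- c("subject_id", "session_id", "age", "sex", "scanner", "protocol")
  miss <- setdiff(need, names(demo))
  if (length(miss))
    stop("demographics missing columns: ", paste(miss, collapse = ", "))
  if (!"cdr" %in% names(demo)) demo$cdr <- NA_real_
  demo$subject_id <- as.character(demo$subject_id)
  demo$session_id <- as.character(demo$session_id)
  ids <- scan_ids(demo)
  if (anyDuplicated(ids))
    stop("duplicate (subject_id, session_id) pairs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (nrow(demo) > 0 && any(!is.finite(demo$age) | demo$age <= 0))
    stop("age must be finite and positive for every scan")
  metrics <- as.matrix(metrics)
  storage.mode(metrics) <- "double"
  rownames(metrics) <- ids
  structure(list(demo = demo, metrics = metrics, provenance = provenance),
            class = "som_cohort")
}

#' Scan identifiers
#' @param x A \code{som_cohort} or demographics data.frame.
#' @return Character vector \code{subject_id:session_id}.
#' @export
scan_ids <- function(x) {
  d <- if (inherits(x, "som_cohort")) x$demo else x
  paste(d$subject_id, d$session_id, sep = ":")
}

#' Number of scans in a cohort
#' @param cohort A \code{som_cohort}.
#' @return Integer count.
#' @export
n_scans <- function(cohort) nrow(cohort$demo)

#' @export
print.som_cohort <- function(x, ...) {
  cat(sprintf("<som_cohort> %d scans, %d subjects, %d metrics (%s)\n",
              n_scans(x), length(unique(x$demo$subject_id)),
              ncol(x$metrics), x$provenance))
  invisible(x)
}

#' Subset a cohort by scan index
#' @param cohort A \code{som_cohort}.
#' @param idx Integer or logical index over scans.
#' @return A \code{som_cohort} with the selected scans.
#' @export
cohort_subset <- function(cohort, idx) {
  som_cohort(cohort$demo[idx, , drop = FALSE],
             cohort$metrics[idx, , drop = FALSE],
             provenance = cohort$provenance)
}

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a cohort from metrics and demographics tables
#'
#' The metrics table is either wide (one row per scan, one column per
#' catalog metric) or long (columns subject_id, session_id, metric, value).
#' Delimiters are auto-detected between comma and TAB.  Metric columns not
#' in the catalog are reported and ignored.
#'
#' @param metrics_table Path to the metrics CSV/TSV.
#' @param demographics_table Path to the demographics CSV/TSV.
#' @param catalog A \code{som_catalog}.
#' @param format \code{"auto"}, \code{"wide"} or \code{"long"}.
#' @param provenance Source tag recorded on the cohort.
#' @return A \code{som_cohort}.
#' @export
read_cohort <- function(metrics_table, demographics_table, catalog,
                        format = c("auto", "wide", "long"),
                        provenance = metrics_table) {
  format <- match.arg(format)
  stopifnot(file.exists(metrics_table), file.exists(demographics_table))
  demo <- as.data.frame(data.table::fread(
    demographics_table, sep = .detect_sep(demographics_table)))
  need <- c("subject_id", "session_id")
  if (!all(need %in% names(demo)))
    stop("demographics table lacks join key (subject_id, session_id)")
  for (cn in need) demo[[cn]] <- as.character(demo[[cn]])
  met <- as.data.frame(data.table::fread(metrics_table,
                                         sep = .detect_sep(metrics_table)))
  for (cn in intersect(need, names(met))) met[[cn]] <- as.character(met[[cn]])
  if (nrow(met) == 0L) {
    warning("empty metrics table: returning a cohort with 0 scans")
    m <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(som_cohort(demo[0, , drop = FALSE], m, provenance))
  }
  if (!all(need %in% names(met)))
    stop("metrics table lacks join key (subject_id, session_id)")
  if (format == "auto")
    format <- if (all(c("metric", "value") %in% names(met))) "long" else "wide"
  all_names <- catalog_all_names(catalog)
  if (format == "long") {
    unknown <- setdiff(unique(met$metric), all_names)
    if (length(unknown))
      warning("ignoring ", length(unknown), " unknown metrics: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    met <- met[met$metric %in% all_names, , drop = FALSE]
    if (!is.numeric(met$value)) {
      bad <- which(is.na(suppressWarnings(as.numeric(met$value))) &
                     !is.na(met$value) & met$value != "NA")
      stop("non-numeric metric values, e.g. scan ",
           paste(met$subject_id[bad[1]], met$session_id[bad[1]], sep = ":"),
           " metric ", met$metric[bad[1]])
    }
    wide <- data.table::dcast(data.table::as.data.table(met),
                              subject_id + session_id ~ metric,
                              value.var = "value")
    met <- as.data.frame(wide)
  } else {
    cols <- setdiff(names(met), need)
    unknown <- setdiff(cols, all_names)
    if (length(unknown))
      warning("ignoring ", length(unknown), " unknown columns: ",
              paste(utils::head(unknown, 5), collapse = ", "))
    met <- met[, c(need, intersect(cols, all_names)), drop = FALSE]
    for (cn in setdiff(names(met), need))
      if (!is.numeric(met[[cn]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(met[[cn]]))) &
                       !is.na(met[[cn]]))
        stop("non-numeric value in metric column ", cn, " for scan ",
             paste(met$subject_id[bad[1]], met$session_id[bad[1]], sep = ":"))
      }
  }
  key_m <- paste(met$subject_id, met$session_id, sep = ":")
  if (anyDuplicated(key_m))
    stop("duplicate (subject_id, session_id) in metrics table: ",
         key_m[duplicated(key_m)][1])
  key_d <- paste(demo$subject_id, demo$session_id, sep = ":")
  if (anyDuplicated(key_d))
    stop("duplicate (subject_id, session_id) in demographics table")
  j <- match(key_m, key_d)
  if (anyNA(j))
    stop("scans in metrics table missing from demographics: ",
         paste(utils::head(key_m[is.na(j)], 5), collapse = ", "))
  demo <- demo[j, , drop = FALSE]
  rownames(demo) <- NULL
  mcols <- setdiff(names(met), need)
  mat <- as.matrix(met[, mcols, drop = FALSE])
  som_cohort(demo, mat, provenance)
}

#' Write a cohort to wide metrics and demographics tables
#'
#' Inverse of \code{\link{read_cohort}}; floats are written with 15
#' significant digits so that read-after-write is stable to at least 12
#' significant digits.
#'
#' @param cohort A \code{som_cohort}.
#' @param metrics_table,demographics_table Output paths (.csv or .tsv).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, metrics_table, demographics_table) {
  sep <- if (grepl("\\.tsv$", metrics_table)) "\t" else ","
  met <- data.frame(subject_id = cohort$demo$subject_id,
                    session_id = cohort$demo$session_id,
                    stringsAsFactors = FALSE)
  met <- cbind(met, as.data.frame(cohort$metrics, row.names = NULL))
  data.table::fwrite(met, metrics_table, sep = sep)
  data.table::fwrite(cohort$demo, demographics_table,
                     sep = if (grepl("\\.tsv$", demographics_table)) "\t" else ",")
  invisible(c(metrics_table, demographics_table))
}

#' Translate FreeSurfer-style export column names to canonical names
#'
#' Maps common aparc/aseg tabular export headers (e.g.
#' \code{lh_entorhinal_thickness}, \code{Left-Hippocampus},
#' \code{EstimatedTotalIntraCranialVol}) onto the catalog's
#' \code{<hemi>.<region>.<kind>} scheme.  Unrecognized names are returned
#' unchanged.
#'
#' @param x Character vector of column names.
#' @return Character vector of the same length.
#' @export
translate_freesurfer_names <- function(x) {
  out <- x
  # aparc exports: lh_<region>_thickness / _volume / _thicknessstd
  m <- regmatches(x, regexec("^(lh|rh)_([a-z]+)_(thickness|thicknessstd|volume)$", x))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 4L) {
      kind <- c(thickness = "mean_cth", thicknessstd = "sd_cth",
                volume = "volume")[m[[i]][4]]
      out[i] <- paste(m[[i]][2], m[[i]][3], kind, sep = ".")
    }
  }
  aseg <- c("Left-Thalamus-Proper" = "lh.thalamus_proper.volume",
            "Right-Thalamus-Proper" = "rh.thalamus_proper.volume",
            "Left-Caudate" = "lh.caudate.volume",
            "Right-Caudate" = "rh.caudate.volume",
            "Left-Putamen" = "lh.putamen.volume",
            "Right-Putamen" = "rh.putamen.volume",
            "Left-Pallidum" = "lh.pallidum.volume",
            "Right-Pallidum" = "rh.pallidum.volume",
            "Left-Accumbens-area" = "lh.accumbens_area.volume",
            "Right-Accumbens-area" = "rh.accumbens_area.volume",
            "Left-Hippocampus" = "lh.hippocampus.volume",
            "Right-Hippocampus" = "rh.hippocampus.volume",
            "Left-Amygdala" = "lh.amygdala.volume",
            "Right-Amygdala" = "rh.amygdala.volume",
            "Left-VentralDC" = "lh.ventral_dc.volume",
            "Right-VentralDC" = "rh.ventral_dc.volume",
            "Brain-Stem" = "mid.brainstem.volume",
            "3rd-Ventricle" = "mid.ventricle_3rd.volume",
            "4th-Ventricle" = "mid.ventricle_4th.volume",
            "EstimatedTotalIntraCranialVol" = "icv",
            "eTIV" = "icv")
  hit <- x %in% names(aseg)
  out[hit] <- aseg[x[hit]]
  out
}

#' Validate a cohort against the catalog
#'
#' Report-only check listing scans with missing catalog metrics,
#' non-positive ICV, missing covariates, or age outside a plausible range.
#'
#' @param cohort A \code{som_cohort}.
#' @param catalog A \code{som_catalog}.
#' @param age_range Plausible age range in years.
#' @return A list of class \code{som_validation} with elements
#'   \code{missing_metrics} (data.frame scan_id, metric),
#'   \code{non_positive_icv}, \code{missing_covariates} (data.frame
#'   scan_id, field), \code{age_out_of_range} (scan id vectors).
#' @export
validate_cohort <- function(cohort, catalog, age_range = c(18, 110)) {
  ids <- scan_ids(cohort)
  raw <- catalog_raw_names(catalog)
  have <- intersect(raw, colnames(cohort$metrics))
  mm <- list()
  if (n_scans(cohort) > 0) {
    absent <- setdiff(raw, have)
    for (i in seq_len(n_scans(cohort))) {
      miss <- c(absent, have[!is.finite(cohort$metrics[i, have])])
      if (length(miss))
        mm[[length(mm) + 1L]] <- data.frame(scan_id = ids[i], metric = miss,
                                            stringsAsFactors = FALSE)
    }
  }
  mm <- if (length(mm)) do.call(rbind, mm) else
    data.frame(scan_id = character(), metric = character())
  icv_bad <- if ("icv" %in% colnames(cohort$metrics))
    ids[!is.na(cohort$metrics[, "icv"]) & cohort$metrics[, "icv"] <= 0]
  else character()
  mc <- list()
  for (f in c("sex", "scanner", "protocol")) {
    bad <- ids[is.na(cohort$demo[[f]]) | cohort$demo[[f]] == ""]
    if (length(bad))
      mc[[length(mc) + 1L]] <- data.frame(scan_id = bad, field = f,
                                          stringsAsFactors = FALSE)
  }
  mc <- if (length(mc)) do.call(rbind, mc) else
    data.frame(scan_id = character(), field = character())
  age_bad <- ids[cohort$demo$age < age_range[1] | cohort$demo$age > age_range[2]]
  structure(list(missing_metrics = mm, non_positive_icv = icv_bad,
                 missing_covariates = mc, age_out_of_range = age_bad),
            class = "som_validation")
}

#' Is a validation report empty?
#' @param report A \code{som_validation}.
#' @return TRUE when no issues were found.
#' @export
is_clean_report <- function(report) {
  nrow(report$missing_metrics) == 0 && length(report$non_positive_icv) == 0 &&
    nrow(report$missing_covariates) == 0 && length(report$age_out_of_range) == 0
}

#' @export
print.som_validation <- function(x, ...) {
  cat("<som_validation>",
      if (is_clean_report(x)) "clean\n" else "\n")
  if (nrow(x$missing_metrics))
    cat("  missing metrics:", nrow(x$missing_metrics), "entries on",
        length(unique(x$missing_metrics$scan_id)), "scans\n")
  if (length(x$non_positive_icv))
    cat("  non-positive ICV:", paste(x$non_positive_icv, collapse = ", "), "\n")
  if (nrow(x$missing_covariates))
    cat("  missing covariates:", nrow(x$missing_covariates), "entries\n")
  if (length(x$age_out_of_range))
    cat("  age out of range:", paste(x$age_out_of_range, collapse = ", "), "\n")
  invisible(x)
}
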