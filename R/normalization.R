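#' Normalization context
#'
#' Holds the reference mean intracranial volume (ICV) of the normative
#' cohort.  Volumes are rescaled to this reference; thickness metrics are
#' rescaled isometrically with the cube root of the ICV ratio.  The
#' context must be recomputed whenever the normative cohort changes (e.g.
#' after LOOCV cleaning).
#'
#' @param cohort A \code{som_cohort} holding the normative scans, or NULL
#'   when \code{icv_ref_mean} is given directly.
#' @param icv_ref_mean Reference mean ICV in mm^3.
#' @return An object of class \code{som_normctx}.
#' @export
normalization_context <- function(cohort = NULL, icv_ref_mean = NULL) {
  if (is.null(icv_ref_mean)) {
    stopifnot(inherits(cohort, "som_cohort"),
              "icv" %in% colnames(cohort$metrics))
    icv_ref_mean <- mean(cohort$metrics[, "icv"], na.rm = TRUE)
  }
  if (!is.finite(icv_ref_mean) || icv_ref_mean <= 0)
    stop("icv_ref_mean must be positive")
  structure(list(icv_ref_mean = icv_ref_mean), class = "som_normctx")
}

#' Signed asymmetry index of a bilateral metric
#'
#' AI = 2 (L - R) / (L + R), dimensionless and in [-2, 2].  The index is
#' invariant under common rescaling of both sides, which is why brain-size
#' normalization leaves asymmetry entries unchanged.  Degenerate inputs
#' with L + R = 0 yield 0 and are flagged.
#'
#' @param left,right Metric values (vectorized).
#' @return Numeric vector; attribute \code{degenerate} marks L + R = 0
#'   entries when any occur.
#' @export
asymmetry_index <- function(left, right) {
  s <- left + right
  degen <- is.finite(s) & s == 0
  out <- ifelse(degen, 0, 2 * (left - right) / s)
  if (any(degen)) {
    warning("asymmetry index undefined for L + R = 0; returning 0")
    attr(out, "degenerate") <- degen
  }
  out
}

#' Normalize a single metric value for brain size
#'
#' Volumes scale linearly with the ICV ratio; mean and SD of cortical
#' thickness scale with its cube root, respecting the cortex's geometry
#' as a folded two-dimensional sheet.
#'
#' @param value Raw metric value(s).
#' @param kind \code{"volume"}, \code{"mean_cth"} or \code{"sd_cth"}.
#' @param icv Scan ICV in mm^3 (> 0).
#' @param ctx A \code{som_normctx}.
#' @return Normalized value(s).
#' @export
normalize_metric <- function(value, kind = c("volume", "mean_cth", "sd_cth"),
                             icv, ctx) {
  kind <- match.arg(kind)
  if (any(!is.finite(icv) | icv <= 0)) stop("icv must be positive")
  ratio <- ctx$icv_ref_mean / icv
  if (kind == "volume") value * ratio else value * ratio^(1 / 3)
}

#' Add normalized metric variants to a cohort
#'
#' Appends one \code{.norm} column per normalizable catalog entry (239 for
#' the full catalog).  Asymmetry indices and ICV are not duplicated: the
#' former are scale-invariant and the latter normalizes to a constant.
#' Scans without a finite positive ICV are skipped with a warning (their
#' normalized entries are NA).
#'
#' @param cohort A \code{som_cohort}.
#' @param catalog A \code{som_catalog}.
#' @param ctx A \code{som_normctx}; defaults to the cohort's own mean ICV.
#' @return The cohort with normalized columns appended.
#' @export
apply_normalization <- function(cohort, catalog, ctx = NULL) {
  if (!"icv" %in% colnames(cohort$metrics))
    stop("cohort has no icv metric; cannot normalize")
  if (is.null(ctx)) ctx <- normalization_context(cohort)
  icv <- cohort$metrics[, "icv"]
  ok <- is.finite(icv) & icv > 0
  if (any(!ok))
    warning(sum(!ok), " scan(s) without valid ICV skipped in normalization")
  norm_entries <- catalog[catalog$normalizable, , drop = FALSE]
  norm_entries <- norm_entries[norm_entries$name %in% colnames(cohort$metrics), ,
                               drop = FALSE]
  ratio <- ctx$icv_ref_mean / icv
  ratio[!ok] <- NA_real_
  add <- matrix(NA_real_, nrow = n_scans(cohort), ncol = nrow(norm_entries),
                dimnames = list(rownames(cohort$metrics),
                                paste0(norm_entries$name, ".norm")))
  for (j in seq_len(nrow(norm_entries))) {
    v <- cohort$metrics[, norm_entries$name[j]]
    add[, j] <- if (norm_entries$kind[j] == "volume") v * ratio
                else v * ratio^(1 / 3)
  }
  keep <- setdiff(colnames(cohort$metrics), colnames(add))
  cohort$metrics <- cbind(cohort$metrics[, keep, drop = FALSE], add)
  cohort
}
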