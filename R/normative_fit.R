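#' Resampling configuration for uniform age sampling
#'
#' @param n_bins Number of equal-width age bins (default 10).
#' @param n_resamples Number of resamples averaged per model (default 100).
#' @param seed Integer seed for the fit run, or NULL to use the current
#'   RNG state.
#' @return A list of class \code{som_resampling_config}.
#' @export
resampling_config <- function(n_bins = 10L, n_resamples = 100L, seed = NULL) {
  stopifnot(n_bins >= 1, n_resamples >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 n_resamples = as.integer(n_resamples), seed = seed),
            class = "som_resampling_config")
}

#' Fitting configuration
#'
#' @param f_test_alpha Significance level of the nested F-test used to
#'   step up the polynomial degree (default 0.05).
#' @param iqr_factor Tukey-fence multiplier for outlier rejection
#'   (default 1.5).
#' @param age_window_frac Half-width of the age-local window as a fraction
#'   of the query age (default 0.10).
#' @param pi_level Prediction-interval coverage (default 0.95).
#' @return A list of class \code{som_fit_config}.
#' @export
fit_config <- function(f_test_alpha = 0.05, iqr_factor = 1.5,
                       age_window_frac = 0.10, pi_level = 0.95) {
  stopifnot(f_test_alpha > 0, f_test_alpha < 1, iqr_factor > 0)
  structure(list(f_test_alpha = f_test_alpha, iqr_factor = iqr_factor,
                 age_window_frac = age_window_frac, pi_level = pi_level),
            class = "som_fit_config")
}

# run expr with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Maximum allowed polynomial degree
#'
#' Overfitting guard: the cap is the odd number
#' 2 * floor(ln(n / 10) + 1) - 1 for n reference scans, e.g. 11 for
#' n = 1927.  Below n = 10 the formula is undefined and degree 1 is
#' returned with a warning.
#'
#' @param n Number of available samples.
#' @return Odd integer degree cap.
#' @export
max_poly_degree <- function(n) {
  if (n < 10) {
    warning("degree cap undefined for n < 10; returning 1")
    return(1L)
  }
  as.integer(2L * floor(log(n / 10) + 1) - 1L)
}

#' Tukey-fence outlier mask
#'
#' Flags values below Q1 - factor * IQR or above Q3 + factor * IQR, with
#' quartiles by linear interpolation between order statistics (quantile
#' type 7).  Fewer than 4 finite values yields no flags with a warning.
#'
#' @param values Numeric vector.
#' @param factor Fence multiplier (default 1.5).
#' @return Logical vector, TRUE for outliers.
#' @export
iqr_outlier_mask <- function(values, factor = 1.5) {
  out <- rep(FALSE, length(values))
  fin <- is.finite(values)
  if (sum(fin) < 4L) {
    warning("fewer than 4 finite values; no outliers flagged")
    return(out)
  }
  qs <- stats::quantile(values[fin], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  out[fin] <- values[fin] < qs[1] - factor * iqr |
    values[fin] > qs[2] + factor * iqr
  out
}

#' Uniform age resampling
#'
#' Builds an equal-width age histogram over [min(age), max(age)] and draws
#' n_min indices without replacement from every non-empty bin, n_min being
#' the smallest non-empty bin count.  Uniform age distributions are left
#' unchanged (the draw is a permutation of all indices); skewed
#' distributions are rendered approximately uniform.
#'
#' @param ages Numeric vector of ages.
#' @param cfg A \code{som_resampling_config}; its seed, when non-NULL,
#'   makes the draw reproducible, otherwise the current RNG stream is
#'   consumed.
#' @return Integer vector of selected indices.
#' @export
uniform_age_resample <- function(ages, cfg = resampling_config()) {
  stopifnot(length(ages) >= 1, all(is.finite(ages)))
  .with_seed(cfg$seed, {
    rng <- range(ages)
    if (rng[1] == rng[2]) return(seq_along(ages))
    breaks <- seq(rng[1], rng[2], length.out = cfg$n_bins + 1L)
    bin <- findInterval(ages, breaks, rightmost.closed = TRUE)
    idx_by_bin <- split(seq_along(ages), bin)
    n_min <- min(lengths(idx_by_bin))
    unlist(lapply(idx_by_bin, function(ix)
      if (length(ix) == 1L) ix else sample(ix, n_min)), use.names = FALSE)
  })
}

# Horner evaluation of ascending-degree coefficients
.poly_eval <- function(coef, x) {
  out <- rep(coef[length(coef)], length(x))
  for (j in rev(seq_len(length(coef) - 1L))) out <- out * x + coef[j]
  out
}

# convert coefficients in u = (x - center) / scale to the x basis
.poly_unscale <- function(coef_u, center, scale) {
  d <- length(coef_u) - 1L
  out <- numeric(d + 1L)
  lin <- c(-center / scale, 1 / scale)   # u as a polynomial in x
  out[1] <- coef_u[1]
  for (k in seq_len(d)) {
    pw <- .poly_mult_idx(k, lin)         # coefficients of lin^k
    out[seq_along(pw)] <- out[seq_along(pw)] + coef_u[k + 1L] * pw
  }
  out
}

# lin^k by repeated convolution
.poly_mult_idx <- function(k, lin) {
  pw <- 1
  for (i in seq_len(k)) {
    res <- numeric(length(pw) + 1L)
    res[seq_along(pw)] <- res[seq_along(pw)] + pw * lin[1]
    res[seq_along(pw) + 1L] <- res[seq_along(pw) + 1L] + pw * lin[2]
    pw <- res
  }
  pw
}

# Nested-RSS path via one QR of the Vandermonde matrix in u.
# Returns list(degree, coef) with coef in the u basis, or NULL on failure.
.poly_fit_path <- function(u, y, d_max, alpha) {
  n <- length(y)
  d_max <- max(0L, min(d_max, n - 2L, length(unique(u)) - 1L))
  V <- outer(u, 0:d_max, `^`)
  qrV <- qr(V)
  if (qrV$rank < ncol(V) || !identical(qrV$pivot, seq_len(ncol(V)))) {
    d_max <- max(0L, qrV$rank - 1L)
    V <- V[, seq_len(d_max + 1L), drop = FALSE]
    qrV <- qr(V)
    if (qrV$rank < ncol(V)) {  # truly degenerate design: constant fallback
      return(list(degree = 0L, coef = mean(y)))
    }
  }
  qty <- qr.qty(qrV, y)[seq_len(d_max + 1L)]
  tss <- sum((y - mean(y))^2)
  rss <- pmax(sum(y^2) - cumsum(qty^2), 0)   # rss[d + 1] = RSS(degree d)
  tol <- max(tss, 1) * 1e-12
  d <- 0L
  while (d < d_max) {
    if (rss[d + 1L] <= tol) break           # already a perfect fit
    df2 <- n - d - 2L
    if (df2 < 1L) break
    num <- rss[d + 1L] - rss[d + 2L]
    den <- rss[d + 2L] / df2
    pval <- if (den <= 0) 0 else
      stats::pf(num / den, 1, df2, lower.tail = FALSE)
    if (pval < alpha) d <- d + 1L else break
  }
  R <- qr.R(qrV)[seq_len(d + 1L), seq_len(d + 1L), drop = FALSE]
  list(degree = d, coef = as.numeric(backsolve(R, qty[seq_len(d + 1L)])))
}

#' Select the polynomial degree by nested F-tests
#'
#' Least-squares polynomial fits of increasing degree, starting at zero
#' and stepping up while the reduction in residual sum of squares is
#' significant in a nested F-test (1 numerator df, n - d - 2 denominator
#' df), capped at \code{d_max}.
#'
#' @param ages,values Paired numeric vectors.
#' @param cfg A \code{som_fit_config}.
#' @param d_max Degree cap (default from \code{\link{max_poly_degree}}).
#' @return List with \code{degree} and \code{coefficients} (ascending
#'   powers of age).
#' @export
select_poly_degree <- function(ages, values, cfg = fit_config(),
                               d_max = max_poly_degree(length(ages))) {
  stopifnot(length(ages) == length(values), length(ages) >= 2)
  ctr <- mean(range(ages))
  scl <- diff(range(ages)) / 2
  if (scl == 0) scl <- 1
  fit <- .poly_fit_path((ages - ctr) / scl, values, d_max, cfg$f_test_alpha)
  list(degree = fit$degree,
       coefficients = .poly_unscale(fit$coef, ctr, scl))
}

#' Scan-rescan measurement uncertainty of a metric
#'
#' Pools within-subject differences over all scan pairs whose ages differ
#' by less than \code{age_window_frac} of the pair's mean age:
#' sigma_meas = sqrt(mean(diff^2) / 2).  Repeated scans under routine
#' conditions make this an upper bound of the true same-session
#' uncertainty.  Returns 0 with a warning when no qualifying pairs exist.
#'
#' @param cohort A \code{som_cohort}.
#' @param metric Metric name.
#' @param age_window_frac Maximum relative age difference (default 0.10).
#' @param scan_keep Optional logical over scans restricting the pairs
#'   (e.g. to non-outlier scans).
#' @return Non-negative SD in metric units.
#' @export
measurement_uncertainty <- function(cohort, metric, age_window_frac = 0.10,
                                    scan_keep = NULL) {
  v <- cohort$metrics[, metric]
  a <- cohort$demo$age
  keep <- is.finite(v)
  if (!is.null(scan_keep)) keep <- keep & scan_keep
  diffs <- numeric(0)
  for (ix in split(which(keep), cohort$demo$subject_id[keep])) {
    if (length(ix) < 2L) next
    for (i in seq_len(length(ix) - 1L))
      for (j in seq(i + 1L, length(ix))) {
        ai <- a[ix[i]]; aj <- a[ix[j]]
        if (abs(ai - aj) < age_window_frac * mean(c(ai, aj)))
          diffs <- c(diffs, v[ix[i]] - v[ix[j]])
      }
  }
  if (!length(diffs)) {
    warning("no qualifying repeated scans for ", metric,
            "; measurement uncertainty set to 0")
    return(0)
  }
  sqrt(mean(diffs^2) / 2)
}

#' Fit a per-metric normative age model
#'
#' For each of \code{n_resamples} uniform-age resamples: reject value
#' outliers by Tukey fences, select the polynomial degree by nested
#' F-tests, reject fit-residue outliers, and re-run degree selection on
#' the retained points for the final fit.  The normative trajectory is
#' the coefficient average of all resample fits (zero-padded to the
#' largest selected degree), which for polynomials equals averaging the
#' predicted curves.  Fit residues are then computed for every reference
#' scan against the averaged trajectory; scans failing the value or
#' residue fences are flagged as outliers and contribute neither to the
#' stored residues nor to downstream matched reference sets.  The
#' measurement uncertainty is estimated from the retained repeated scans.
#'
#' @param cohort A \code{som_cohort} (the normative cohort).
#' @param metric Metric name present in the cohort.
#' @param rcfg A \code{som_resampling_config}.
#' @param fcfg A \code{som_fit_config}.
#' @return An object of class \code{som_model}: metric name, averaged
#'   coefficients in a centered/scaled age basis (\code{coef},
#'   \code{age_center}, \code{age_scale}), raw-age coefficients
#'   (\code{coef_age}), \code{degree_counts}, \code{d_max},
#'   \code{outlier_flags}, retained \code{residues} with their
#'   \code{residue_ages} and scan ids, \code{sigma_meas}, \code{n_fit},
#'   and the seed used.
#' @export
fit_metric_model <- function(cohort, metric, rcfg = resampling_config(),
                             fcfg = fit_config()) {
  if (!metric %in% colnames(cohort$metrics))
    stop("metric not present in cohort: ", metric)
  v_all <- cohort$metrics[, metric]
  ok <- is.finite(v_all) & is.finite(cohort$demo$age)
  if (sum(ok) < 20L)
    stop("too few scans (", sum(ok), ") to fit a normative model for ", metric)
  idx_ok <- which(ok)
  ages <- cohort$demo$age[idx_ok]
  vals <- v_all[idx_ok]
  n <- length(vals)
  d_cap <- max_poly_degree(n)
  ctr <- mean(range(ages))
  scl <- diff(range(ages)) / 2
  if (scl == 0) scl <- 1
  u <- (ages - ctr) / scl
  rcfg_local <- rcfg
  rcfg_local$seed <- NULL   # one seeded stream for the whole fit run
  coefs <- matrix(0, nrow = rcfg$n_resamples, ncol = d_cap + 1L)
  degs <- integer(rcfg$n_resamples)
  fit_ns <- integer(rcfg$n_resamples)
  .with_seed(rcfg$seed, {
    for (r in seq_len(rcfg$n_resamples)) {
      ix <- uniform_age_resample(ages, rcfg_local)
      keep1 <- ix[!iqr_outlier_mask(vals[ix], fcfg$iqr_factor)]
      f1 <- .poly_fit_path(u[keep1], vals[keep1], d_cap, fcfg$f_test_alpha)
      res1 <- vals[keep1] - .poly_eval(f1$coef, u[keep1])
      keep2 <- keep1[!iqr_outlier_mask(res1, fcfg$iqr_factor)]
      f2 <- .poly_fit_path(u[keep2], vals[keep2], d_cap, fcfg$f_test_alpha)
      degs[r] <- f2$degree
      fit_ns[r] <- length(keep2)
      coefs[r, seq_len(f2$degree + 1L)] <- f2$coef
    }
  })
  d_sel_max <- max(degs)
  coef_mean <- colMeans(coefs)[seq_len(d_sel_max + 1L)]
  p_eff <- mean(degs) + 1          # effective parameter count of the fits
  n_eff <- mean(fit_ns)            # effective per-resample fit size
  pred <- .poly_eval(coef_mean, u)
  resid <- vals - pred
  # Reference-exclusion flags are residue-based: value fences guard the
  # fits inside the resample loop, but a scan is anomalous with respect
  # to the trajectory, not to the age-pooled value distribution.
  flags <- iqr_outlier_mask(resid, fcfg$iqr_factor)
  ids <- scan_ids(cohort)[idx_ok]
  keep_all <- rep(FALSE, n_scans(cohort))
  keep_all[idx_ok[!flags]] <- TRUE
  sigma_meas <- suppressWarnings(
    measurement_uncertainty(cohort, metric, fcfg$age_window_frac,
                            scan_keep = keep_all))
  structure(list(
    metric = metric,
    coef = coef_mean, age_center = ctr, age_scale = scl,
    coef_age = .poly_unscale(coef_mean, ctr, scl),
    degree_counts = table(factor(degs, levels = 0:d_cap)),
    d_max = d_cap,
    outlier_flags = stats::setNames(flags, ids),
    residues = stats::setNames(resid[!flags], ids[!flags]),
    residue_ages = stats::setNames(ages[!flags], ids[!flags]),
    sigma_meas = sigma_meas,
    trim_fraction = mean(flags),
    p_eff = p_eff, n_eff = n_eff,
    n_fit = sum(!flags),
    seed = rcfg$seed, n_resamples = rcfg$n_resamples),
    class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "<som_model> %s: degree cap %d, modal degree %s, n_fit %d, sigma_meas %.4g\n",
    x$metric, x$d_max,
    names(which.max(x$degree_counts)), x$n_fit, x$sigma_meas))
  invisible(x)
}

#' Evaluate the normative trajectory at given ages
#' @param model A \code{som_model}.
#' @param age Ages in years.
#' @return Trajectory values in metric units.
#' @export
predict_trajectory <- function(model, age) {
  .poly_eval(model$coef, (age - model$age_center) / model$age_scale)
}

#' Age-local residue statistics of a normative model
#'
#' Mean and sample SD of the retained (non-outlier) fit residues among
#' reference scans within \code{age_window_frac} of the query age,
#' optionally restricted to a covariate-matched subset.  When fewer than
#' \code{min_local_n} scans fall in the window it widens to the nearest
#' \code{min_local_n} scans (by age distance) and the result is flagged;
#' this keeps the SD estimate stable on small reference sets while never
#' binding on large ones, where the 10% window alone holds far more
#' scans.
#'
#' @param model A \code{som_model}.
#' @param age Query age in years.
#' @param age_window_frac Window half-width as a fraction of the age.
#' @param subset_ids Optional scan ids restricting the reference residues
#'   (e.g. a covariate-matched subset).
#' @param min_local_n Minimum number of residues the window is widened to
#'   (default 100; the full matched subset when it is smaller).
#' @return List with \code{mean}, \code{sd}, \code{n} and
#'   \code{extrapolated}.
#' @export
local_population_sd <- function(model, age, age_window_frac = 0.10,
                                subset_ids = NULL, min_local_n = 100L) {
  r <- model$residues
  a <- model$residue_ages
  if (!is.null(subset_ids)) {
    keep <- names(r) %in% subset_ids
    r <- r[keep]; a <- a[keep]
  }
  if (!length(r)) return(list(mean = NA_real_, sd = NA_real_, n = 0L,
                              extrapolated = TRUE))
  inwin <- abs(a - age) <= age_window_frac * age
  extrapolated <- FALSE
  if (sum(inwin) < min_local_n) {
    ord <- order(abs(a - age))
    inwin <- seq_along(r) %in% ord[seq_len(min(min_local_n, length(r)))]
    extrapolated <- TRUE
    if (sum(inwin) < 2L) return(list(mean = mean(r[inwin]), sd = NA_real_,
                                     n = sum(inwin), extrapolated = TRUE))
  }
  # The stored residues are the survivors of Tukey-fence trimming, so
  # their sample SD is biased low.  With the trimmed fraction f observed
  # on the model, the truncated-Gaussian consistency factor is computed
  # from the implied cut point z_cut = qnorm(1 - f/2):
  # Var_trunc = 1 - 2 z_cut phi(z_cut) / (1 - f), and the SD is rescaled
  # by 1/sqrt(Var_trunc) (the same logic that gives the MAD its 1.4826).
  # In-sample residues of a p-parameter fit on n points are additionally
  # shrunk relative to out-of-sample deviations by roughly
  # sqrt((1 - p/n)/(1 + p/n)); that is undone via the model's effective
  # degree and resample size.
  f <- min(if (is.null(model$trim_fraction)) 0 else model$trim_fraction, 0.2)
  trunc_corr <- if (f > 0) {
    z_cut <- stats::qnorm(1 - f / 2)
    1 / sqrt(1 - 2 * z_cut * stats::dnorm(z_cut) / (1 - f))
  } else 1
  pred_corr <- if (!is.null(model$p_eff) && is.finite(model$n_eff) &&
                   model$n_eff > 2 * model$p_eff) {
    rho <- model$p_eff / model$n_eff
    sqrt((1 + rho) / (1 - rho))
  } else 1
  rw <- r[inwin]
  list(mean = mean(rw), sd = stats::sd(rw) * trunc_corr * pred_corr,
       n = sum(inwin), extrapolated = extrapolated)
}

#' Normative prediction interval at an age
#'
#' trajectory(age) +/- z * sqrt(sigma_pop^2 + sigma_meas^2), with the
#' Gaussian quantile z of the requested coverage, the age-local population
#' SD and the scan-rescan measurement uncertainty.
#'
#' @param model A \code{som_model}.
#' @param age Query age in years.
#' @param level Coverage probability (default the fit config's 0.95).
#' @param age_window_frac Window for the local SD.
#' @return Numeric vector \code{c(low, high)}; attribute
#'   \code{extrapolated} when the local window had to be widened.
#' @export
prediction_interval <- function(model, age, level = 0.95,
                                age_window_frac = 0.10) {
  mid <- predict_trajectory(model, age)
  loc <- local_population_sd(model, age, age_window_frac)
  s <- sqrt(loc$sd^2 + model$sigma_meas^2)
  z <- stats::qnorm((1 + level) / 2)
  out <- c(low = mid - z * s, high = mid + z * s)
  attr(out, "extrapolated") <- loc$extrapolated
  out
}

#' Fit normative models for many metrics
#'
#' @param cohort A \code{som_cohort}.
#' @param metrics Metric names (default: all raw catalog metrics present).
#' @param rcfg,fcfg Configurations; the run seed spawns one deterministic
#'   sub-seed per metric so the model set is independent of metric order.
#' @param catalog Catalog used for the default metric set.
#' @return Named list of \code{som_model} objects.
#' @export
fit_models <- function(cohort, metrics = NULL, rcfg = resampling_config(),
                       fcfg = fit_config(), catalog = build_metric_catalog()) {
  if (is.null(metrics)) {
    metrics <- setdiff(intersect(catalog_raw_names(catalog),
                                 colnames(cohort$metrics)), "icv")
  }
  out <- vector("list", length(metrics))
  names(out) <- metrics
  for (m in metrics) {
    rc <- rcfg
    if (!is.null(rcfg$seed)) rc$seed <- .derive_seed(rcfg$seed, m)
    out[[m]] <- fit_metric_model(cohort, m, rc, fcfg)
  }
  out
}

# deterministic 31-bit seed from a master seed and a string label
.derive_seed <- function(master, label) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
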