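#' Synthetic cohort configuration
#'
#' Generative parameters for cohorts with the statistical structure the
#' normative pipeline assumes: a large healthy-control pool with repeated
#' scans, a skewed age distribution over roughly 43-97 years, two field
#' strengths spread over four scanner labels, brain-size coupling through
#' a per-subject ICV, weak linear thickness decline and mild quadratic
#' volume decline with age, and separate between-subject and scan-rescan
#' noise.
#'
#' Thickness declines by 0.004 mm/yr by default (0.1 mm corresponds to
#' about 25 years of healthy aging); volumes follow a mild quadratic
#' trend.  Scanner labels carry small additive mean shifts so covariate
#' matching has a role to play.
#'
#' @param n_subjects Number of subjects (default 696).
#' @param age_range Age range in years (default c(42.7, 97)).
#' @param age_distribution \code{"skewed"} (Beta(3.5, 3.7), matching a
#'   mean near 69 and SD near 9.3 years) or \code{"uniform"}.
#' @param scans_per_subject_lambda Poisson mean of extra scans per subject
#'   (default 1.77, i.e. about 2.77 scans/subject).
#' @param rescan_probability Probability that an extra scan is a
#'   same-session rescan (tiny age offset) rather than a follow-up visit.
#' @param sex_freq,scanner_freq Category frequencies.
#' @param protocols Protocol labels, sampled uniformly per scan.
#' @param icv_mean,icv_sd Subject ICV distribution in mm^3.
#' @param cth_slope Thickness decline in mm/yr.
#' @param sdcth_slope Slope of the thickness-SD metrics in mm/yr.
#' @param vol_lin,vol_quad Relative linear and quadratic volume trend per
#'   year (centered at age 70).
#' @param between_sd_cth,between_sd_sdcth Between-subject SD of thickness
#'   metrics in mm.
#' @param between_frac_vol Between-subject volume SD as a fraction of the
#'   regional baseline.
#' @param rescan_sd_cth,rescan_sd_sdcth Scan-rescan SD of thickness
#'   metrics in mm.
#' @param rescan_frac_vol Scan-rescan volume SD as a fraction of baseline.
#' @param scanner_shift_cth Half-range of scanner mean shifts for
#'   thickness (mm); shifts are evenly spaced over the scanner labels.
#' @param scanner_shift_volfrac Half-range of relative scanner shifts for
#'   volumes.
#' @param sex_icv_effect Relative sex effect on ICV (males shifted up,
#'   females down by roughly this fraction); 0 gives a sex-homogeneous
#'   null cohort.
#' @param seed Integer seed (required for generation).
#' @return A list of class \code{som_synth_config}.
#' @export
synthetic_cohort_config <- function(
    n_subjects = 696L,
    age_range = c(42.7, 97.0),
    age_distribution = c("skewed", "uniform"),
    scans_per_subject_lambda = 1.77,
    rescan_probability = 0.5,
    sex_freq = c(F = 0.602, M = 0.398),
    scanner_freq = c(sonata15 = 0.008, avanto15 = 0.008,
                     trio3 = 0.492, biograph3 = 0.492),
    protocols = c("p1", "p2"),
    icv_mean = 1.5e6, icv_sd = 1.2e5,
    cth_slope = -0.004, sdcth_slope = 0.0005,
    vol_lin = -0.002, vol_quad = -2e-5,
    between_sd_cth = 0.12, between_sd_sdcth = 0.05,
    between_frac_vol = 0.08,
    rescan_sd_cth = 0.03, rescan_sd_sdcth = 0.015,
    rescan_frac_vol = 0.015,
    scanner_shift_cth = 0.02, scanner_shift_volfrac = 0.005,
    sex_icv_effect = 0.05,
    seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  stopifnot(n_subjects >= 1, diff(age_range) > 0,
            rescan_probability >= 0, rescan_probability <= 1,
            all(c(between_sd_cth, between_sd_sdcth, between_frac_vol,
                  rescan_sd_cth, rescan_sd_sdcth, rescan_frac_vol) >= 0))
  structure(as.list(environment()), class = "som_synth_config")
}

# deterministic per-metric baselines for the raw, normalizable metrics
.metric_baselines <- function(catalog) {
  ent <- catalog[catalog$normalizable, c("name", "kind", "region", "hemisphere")]
  sub_base <- c(thalamus_proper = 7500, caudate = 3800, putamen = 5300,
                pallidum = 1800, accumbens_area = 600, hippocampus = 4000,
                amygdala = 1700, ventral_dc = 4000)
  mid_base <- c(brainstem = 20000, ventricle_3rd = 1500, ventricle_4th = 1800)
  lobe_base <- c(frontal_lobe = 160000, parietal_lobe = 100000,
                 temporal_lobe = 110000, occipital_lobe = 60000,
                 cingulate_lobe = 25000, insula_lobe = 15000)
  dk <- dk_regions()
  base <- numeric(nrow(ent))
  for (i in seq_len(nrow(ent))) {
    r <- ent$region[i]; k <- ent$kind[i]
    base[i] <-
      if (r %in% names(sub_base)) sub_base[[r]]
      else if (r %in% names(mid_base)) mid_base[[r]]
      else if (r %in% names(lobe_base)) lobe_base[[r]]
      else if (r == "cortex") { if (k == "volume") 250000 else 2.5 }
      else {                               # DK cortical parcel
        j <- match(r, dk)
        if (k == "volume") 1500 + 600 * ((j - 1) %% 25)
        else if (k == "mean_cth") 2.2 + 0.6 * (j - 1) / 33
        else 0.45 + 0.1 * (j - 1) / 33
      }
  }
  ent$base <- base
  ent
}

# per-metric generative pieces given a config
.metric_gen_params <- function(cfg, catalog) {
  bl <- .metric_baselines(catalog)
  n_sc <- length(cfg$scanner_freq)
  shift_grid <- if (n_sc > 1) seq(-1, 1, length.out = n_sc) else 0
  bl$between_sd <- ifelse(bl$kind == "volume", cfg$between_frac_vol * bl$base,
                   ifelse(bl$kind == "mean_cth", cfg$between_sd_cth,
                          cfg$between_sd_sdcth))
  bl$rescan_sd <- ifelse(bl$kind == "volume", cfg$rescan_frac_vol * bl$base,
                  ifelse(bl$kind == "mean_cth", cfg$rescan_sd_cth,
                         cfg$rescan_sd_sdcth))
  list(bl = bl, shift_grid = shift_grid)
}

# noiseless trajectory of a raw metric at given ages
.metric_trajectory <- function(cfg, kind, base, age) {
  t <- age - 70
  switch(kind,
         volume = base * (1 + cfg$vol_lin * t + cfg$vol_quad * t^2),
         mean_cth = base + cfg$cth_slope * t,
         sd_cth = base + cfg$sdcth_slope * t)
}

#' Expected (noise-free) value of a raw metric under the generator
#'
#' The generating trajectory at reference ICV; useful as the ground truth
#' in parameter-recovery checks.
#'
#' @param cfg A \code{som_synth_config}.
#' @param metric Raw metric name (non-asymmetry, non-ICV).
#' @param age Ages in years.
#' @param catalog A \code{som_catalog}.
#' @return Numeric vector of expected values.
#' @export
synthetic_expected_value <- function(cfg, metric, age,
                                     catalog = build_metric_catalog()) {
  bl <- .metric_baselines(catalog)
  i <- match(metric, bl$name)
  if (is.na(i)) stop("not a generated raw metric: ", metric)
  .metric_trajectory(cfg, bl$kind[i], bl$base[i], age)
}

# core generator: scan layout is supplied so converters can reuse it
.generate_from_layout <- function(cfg, subj, ages, session, catalog) {
  n <- length(ages)
  gp <- .metric_gen_params(cfg, catalog)
  bl <- gp$bl
  n_subj <- max(subj)
  sex <- sample(names(cfg$sex_freq), n_subj, TRUE, cfg$sex_freq)
  scanner <- sample(names(cfg$scanner_freq), n_subj, TRUE, cfg$scanner_freq)
  icv_subj <- stats::rnorm(n_subj, cfg$icv_mean, cfg$icv_sd) *
    ifelse(sex == "M", 1 + 1.2 * cfg$sex_icv_effect,
           1 - 0.8 * cfg$sex_icv_effect)
  icv_subj <- pmax(icv_subj, 0.5 * cfg$icv_mean)
  protocol <- sample(cfg$protocols, n, TRUE)
  eff <- matrix(stats::rnorm(n_subj * nrow(bl)), n_subj, nrow(bl))
  eff <- sweep(eff, 2, bl$between_sd, `*`)
  icv <- icv_subj[subj]
  ratio <- icv / cfg$icv_mean
  sc_idx <- match(scanner, names(cfg$scanner_freq))[subj]
  met <- matrix(NA_real_, n, nrow(bl), dimnames = list(NULL, bl$name))
  for (j in seq_len(nrow(bl))) {
    traj <- .metric_trajectory(cfg, bl$kind[j], bl$base[j], ages)
    shift <- gp$shift_grid[sc_idx] *
      if (bl$kind[j] == "volume") cfg$scanner_shift_volfrac * bl$base[j]
      else if (bl$kind[j] == "mean_cth") cfg$scanner_shift_cth
      else 0.5 * cfg$scanner_shift_cth
    noise <- stats::rnorm(n, 0, bl$rescan_sd[j])
    pw <- if (bl$kind[j] == "volume") 1 else 1 / 3
    met[, j] <- (traj + eff[subj, j] + shift + noise) * ratio^pw
  }
  full <- .assemble_raw_matrix(met, icv, catalog)
  demo <- data.frame(
    subject_id = sprintf("sub%04d", subj),
    session_id = session,
    age = ages, sex = sex[subj], scanner = scanner[subj],
    protocol = protocol, cdr = 0, stringsAsFactors = FALSE)
  som_cohort(demo, full, provenance = "synthetic")
}

# append asymmetry indices and the ICV column to a normalizable-metric matrix
.assemble_raw_matrix <- function(met, icv, catalog) {
  asym_ent <- catalog[catalog$kind == "asymmetry", , drop = FALSE]
  asym <- matrix(NA_real_, nrow(met), nrow(asym_ent),
                 dimnames = list(NULL, asym_ent$name))
  for (j in seq_len(nrow(asym_ent))) {
    kk <- sub(paste0("^asym\\.", asym_ent$region[j], "\\."), "",
              asym_ent$name[j])
    pair <- .asym_pair(asym_ent$region[j], kk)
    asym[, j] <- suppressWarnings(asymmetry_index(met[, pair["left"]],
                                                  met[, pair["right"]]))
  }
  cbind(met, asym, icv = icv)
}

#' Generate a synthetic healthy-control cohort
#'
#' Each subject receives a baseline age from the configured distribution,
#' a Poisson number of extra scans (same-session rescans or follow-up
#' visits), a per-subject ICV, and per-metric values
#' trajectory(age) + subject effect + scanner shift + rescan noise, all
#' scaled by the subject's ICV ratio (linearly for volumes, cube-root for
#' thickness) so brain-size normalization is meaningful.  All 358 raw
#' catalog metrics are emitted, asymmetry indices computed from the
#' generated left/right values.
#'
#' @param cfg A \code{som_synth_config}.
#' @param catalog A \code{som_catalog}.
#' @return A \code{som_cohort} (cdr = 0, provenance "synthetic") with the
#'   generating config attached as attribute \code{config}.
#' @export
generate_cohort <- function(cfg = synthetic_cohort_config(),
                            catalog = build_metric_catalog()) {
  .with_seed(cfg$seed, {
    n_extra <- stats::rpois(cfg$n_subjects, cfg$scans_per_subject_lambda)
    base_age <- if (cfg$age_distribution == "skewed")
      cfg$age_range[1] + diff(cfg$age_range) *
        stats::rbeta(cfg$n_subjects, 3.5, 3.7)
    else stats::runif(cfg$n_subjects, cfg$age_range[1], cfg$age_range[2])
    subj <- integer(0); ages <- numeric(0); sess <- character(0)
    for (s in seq_len(cfg$n_subjects)) {
      a <- base_age[s]
      aa <- a
      for (k in seq_len(n_extra[s])) {
        gap <- if (stats::runif(1) < cfg$rescan_probability) 0.003
               else stats::runif(1, 0.5, 3)
        a <- min(a + gap, cfg$age_range[2])
        aa <- c(aa, a)
      }
      subj <- c(subj, rep(s, length(aa)))
      ages <- c(ages, aa)
      sess <- c(sess, sprintf("ses%02d", seq_along(aa)))
    }
    out <- .generate_from_layout(cfg, subj, ages, sess, catalog)
    attr(out, "config") <- cfg
    out
  })
}

#' Define an atrophy pattern
#'
#' @param regions Affected catalog regions (e.g. entorhinal, fusiform,
#'   precuneus, supramarginal).
#' @param effect_size Shift in units of the between-subject SD (negative
#'   for atrophy).
#' @param kinds Affected metric kinds (default \code{mean_cth}).
#' @param hemispheres Affected hemispheres (default both).
#' @return A list of class \code{som_atrophy_pattern}.
#' @export
atrophy_pattern <- function(regions, effect_size = -1,
                            kinds = "mean_cth",
                            hemispheres = c("lh", "rh")) {
  stopifnot(is.finite(effect_size))
  structure(list(regions = regions, effect_size = effect_size,
                 kinds = kinds, hemispheres = hemispheres),
            class = "som_atrophy_pattern")
}

#' Inject a regional atrophy pattern into a cohort
#'
#' Shifts the affected regional metrics by effect_size x between-subject
#' SD (negative for atrophy), leaves all other regions untouched, and
#' recomputes the asymmetry indices of affected regions.  Used to turn a
#' healthy synthetic cohort into a patient group with a known effect.
#' The between-subject SD unit combines the configured subject-effect SD
#' with the ICV-coupling component (head-size differences are
#' between-subject variation too), so an effect of -1 yields a group
#' Cohen's d close to -1 at scan level.
#'
#' @param cohort A synthetic \code{som_cohort}.
#' @param pattern A \code{som_atrophy_pattern}.
#' @param cfg The generating \code{som_synth_config} (supplies the
#'   between-subject SDs).
#' @param effect_scale Multiplier on the pattern's effect size (used for
#'   severity gradients over strata).
#' @param cdr CDR value recorded on the injected scans (default 1).
#' @param catalog A \code{som_catalog}.
#' @return The modified cohort.
#' @export
inject_pattern <- function(cohort, pattern, cfg, effect_scale = 1,
                           cdr = 1, catalog = build_metric_catalog()) {
  bl <- .metric_gen_params(cfg, catalog)$bl
  icv_rel <- cfg$icv_sd / cfg$icv_mean
  bad <- setdiff(pattern$regions, catalog$region)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "))
  for (r in pattern$regions)
    for (k in pattern$kinds) {
      for (h in pattern$hemispheres) {
        nm <- paste(h, r, k, sep = ".")
        i <- match(nm, bl$name)
        if (is.na(i)) stop("pattern names a metric not in the catalog: ", nm)
        pw <- if (bl$kind[i] == "volume") 1 else 1 / 3
        sd_unit <- sqrt(bl$between_sd[i]^2 + (bl$base[i] * pw * icv_rel)^2)
        cohort$metrics[, nm] <- cohort$metrics[, nm] +
          pattern$effect_size * effect_scale * sd_unit
      }
      anm <- paste("asym", r, k, sep = ".")
      if (anm %in% colnames(cohort$metrics)) {
        pair <- .asym_pair(r, k)
        cohort$metrics[, anm] <- suppressWarnings(
          asymmetry_index(cohort$metrics[, pair["left"]],
                          cohort$metrics[, pair["right"]]))
      }
    }
  cohort$demo$cdr <- cdr
  cohort$provenance <- paste0(cohort$provenance, "+injected")
  cohort
}

#' Generate paired longitudinal cohorts with planted decline
#'
#' One baseline and one follow-up scan per subject, the follow-up offset
#' by \code{interval_years} and carrying an additional planted decline
#' (mm per year per region, applied to the affected thickness metrics on
#' both hemispheres) on top of the generating age trend and fresh rescan
#' noise.
#'
#' @param cfg A \code{som_synth_config}.
#' @param decline Named numeric vector, region -> mm decline per year
#'   (positive = thinning).
#' @param interval_years Scan interval in years (default 2.2).
#' @param kind Affected metric kind (default \code{mean_cth}).
#' @param catalog A \code{som_catalog}.
#' @return List with \code{baseline} and \code{followup} cohorts.
#' @export
generate_converters <- function(cfg, decline, interval_years = 2.2,
                                kind = "mean_cth",
                                catalog = build_metric_catalog()) {
  stopifnot(all(is.finite(decline)), interval_years > 0)
  bad <- setdiff(names(decline), catalog$region)
  if (length(bad)) stop("unknown region(s) in decline map: ",
                        paste(bad, collapse = ", "))
  .with_seed(cfg$seed, {
    base_age <- if (cfg$age_distribution == "skewed")
      cfg$age_range[1] + diff(cfg$age_range) *
        stats::rbeta(cfg$n_subjects, 3.5, 3.7)
    else stats::runif(cfg$n_subjects, cfg$age_range[1], cfg$age_range[2])
    subj <- rep(seq_len(cfg$n_subjects), each = 2L)
    ages <- as.numeric(rbind(base_age, base_age + interval_years))
    sess <- rep(c("ses01", "ses02"), cfg$n_subjects)
    both <- .generate_from_layout(cfg, subj, ages, sess, catalog)
    fu_rows <- seq(2L, n_scans(both), by = 2L)
    for (r in names(decline))
      for (h in c("lh", "rh")) {
        nm <- paste(h, r, kind, sep = ".")
        both$metrics[fu_rows, nm] <- both$metrics[fu_rows, nm] -
          decline[[r]] * interval_years
      }
    for (r in names(decline)) {
      anm <- paste("asym", r, kind, sep = ".")
      pair <- .asym_pair(r, kind)
      both$metrics[, anm] <- suppressWarnings(
        asymmetry_index(both$metrics[, pair["left"]],
                        both$metrics[, pair["right"]]))
    }
    list(baseline = cohort_subset(both, seq(1L, n_scans(both), by = 2L)),
         followup = cohort_subset(both, fu_rows))
  })
}

#' Plant corrupted scans for cleaning experiments
#'
#' Mimics artifact-driven multi-metric outliers: on a random subset of
#' scans, a random 8-12% of the non-asymmetry raw metrics receive gross
#' offsets of +/- \code{offset_mult} column SDs; asymmetry indices of
#' affected regions are recomputed.
#'
#' @param cohort A \code{som_cohort}.
#' @param fraction Fraction of scans to corrupt (default 0.05).
#' @param metric_fraction_range Range of the per-scan corrupted-metric
#'   fraction (default c(0.08, 0.12)).
#' @param offset_mult Offset magnitude in column SDs (default 6).
#' @param seed Integer seed.
#' @param catalog A \code{som_catalog}.
#' @return List with \code{cohort} (corrupted) and \code{corrupted}
#'   (scan ids).
#' @export
corrupt_scans <- function(cohort, fraction = 0.05,
                          metric_fraction_range = c(0.08, 0.12),
                          offset_mult = 6, seed = 1L,
                          catalog = build_metric_catalog()) {
  .with_seed(seed, {
    ids <- scan_ids(cohort)
    n_bad <- max(1L, round(fraction * n_scans(cohort)))
    bad <- sort(sample(n_scans(cohort), n_bad))
    targets <- setdiff(intersect(catalog$name[catalog$kind != "asymmetry"],
                                 colnames(cohort$metrics)), "icv")
    col_sd <- apply(cohort$metrics[, targets, drop = FALSE], 2, stats::sd)
    touched_regions <- character(0)
    for (i in bad) {
      frac <- stats::runif(1, metric_fraction_range[1], metric_fraction_range[2])
      m <- max(1L, round(frac * length(targets)))
      pick <- sample(targets, m)
      sgn <- sample(c(-1, 1), m, TRUE)
      cohort$metrics[i, pick] <- cohort$metrics[i, pick] +
        sgn * offset_mult * col_sd[pick]
      touched_regions <- union(touched_regions, pick)
    }
    for (nm in touched_regions) {
      ent <- catalog[catalog$name == nm, ]
      if (!ent$hemisphere %in% c("lh", "rh")) next
      anm <- paste("asym", ent$region, ent$kind, sep = ".")
      if (!anm %in% colnames(cohort$metrics)) next
      pair <- .asym_pair(ent$region, ent$kind)
      cohort$metrics[, anm] <- suppressWarnings(
        asymmetry_index(cohort$metrics[, pair["left"]],
                        cohort$metrics[, pair["right"]]))
    }
    list(cohort = cohort, corrupted = ids[bad])
  })
}
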