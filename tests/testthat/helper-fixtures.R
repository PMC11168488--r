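# Small fixtures built in code.

the_catalog <- build_metric_catalog()

# hand-built three-scan cohort over a handful of metrics
tiny_cohort <- function() {
  demo <- data.frame(
    subject_id = c("s1", "s1", "s2"),
    session_id = c("a", "b", "a"),
    age = c(60, 61, 72.5),
    sex = c("F", "F", "M"),
    scanner = c("trio3", "trio3", "biograph3"),
    protocol = c("p1", "p1", "p2"),
    cdr = c(0, 0, 0.5),
    stringsAsFactors = FALSE)
  metrics <- cbind(
    `lh.hippocampus.volume` = c(4100.25, 4080.5, 3900.125),
    `rh.hippocampus.volume` = c(4000, 4010, 3850),
    `lh.entorhinal.mean_cth` = c(3.1, 3.05, 2.9),
    icv = c(1.45e6, 1.45e6, 1.62e6))
  som_cohort(demo, metrics, provenance = "tiny-fixture")
}

# fabricate a fitted model with known residue structure (flat trajectory)
fake_model <- function(residues, ages = rep(70, length(residues)),
                       level = 0, sigma_meas = 0, metric = "m") {
  ids <- sprintf("s%03d:a", seq_along(residues))
  structure(list(
    metric = metric, coef = level, age_center = 70, age_scale = 1,
    coef_age = level,
    degree_counts = table(factor(0, levels = 0)), d_max = 1L,
    outlier_flags = stats::setNames(rep(FALSE, length(residues)), ids),
    residues = stats::setNames(residues, ids),
    residue_ages = stats::setNames(ages, ids),
    sigma_meas = sigma_meas, trim_fraction = 0,
    p_eff = NULL, n_eff = NA_real_,
    n_fit = length(residues), seed = NULL, n_resamples = 1L),
    class = "som_model")
}

# quick synthetic cohort with reduced size
small_synth <- function(n_subjects = 30, seed = 5, ...) {
  generate_cohort(synthetic_cohort_config(n_subjects = n_subjects,
                                          seed = seed, ...),
                  the_catalog)
}
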