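test_that("z to signed log10(p) follows the Gaussian two-sided mapping", {
  mod <- fake_model(c(-1, 0, 1))      # flat trajectory at 0, sigma_pop = 1
  ref <- names(mod$residues)
  # value at the expectation
  e0 <- evaluate_metric(0, 70, mod, ref)
  expect_equal(e0$z, 0)
  expect_equal(e0$p, 1)
  expect_equal(e0$signed_log10p, 0)
  # the q = 0.01 boundary: residual = 2.5758293 sigma
  e1 <- evaluate_metric(2.5758293, 70, mod, ref)
  expect_equal(e1$p, 0.01, tolerance = 1e-6)
  expect_equal(e1$signed_log10p, 2, tolerance = 1e-5)
  # below expectation: negative sign (atrophy convention)
  e2 <- evaluate_metric(-2.5758293, 70, mod, ref)
  expect_equal(e2$signed_log10p, -2, tolerance = 1e-5)
  expect_lt(e2$residual, 0)
})

test_that("detection boundary |signed log10 p| = 2 is equivalent to p < 0.01", {
  mod <- fake_model(rnorm(200, sd = 1), sigma_meas = 0)
  ref <- names(mod$residues)
  for (v in c(-4, -2, -1, 0.5, 1.5, 3, 5)) {
    e <- evaluate_metric(v, 70, mod, ref)
    expect_equal(e$p < 0.01, abs(e$signed_log10p) > 2)
  }
})

test_that("monotonicity of z in the residual and p in |z|", {
  mod <- fake_model(c(-2, -1, 0, 1, 2))
  ref <- names(mod$residues)
  vals <- seq(-3, 3, by = 0.5)
  ev <- do.call(rbind, lapply(vals, evaluate_metric, age = 70, model = mod,
                              ref_ids = ref))
  expect_true(all(diff(ev$z) > 0))
  expect_true(all(diff(ev$p[vals >= 0]) < 0))
})

test_that("artifact probability gauges deviations against sigma_meas", {
  mod <- fake_model(c(-1, 0, 1), sigma_meas = 0.5)
  e <- evaluate_metric(1, 70, mod, names(mod$residues))
  expect_equal(e$artifact_p, 2 * pnorm(-2), tolerance = 1e-6)
  m0 <- fake_model(c(-1, 0, 1), sigma_meas = 0)
  expect_equal(evaluate_metric(1, 70, m0, names(m0$residues))$artifact_p, 1)
})

test_that("degenerate zero-spread models skip the metric with a flag", {
  mod <- fake_model(rep(0, 10), sigma_meas = 0)
  e <- evaluate_metric(1, 70, mod, names(mod$residues))
  expect_true(is.na(e$z))
  expect_true(is.na(e$signed_log10p))
})

test_that("covariate matching relaxes keys from the end", {
  demo <- data.frame(
    subject_id = sprintf("s%02d", 1:30), session_id = "a",
    age = runif(30, 50, 90), sex = "F", scanner = "trio3",
    protocol = rep(c("p1", "p2"), c(25, 5)), stringsAsFactors = FALSE)
  co <- som_cohort(demo, cbind(m = rnorm(30)))
  scan <- list(sex = "F", scanner = "trio3", protocol = "p1")
  m1 <- match_reference(scan, co, evaluation_config(min_match_size = 20))
  expect_equal(m1$level, "exact")
  expect_length(m1$scan_ids, 25L)
  # too few exact matches on protocol: protocol key dropped first
  scan2 <- list(sex = "F", scanner = "trio3", protocol = "p2")
  m2 <- match_reference(scan2, co, evaluation_config(min_match_size = 20))
  expect_equal(m2$level, "relaxed-protocol")
  expect_length(m2$scan_ids, 30L)
  # sex is never dropped: a male scan in an all-female cohort relaxes to
  # "all" and errors only below 3 references
  scan3 <- list(sex = "M", scanner = "trio3", protocol = "p1")
  m3 <- match_reference(scan3, co, evaluation_config(min_match_size = 20))
  expect_equal(m3$level, "all")
})

test_that("outlier-flagged reference scans never enter a matched subset", {
  demo <- data.frame(
    subject_id = sprintf("s%02d", 1:25), session_id = "a",
    age = runif(25, 50, 90), sex = "F", scanner = "x", protocol = "p",
    stringsAsFactors = FALSE)
  co <- som_cohort(demo, cbind(m = rnorm(25)))
  retained <- scan_ids(co)[1:20]       # scans 21..25 flagged
  m <- match_reference(list(sex = "F", scanner = "x", protocol = "p"),
                       co, evaluation_config(min_match_size = 5),
                       retained_ids = retained)
  expect_length(intersect(m$scan_ids, scan_ids(co)[21:25]), 0L)
})

test_that("matching errors when even full relaxation leaves < 3 scans", {
  demo <- data.frame(subject_id = c("a", "b"), session_id = "1",
                     age = c(60, 70), sex = "F", scanner = "x",
                     protocol = "p", stringsAsFactors = FALSE)
  co <- som_cohort(demo, cbind(m = c(1, 2)))
  expect_error(match_reference(list(sex = "M", scanner = "y", protocol = "q"),
                               co, evaluation_config()),
               "fewer than 3")
})

test_that("scan flagging uses the ceiling of the 5% rule", {
  mk_evals <- function(n_ab, n = 358) {
    data.frame(metric = sprintf("m%03d", 1:n),
               p = c(rep(0.001, n_ab), rep(0.5, n - n_ab)))
  }
  f18 <- flag_anomalous_scan(mk_evals(18), evaluation_config())
  expect_equal(f18$threshold, 18L)
  expect_true(f18$is_anomalous)
  expect_false(flag_anomalous_scan(mk_evals(17), evaluation_config())$is_anomalous)
  expect_false(flag_anomalous_scan(mk_evals(0), evaluation_config())$is_anomalous)
  # incomplete metric vectors scale the threshold
  f_small <- flag_anomalous_scan(mk_evals(2, n = 30), evaluation_config())
  expect_equal(f_small$threshold, 2L)
  expect_true(f_small$is_anomalous)
  expect_error(flag_anomalous_scan(data.frame(metric = character(),
                                              p = numeric())),
               "no evaluations")
})

test_that("evaluate_scan collects per-metric errors without aborting", {
  co <- small_synth(n_subjects = 25, seed = 14)
  rc <- resampling_config(n_resamples = 8, seed = 5)
  mets <- c("lh.lingual.mean_cth", "rh.putamen.volume")
  mods <- fit_models(co, mets, rc)
  # a degenerate model that will error during evaluation
  mods$broken <- fake_model(rep(0, 5), metric = "rh.putamen.volume")
  mods$broken$residues <- mods$broken$residues[0]
  ev <- evaluate_scan(co$demo[1, , drop = FALSE], co$metrics[1, ], mods, co)
  expect_equal(nrow(ev), 3L)
  expect_true(all(c("residual", "z", "p", "signed_log10p") %in% names(ev)))
  expect_true(all(is.finite(ev$signed_log10p[1:2])))
})

test_that("significance maps cover the 68 DK regions in catalog order", {
  ev <- data.frame(metric = catalog_dk_names(the_catalog, "mean_cth"),
                   signed_log10p = seq_len(68) / 10)
  map <- significance_map(ev, the_catalog, "mean_cth", normalized = FALSE)
  expect_equal(nrow(map), 68L)
  expect_setequal(map$region, dk_regions())
  expect_equal(sort(unique(map$hemisphere)), c("lh", "rh"))
  expect_false(anyNA(map$signed_log10p))
})
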