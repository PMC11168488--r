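test_that("degree cap follows the odd-number rule", {
  expect_equal(max_poly_degree(1927), 11L)
  expect_equal(max_poly_degree(10), 1L)
  # ln(27.1) ~ 3.2995 -> floor(4.2995) = 4 -> 2*4 - 1
  expect_equal(max_poly_degree(271), 7L)
  expect_warning(d <- max_poly_degree(5), "n < 10")
  expect_equal(d, 1L)
  for (n in c(10, 27, 100, 500, 1927, 10000))
    expect_true(max_poly_degree(n) %% 2 == 1)
})

test_that("Tukey fences flag only genuine outliers", {
  expect_equal(iqr_outlier_mask(rep(3, 10)), rep(FALSE, 10))
  # {1..9, 100}: Q1 = 3.25, Q3 = 7.75 (type 7), upper fence 14.5
  expect_equal(which(iqr_outlier_mask(c(1:9, 100))), 10L)
  expect_equal(sum(iqr_outlier_mask(1:9)), 0L)
  expect_warning(m <- iqr_outlier_mask(c(1, 2, 3)), "fewer than 4")
  expect_equal(m, rep(FALSE, 3))
})

test_that("uniform age resampling leaves uniform distributions intact", {
  ages <- rep(seq(5, 95, by = 10), each = 4)     # 10 bins, 4 each
  idx <- uniform_age_resample(ages, resampling_config(seed = 1))
  expect_equal(sort(idx), seq_along(ages))       # a permutation of all
})

test_that("uniform age resampling draws n_min per non-empty bin", {
  ages <- c(rep(1, 5), rep(2, 10))
  idx <- uniform_age_resample(ages, resampling_config(n_bins = 2, seed = 3))
  expect_length(idx, 10L)
  expect_equal(sum(idx <= 5), 5L)
  expect_equal(sum(idx > 5), 5L)
  expect_false(anyDuplicated(idx) > 0)           # without replacement
})

test_that("resampling is deterministic under a seed and handles ties", {
  ages <- rbeta(80, 3.5, 3.7) * 50 + 45
  cfg <- resampling_config(seed = 11)
  expect_identical(uniform_age_resample(ages, cfg),
                   uniform_age_resample(ages, cfg))
  expect_equal(uniform_age_resample(rep(63, 7), cfg), 1:7)  # single bin
})

test_that("degree selection stops at the right complexity", {
  ages <- seq(50, 90, length.out = 60)
  fit0 <- select_poly_degree(ages, rep(4.2, 60))
  expect_equal(fit0$degree, 0L)
  expect_equal(fit0$coefficients, 4.2, tolerance = 1e-9)
  fit1 <- select_poly_degree(ages, 2 + 3 * ages)
  expect_equal(fit1$degree, 1L)
  expect_equal(fit1$coefficients, c(2, 3), tolerance = 1e-9)
  # cubic signal with a cap of 1 returns the cap
  y3 <- 0.001 * (ages - 70)^3 + rnorm(60, sd = 1e-4)
  fitc <- select_poly_degree(ages, y3, d_max = 1L)
  expect_equal(fitc$degree, 1L)
  # duplicate single age falls back to degree 0
  fitd <- select_poly_degree(rep(60, 20), rnorm(20))
  expect_equal(fitd$degree, 0L)
})

test_that("degree selection is calibrated under the null", {
  # on independent null datasets the F-test should step up at ~alpha rate
  set.seed(2024)
  n_up <- 0L
  for (r in 1:40) {
    ages <- runif(80, 50, 90)
    fit <- select_poly_degree(ages, rnorm(80), d_max = 5L)
    n_up <- n_up + (fit$degree > 0L)
  }
  expect_lte(n_up, qbinom(0.995, 40, 0.05))
})

test_that("measurement uncertainty pools close-in-age rescans", {
  demo <- data.frame(subject_id = c("a", "a", "b", "b"),
                     session_id = c("1", "2", "1", "2"),
                     age = c(60, 60.01, 70, 70.01),
                     sex = "F", scanner = "x", protocol = "p",
                     stringsAsFactors = FALSE)
  m <- cbind(v = c(10, 11, 20, 21))               # two pairs, diffs {1, 1}
  co <- som_cohort(demo, m)
  expect_equal(measurement_uncertainty(co, "v"), sqrt(0.5), tolerance = 1e-12)
  m2 <- cbind(v = c(10, 10, 20, 20))
  expect_equal(measurement_uncertainty(som_cohort(demo, m2), "v"), 0)
  demo3 <- demo; demo3$subject_id <- c("a", "b", "c", "d")
  expect_warning(
    u <- measurement_uncertainty(som_cohort(demo3, m), "v"),
    "no qualifying")
  expect_equal(u, 0)
  # pairs outside the 10% age window are excluded
  demo4 <- demo; demo4$age <- c(50, 60, 70, 70.01)
  expect_equal(measurement_uncertainty(som_cohort(demo4, m), "v"),
               sqrt(1 / 2))
})

test_that("age-local residue statistics reduce to hand arithmetic", {
  mod <- fake_model(c(-1, 1))
  loc <- local_population_sd(mod, 70, min_local_n = 2L)
  expect_equal(loc$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(loc$mean, 0)
  mod0 <- fake_model(rep(0, 12))
  expect_equal(local_population_sd(mod0, 70, min_local_n = 2L)$sd, 0)
  # query far outside the reference ages flags extrapolation
  modf <- fake_model(rnorm(20), ages = runif(20, 60, 80))
  loc2 <- local_population_sd(modf, 20, min_local_n = 5L)
  expect_true(loc2$extrapolated)
})

test_that("prediction interval combines population and measurement SDs", {
  mod <- fake_model(c(-1, 0, 1), level = 10)   # sample SD exactly 1
  pi_ <- prediction_interval(mod, 70, level = 0.95)
  expect_equal(as.numeric(pi_), c(10 - 1.959964, 10 + 1.959964),
               tolerance = 1e-4)
  # degenerate: no spread at all
  mod0 <- fake_model(rep(0, 5), level = 3)
  expect_equal(as.numeric(prediction_interval(mod0, 70)), c(3, 3))
  # width is monotone in sigma_meas
  widths <- sapply(c(0, 0.5, 1, 2), function(sm) {
    m <- fake_model(c(-1, 0, 1), sigma_meas = sm)
    diff(prediction_interval(m, 70))
  })
  expect_true(all(diff(widths) >= 0))
})

test_that("fit recovers a linear decline within sampling error", {
  set.seed(77)
  n <- 500
  ages <- runif(n, 50, 90)
  slope <- -0.005; noise <- 0.05
  demo <- data.frame(subject_id = sprintf("s%03d", 1:n),
                     session_id = "a", age = ages, sex = "F",
                     scanner = "x", protocol = "p", stringsAsFactors = FALSE)
  y <- 2.5 + slope * (ages - 70) + rnorm(n, sd = noise)
  co <- som_cohort(demo, cbind(cth = y))
  mod <- fit_metric_model(co, "cth", resampling_config(n_resamples = 30,
                                                       seed = 7))
  est_slope <- (predict_trajectory(mod, 75) - predict_trajectory(mod, 65)) / 10
  se <- noise / (sd(ages) * sqrt(n))
  expect_lt(abs(est_slope - slope), 3 * se)
  # trajectory level at the center
  expect_lt(abs(predict_trajectory(mod, 70) - 2.5), 3 * noise / sqrt(n) * 3)
})

test_that("constant metrics select degree 0 in almost all resamples", {
  set.seed(31)
  n <- 200
  demo <- data.frame(subject_id = sprintf("s%03d", 1:n), session_id = "a",
                     age = runif(n, 50, 90), sex = "F", scanner = "x",
                     protocol = "p", stringsAsFactors = FALSE)
  co <- som_cohort(demo, cbind(m = rnorm(n, 10, 1)))
  mod <- fit_metric_model(co, "m", resampling_config(n_resamples = 100,
                                                     seed = 12))
  expect_gte(mod$degree_counts[["0"]], 90)
  # every selected degree honors the cap
  expect_true(all(as.integer(names(mod$degree_counts))[mod$degree_counts > 0]
                  <= mod$d_max))
})

test_that("fits are bit-reproducible under a fixed seed", {
  co <- small_synth(n_subjects = 25, seed = 4)
  rc <- resampling_config(n_resamples = 10, seed = 99)
  m1 <- fit_metric_model(co, "lh.fusiform.mean_cth", rc)
  m2 <- fit_metric_model(co, "lh.fusiform.mean_cth", rc)
  expect_identical(m1$coef, m2$coef)
  expect_identical(m1$residues, m2$residues)
})

test_that("retained residues of a null fit center on zero", {
  co <- small_synth(n_subjects = 60, seed = 21)
  mod <- fit_metric_model(co, "lh.cuneus.mean_cth",
                          resampling_config(n_resamples = 15, seed = 2))
  r <- mod$residues
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
  # flagged scans appear in neither residues nor their ages
  flagged <- names(which(mod$outlier_flags))
  expect_length(intersect(flagged, names(mod$residues)), 0L)
})

test_that("model persistence round-trips through JSON", {
  co <- small_synth(n_subjects = 25, seed = 4)
  rc <- resampling_config(n_resamples = 8, seed = 123)
  mods <- fit_models(co, c("lh.insula.mean_cth", "rh.caudate.volume"), rc)
  path <- tempfile(fileext = ".json")
  write_models(mods, path)
  back <- read_models(path)
  expect_setequal(names(back), names(mods))
  ages <- c(55, 65, 75, 85)
  for (nm in names(mods)) {
    expect_equal(predict_trajectory(back[[nm]], ages),
                 predict_trajectory(mods[[nm]], ages), tolerance = 1e-9)
    expect_equal(back[[nm]]$sigma_meas, mods[[nm]]$sigma_meas,
                 tolerance = 1e-9)
  }
})
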