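test_that("normalized L2-distance hits its three anchor values", {
  a <- c(0.5, -1, 2, 0.3, -0.7)
  expect_equal(normalized_l2(a, a), 0)
  expect_equal(normalized_l2(a, -a), 2)
  # disjoint support, equal norms: orthogonal
  x <- c(1, 1, 0, 0); y <- c(0, 0, 1, 1)
  expect_equal(normalized_l2(x, y), sqrt(2), tolerance = 1e-12)
  expect_error(normalized_l2(a, rep(0, 5)), "zero map")
})

test_that("normalized L2 is symmetric, scale-invariant, and triangular", {
  set.seed(9)
  for (r in 1:20) {
    a <- rnorm(10); b <- rnorm(10); c_ <- rnorm(10)
    expect_equal(normalized_l2(a, b), normalized_l2(b, a), tolerance = 1e-12)
    expect_equal(normalized_l2(3.7 * a, b), normalized_l2(a, b),
                 tolerance = 1e-12)
    expect_lte(normalized_l2(a, c_),
               normalized_l2(a, b) + normalized_l2(b, c_) + 1e-12)
    expect_true(normalized_l2(a, b) >= 0 && normalized_l2(a, b) <= 2)
  }
})

test_that("Cohen's d map reduces to the pooled-SD formula", {
  A <- cbind(r1 = c(-1, 0, 1), r2 = c(5, 5, 5))
  B <- cbind(r1 = c(0, 1, 2), r2 = c(5, 5, 5))
  ct <- cohens_d_map(A, B)
  expect_equal(unname(ct$d["r1"]), -1)          # means 0 vs 1, pooled SD 1
  expect_true(is.na(ct$d["r2"]))                # zero pooled SD flagged
  expect_equal(ct$undefined, "r2")
  same <- cbind(r = rnorm(10))
  expect_equal(unname(cohens_d_map(same, same)$d), 0)
})

test_that("ROC equals the brute-force pairwise win fraction", {
  brute_auc <- function(scores, labels) {
    cs <- scores[labels]; ct <- scores[!labels]
    mean(outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  r0 <- roc_from_scores(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r0$auc, 0.75)
  expect_equal(r0$auc, brute_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)))
  r1 <- roc_from_scores(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1.0)
  set.seed(15)
  for (rep_ in 1:20) {
    s <- sample(0:5, 30, replace = TRUE)         # plenty of ties
    l <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(l) || all(l)) next
    expect_equal(roc_from_scores(s, l)$auc, brute_auc(s, l),
                 tolerance = 1e-12)
  }
  expect_error(roc_from_scores(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC agrees with an independent implementation and the null band", {
  skip_if_not_installed("pROC")
  set.seed(22)
  s <- rnorm(200); l <- c(rep(TRUE, 80), rep(FALSE, 120))
  s[l] <- s[l] + 0.8
  ours <- roc_from_scores(s, l)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-9)
  # label-independent scores give AUC near 1/2
  set.seed(23)
  s0 <- rnorm(2000); l0 <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(roc_from_scores(s0, l0)$auc - 0.5), 0.04)
})

test_that("ROC curve is monotone and the best point is closest to (0,1)", {
  set.seed(3)
  s <- rnorm(50); l <- rep(c(TRUE, FALSE), 25); s[l] <- s[l] + 1
  r <- roc_from_scores(s, l)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  d <- sqrt(r$fpr^2 + (1 - r$tpr)^2)
  expect_equal(sqrt(r$best_point[["fpr"]]^2 + (1 - r$best_point[["tpr"]])^2),
               min(d))
})

test_that("percentage maps count threshold crossings per direction", {
  mk <- function(v) data.frame(region = c("entorhinal", "cuneus"),
                               hemisphere = "lh", signed_log10p = v)
  maps <- c(lapply(1:3, function(i) mk(c(-3, 0))),
            lapply(1:7, function(i) mk(c(0, 0))))
  dec <- anomaly_percentage_map(maps, "decrease")
  inc <- anomaly_percentage_map(maps, "increase")
  expect_equal(unname(dec["lh.entorhinal"]), 30)
  expect_equal(unname(dec["lh.cuneus"]), 0)
  expect_equal(unname(inc), c(0, 0))
  # boundary is exclusive at exactly -2
  m2 <- anomaly_percentage_map(list(mk(c(-2, -2.0001))), "decrease")
  expect_equal(unname(m2), c(0, 100))
  expect_equal(unname(anomaly_percentage_map(lapply(1:4, function(i) mk(c(0, 0))),
                                             "decrease")), c(0, 0))
})

test_that("template averaging and map stacking are order-invariant", {
  mk <- function(v) data.frame(region = c("a", "b"), hemisphere = "lh",
                               signed_log10p = v)
  maps <- list(mk(c(1, 2)), mk(c(3, 4)), mk(c(5, 0)))
  avg <- average_map(maps)
  expect_equal(unname(avg), c(3, 2))
  expect_equal(average_map(rev(maps)), avg)
})

test_that("stratification partitions records and preserves counts", {
  df <- data.frame(scan = 1:5, cdr = c(0.5, 0.5, 0.5, 1, 1))
  st <- stratify(df, "cdr")
  expect_equal(sort(names(st)), c("0.5", "1"))
  expect_equal(unname(sapply(st, nrow)), c(3L, 2L))
  expect_equal(sum(sapply(st, nrow)), nrow(df))
  dfna <- data.frame(scan = 1:4, cdr = c(0.5, NA, 1, NA))
  expect_equal(sum(sapply(stratify(dfna, "cdr"), nrow)), 4L)
  expect_equal(sum(sapply(stratify(dfna, "cdr", drop_na = TRUE), nrow)), 2L)
})

test_that("longitudinal change maps use follow-up minus baseline", {
  cv <- generate_converters(
    synthetic_cohort_config(n_subjects = 25, seed = 44),
    decline = c(entorhinal = 0), interval_years = 2)
  expect_true(all(cv$followup$demo$age > cv$baseline$demo$age))
  # zero decline: mean change is the aging trend plus noise, near zero
  map0 <- longitudinal_change_map(cv$baseline, cv$followup, the_catalog,
                                  normalized = FALSE)
  expect_equal(nrow(map0), 68L)
  expect_lt(max(abs(map0$mean_change)), 0.05)
  # planted thinning shows up with a negative sign
  cv2 <- generate_converters(
    synthetic_cohort_config(n_subjects = 40, seed = 45),
    decline = c(entorhinal = 0.05), interval_years = 2)
  map2 <- longitudinal_change_map(cv2$baseline, cv2$followup, the_catalog,
                                  normalized = FALSE)
  ent <- map2$mean_change[map2$region == "entorhinal"]
  expect_true(all(ent < 0))
  se <- 0.03 * sqrt(2) / sqrt(40)
  expect_true(all(abs(ent - (-0.1 - 0.004 * 2)) < 3 * se + 0.02))
  # mismatched subjects abort
  bad <- cv$followup
  bad$demo$subject_id <- rev(bad$demo$subject_id)
  expect_error(longitudinal_change_map(cv$baseline, bad, the_catalog),
               "different subjects")
})

test_that("interval change rate reports percent shrinkage over the interval", {
  r <- interval_change_rate(4.0, 3.5, 2.2)
  expect_equal(as.numeric(r), 12.5)
  expect_equal(attr(r, "years"), 2.2)
  expect_equal(as.numeric(interval_change_rate(3, 3, 1)), 0)
  expect_lt(interval_change_rate(3, 3.3, 1), 0)   # growth is negative
  expect_error(interval_change_rate(0, 1, 1), "positive")
  expect_error(interval_change_rate(1, 1, 0), "positive")
})

test_that("rank-sum utility reproduces the Wilcoxon test", {
  set.seed(8)
  x <- rnorm(12); y <- rnorm(12) + 1
  ours <- rank_sum_test(x, y)
  expect_s3_class(ours, "htest")
  expect_equal(ours$p.value, stats::wilcox.test(x, y)$p.value)
})
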