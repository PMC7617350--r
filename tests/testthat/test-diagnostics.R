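test_that("exact binomial intervals match closed-form degenerate cases", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  # analytic bound: for x = n the lower limit solves p^n = alpha/2
  for (n in c(5, 16, 29)) {
    expect_equal(clopper_pearson(n, n)[["lower"]], 0.025^(1 / n),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson(5, 4), "x <= n")
  expect_error(clopper_pearson(0, 0), "n >= 1")
  # agreement with the exact interval of stats::binom.test
  set.seed(60)
  for (i in 1:25) {
    n <- sample(1:60, 1)
    x <- sample(0:n, 1)
    expect_equal(unname(clopper_pearson(x, n)),
                 binom.test(x, n)$conf.int[1:2], tolerance = 1e-9)
  }
})

test_that("interval bounds are nondecreasing in the success count", {
  for (n in c(10, 41)) {
    b <- t(vapply(0:n, function(x) clopper_pearson(x, n), numeric(2)))
    expect_true(all(diff(b[, 1]) >= 0))
    expect_true(all(diff(b[, 2]) >= 0))
  }
})

test_that("sensitivity and specificity carry exact intervals and drop exclusions", {
  truth <- c(rep(TRUE, 20), rep(FALSE, 41))
  pred <- c(rep(TRUE, 16), rep(FALSE, 4), rep(FALSE, 40), TRUE)
  est <- sens_spec(pred, truth)
  sens <- est[est$metric == "sensitivity", ]
  expect_equal(sens$x, 16); expect_equal(sens$n, 20)
  expect_equal(round(100 * c(sens$ci_lower, sens$ci_upper), 1), c(56.3, 94.3))
  spec <- est[est$metric == "specificity", ]
  expect_equal(round(100 * spec$point, 1), 97.6)
  # perfect classifier
  est <- sens_spec(truth, truth)
  expect_true(all(est$point == 1))
  expect_equal(est$ci_upper, c(1, 1))
  # excluded predictions are dropped and counted
  est <- sens_spec(c(TRUE, NA, FALSE, NA), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(attr(est, "n_excluded"), 2)
  expect_equal(est$n, c(1, 1))
  # a side without samples is undefined, not an error
  est <- sens_spec(c(TRUE, FALSE), c(TRUE, TRUE))
  expect_true(is.na(est$point[est$metric == "specificity"]))
})

test_that("the empirical ROC matches pair-counting and pROC", {
  r <- roc_curve(1:6, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1.0)
  expect_true(all(c(0, 1) %in% r$points$fpr))
  set.seed(61)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n0), 1))  # ties likely
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    expect_equal(roc_curve(scores, labels)$auc, brute_force_auc(scores, labels))
  }
  scores <- c(rexp(15), rexp(15) + 0.3)
  labels <- rep(c(FALSE, TRUE), each = 15)
  expect_equal(roc_curve(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
  # labels independent of scores: AUC near 1/2
  n1 <- n0 <- 300
  scores <- rnorm(n1 + n0)
  labels <- rep(c(TRUE, FALSE), c(n1, n0))
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_curve(scores, labels)$auc - 0.5), 3 * se)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("the paired-difference t-interval matches hand computation", {
  ci <- paired_difference_ci(rep(0, 5))
  expect_equal(c(ci$lower, ci$upper), c(0, 0))
  ci <- paired_difference_ci(c(1, 0))
  expect_equal(ci$delta, 0.5)
  expect_equal(ci$sd, 0.70711, tolerance = 1e-4)
  expect_equal(ci$t_crit, 12.7062, tolerance = 1e-4)
  expect_equal(c(ci$lower, ci$upper), c(-5.853, 6.853), tolerance = 1e-3)
  # width scales as t-quantile over sqrt(N) for fixed dispersion
  d4 <- c(-1, 1, -1, 1)
  d16 <- rep(c(-1, 1), 8) * sd(d4) / sd(rep(c(-1, 1), 8))
  w4 <- with(paired_difference_ci(d4), upper - lower)
  w16 <- with(paired_difference_ci(d16), upper - lower)
  expect_equal(w4 / w16, qt(0.975, 3) / qt(0.975, 15) * 2, tolerance = 1e-9)
  # SE interpretation switch skips the sqrt(N) division
  ci_se <- paired_difference_ci(c(1, 0), sd_is_se = TRUE)
  expect_equal(ci_se$upper - ci_se$delta, ci$t_crit * ci$sd)
  expect_error(paired_difference_ci(1), "at least 2")
})

test_that("paired concordance splits by signal level and flags degeneracy", {
  x <- c(2, 3, 4, 5, 0.1, 0.3, 0.5, 0.7)
  pc <- paired_concordance(x, x)
  expect_equal(pc$r_above, 1.0)
  expect_equal(pc$r_below, 1.0)
  expect_equal(pc$n_discordant, 0)
  pc <- paired_concordance(x, rep(2, 8))
  expect_true(is.na(pc$r_above))
  pc <- paired_concordance(c(2, 3), c(2, 3))  # < 3 pairs in stratum
  expect_true(is.na(pc$r_above))
})

test_that("stratified evaluation is consistent across complementary strata", {
  panel_regions <- c("R1", "R2")
  set.seed(62)
  n <- 24
  subjects <- data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("control_healthy", "cancer"), each = n / 2),
    grade = c(rep("unknown", n / 2), sample(c("1", "2", "3"), n / 2, replace = TRUE)),
    stage = "unknown", brca_status = "unknown",
    sample_date = as.Date("2020-01-01"),
    days_to_diagnosis = c(rep(NA, n / 2), sample(100:800, n / 2)))
  scores <- data.frame(
    sample_id = subjects$subject_id,
    wid_cfoc_positive = runif(n) < 0.4,
    ca125_status = sample(c("positive", "negative", "excluded"), n,
                          replace = TRUE, prob = c(0.3, 0.6, 0.1)))
  scores$combined <- combined_score(scores$wid_cfoc_positive, scores$ca125_status)
  contamination <- stratify_by_median(
    data.frame(sample_id = subjects$subject_id, ratio = rlnorm(n)))
  strata <- list(all = list(),
                 lower = list(contamination = "lower"),
                 higher = list(contamination = "higher"),
                 empty = list(brca = "BRCA1"))
  est <- evaluate_strata(subjects, scores, contamination, strata)
  for (metric in c("sensitivity", "specificity")) {
    for (mk in c("wid_cfoc", "ca125", "combined")) {
      pick <- function(s) est[est$stratum == s & est$marker == mk &
                                est$metric == metric, ]
      expect_equal(pick("lower")$n + pick("higher")$n, pick("all")$n)
      expect_equal(pick("lower")$x + pick("higher")$x, pick("all")$x)
    }
  }
  empty <- est[est$stratum == "empty", ]
  expect_true(all(is.na(empty$point)))
  expect_error(evaluate_strata(subjects, scores, contamination,
                               list(bad = list(nonsense = 1))), "unknown stratum")
})

test_that("stage detection tables partition the cancer cases", {
  subjects <- data.frame(subject_id = c("a", "b", "c", "d"),
                         group = c("cancer", "cancer", "cancer", "control_healthy"),
                         grade = "3", stage = c("I", "III", "III", "unknown"),
                         brca_status = "unknown",
                         sample_date = as.Date("2020-01-01"))
  scores <- data.frame(sample_id = c("a", "b", "c", "d"),
                       wid_cfoc_positive = c(FALSE, TRUE, TRUE, FALSE),
                       ca125_status = "negative",
                       combined = c("negative", "positive", "positive", "negative"))
  tab <- stage_detection_table(subjects, scores, "wid_cfoc")
  expect_equal(sum(tab$n_total), 3)
  expect_equal(tab$n_detected[tab$stage == "III"], 2)
  expect_equal(tab$n_detected[tab$stage == "I"], 0)
})
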