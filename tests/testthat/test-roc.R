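test_that("empirical ROC handles separation, ties and uninformative scores", {
  perfect <- roc_curve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$fpr[1], 0)
  expect_equal(perfect$tpr[1], 0)
  expect_equal(utils::tail(perfect$fpr, 1), 1)
  expect_equal(utils::tail(perfect$tpr, 1), 1)

  flat <- roc_curve(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(flat$auc, 0.5)

  tied <- roc_curve(c(1, 2, 2, 3), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(tied$auc, 0.875)  # 4 pairs: 3 wins + 1 half-credit tie

  expect_error(roc_curve(1:4, c(TRUE, TRUE, TRUE, TRUE)),
               "single class")
  expect_error(roc_curve(c(1, NA, 3), c(TRUE, FALSE, TRUE)), "finite")
})

test_that("ROC points are monotone and trapezoid area equals the pairwise oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    expect_true(all(diff(r$fpr) >= 0))
    expect_true(all(diff(r$tpr) >= 0))
    oracle <- brute_auc(scores, labels)
    expect_equal(r$auc, oracle, tolerance = 1e-12)
    expect_equal(auc_mann_whitney(scores, labels), oracle,
                 tolerance = 1e-12)
  }
})

test_that("AUC is rank-invariant and complements under label/score inversion", {
  set.seed(5)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4) == 1
  a <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(2 * scores + 7, labels)$auc, a)
  expect_equal(roc_curve(exp(scores), labels)$auc, a)
  expect_equal(roc_curve(-scores, labels)$auc, 1 - a)
  expect_equal(auc_mann_whitney(scores, !labels), 1 - a)
})

test_that("DeLong AUC, variance and CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    labels <- c(rep(TRUE, 8), rep(FALSE, 8),
                rbinom(n - 16, 1, 0.5) == 1)
    scores <- rnorm(n) + labels
    ours <- auc_delong_ci(scores, labels)
    ref <- pROC::roc(response = labels, predictor = scores,
                     direction = "<", quiet = TRUE)
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)),
                 tolerance = 1e-12)
    ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(ours$ci[1], ref_ci[1], tolerance = 1e-9)
    expect_equal(ours$ci[2], ref_ci[3], tolerance = 1e-9)
  }
})

test_that("DeLong variance is nonnegative and zero under perfect separation", {
  sep <- auc_delong_ci(c(rnorm(20), rnorm(20) + 100),
                       rep(c(FALSE, TRUE), each = 20))
  expect_equal(sep$auc, 1)
  expect_equal(sep$se, 0)
  set.seed(23)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    labels <- c(TRUE, TRUE, FALSE, FALSE,
                rbinom(n - 4, 1, 0.5) == 1)
    expect_gte(auc_delong_ci(rnorm(n), labels)$se, 0)
  }
  expect_error(auc_delong_ci(1:3, c(TRUE, FALSE, FALSE)),
               "at least 2")
})

test_that("binormal simulation recovers the closed-form AUC and CLT CI shrinkage", {
  set.seed(31)
  delta <- 1.19
  truth <- pnorm(delta / sqrt(2))  # ~0.8
  n <- 10000
  scores <- c(rnorm(n), rnorm(n) + delta)
  labels <- rep(c(FALSE, TRUE), each = n)
  est <- auc_delong_ci(scores, labels)
  expect_lt(abs(est$auc - truth), 3 * est$se)
  # width shrinks roughly as 1/sqrt(n) when n quadruples
  small <- auc_delong_ci(scores[c(1:2500, n + 1:2500)],
                         labels[c(1:2500, n + 1:2500)])
  expect_equal(diff(small$ci) / diff(est$ci), 2, tolerance = 0.35)
})

test_that("paired DeLong comparison: null cases, rank invariance, power, pROC agreement", {
  set.seed(41)
  labels <- rbinom(100, 1, 0.5) == 1
  a <- rnorm(100) + labels
  same <- compare_auc_delong(a, a, labels)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  shifted <- compare_auc_delong(a, 2 * a + 7, labels)
  expect_equal(shifted$difference, 0)
  expect_equal(shifted$p, 1)

  # informative vs pure noise at n = 400: the difference is detectable
  set.seed(43)
  lab400 <- rep(c(FALSE, TRUE), each = 200)
  informative <- rnorm(400) + 1.19 * lab400
  noise <- rnorm(400)
  cmp <- compare_auc_delong(informative, noise, lab400)
  expect_lt(cmp$p, 0.05)
  expect_equal(sign(cmp$z), sign(cmp$difference))

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(
    pROC::roc(lab400, informative, direction = "<", quiet = TRUE),
    pROC::roc(lab400, noise, direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-9)
  expect_equal(unname(cmp$z), unname(ref$statistic), tolerance = 1e-9)
})

test_that("Youden cutoff equals the exhaustive scan oracle", {
  sep <- roc_curve(c(1, 2, 3, 5, 6, 7),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  opt <- youden_optimal_cutoff(sep)
  expect_equal(opt$youden, 1)
  expect_gte(opt$cutoff, 3)
  expect_lt(opt$cutoff, 5)

  flat <- roc_curve(rep(1, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(youden_optimal_cutoff(flat)$youden, 0)

  set.seed(59)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    scores <- sample(round(runif(n, 0, 4), 1))
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    got <- youden_optimal_cutoff(r)
    want <- brute_youden(scores, labels)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden, want$youden, tolerance = 1e-12)
  }
})

test_that("confusion counts use strict > positivity", {
  counts <- confusion_at_cutoff(c(0.5, 0.9, 1.0, 2.0),
                                c(FALSE, FALSE, TRUE, TRUE), 0.9)
  expect_equal(counts, c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))
  high <- confusion_at_cutoff(1:4, c(TRUE, TRUE, FALSE, FALSE), 10)
  expect_equal(high[["tp"]], 0L)
  expect_equal(high[["fp"]], 0L)
  all_pos <- confusion_at_cutoff(2:5, rep(TRUE, 4), 1)
  expect_equal(all_pos[["fn"]], 0L)
  expect_equal(all_pos[["fp"]], 0L)
})

test_that("positivity rate follows the strict-> convention", {
  expect_equal(positivity_rate(1:5, 0), 1)
  expect_equal(positivity_rate(1:5, 5), 0)
  expect_equal(positivity_rate(1:5, 2.5), 0.6)
  expect_error(positivity_rate(numeric(0), 1), "empty")
})

test_that("diagnostic summary identities hold exactly on counts", {
  set.seed(61)
  for (i in 1:100) {
    counts <- c(tp = sample(1:60, 1), fp = sample(1:60, 1),
                tn = sample(1:60, 1), fn = sample(1:60, 1))
    ds <- diagnostic_summary(counts)
    expect_equal(ds$sensitivity, counts[["tp"]] /
                   (counts[["tp"]] + counts[["fn"]]))
    expect_equal(ds$specificity, counts[["tn"]] /
                   (counts[["tn"]] + counts[["fp"]]))
    expect_equal(ds$youden, ds$sensitivity + ds$specificity - 1)
    expect_equal(ds$plr, ds$sensitivity / (1 - ds$specificity))
    expect_equal(ds$nlr, (1 - ds$sensitivity) / ds$specificity)
    # Bayes PPV/NPV at empirical prevalence equals the count ratios
    expect_equal(ds$ppv, counts[["tp"]] /
                   (counts[["tp"]] + counts[["fp"]]),
                 tolerance = 1e-12)
    expect_equal(ds$npv, counts[["tn"]] /
                   (counts[["tn"]] + counts[["fn"]]),
                 tolerance = 1e-12)
    # Clopper-Pearson bounds bracket the point estimates
    expect_true(ds$sensitivity_ci[1] <= ds$sensitivity &&
                  ds$sensitivity <= ds$sensitivity_ci[2])
  }
})

test_that("degenerate ratios are flagged as infinite, perfect test is perfect", {
  perfect <- diagnostic_summary(c(tp = 10, fp = 0, tn = 10, fn = 0))
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_identical(perfect$plr, Inf)
  expect_equal(perfect$nlr, 0)
  ideal <- diagnostic_summary(sensitivity = 1, specificity = 1,
                              prevalence = 0.3)
  expect_equal(ideal$ppv, 1)
  expect_equal(ideal$npv, 1)
  expect_error(diagnostic_summary(c(tp = 0, fp = 5, tn = 5, fn = 0)),
               "disease class")
  expect_error(diagnostic_summary(sensitivity = 0.8,
                                  specificity = 0.7), "prevalence")
})
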