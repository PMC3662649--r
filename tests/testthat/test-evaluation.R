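test_that("confusion metrics treat poor prognosis as the positive class", {
  truth <- rep(c("poor", "good"), c(4, 6))
  expect_equal(confusion_metrics(truth, truth),
               c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_equal(confusion_metrics(rep("poor", 10), truth),
               c(sensitivity = 1, specificity = 0, accuracy = 0.4))

  # TP = 9, FN = 1, TN = 5, FP = 5
  truth2 <- rep(c("poor", "good"), each = 10)
  pred2 <- c(rep("poor", 9), "good", rep("poor", 5), rep("good", 5))
  expect_equal(confusion_metrics(pred2, truth2),
               c(sensitivity = 0.9, specificity = 0.5, accuracy = 0.7))

  expect_error(
    confusion_metrics(c(a = "poor", b = "good"), c(a = "poor", c = "good")),
    class = "ktsp_alignment_error")

  # accuracy is the class-size-weighted mix of sensitivity and specificity
  for (seed in 1:5) {
    n_p <- 7; n_g <- 12
    truth3 <- rep(c("poor", "good"), c(n_p, n_g))
    pred3 <- withr::with_seed(seed, sample(c("poor", "good"), n_p + n_g,
                                           replace = TRUE))
    m <- confusion_metrics(pred3, truth3)
    expect_equal(unname(m[["accuracy"]]),
                 (n_p * m[["sensitivity"]] + n_g * m[["specificity"]]) /
                   (n_p + n_g))
  }
})

test_that("ROC enumerates decreasing thresholds with monotone rates", {
  scores <- c(3, 3, 2, 1, 1, 0)
  labels <- c("poor", "poor", "poor", "good", "good", "good")
  res <- roc_and_auc(scores, labels, thresholds = 4:0)
  expect_true(all(diff(res$roc$threshold) < 0))
  expect_true(all(diff(res$roc$tpr) >= 0))
  expect_true(all(diff(res$roc$fpr) >= 0))
  expect_equal(res$auc, 1.0)

  # label-permuted scores give null AUC on average
  aucs <- vapply(1:200, function(s) {
    perm <- withr::with_seed(s, sample(labels))
    tryCatch(roc_and_auc(scores, perm)$auc, ktsp_degenerate_error =
               function(e) NA_real_)
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.05)
})

test_that("trapezoid AUC equals the Mann-Whitney form and pROC agrees", {
  for (seed in 1:25) {
    sim <- withr::with_seed(seed, {
      n <- sample(6:40, 1)
      list(scores = sample(0:8, n, replace = TRUE),
           labels = c("poor", "good",
                      sample(c("poor", "good"), n - 2, replace = TRUE)))
    })
    res <- roc_and_auc(sim$scores, sim$labels)
    expect_equal(res$auc, resubstitution_auc(sim$scores, sim$labels),
                 tolerance = 1e-12)
    expect_equal(res$auc, oracle_auc_pairwise(sim$scores, sim$labels),
                 tolerance = 1e-12)
  }
  # independent library cross-check on one instance
  scores <- c(0, 1, 1, 2, 3, 3, 4, 5)
  labels <- c("good", "good", "poor", "good", "poor", "good", "poor", "poor")
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("good", "poor"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_and_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("bootstrap CI is deterministic, stratified and percentile-based", {
  scores <- c(5, 4, 4, 3, 2, 2, 1, 1, 0, 3)
  labels <- rep(c("poor", "good"), each = 5)
  ci1 <- auc_bootstrap_ci(scores, labels, n_boot = 500, seed = 99)
  ci2 <- auc_bootstrap_ci(scores, labels, n_boot = 500, seed = 99)
  expect_identical(ci1, ci2)

  # independent resampling loop with the same seed stream
  boots <- withr::with_seed(99L, vapply(1:500, function(i) {
    p <- sample(which(labels == "poor"), replace = TRUE)
    g <- sample(which(labels == "good"), replace = TRUE)
    oracle_auc_pairwise(c(scores[p], scores[g]),
                        rep(c("poor", "good"), c(length(p), length(g))))
  }, numeric(1)))
  expect_equal(unname(ci1),
               unname(quantile(boots, c(0.025, 0.975))), tolerance = 1e-12)

  # a cleanly separated large sample collapses toward (1, 1)
  big_scores <- rep(c(10, 0), each = 100)
  big_labels <- rep(c("poor", "good"), each = 100)
  ci <- auc_bootstrap_ci(big_scores, big_labels, n_boot = 200, seed = 1)
  expect_equal(unname(ci), c(1, 1))

  expect_error(auc_bootstrap_ci(scores, labels, n_boot = 10),
               class = "ktsp_input_error")
  expect_error(auc_bootstrap_ci(1:3, c("poor", "good", "good"), seed = 1),
               class = "ktsp_degenerate_error")
})

test_that("Kaplan-Meier estimator reproduces hand and library references", {
  # all censored -> survival stays 1
  km <- kaplan_meier(c(3, 8, 12), c(0, 0, 0))
  expect_true(all(km$surv == 1))

  # no censoring -> 1 - ECDF at the event times
  times <- c(2, 5, 9, 14, 20)
  km2 <- kaplan_meier(times, rep(1, 5))
  expect_equal(km2$surv, 1 - ecdf(times)(km2$time))

  # 6-record toy with one censoring, hand-computed product-limit table:
  # t=1 (d=1,n=6) S=5/6; t=2 censored S=5/6; t=3 (d=1,n=4) S=5/6*3/4;
  # t=4 (d=2,n=3) S=5/6*3/4*1/3; t=6 censored
  km3 <- kaplan_meier(c(1, 2, 3, 4, 4, 6), c(1, 0, 1, 1, 1, 0))
  expect_equal(km3$surv, c(5/6, 5/6, 5/8, 5/24, 5/24))

  # library oracle on random censored data
  for (seed in 1:3) {
    sim <- withr::with_seed(seed, {
      t_ev <- rexp(40, 0.1); t_c <- rexp(40, 0.05)
      list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
    })
    fit <- survival::survfit(survival::Surv(sim$time, sim$event) ~ 1)
    km4 <- kaplan_meier(sim$time, sim$event)
    expect_equal(km4$surv, summary(fit, times = km4$time)$surv,
                 tolerance = 1e-12)
  }

  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), class = "ktsp_input_error")
})

test_that("log-rank statistic matches hand computation and survdiff", {
  # exact copies of one group -> statistic 0
  time <- c(2, 4, 6, 8, 2, 4, 6, 8)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  group <- rep(c("poor", "good"), each = 4)
  res <- logrank_test(time, event, group)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # 8-record toy, hand-computed hypergeometric terms:
  # group A times 1,3 (events), 5, 7+ ; group B 2, 4, 6, 8 (events)
  timeB <- c(1, 3, 5, 7, 2, 4, 6, 8)
  eventB <- c(1, 1, 1, 1, 1, 1, 1, 1)
  groupB <- rep(c("A", "B"), each = 4)
  mine <- logrank_test(timeB, eventB, groupB)
  sd <- survival::survdiff(survival::Surv(timeB, eventB) ~ groupB)
  expect_equal(mine$statistic, sd$chisq, tolerance = 1e-12)

  for (seed in 4:6) {
    sim <- withr::with_seed(seed, {
      n <- 30
      list(time = rexp(2 * n, rep(c(0.05, 0.1), each = n)),
           event = rbinom(2 * n, 1, 0.8),
           group = rep(c("poor", "good"), each = n))
    })
    mine <- logrank_test(sim$time, sim$event, sim$group)
    sd <- survival::survdiff(survival::Surv(sim$time, sim$event) ~ sim$group)
    expect_equal(mine$statistic, sd$chisq, tolerance = 1e-10)
  }

  expect_error(logrank_test(time, event, rep("poor", 8)),
               class = "ktsp_degenerate_error")
})

test_that("evaluation report assembles metrics, ROC, CI and survival", {
  cohort <- generate_cohort(n_genes = 20, n_poor = 15, n_good = 20,
                            planted = data.frame(pair = 1:2, p_poor = 0.95,
                                                 p_good = 0.05),
                            seed = 51)
  surv <- generate_survival(cohort, hazard_ratio = 3, baseline_rate = 0.02,
                            censor_rate = 0.01, seed = 52)
  cohort <- with_survival(cohort, surv)
  model <- ktsp_train(cohort, k_range = c(2, 5))
  report <- ktsp_evaluate(model, cohort, n_boot = 200, seed = 53)
  expect_s3_class(report, "ktsp_report")
  expect_equal(report$sensitivity, 1.0)
  expect_identical(nrow(report$roc), model$k + 2L)
  expect_true(report$auc_ci[["low"]] <= report$auc_ci[["high"]])
  expect_true(report$auc_ci[["low"]] >= 0 && report$auc_ci[["high"]] <= 1)
  expect_true(!is.null(report$logrank))
  expect_identical(sort(names(report$km)), c("good", "poor"))

  # evaluating from the calls table gives the same metrics
  pred <- predict(model, cohort)
  report2 <- evaluate_predictions(pred, cohort, k = model$k, n_boot = 0)
  expect_equal(report2$auc, report$auc)
  expect_equal(report2$accuracy, report$accuracy)
})
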