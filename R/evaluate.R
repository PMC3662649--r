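# Validation metrics: confusion statistics, ROC/AUC with bootstrap CI,
# Kaplan-Meier curves and the two-group log-rank test.

#' Confusion metrics with poor prognosis as the positive class
#'
#' Sensitivity is the fraction of poor-prognosis samples called poor;
#' specificity the fraction of good-prognosis samples called good;
#' accuracy the overall fraction correct.
#'
#' @param predicted,truth character vectors of `"poor"` / `"good"`. If both
#'   are named they are aligned by name; otherwise they are compared
#'   positionally and must have equal length.
#' @return Named numeric vector `(sensitivity, specificity, accuracy)`.
#' @export
confusion_metrics <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth))) {
      stop_ktsp(sprintf(
        "sample sets differ (only in predicted: %s; only in truth: %s)",
        paste(setdiff(names(predicted), names(truth)), collapse = ", "),
        paste(setdiff(names(truth), names(predicted)), collapse = ", ")),
        "ktsp_alignment_error")
    }
    predicted <- predicted[names(truth)]
  } else if (length(predicted) != length(truth)) {
    stop_ktsp("predicted and truth differ in length", "ktsp_alignment_error")
  }
  pos <- truth == "poor"
  if (!any(pos) || all(pos)) {
    stop_ktsp("both classes must be present in truth", "ktsp_degenerate_error")
  }
  c(sensitivity = mean(predicted[pos] == "poor"),
    specificity = mean(predicted[!pos] == "good"),
    accuracy = mean(predicted == truth))
}

#' ROC curve and AUC over all score thresholds
#'
#' Enumerates thresholds in strictly decreasing order; at threshold t a
#' sample is called poor when `score >= t`, so both TPR and FPR are
#' monotone non-decreasing along the curve. The AUC is the trapezoidal
#' area, which equals the Mann-Whitney form (ties one-half) exactly.
#'
#' @param scores numeric per-sample scores (higher = more evidence for
#'   poor prognosis).
#' @param labels `"poor"` / `"good"` per sample.
#' @param thresholds optional thresholds; defaults to `Inf` followed by
#'   the distinct scores in decreasing order. For integer vote scores of a
#'   K-pair model pass `(K+1):0` to enumerate every integer threshold.
#' @return List with `roc` (`data.frame` of `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc_and_auc <- function(scores, labels, thresholds = NULL) {
  poor <- labels == "poor"
  if (!any(poor) || !any(!poor)) {
    stop_ktsp("both classes must be present", "ktsp_degenerate_error")
  }
  if (is.null(thresholds)) {
    thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  } else {
    thresholds <- sort(unique(thresholds), decreasing = TRUE)
  }
  tpr <- vapply(thresholds, function(t) mean(scores[poor] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!poor] >= t), numeric(1))
  roc <- data.frame(threshold = thresholds, tpr = tpr, fpr = fpr)
  # trapezoid over the full (0,0)..(1,1) sweep
  fpr_full <- c(fpr, 1)
  tpr_full <- c(tpr, 1)
  auc <- sum(diff(fpr_full) * (utils::head(tpr_full, -1) +
                                 utils::tail(tpr_full, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Stratified bootstrap percentile CI for the AUC
#'
#' Resamples within each class (so class sizes are preserved), recomputes
#' the Mann-Whitney AUC on each resample, and returns the percentile
#' interval. Deterministic given `seed`.
#'
#' @inheritParams roc_and_auc
#' @param level confidence level in (0, 1); default 0.95.
#' @param n_boot number of bootstrap resamples; default 2000.
#' @param seed integer seed (required, so intervals are reproducible).
#' @return Named numeric vector `(low, high)`.
#' @export
auc_bootstrap_ci <- function(scores, labels, level = 0.95, n_boot = 2000L,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    stop_ktsp("a seed is required for the bootstrap CI", "ktsp_input_error")
  }
  poor_idx <- which(labels == "poor")
  good_idx <- which(labels == "good")
  if (length(poor_idx) < 2L || length(good_idx) < 2L) {
    stop_ktsp("bootstrap CI needs at least 2 samples per class",
              "ktsp_degenerate_error")
  }
  if (level <= 0 || level >= 1) {
    stop_ktsp("level must lie in (0, 1)", "ktsp_input_error")
  }
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      p <- sample(poor_idx, replace = TRUE)
      g <- sample(good_idx, replace = TRUE)
      idx <- c(p, g)
      auc_mann_whitney(scores[idx],
                       rep(c("poor", "good"), c(length(p), length(g))))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  c(low = ci[1], high = ci[2])
}

#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survival function of one group from right-censored event
#' times: at each distinct event time t_i with d_i events among n_i at
#' risk, the estimate multiplies by (1 - d_i / n_i). The result is a
#' right-continuous non-increasing step function with S(0-) = 1.
#'
#' @param time non-negative event/censoring times.
#' @param event 1 = event observed, 0 = censored.
#' @return `data.frame` with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor` and `surv` (the estimate just after
#'   `time`).
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) != length(event) || length(time) == 0L) {
    stop_ktsp("time and event must be non-empty and of equal length",
              "ktsp_input_error")
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop_ktsp("times must be finite and >= 0", "ktsp_input_error")
  }
  if (!all(event %in% c(0, 1))) {
    stop_ktsp("event indicator must be 0 or 1", "ktsp_input_error")
  }
  times <- sort(unique(time))
  n <- length(time)
  n_risk <- vapply(times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(times, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(times, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = times, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in group one
#' is compared with its hypergeometric expectation given the risk sets;
#' the statistic is `(O - E)^2 / V` with the usual variance sum, referred
#' to a chi-square distribution with one degree of freedom.
#'
#' @param time,event as in [kaplan_meier()].
#' @param group two-level grouping vector (e.g. predicted `"poor"` /
#'   `"good"`).
#' @return List with `statistic` (chi-square), `p_value`, and the per-group
#'   `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2L) {
    stop_ktsp("log-rank test needs exactly two non-empty groups",
              "ktsp_degenerate_error")
  }
  if (length(time) != length(event) || length(time) != length(group)) {
    stop_ktsp("time, event and group must have equal length",
              "ktsp_input_error")
  }
  g1 <- group == unique(group)[1]
  event_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1_j
    e1 <- e1 + d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  statistic <- if (v > 0) (o1 - e1)^2 / v else 0
  observed <- c(o1, sum(event == 1) - o1)
  expected <- c(e1, sum(event == 1) - e1)
  names(observed) <- names(expected) <- as.character(unique(group)[1:2])
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       observed = observed, expected = expected)
}

#' Evaluate a trained model on a labeled cohort
#'
#' Predicts every sample, then reports confusion metrics, the full integer-
#' threshold ROC curve with its AUC, an optional bootstrap CI for the AUC,
#' and -- when the cohort carries survival records -- Kaplan-Meier curves
#' per predicted group and the log-rank comparison between them.
#'
#' @param model a [ktsp_model()].
#' @param cohort a labeled [ktsp_cohort()].
#' @param n_boot bootstrap resamples for the AUC CI (0 disables the CI).
#' @param level confidence level for the CI.
#' @param seed integer seed for the bootstrap (required when `n_boot > 0`).
#' @return Object of class `ktsp_report`: a list with `sensitivity`,
#'   `specificity`, `accuracy`, `roc`, `auc`, `auc_ci` (or `NULL`),
#'   `logrank` and `km` (or `NULL`), `predictions`, and the evaluation
#'   parameters.
#' @export
ktsp_evaluate <- function(model, cohort, n_boot = 2000L, level = 0.95,
                          seed = NULL) {
  stopifnot(inherits(model, "ktsp_model"), inherits(cohort, "ktsp_cohort"))
  pred <- stats::predict(model, cohort)
  evaluate_predictions(pred, cohort, k = model$k, n_boot = n_boot,
                       level = level, seed = seed)
}

#' Evaluate pre-computed predictions on a labeled cohort
#'
#' Same report as [ktsp_evaluate()], but from a predictions table (e.g. a
#' calls file written by the CLI) instead of a model.
#'
#' @param predictions `data.frame` with columns `sample_id`, `score`,
#'   `label` (as returned by [predict.ktsp_model()]).
#' @param cohort a labeled [ktsp_cohort()].
#' @param k number of pairs behind the scores (sets the enumerated integer
#'   thresholds); defaults to the maximum observed score.
#' @inheritParams ktsp_evaluate
#' @return A `ktsp_report` (see [ktsp_evaluate()]).
#' @export
evaluate_predictions <- function(predictions, cohort, k = NULL,
                                 n_boot = 2000L, level = 0.95, seed = NULL) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  check_two_classes(cohort)
  need <- c("sample_id", "score", "label")
  if (!is.data.frame(predictions) || !all(need %in% names(predictions))) {
    stop_ktsp("predictions need columns sample_id, score, label",
              "ktsp_input_error")
  }
  samples <- names(cohort$labels)
  if (!setequal(predictions$sample_id, samples) ||
      anyDuplicated(predictions$sample_id)) {
    stop_ktsp("predictions must cover each cohort sample exactly once",
              "ktsp_alignment_error")
  }
  pred <- predictions[match(samples, predictions$sample_id), , drop = FALSE]
  truth <- cohort$labels
  if (is.null(k)) k <- max(pred$score)
  cm <- confusion_metrics(stats::setNames(pred$label, pred$sample_id), truth)
  roc <- roc_and_auc(pred$score, truth, thresholds = (k + 1L):0L)
  auc_ci <- NULL
  if (n_boot > 0L) {
    auc_ci <- auc_bootstrap_ci(pred$score, truth, level = level,
                               n_boot = n_boot, seed = seed)
  }
  logrank <- NULL
  km <- NULL
  if (!is.null(cohort$survival)) {
    s <- cohort$survival
    grp <- pred$label[match(s$sample_id, pred$sample_id)]
    if (length(unique(grp)) == 2L) {
      logrank <- logrank_test(s$time_months, s$event, grp)
    }
    km <- lapply(split(seq_len(nrow(s)), grp), function(i) {
      kaplan_meier(s$time_months[i], s$event[i])
    })
  }
  structure(list(sensitivity = unname(cm[["sensitivity"]]),
                 specificity = unname(cm[["specificity"]]),
                 accuracy = unname(cm[["accuracy"]]),
                 roc = roc$roc, auc = roc$auc, auc_ci = auc_ci,
                 logrank = logrank, km = km, predictions = pred,
                 params = list(n_boot = n_boot, level = level, seed = seed)),
            class = "ktsp_report")
}

#' Write a performance report to disk
#'
#' @param report a `ktsp_report`.
#' @param json path for the JSON report (metrics, AUC and CI, log-rank).
#' @param text optional path for a human-readable text table.
#' @param roc_csv optional path for the ROC points as CSV.
#' @export
write_report <- function(report, json, text = NULL, roc_csv = NULL) {
  stopifnot(inherits(report, "ktsp_report"))
  obj <- list(sensitivity = report$sensitivity,
              specificity = report$specificity,
              accuracy = report$accuracy,
              auc = report$auc,
              auc_ci = if (is.null(report$auc_ci)) NULL else
                list(low = unname(report$auc_ci[["low"]]),
                     high = unname(report$auc_ci[["high"]]),
                     level = report$params$level,
                     n_boot = report$params$n_boot,
                     seed = report$params$seed),
              logrank = if (is.null(report$logrank)) NULL else
                list(statistic = report$logrank$statistic,
                     p_value = report$logrank$p_value),
              n_samples = nrow(report$predictions))
  jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(text)) {
    con <- file(text, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  }
  if (!is.null(roc_csv)) {
    utils::write.csv(report$roc, roc_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(json)
}

#' @export
print.ktsp_report <- function(x, ...) {
  cat("K-TSP performance report\n")
  cat(sprintf("  sensitivity: %.3f\n", x$sensitivity))
  cat(sprintf("  specificity: %.3f\n", x$specificity))
  cat(sprintf("  accuracy:    %.3f\n", x$accuracy))
  if (is.null(x$auc_ci)) {
    cat(sprintf("  AUC:         %.3f\n", x$auc))
  } else {
    cat(sprintf("  AUC:         %.3f (%d%% CI: %.3f - %.3f)\n", x$auc,
                round(100 * x$params$level), x$auc_ci[["low"]],
                x$auc_ci[["high"]]))
  }
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank:    chi-square = %.3f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p_value))
  }
  invisible(x)
}
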