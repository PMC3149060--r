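# Model evaluation: confusion reports at probability cut-offs with
# exact binomial intervals, rank-based ROC AUC, and calibration tables.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Two-sided exact interval via beta-quantile inversion of the binomial
#' tails: lower bound `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#' upper bound `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` on the proportion
#'   scale.
#' @export
#' @examples
#' round(100 * clopper_pearson(81, 82), 1) # 93.4, 99.9
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      x < 0 || n < 1 || x > n) {
    abort("need 0 <= x <= n with n >= 1.")
  }
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1).")
  alpha <- 1 - level
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Confusion report from 2x2 counts
#'
#' Builds the full classification report (sensitivity, specificity,
#' positive and negative predictive values, each with an exact 95%
#' Clopper-Pearson interval) from the four cells of a 2x2 contingency
#' table at a probability cut-off.
#'
#' @param tp,fp,fn,tn Cell counts.
#' @param cutoff Probability cut-off the counts correspond to
#'   (recorded; may be `NA` for a bare table).
#' @param level Confidence level for the exact intervals.
#' @return A tibble of class `drm_confusion` with one row per metric:
#'   `metric`, `numerator`, `denominator`, `estimate`, `conf.low`,
#'   `conf.high`, plus attributes `counts`, `cutoff` and
#'   `flagged_fraction`.
#' @export
#' @examples
#' confusion_from_counts(81, 55, 1, 400, cutoff = 0.107)
confusion_from_counts <- function(tp, fp, fn, tn, cutoff = NA_real_,
                                  level = 0.95) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) abort("counts must be non-negative.")
  n <- sum(counts)
  if (n == 0) abort("empty table.")
  cells <- tibble::tribble(
    ~metric,       ~numerator, ~denominator,
    "sensitivity", tp,         tp + fn,
    "specificity", tn,         tn + fp,
    "ppv",         tp,         tp + fp,
    "npv",         tn,         tn + fn
  )
  est <- cells$numerator / cells$denominator
  ci <- t(mapply(clopper_pearson, cells$numerator, cells$denominator,
                 MoreArgs = list(level = level)))
  out <- dplyr::mutate(cells, estimate = est,
                       conf.low = ci[, 1], conf.high = ci[, 2])
  attr(out, "counts") <- counts
  attr(out, "cutoff") <- cutoff
  attr(out, "flagged_fraction") <- (tp + fp) / n
  class(out) <- c("drm_confusion", class(out))
  out
}

#' Confusion report for predicted probabilities at a cut-off
#'
#' Classifies episodes as predicted-positive when the predicted
#' probability is strictly greater than the cut-off and cross-tabulates
#' against the reference outcome.
#'
#' @param probabilities Predicted probabilities.
#' @param truth Binary reference outcome (0/1).
#' @param cutoff Probability cut-off in (0, 1).
#' @param level Confidence level for exact intervals.
#' @return A `drm_confusion` tibble (see [confusion_from_counts()]).
#' @export
confusion_metrics <- function(probabilities, truth, cutoff,
                              level = 0.95) {
  if (length(probabilities) == 0) abort("empty input.")
  if (length(probabilities) != length(truth)) {
    abort("probabilities and truth differ in length.")
  }
  if (!all(truth %in% c(0, 1))) abort("truth must be binary 0/1.")
  if (cutoff <= 0 || cutoff >= 1) abort("cutoff must lie in (0, 1).")
  pos <- probabilities > cutoff
  confusion_from_counts(
    tp = sum(pos & truth == 1), fp = sum(pos & truth == 0),
    fn = sum(!pos & truth == 1), tn = sum(!pos & truth == 0),
    cutoff = cutoff, level = level)
}

# Rank-statistic AUC with midrank tie correction.
auc_rank <- function(probabilities, truth) {
  r <- rank(probabilities)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve with confidence interval
#'
#' AUC by the Mann-Whitney rank statistic (ties counted one half), with
#' a 95% confidence interval by DeLong's method (the default) or by
#' stratified bootstrap, and the empirical ROC curve for plotting.
#'
#' @param probabilities Predicted probabilities (or any monotone score).
#' @param truth Binary reference outcome (0/1).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return A list of class `drm_roc`: `auc`, `conf.low`, `conf.high`,
#'   `ci_method`, `curve` (tibble with `fpr`, `tpr`).
#' @export
roc_auc <- function(probabilities, truth,
                    ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  if (length(unique(truth)) < 2) {
    abort("both outcome classes must be present.")
  }
  auc <- auc_rank(probabilities, truth)
  roc <- pROC::roc(response = truth, predictor = probabilities,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- if (ci_method == "delong") {
    pROC::ci.auc(roc, method = "delong")
  } else {
    pROC::ci.auc(roc, method = "bootstrap", boot.n = 500, progress = "none")
  }
  curve <- tibble::tibble(
    fpr = rev(1 - roc$specificities),
    tpr = rev(roc$sensitivities)
  )
  structure(list(auc = auc, conf.low = as.numeric(ci[1]),
                 conf.high = as.numeric(ci[3]), ci_method = ci_method,
                 curve = curve),
            class = "drm_roc")
}

#' Calibration table (predicted vs observed by risk decile)
#'
#' Splits episodes into equal-frequency bins of predicted probability
#' and reports, per bin, the mean predicted probability and the
#' observed infection proportion with an exact binomial interval.
#'
#' @param probabilities Predicted probabilities.
#' @param truth Binary reference outcome.
#' @param bins Number of equal-frequency bins (default 10).
#' @return A tibble of class `drm_calibration`: `bin`, `n`,
#'   `mean_predicted`, `observed`, `conf.low`, `conf.high`.
#' @export
calibration_table <- function(probabilities, truth, bins = 10) {
  n <- length(probabilities)
  if (n < bins) abort("fewer observations than bins.")
  breaks <- unique(quantile(probabilities, probs = seq(0, 1, 1 / bins)))
  if (length(breaks) < 2) {
    grp <- factor(rep(1, n))
  } else {
    grp <- cut(probabilities, breaks = breaks, include.lowest = TRUE)
  }
  out <- tibble::tibble(p = probabilities, y = truth, bin = grp) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_predicted = mean(.data$p),
      events = sum(.data$y),
      observed = mean(.data$y),
      .groups = "drop"
    )
  ci <- t(mapply(clopper_pearson, out$events, out$n))
  out$conf.low <- ci[, 1]
  out$conf.high <- ci[, 2]
  out$bin <- seq_len(nrow(out))
  class(out) <- c("drm_calibration", class(out))
  out
}

#' Fraction of episodes flagged for manual review
#'
#' The proportion of episodes with predicted probability strictly above
#' the cut-off — the chart-review workload remaining after automated
#' triage.
#'
#' @param probabilities Predicted probabilities.
#' @param cutoff Probability cut-off.
#' @return A proportion in `[0, 1]`.
#' @export
#' @examples
#' workload_reduction(c(0.5, 0.05, 0.02, 0.9), 0.107) # 0.5
workload_reduction <- function(probabilities, cutoff) {
  if (length(probabilities) == 0) abort("empty input.")
  mean(probabilities > cutoff)
}

#' Percentages as printed in surveillance reports
#'
#' Rounds a proportion to a percentage with `digits` decimals, with the
#' reporting convention that a quantity strictly below 1 (above 0) is
#' never displayed as 100% (0%): an exact upper confidence bound of
#' 0.9997 prints as 99.9, not 100.0.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @param digits Decimals shown (default 1).
#' @return Numeric vector on the percent scale.
#' @export
#' @examples
#' report_percent(clopper_pearson(81, 82)) # 93.4 99.9
report_percent <- function(p, digits = 1) {
  out <- round(100 * p, digits)
  eps <- 10^(-digits)
  out <- ifelse(p < 1 & out >= 100, 100 - eps, out)
  ifelse(p > 0 & out <= 0, eps, out)
}

#' @export
print.drm_confusion <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("<drm_confusion> cutoff %s  (tp %d, fp %d, fn %d, tn %d)\n",
              format(attr(x, "cutoff")), counts["tp"], counts["fp"],
              counts["fn"], counts["tn"]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %5.1f%%  (%.1f-%.1f)\n", x$metric[i],
                report_percent(x$estimate[i]),
                report_percent(x$conf.low[i]),
                report_percent(x$conf.high[i])))
  }
  invisible(x)
}
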