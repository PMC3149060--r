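# Confusion reports, exact intervals, ROC, calibration, workload and
# group-level surveillance.

test_that("clopper_pearson matches brute-force tail inversion", {
  # oracle: solve the binomial tail equations numerically
  cp_oracle <- function(x, n, level = 0.95) {
    a <- (1 - level) / 2
    lower <- if (x == 0) 0 else
      uniroot(function(p) 1 - pbinom(x - 1, n, p) - a,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    upper <- if (x == n) 1 else
      uniroot(function(p) pbinom(x, n, p) - a,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    c(lower, upper)
  }
  for (n in c(1, 5, 12, 20)) {
    for (x in 0:n) {
      got <- clopper_pearson(x, n)
      expect_equal(unname(got), cp_oracle(x, n), tolerance = 1e-7,
                   label = paste0("x=", x, " n=", n))
    }
  }
  expect_equal(unname(clopper_pearson(82, 82))[2], 1)
  expect_equal(unname(clopper_pearson(0, 82))[1], 0)
  expect_error(clopper_pearson(5, 4), "x <= n")
  expect_error(clopper_pearson(1, 4, level = 1.2), "level")
})

test_that("confusion report is internally consistent with its counts", {
  cm <- confusion_from_counts(81, 55, 1, 400, cutoff = 0.107)
  counts <- attr(cm, "counts")
  expect_equal(sum(counts), 537)
  # metric * denominator = numerator, exactly, before rounding
  expect_equal(cm$estimate * cm$denominator, cm$numerator)
  expect_true(all(cm$conf.low <= cm$estimate &
                    cm$estimate <= cm$conf.high))
  expect_equal(attr(cm, "flagged_fraction"), 136 / 537)
})

test_that("probability classification is strictly greater-than", {
  p <- c(0.107, 0.2, 0.05, 0.107)
  y <- c(1, 1, 0, 0)
  cm <- confusion_metrics(p, y, cutoff = 0.107)
  counts <- attr(cm, "counts")
  # the two scores at exactly the cut-off fall on the negative side
  expect_equal(unname(counts), c(1, 0, 1, 2))

  perfect <- confusion_metrics(c(0.9, 0.8, 0.1), c(1, 1, 0), 0.5)
  expect_equal(perfect$estimate, rep(1, 4))

  expect_error(confusion_metrics(numeric(0), numeric(0), 0.5), "empty")
  expect_error(confusion_metrics(p, c(1, 2, 0, 1), 0.5), "binary")
  expect_error(confusion_metrics(p, y, 1.5), "cutoff")
})

test_that("report percentages cap displayed bounds inside (0, 100)", {
  expect_equal(report_percent(clopper_pearson(81, 82)),
               c(lower = 93.4, upper = 99.9))
  expect_equal(report_percent(clopper_pearson(82, 82))[["upper"]], 100)
  expect_equal(report_percent(0.0001), 0.1)
})

test_that("rank AUC equals the O(n^2) concordance oracle", {
  auc_oracle <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    tot <- 0
    for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
    tot / (length(pos) * length(neg))
  }
  set.seed(111)
  for (i in 1:15) {
    n <- sample(20:300, 1)
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    # discretise some scores to force ties
    p <- round(plogis(rnorm(n) + y), sample(1:2, 1))
    r <- roc_auc(p, y)
    expect_equal(r$auc, auc_oracle(p, y), tolerance = 1e-12)
    expect_true(r$conf.low <= r$auc & r$auc <= r$conf.high)
    # rank invariance under monotone transform
    expect_equal(roc_auc(qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)), y)$auc,
                 r$auc)
  }
  # pROC warns that a degenerate AUC of 1 has a degenerate interval
  expect_equal(suppressWarnings(
    roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc), 1)
  expect_error(roc_auc(c(0.5, 0.6), c(1, 1)), "both outcome classes")
})

test_that("calibration table tracks the diagonal on calibrated data", {
  set.seed(112)
  n <- 2000
  p <- plogis(rnorm(n, -1.5, 1.2))
  y <- as.numeric(runif(n) < p)
  tab <- calibration_table(p, y, bins = 10)
  expect_equal(sum(tab$n), n)
  # each bin's observed rate lies inside its own exact binomial CI
  # around the mean prediction in most bins
  inside <- tab$mean_predicted >= tab$conf.low &
    tab$mean_predicted <= tab$conf.high
  expect_gte(mean(inside), 0.8)

  # bins = 1 collapses to overall prevalence
  one <- calibration_table(p, y, bins = 1)
  expect_equal(one$observed, mean(y))

  # constant probability: a single effective bin near p
  const <- calibration_table(rep(0.3, 500),
                             as.numeric(runif(500) < 0.3), bins = 10)
  expect_equal(nrow(const), 1L)
  expect_equal(const$mean_predicted, 0.3)

  expect_error(calibration_table(runif(5), rbinom(5, 1, 0.5), bins = 10),
               "fewer")
})

test_that("workload reduction is the flagged fraction", {
  set.seed(113)
  p <- c(rep(0.2, 136), rep(0.05, 401))
  expect_equal(report_percent(workload_reduction(p, 0.107)), 25.3)
  expect_equal(workload_reduction(p, 0.9), 0)
  expect_equal(workload_reduction(p, 0.01), 1)
  expect_error(workload_reduction(numeric(0), 0.5), "empty")
})

test_that("surveillance summary sums probabilities into rates", {
  d <- tibble::tibble(probability = c(1, 0, 0), year = 2005,
                      days_at_risk = c(10, 5, 5), drm_flag = c(1, 0, 0))
  s <- surveillance_summary(d, truth = "drm_flag")
  expect_equal(s$expected_infections, 1)
  expect_equal(s$observed_infections, 1)

  # 10 episodes of 100 days each: rate = 1000 * sum(p) / 1000 days
  d2 <- tibble::tibble(probability = rep(0.135, 10), year = 2006,
                       days_at_risk = 100)
  s2 <- surveillance_summary(d2)
  expect_equal(s2$expected_infections, 1.35)
  expect_equal(s2$predicted_rate, 1.35)

  # spec invariant: expected infections never exceed the episode count
  set.seed(114)
  d3 <- tibble::tibble(probability = runif(200),
                       year = sample(2004:2009, 200, TRUE),
                       days_at_risk = sample(3:40, 200, TRUE))
  s3 <- surveillance_summary(d3)
  expect_true(all(s3$expected_infections >= 0 &
                    s3$expected_infections <= s3$episodes))
  expect_equal(sum(s3$episodes), 200)

  expect_error(surveillance_summary(
    tibble::tibble(probability = 0.5, year = 2004, days_at_risk = 0)),
    "zero days")
})

test_that("predicted probabilities follow the logistic identity", {
  rule <- build_prediction_rule(c(culture_positive = 13.70), "fitted",
                                intercept = -3)
  # all-reference patient: P = 1 / (1 + e^3)
  p0 <- predict_probability(rule, tibble::tibble(culture_positive = 0))
  expect_equal(p0, 1 / (1 + exp(3)))
  # flipping the culture flag multiplies the odds by 13.70
  p1 <- predict_probability(rule, tibble::tibble(culture_positive = 1))
  expect_equal((p1 / (1 - p1)) / (p0 / (1 - p0)), 13.70)
  # LP = 0 gives one half
  zero <- build_prediction_rule(c(x = exp(2)), "fitted", intercept = -2)
  expect_equal(predict_probability(zero, tibble::tibble(x = 1)), 0.5)

  # missing predictors are a scoring error, not a silent guess
  expect_error(predict_probability(rule, tibble::tibble(other = 1)),
               "absent")
  expect_error(
    predict_probability(rule,
                        tibble::tibble(culture_positive = NA_real_)),
    "missing predictor")
})
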