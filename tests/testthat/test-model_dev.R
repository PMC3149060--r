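# Screening, logistic fitting (ML + Firth fallback), backward selection
# and bootstrap optimism correction.

# helper: imputation-set wrapper around complete data
as_imp <- function(data, m = 2) {
  structure(list(matrices = rep(list(data), m), m = m, seed = 1,
                 method = "complete"), class = "drm_imputation")
}

expand_2x2 <- function(n11, n10, n01, n00) {
  # x = 1/0 exposure, y = 1/0 outcome
  tibble::tibble(
    x = c(rep(1, n11 + n10), rep(0, n01 + n00)),
    y = c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00)))
}

test_that("univariate screening picks the appropriate test", {
  # drain type 2x2 from the development cohort: 71/82 vs 266/455 EVD
  d <- expand_2x2(71, 266, 11, 189)
  names(d) <- c("drain_type_evd", "drm_flag")
  scr <- univariate_screen(d, variables = "drain_type_evd")
  expect_equal(scr$test, "chi-square")
  expect_lt(scr$p.value, 0.001)
  expect_true(scr$selected)

  # skewed continuous variable: Mann-Whitney; normal-tagged: t
  set.seed(81)
  d2 <- tibble::tibble(drm_flag = rep(c(0, 1), each = 100),
                       crp = rlnorm(200, 4 + 0.5 * rep(c(0, 1), each = 100)),
                       age = rnorm(200, 60, 10))
  scr2 <- univariate_screen(d2)
  expect_equal(scr2$test[scr2$variable == "crp"], "Mann-Whitney U")
  expect_equal(scr2$test[scr2$variable == "age"], "t")
  expect_true(scr2$selected[scr2$variable == "crp"])

  # constant variable flagged, never selected
  d2$flat <- 1
  scr3 <- univariate_screen(d2, variables = "flat")
  expect_true(scr3$zero_variance)
  expect_false(scr3$selected)
})

test_that("screening false-positive rate is near the nominal level", {
  set.seed(82)
  hits <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    d <- tibble::tibble(drm_flag = rep(c(0, 1), each = 40),
                        v = rnorm(80))
    hits <- hits + univariate_screen(d, variables = "v")$selected
  }
  # nominal 5%; 3 SE band around it
  expect_lt(abs(hits / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("logistic fit matches the closed-form 2x2 log odds ratio", {
  d <- expand_2x2(81, 55, 1, 400)
  names(d) <- c("culture", "drm_flag")
  fit <- fit_logistic(d, "drm_flag", "culture")
  expect_false(fit$separation)
  expect_equal(unname(fit$coefficients["culture"]),
               log((81 * 400) / (55 * 1)), tolerance = 1e-6)
  # closed-form SE: sqrt of summed reciprocal cell counts
  expect_equal(unname(sqrt(diag(fit$vcov))["culture"]),
               sqrt(1 / 81 + 1 / 55 + 1 / 1 + 1 / 400), tolerance = 1e-3)
})

test_that("separation triggers a flagged penalized fit", {
  d <- tibble::tibble(x = c(rep(0, 50), rep(1, 50)),
                      drm_flag = c(rep(0, 50), rep(1, 50)))
  fit <- fit_logistic(d, "drm_flag", "x")
  expect_true(fit$separation)
  expect_equal(fit$method, "firth")
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(sqrt(diag(fit$vcov)))))
  # Firth estimate for this 50/50 perfectly separated table is finite
  # and large-positive
  expect_gt(fit$coefficients["x"], 2)
})

test_that("fit_logistic validates its inputs", {
  d <- tibble::tibble(x = rnorm(10), drm_flag = rep(c(0, 1), 5))
  d$x[1] <- NA
  expect_error(fit_logistic(d, "drm_flag", "x"), "missing cells")
  d2 <- tibble::tibble(x = rnorm(3), y = rnorm(3), z = rnorm(3),
                       drm_flag = c(0, 1, 0))
  expect_error(fit_logistic(d2, "drm_flag", c("x", "y", "z")),
               "more parameters")
})

test_that("backward selection removes weak terms and respects hierarchy", {
  rule <- build_prediction_rule(
    reference_odds_ratios()[c("culture_positive", "n_abx_started")],
    "fitted", intercept = -3)
  sim <- simulate_from_rule(rule, n = 4000, seed = 91,
                            config = sim_config())
  imp <- as_imp(sim$data)

  # strongly predictive candidates are all retained
  sel <- backward_select(imp, c("culture_positive", "n_abx_started"))
  expect_setequal(sel$selected, c("culture_positive", "n_abx_started"))
  expect_equal(nrow(sel$history), 0L)

  # a fixed point: re-running on its own output changes nothing
  sel2 <- backward_select(imp, sel$selected)
  expect_setequal(sel2$selected, sel$selected)

  # output is always a subset of the candidates
  sel3 <- backward_select(imp, c("culture_positive", "n_abx_started",
                                 "empiric_abx", "drain_type_evd"))
  expect_true(all(sel3$selected %in% c("culture_positive", "n_abx_started",
                                       "empiric_abx", "drain_type_evd")))

  expect_error(backward_select(imp, character(0)), "empty")
})

test_that("linear CRP survives selection while a power term is retained", {
  # generating model: only the cubic CRP term and culture matter, the
  # linear CRP coefficient is null
  or <- c(crp_cu = 1.35, culture_positive = 13.7)
  rule <- build_prediction_rule(or, "fitted", intercept = -3)
  kept <- 0
  for (r in 1:10) {
    sim <- simulate_from_rule(rule, n = 3000, seed = 500 + r,
                              config = sim_config())
    sel <- backward_select(as_imp(sim$data),
                           c("crp", "crp_sq", "crp_cu",
                             "culture_positive"))
    if (any(c("crp_sq", "crp_cu") %in% sel$selected)) {
      expect_true("crp" %in% sel$selected)
      kept <- kept + 1
    }
  }
  # the scenario must actually exercise the hierarchy rule
  expect_gt(kept, 5)
})

test_that("bootstrap optimism detects overfitting and spares honest fits", {
  rule <- build_prediction_rule(
    reference_odds_ratios()[c("culture_positive", "n_abx_started")],
    "fitted", intercept = -3)

  # large n, true model: shrinkage close to 1
  sim <- simulate_from_rule(rule, n = 8000, seed = 93,
                            config = sim_config())
  opt <- bootstrap_optimism(as_imp(sim$data),
                            c("culture_positive", "n_abx_started"),
                            B = 40, seed = 7)
  expect_gt(opt$shrinkage, 0.95)
  expect_lte(opt$shrinkage, 1)
  expect_lte(opt$corrected_auc, opt$apparent_auc)

  # small n with noise predictors: shrinkage well below 1
  set.seed(94)
  small <- simulate_from_rule(rule, n = 120, seed = 95,
                              config = sim_config())$data
  for (k in 1:8) small[[paste0("noise", k)]] <- rnorm(120)
  opt2 <- bootstrap_optimism(as_imp(small),
                             c("culture_positive", "n_abx_started",
                               paste0("noise", 1:8)),
                             B = 40, seed = 8)
  expect_lt(opt2$shrinkage, 0.95)
  expect_lt(opt2$corrected_auc, opt2$apparent_auc)

  expect_error(bootstrap_optimism(as_imp(small), "culture_positive",
                                  B = 5), "at least 10")
})

test_that("prediction rules are assembled from odds ratios correctly", {
  r <- build_prediction_rule(c(culture_positive = 13.70), "fitted",
                             intercept = -2)
  expect_equal(unname(r$coefficients["culture_positive"]), log(13.70))
  expect_equal(round(unname(r$coefficients["culture_positive"]), 3),
               2.617)

  # all unit odds ratios: LP is the intercept everywhere
  flat <- build_prediction_rule(c(a = 1, b = 1), "fitted",
                                intercept = -1.5)
  p <- predict_probability(flat, tibble::tibble(a = rnorm(5),
                                                b = rnorm(5)))
  expect_equal(p, rep(plogis(-1.5), 5))

  expect_error(build_prediction_rule(c(a = -2), "fitted", intercept = 0),
               "positive")

  # published mode calibrates the intercept to the target prevalence
  sim <- simulate_from_rule(
    build_prediction_rule(reference_odds_ratios(), "fitted",
                          intercept = -8),
    n = 2000, seed = 96, config = sim_config())
  pub <- build_prediction_rule(reference_odds_ratios(), "published",
                               reference_data = sim$data,
                               prevalence = 0.153)
  expect_equal(pub$provenance, "published")
  expect_lt(abs(mean(predict_probability(pub, sim$data)) - 0.153), 0.001)
})

test_that("develop_model returns a scoreable shrunk rule with tidiers", {
  rule <- build_prediction_rule(
    reference_odds_ratios()[c("culture_positive", "n_abx_started",
                              "drain_type_evd")],
    "fitted", intercept = -3)
  sim <- simulate_from_rule(rule, n = 1200, seed = 97,
                            config = sim_config())
  imp <- impute_features(sim$data, m = 2, seed = 98)
  fit <- develop_model(imp, B = 15, seed = 99)
  expect_s3_class(fit, "drm_model")
  expect_true(all(fit$rule$coefficients != 0))
  expect_gt(fit$optimism$apparent_auc, 0.8)

  td <- tidy(fit$rule)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(exp(td$estimate[-1]), td$odds.ratio[-1])
  g <- glance(fit)
  expect_equal(g$n, 1200)
  expect_true(g$shrinkage > 0 && g$shrinkage <= 1)

  p <- predict_probability(fit$rule, mean_dataset(imp))
  expect_true(all(p > 0 & p < 1))
})
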