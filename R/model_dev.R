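# Prediction-model development: univariate screening, logistic fitting
# (with a Firth-type penalized fallback under separation), pooled-Wald
# backward selection with the CRP hierarchy rule, and bootstrap
# calibration-slope optimism correction.

CRP_LINEAR <- "crp"
CRP_HIGHER <- c("crp_sq", "crp_cu")

#' Univariate screening of candidate predictors
#'
#' Tests each variable against the outcome in a single (mean) dataset:
#' chi-square for categorical variables, Student's t for variables
#' tagged normal, Mann-Whitney U otherwise. Two-sided p-values;
#' variables with p < `alpha` are flagged as selected. Zero-variance
#' variables are reported but never selected.
#'
#' @param data A completed feature tibble (e.g. [mean_dataset()]).
#' @param outcome Name of the binary outcome column.
#' @param variables Variables to screen (default: all numeric columns
#'   except identifiers and the outcome).
#' @param normal_tagged Variables to test with Student's t.
#' @param alpha Selection threshold (default 0.05).
#' @return A tibble of class `drm_screen`: `variable`, `test`,
#'   `statistic`, `p.value`, `selected`, `zero_variance`.
#' @export
univariate_screen <- function(data, outcome = "drm_flag",
                              variables = NULL,
                              normal_tagged = "age",
                              alpha = 0.05) {
  if (!outcome %in% names(data)) abort("outcome column not found.")
  y <- data[[outcome]]
  if (is.null(variables)) {
    variables <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c(ID_COLUMNS, DERIVED_COLUMNS, outcome))
  }
  rows <- purrr::map(variables, function(v) {
    x <- data[[v]]
    zero_var <- stats::sd(x, na.rm = TRUE) == 0
    if (zero_var || all(is.na(x))) {
      return(tibble::tibble(variable = v, test = NA_character_,
                            statistic = NA_real_, p.value = NA_real_,
                            selected = FALSE, zero_variance = TRUE))
    }
    if (is_binary_col(x)) {
      tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
      ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
      test <- "chi-square"
    } else if (v %in% normal_tagged) {
      ht <- t.test(x ~ y)
      test <- "t"
    } else {
      ht <- suppressWarnings(wilcox.test(x ~ y))
      test <- "Mann-Whitney U"
    }
    tibble::tibble(variable = v, test = test,
                   statistic = unname(ht$statistic),
                   p.value = ht$p.value,
                   selected = ht$p.value < alpha, zero_variance = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("drm_screen", class(out))
  out
}

#' Maximum-likelihood logistic regression with separation fallback
#'
#' Fits `outcome ~ predictors` by ML (`stats::glm`). If the fit fails
#' to converge or shows signs of separation (unbounded coefficients),
#' it is refit with Firth-type penalization (Jeffreys-prior score
#' correction) and flagged.
#'
#' @param data Completed tibble with no missing cells in the model
#'   columns.
#' @param outcome Outcome column name (0/1).
#' @param predictors Character vector of predictor columns.
#' @return A list of class `drm_logistic`: `coefficients`, `vcov`,
#'   `converged`, `separation`, `method`, `n`.
#' @export
fit_logistic <- function(data, outcome = "drm_flag", predictors) {
  cols <- c(outcome, predictors)
  if (anyNA(data[cols])) abort("missing cells in model columns.")
  if (nrow(data) <= length(predictors) + 1) {
    abort("more parameters than observations.")
  }
  f <- as.formula(paste(outcome, "~",
                        paste(sprintf("`%s`", predictors), collapse = "+")))
  fit <- suppressWarnings(glm(f, data = data, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE) ||
    anyNA(coef(fit))
  if (separated) {
    X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
    fr <- firth_logistic(X, data[[outcome]])
    return(structure(list(coefficients = fr$coefficients, vcov = fr$vcov,
                          converged = fr$converged, separation = TRUE,
                          method = "firth", n = nrow(data)),
                     class = "drm_logistic"))
  }
  beta <- coef(fit)
  names(beta) <- clean_term_names(names(beta))
  V <- vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = V, converged = fit$converged,
                 separation = FALSE, method = "ml", n = nrow(data)),
            class = "drm_logistic")
}

clean_term_names <- function(x) gsub("`", "", x)

# Firth-type penalized logistic regression: IRLS with the standard
# hat-diagonal correction to the score, U*(b) = X'(y - p + h(1/2 - p)).
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  p_dim <- ncol(X)
  beta <- numeric(p_dim)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- tryCatch(solve(info), error = function(e)
      solve(info + diag(1e-6, p_dim)))
    h <- rowSums((XW %*% info_inv) * XW)
    score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- drop(info_inv %*% score)
    # dampen very large steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  w <- pmax(plogis(eta) * (1 - plogis(eta)), 1e-10)
  V <- solve(crossprod(X * sqrt(w)) + diag(1e-10, p_dim))
  beta <- setNames(beta, colnames(X))
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = V, converged = converged)
}

# Fit the same predictor set on every completed matrix and pool.
pooled_fit <- function(imp, outcome, predictors) {
  fits <- purrr::map(imp$matrices, fit_logistic, outcome = outcome,
                     predictors = predictors)
  est <- t(vapply(fits, function(f) f$coefficients,
                  numeric(length(predictors) + 1)))
  vars <- t(vapply(fits, function(f) diag(f$vcov),
                   numeric(length(predictors) + 1)))
  colnames(est) <- colnames(vars) <- names(fits[[1]]$coefficients)
  list(pooled = pool_rubin(est, vars), fits = fits)
}

#' Backward selection with Rubin-pooled Wald tests
#'
#' Iteratively removes the candidate with the largest pooled Wald
#' p-value until all remaining predictors have p < `alpha`. The linear
#' CRP term is never removed while a higher-order CRP term
#' (`crp_sq`, `crp_cu`) remains in the model, regardless of its
#' p-value (polynomial hierarchy rule).
#'
#' @param imp A `drm_imputation` object.
#' @param candidates Character vector of candidate predictors.
#' @param outcome Outcome column name.
#' @param alpha Removal threshold (default 0.05).
#' @return A list of class `drm_selection`: `selected`, `history`
#'   (tibble of removals), `pooled` (final pooled coefficient table).
#' @export
backward_select <- function(imp, candidates, outcome = "drm_flag",
                            alpha = 0.05) {
  if (length(candidates) == 0) abort("empty candidate set.")
  current <- candidates
  history <- list()
  repeat {
    pf <- pooled_fit(imp, outcome, current)
    tab <- pf$pooled[pf$pooled$term != "(Intercept)", ]
    removable <- tab$term
    if (CRP_LINEAR %in% removable && any(CRP_HIGHER %in% current)) {
      removable <- setdiff(removable, CRP_LINEAR)
    }
    cand_tab <- tab[tab$term %in% removable, ]
    worst <- cand_tab[which.max(cand_tab$p.value), ]
    if (nrow(worst) == 0 || worst$p.value < alpha) {
      return(structure(list(selected = current,
                            history = dplyr::bind_rows(history),
                            pooled = pf$pooled),
                       class = "drm_selection"))
    }
    history[[length(history) + 1]] <- tibble::tibble(
      removed = worst$term, p.value = worst$p.value,
      step = length(history) + 1)
    current <- setdiff(current, worst$term)
    if (length(current) == 0) {
      return(structure(list(selected = character(0),
                            history = dplyr::bind_rows(history),
                            pooled = pf$pooled[
                              pf$pooled$term == "(Intercept)", ]),
                       class = "drm_selection"))
    }
  }
}

#' Bootstrap optimism correction (calibration-slope shrinkage)
#'
#' For each completed matrix, draws `B` bootstrap resamples, refits the
#' model in each, and evaluates the bootstrap model on the original
#' matrix. The average calibration slope of the bootstrap linear
#' predictor on the original data is the shrinkage factor; the average
#' AUC optimism (bootstrap-sample AUC minus original-sample AUC of the
#' same model) is subtracted from the apparent AUC.
#'
#' @param imp A `drm_imputation` object.
#' @param predictors Selected predictor set.
#' @param outcome Outcome column name.
#' @param B Bootstrap resamples per imputation set (default 100;
#'   fewer than 10 is rejected).
#' @param seed Integer seed for the resampling.
#' @return A list of class `drm_optimism`: `shrinkage` (clamped to
#'   (0, 1]), `raw_slope`, `optimism`, `apparent_auc`,
#'   `corrected_auc`, `B`.
#' @export
bootstrap_optimism <- function(imp, predictors, outcome = "drm_flag",
                               B = 100, seed = 1L) {
  if (B < 10) abort("B must be at least 10 bootstrap resamples.")
  set.seed(seed)
  slopes <- numeric(0); optimisms <- numeric(0); apparents <- numeric(0)
  for (mat in imp$matrices) {
    y <- mat[[outcome]]
    X <- as.matrix(mat[predictors])
    orig <- fit_logistic(mat, outcome, predictors)
    lp_orig <- drop(cbind(1, X) %*% orig$coefficients)
    apparents <- c(apparents, auc_rank(plogis(lp_orig), y))
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(mat), replace = TRUE)
      boot <- mat[idx, ]
      if (length(unique(boot[[outcome]])) < 2) next
      # bootstrap refits use plain maximum likelihood: resamples that
      # separate produce extreme linear predictors and correctly pull
      # the calibration slope towards zero
      fit_b <- tryCatch(
        list(coefficients = coef(suppressWarnings(glm.fit(
          cbind(1, as.matrix(boot[predictors])), boot[[outcome]],
          family = binomial())))),
        error = function(e) NULL)
      if (is.null(fit_b) || anyNA(fit_b$coefficients)) next
      lp_boot_on_orig <- drop(cbind(1, X) %*% fit_b$coefficients)
      slope <- tryCatch(
        coef(suppressWarnings(glm(y ~ lp_boot_on_orig,
                                  family = binomial())))[2],
        error = function(e) NA_real_)
      if (is.finite(slope)) slopes <- c(slopes, slope)
      auc_boot <- auc_rank(plogis(drop(
        cbind(1, as.matrix(boot[predictors])) %*% fit_b$coefficients)),
        boot[[outcome]])
      auc_test <- auc_rank(plogis(lp_boot_on_orig), y)
      optimisms <- c(optimisms, auc_boot - auc_test)
    }
  }
  apparent <- mean(apparents)
  optimism <- if (length(optimisms)) mean(optimisms) else 0
  raw_slope <- if (length(slopes)) mean(slopes) else 1
  structure(list(
    shrinkage = min(max(raw_slope, 1e-6), 1),
    raw_slope = raw_slope,
    optimism = optimism,
    apparent_auc = apparent,
    corrected_auc = apparent - max(optimism, 0),
    B = B
  ), class = "drm_optimism")
}

#' Develop the full prediction model from an imputation set
#'
#' Convenience wrapper chaining [univariate_screen()] on the mean
#' dataset, [backward_select()], Rubin pooling, and
#' [bootstrap_optimism()]; coefficients are multiplied by the shrinkage
#' factor and the intercept is re-estimated on the mean dataset so that
#' predictions stay calibrated-in-the-large after shrinkage.
#'
#' @param imp A `drm_imputation` object.
#' @param candidates Candidate predictors for multivariate modeling;
#'   defaults to the model's canonical candidate set present in the
#'   data.
#' @param outcome Outcome column name.
#' @param alpha Selection threshold.
#' @param B Bootstrap resamples per imputation set.
#' @param seed Seed for the bootstrap.
#' @param screen Restrict candidates to those passing univariate
#'   screening (default TRUE; CRP polynomial terms follow the linear
#'   term).
#' @return A list of class `drm_model`: `rule` (a `drm_rule`),
#'   `screening`, `selection`, `pooled`, `optimism`, `n`, `events`,
#'   `m`.
#' @export
develop_model <- function(imp,
                          candidates = NULL,
                          outcome = "drm_flag",
                          alpha = 0.05, B = 100, seed = 1L,
                          screen = TRUE) {
  mean_dat <- mean_dataset(imp)
  default_cands <- c("drain_type_evd", "n_drains", "crp", "crp_sq",
                     "crp_cu", "blood_leukocytes", "csf_leukocytes_log",
                     "culture_positive", "empiric_abx", "n_abx_started")
  if (is.null(candidates)) {
    candidates <- intersect(default_cands, names(mean_dat))
  }
  screening <- univariate_screen(mean_dat, outcome)
  if (screen) {
    keep <- screening$variable[screening$selected & !screening$zero_variance]
    # transformed terms follow their screened parent variable
    if ("crp" %in% keep) keep <- union(keep, CRP_HIGHER)
    if ("csf_leukocytes" %in% keep) {
      keep <- union(keep, "csf_leukocytes_log")
    }
    candidates <- intersect(candidates, keep)
  }
  selection <- backward_select(imp, candidates, outcome, alpha)
  opt <- bootstrap_optimism(imp, selection$selected, outcome, B, seed)
  pooled <- selection$pooled
  beta <- setNames(pooled$estimate, pooled$term)
  shrunk <- beta[setdiff(names(beta), "(Intercept)")] * opt$shrinkage
  intercept <- recalibrate_intercept(mean_dat, outcome, shrunk)
  rule <- new_prediction_rule(intercept, shrunk, opt$shrinkage, "fitted")
  structure(list(rule = rule, screening = screening, selection = selection,
                 pooled = pooled, optimism = opt,
                 n = nrow(mean_dat), events = sum(mean_dat[[outcome]]),
                 m = imp$m),
            class = "drm_model")
}

# Re-estimate the intercept for a fixed (shrunk) linear predictor.
recalibrate_intercept <- function(data, outcome, beta) {
  lp <- drop(as.matrix(data[names(beta)]) %*% beta)
  y <- data[[outcome]]
  fit <- suppressWarnings(glm(y ~ offset(lp), family = binomial()))
  unname(coef(fit)[1])
}
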