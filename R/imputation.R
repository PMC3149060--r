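# Multiple imputation by chained equations, and Rubin's-rule pooling.
#
# Continuous variables are imputed by predictive mean matching (type-1
# PMM: regression coefficients are drawn from their approximate
# posterior, the imputed value is copied from one of the k nearest
# observed donors on the predicted scale, so imputations stay on the
# support of the data). Binary variables are imputed from a logistic
# model with a posterior draw of the coefficients. The outcome is
# always included as a predictor of missingness. Deterministically
# derived columns (CRP polynomial terms, log CSF leukocytes) are
# recomputed from their parents after each sweep rather than imputed.

DERIVED_COLUMNS <- c("crp_sq", "crp_cu", "csf_leukocytes_log",
                     "csf_leuko_binary")
ID_COLUMNS <- c("episode_id", "year", "days_at_risk")

#' Multiple imputation of missing episode-level predictors
#'
#' Produces `m` completed copies of the feature matrix by chained
#' equations (10 sweeps per imputation; PMM for continuous, logistic
#' for binary variables), with fixed per-imputation sub-seeds derived
#' from `seed`. Observed cells are identical across all copies.
#'
#' @param features A `drm_features` tibble (may contain `NA` cells).
#' @param m Number of imputations (default 10).
#' @param seed Integer master seed.
#' @param outcome Name of the outcome column included as predictor of
#'   missingness (default `"drm_flag"`).
#' @param sweeps Chained-equation sweeps per imputation (default 10).
#' @param donors PMM donor pool size (default 5).
#' @param min_observed Minimum observed fraction required per variable
#'   (default 0.1).
#' @return An object of class `drm_imputation`: list with `matrices`
#'   (list of `m` completed tibbles), `m`, `seed` and `method`.
#' @export
impute_features <- function(features, m = 10, seed = 1L,
                            outcome = "drm_flag", sweeps = 10,
                            donors = 5, min_observed = 0.1) {
  if (m < 2) abort("`m` must be at least 2.")
  dat <- tibble::as_tibble(features)
  work_cols <- setdiff(names(dat)[vapply(dat, is.numeric, logical(1))],
                       c(DERIVED_COLUMNS, ID_COLUMNS))
  frac_obs <- vapply(dat[work_cols], function(x) mean(!is.na(x)), numeric(1))
  if (any(frac_obs == 0)) {
    abort(paste0("all-missing column(s): ",
                 paste(work_cols[frac_obs == 0], collapse = ", ")))
  }
  if (any(frac_obs < min_observed)) {
    warn(paste0("variable(s) observed in under ",
                round(100 * min_observed), "% of episodes: ",
                paste(work_cols[frac_obs < min_observed], collapse = ", ")))
  }
  miss_cols <- work_cols[frac_obs < 1]
  binary <- vapply(dat[work_cols], is_binary_col, logical(1))

  sub_seeds <- seed + 1000L * seq_len(m)
  matrices <- purrr::map(sub_seeds, function(s) {
    set.seed(s)
    complete_one(dat, work_cols, miss_cols, binary, outcome,
                 sweeps, donors)
  })
  structure(list(matrices = matrices, m = m, seed = as.integer(seed),
                 method = "chained-equations (PMM/logistic)"),
            class = "drm_imputation")
}

is_binary_col <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2 && all(u %in% c(0, 1))
}

complete_one <- function(dat, work_cols, miss_cols, binary, outcome,
                         sweeps, donors) {
  filled <- dat
  na_idx <- lapply(dat[miss_cols], function(x) which(is.na(x)))
  # initial fill: random draws from the observed values
  for (v in miss_cols) {
    obs <- dat[[v]][!is.na(dat[[v]])]
    filled[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]),
                                       replace = TRUE)
  }
  if (length(miss_cols) == 0) return(recompute_derived(filled))
  for (it in seq_len(sweeps)) {
    for (v in miss_cols) {
      idx <- na_idx[[v]]
      if (length(idx) == 0) next
      preds <- setdiff(work_cols, v)
      if (outcome %in% names(dat)) preds <- union(preds, outcome)
      X <- scale_design(filled[preds])
      y <- filled[[v]]
      filled[[v]][idx] <- if (binary[[v]]) {
        impute_logistic(X, y, idx)
      } else {
        impute_pmm(X, y, idx, donors)
      }
    }
  }
  recompute_derived(filled)
}

# Drop constant columns and build a numerically stable design matrix.
scale_design <- function(df) {
  mat <- as.matrix(df)
  keep <- apply(mat, 2, function(x) stats::sd(x) > 0)
  cbind(`(Intercept)` = 1, mat[, keep, drop = FALSE])
}

# Posterior draw of least-squares coefficients, then donor matching on
# the predicted scale.
impute_pmm <- function(X, y, idx, donors) {
  obs <- setdiff(seq_along(y), idx)
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  ok <- !is.na(fit$coefficients)
  beta <- fit$coefficients[ok]
  Xo <- X[obs, ok, drop = FALSE]
  df <- max(length(obs) - sum(ok), 1)
  sigma2 <- sum(fit$residuals^2) / df
  XtX <- crossprod(Xo)
  V <- tryCatch(sigma2 * solve(XtX + diag(1e-8, ncol(Xo))),
                error = function(e) diag(1e-8, ncol(Xo)))
  beta_dot <- beta + drop(chol_or_zero(V) %*% rnorm(length(beta)))
  yhat_obs <- drop(Xo %*% beta)
  yhat_mis <- drop(X[idx, ok, drop = FALSE] %*% beta_dot)
  vapply(yhat_mis, function(p) {
    d <- abs(yhat_obs - p)
    pool <- obs[order(d)][seq_len(min(donors, length(obs)))]
    y[pool[sample.int(length(pool), 1)]]
  }, numeric(1))
}

impute_logistic <- function(X, y, idx) {
  obs <- setdiff(seq_along(y), idx)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X[obs, , drop = FALSE], y[obs],
                             family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) {
    p_obs <- mean(y[obs])
    return(as.numeric(runif(length(idx)) < p_obs))
  }
  W <- fit$weights
  XtWX <- crossprod(X[obs, , drop = FALSE] * sqrt(W))
  V <- tryCatch(solve(XtWX + diag(1e-8, ncol(X))),
                error = function(e) diag(1e-8, ncol(X)))
  beta_dot <- fit$coefficients + drop(chol_or_zero(V) %*% rnorm(ncol(X)))
  p <- plogis(drop(X[idx, , drop = FALSE] %*% beta_dot))
  as.numeric(runif(length(idx)) < p)
}

chol_or_zero <- function(V) {
  tryCatch(t(chol(V)), error = function(e) matrix(0, nrow(V), ncol(V)))
}

recompute_derived <- function(filled) {
  if ("crp" %in% names(filled)) {
    filled$crp_sq <- (filled$crp / 10)^2
    filled$crp_cu <- (filled$crp / 100)^3
  }
  if ("csf_leukocytes" %in% names(filled)) {
    filled$csf_leukocytes_log <- log(filled$csf_leukocytes + CSF_LOG_OFFSET)
    if ("csf_leuko_binary" %in% names(filled)) {
      thr <- 5
      filled$csf_leuko_binary <- as.numeric(filled$csf_leukocytes > thr)
    }
  }
  filled
}

#' Pool per-imputation estimates with Rubin's rules
#'
#' For each coefficient: pooled estimate is the mean across
#' imputations; total variance is the mean within-imputation variance
#' plus `(1 + 1/m)` times the between-imputation variance; degrees of
#' freedom follow Rubin's small-sample formula.
#'
#' @param estimates m-by-p matrix (or m-vector) of per-imputation
#'   estimates.
#' @param variances Matching matrix of squared standard errors.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `within`, `between`, `variance`, `std.error`, `df`, `statistic`,
#'   `p.value`.
#' @export
#' @examples
#' pool_rubin(matrix(c(0, 1), 2), matrix(c(0, 0), 2))
pool_rubin <- function(estimates, variances) {
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  if (!all(dim(estimates) == dim(variances))) {
    abort("`estimates` and `variances` must have identical dimensions.")
  }
  m <- nrow(estimates)
  if (m < 2) abort("pooling requires m >= 2 imputations.")
  q_bar <- unname(colMeans(estimates))
  w_bar <- unname(colMeans(variances))
  b <- unname(apply(estimates, 2, var))
  t_var <- w_bar + (1 + 1 / m) * b
  df <- ifelse(b > 0, (m - 1) * (1 + w_bar / ((1 + 1 / m) * b))^2, Inf)
  se <- sqrt(t_var)
  stat <- ifelse(se > 0, q_bar / se, Inf * sign(q_bar))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  tibble::tibble(
    term = colnames(estimates) %||% paste0("x", seq_along(q_bar)),
    estimate = q_bar, within = w_bar, between = b, variance = t_var,
    std.error = se, df = df, statistic = stat, p.value = p
  )
}

#' Cell-wise mean dataset of an imputation set
#'
#' Continuous cells are averaged across the `m` completed matrices;
#' binary cells take the majority vote (ties resolved to the positive
#' class). Used for univariate screening "in the mean dataset".
#'
#' @param imp A `drm_imputation` object.
#' @return A single completed tibble.
#' @export
mean_dataset <- function(imp) {
  stopifnot(inherits(imp, "drm_imputation"))
  base <- imp$matrices[[1]]
  num_cols <- names(base)[vapply(base, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, ID_COLUMNS)
  out <- base
  for (v in num_cols) {
    stack <- vapply(imp$matrices, function(mdat) mdat[[v]],
                    numeric(nrow(base)))
    if (nrow(base) == 1) stack <- matrix(stack, nrow = 1)
    if (is_binary_col(base[[v]])) {
      out[[v]] <- as.numeric(rowMeans(stack) >= 0.5)
    } else {
      out[[v]] <- rowMeans(stack)
    }
  }
  recompute_derived(out)
}

#' @export
print.drm_imputation <- function(x, ...) {
  cat("<drm_imputation> m =", x$m, "completed matrices, seed", x$seed,
      "\n  method:", x$method, "\n")
  invisible(x)
}
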