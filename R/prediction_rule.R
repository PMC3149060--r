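# The prediction rule: an intercept plus a map of log-odds coefficients
# defining the linear predictor LP, with P(DRM) = 1 / (1 + exp(-LP)).

new_prediction_rule <- function(intercept, coefficients, shrinkage,
                                provenance) {
  if (shrinkage <= 0 || shrinkage > 1) {
    abort("shrinkage must lie in (0, 1].")
  }
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients,
                 shrinkage = shrinkage,
                 provenance = provenance),
            class = "drm_rule")
}

#' Odds ratios of the reference drain-related meningitis rule
#'
#' The multivariable odds ratios reported for the original development
#' cohort: drain type (EVD) 5.26, number of drains 2.04, CRP 1.02 per
#' mg/L, (CRP/10)^2 0.99, (CRP/100)^3 1.26, blood leukocytes 1.08, CSF
#' leukocytes (log) 1.42, positive drain/CSF culture 13.70, empiric
#' antibiotic therapy 1.32, number of antibiotics started 4.33.
#'
#' @return Named numeric vector of odds ratios, names matching the
#'   feature columns of [extract_features()].
#' @export
reference_odds_ratios <- function() {
  c(drain_type_evd = 5.26, n_drains = 2.04, crp = 1.02, crp_sq = 0.99,
    crp_cu = 1.26, blood_leukocytes = 1.08, csf_leukocytes_log = 1.42,
    culture_positive = 13.70, empiric_abx = 1.32, n_abx_started = 4.33)
}

#' Assemble a prediction rule from coefficients or published odds ratios
#'
#' Two modes. With `provenance = "fitted"`, `or` is interpreted as the
#' odds-ratio map of a model developed on the data at hand (coefficients
#' `log(or)`), and `intercept` must be supplied. With
#' `provenance = "published"` the intercept — which reports of the
#' reference rule do not include — is calibrated by root-finding so
#' that the mean predicted probability on `reference_data` equals
#' `prevalence`.
#'
#' @param or Named numeric vector of odds ratios (all positive).
#' @param provenance `"fitted"` or `"published"`.
#' @param intercept Intercept on the log-odds scale (fitted mode).
#' @param reference_data Completed feature tibble used to calibrate the
#'   intercept (published mode).
#' @param prevalence Target mean predicted probability (default 0.153).
#' @param shrinkage Multiplicative shrinkage already applied (recorded,
#'   default 1).
#' @return A `drm_rule` object.
#' @export
#' @examples
#' log(13.70) # coefficient implied by the culture odds ratio
build_prediction_rule <- function(or,
                                  provenance = c("published", "fitted"),
                                  intercept = NULL,
                                  reference_data = NULL,
                                  prevalence = 0.153,
                                  shrinkage = 1) {
  provenance <- match.arg(provenance)
  if (any(or <= 0)) abort("odds ratios must be positive.")
  if (is.null(names(or)) || any(!nzchar(names(or)))) {
    abort("`or` must be a named vector.")
  }
  beta <- log(or)
  if (provenance == "fitted") {
    if (is.null(intercept)) abort("fitted mode requires an intercept.")
    return(new_prediction_rule(intercept, beta, shrinkage, "fitted"))
  }
  if (is.null(reference_data)) {
    abort("published mode requires `reference_data` for calibration.")
  }
  lp0 <- drop(as.matrix(reference_data[names(beta)]) %*% beta)
  f <- function(a) mean(plogis(a + lp0)) - prevalence
  a <- uniroot(f, c(-50, 50), tol = 1e-10)$root
  new_prediction_rule(a, beta, shrinkage, "published")
}

#' Predicted probability of drain-related meningitis
#'
#' Computes `P = 1 / (1 + exp(-LP))` with
#' `LP = intercept + sum(beta * x)`. Scoring requires every rule
#' predictor to be observed: missing values cannot be imputed for an
#' individual patient, so a missing predictor raises an error rather
#' than a silent guess.
#'
#' @param rule A `drm_rule`.
#' @param features Tibble (or named list/vector) containing every rule
#'   predictor.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(rule, features) {
  stopifnot(inherits(rule, "drm_rule"))
  nm <- names(rule$coefficients)
  if (is.vector(features) && !is.list(features)) {
    features <- tibble::as_tibble(as.list(features))
  }
  missing_cols <- setdiff(nm, names(features))
  if (length(missing_cols)) {
    abort(paste0("cannot score: predictor(s) absent: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(features[nm])
  if (anyNA(X)) {
    abort(paste0(
      "cannot score episodes with missing predictor values ",
      "(single-patient imputation is not possible); affected rows: ",
      paste(head(which(rowSums(is.na(X)) > 0), 5), collapse = ", ")))
  }
  plogis(rule$intercept + drop(X %*% rule$coefficients))
}

#' @export
print.drm_rule <- function(x, ...) {
  cat("<drm_rule>", x$provenance, "\n")
  cat("  P(DRM) = 1 / (1 + exp(-LP))\n")
  cat(sprintf("  LP = %.4f\n", x$intercept))
  for (nm in names(x$coefficients)) {
    cat(sprintf("     %+.4f * %s\n", x$coefficients[[nm]], nm))
  }
  cat(sprintf("  shrinkage applied: %.3f\n", x$shrinkage))
  invisible(x)
}
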