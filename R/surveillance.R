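# Group-level surveillance: summed predicted probabilities as expected
# infection counts, per calendar period, with rates per 1000 drainage
# days at risk.

#' Period-level surveillance summary from summed predicted probabilities
#'
#' For each calendar period the expected number of infections is the
#' sum of predicted probabilities; the predicted rate is
#' `1000 * sum(p) / sum(days at risk)`. When the reference outcome is
#' supplied the observed count and rate are reported alongside.
#' Confidence intervals: normal approximation with variance
#' `sum(p * (1 - p))` for the expected count (Poisson-binomial), exact
#' Poisson for the observed count.
#'
#' @param data Tibble with one row per episode: a `probability` column,
#'   `year` (or other period label), `days_at_risk`, and optionally the
#'   outcome column named by `truth`.
#' @param truth Optional name of the binary outcome column.
#' @param level Confidence level (default 0.95).
#' @return A tibble of class `drm_surveillance`, one row per period.
#' @export
surveillance_summary <- function(data, truth = NULL, level = 0.95) {
  stopifnot(all(c("probability", "year", "days_at_risk") %in% names(data)))
  z <- qnorm(1 - (1 - level) / 2)
  out <- data |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(
      episodes = dplyr::n(),
      days_at_risk = sum(.data$days_at_risk),
      expected_infections = sum(.data$probability),
      expected_var = sum(.data$probability * (1 - .data$probability)),
      .groups = "drop"
    )
  if (any(out$days_at_risk <= 0)) {
    abort("zero days at risk in a period.")
  }
  out$predicted_rate <- 1000 * out$expected_infections / out$days_at_risk
  se_count <- sqrt(out$expected_var)
  out$expected_low <- pmax(0, out$expected_infections - z * se_count)
  out$expected_high <- out$expected_infections + z * se_count
  out$predicted_rate_low <- 1000 * out$expected_low / out$days_at_risk
  out$predicted_rate_high <- 1000 * out$expected_high / out$days_at_risk
  if (!is.null(truth)) {
    obs <- data |>
      dplyr::group_by(year = .data$year) |>
      dplyr::summarise(observed_infections = sum(.data[[truth]]),
                       .groups = "drop")
    out <- dplyr::left_join(out, obs, by = "year")
    pois_ci <- t(vapply(out$observed_infections, function(k) {
      poisson.test(k, conf.level = level)$conf.int
    }, numeric(2)))
    out$observed_rate <- 1000 * out$observed_infections / out$days_at_risk
    out$observed_rate_low <- 1000 * pois_ci[, 1] / out$days_at_risk
    out$observed_rate_high <- 1000 * pois_ci[, 2] / out$days_at_risk
  }
  out$expected_var <- NULL
  class(out) <- c("drm_surveillance", class(out))
  out
}
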