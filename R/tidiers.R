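# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a prediction rule
#'
#' @param x A `drm_rule`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (log-odds) and
#'   `odds.ratio`, the intercept first.
#' @export
tidy.drm_rule <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    odds.ratio = c(NA_real_, unname(exp(x$coefficients)))
  )
}

#' Tidy a developed model (Rubin-pooled coefficient table)
#'
#' @param x A `drm_model` from [develop_model()].
#' @param ... Unused.
#' @return The pooled coefficient tibble (`term`, `estimate`,
#'   `std.error`, `df`, `statistic`, `p.value`, ...), before shrinkage.
#' @export
tidy.drm_model <- function(x, ...) x$pooled

#' One-row model summary
#'
#' @param x A `drm_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `events`, `m`, `n_predictors`,
#'   `shrinkage`, `apparent_auc`, `corrected_auc`.
#' @export
glance.drm_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, events = x$events, m = x$m,
    n_predictors = length(x$rule$coefficients),
    shrinkage = x$rule$shrinkage,
    apparent_auc = x$optimism$apparent_auc,
    corrected_auc = x$optimism$corrected_auc
  )
}

#' Tidy a confusion report
#'
#' @param x A `drm_confusion`.
#' @param ... Unused.
#' @return A tibble with the cut-off attached as a column.
#' @export
tidy.drm_confusion <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$cutoff <- attr(x, "cutoff")
  out
}

#' @export
print.drm_model <- function(x, ...) {
  cat("<drm_model>", x$n, "episodes,", x$events, "events, m =", x$m, "\n")
  cat(sprintf("  shrinkage %.3f | apparent AUC %.3f | corrected AUC %.3f\n",
              x$rule$shrinkage, x$optimism$apparent_auc,
              x$optimism$corrected_auc))
  cat("  predictors:", paste(names(x$rule$coefficients), collapse = ", "),
      "\n")
  invisible(x)
}
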