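# ggplot2 graphics for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Calibration plot
#'
#' Observed infection proportion against mean predicted probability per
#' risk bin, with exact binomial intervals; the dashed diagonal is
#' ideal calibration.
#'
#' @param object A `drm_calibration` from [calibration_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drm_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_predicted,
                                       y = .data$observed)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability of infection",
                  y = "Observed proportion infected",
                  title = "Calibration of the prediction rule") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `drm_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drm_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr,
                                             y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC %.3f, 95%% CI %.3f-%.3f)",
                      object$auc, object$conf.low, object$conf.high)) +
    ggplot2::theme_minimal()
}

#' Yearly surveillance plot (observed vs expected rates)
#'
#' Predicted (summed-probability) and observed infection rates per 1000
#' drainage days at risk, by calendar year, with confidence intervals.
#'
#' @param object A `drm_surveillance` from [surveillance_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.drm_surveillance <- function(object, ...) {
  pred <- tibble::tibble(
    year = object$year, series = "predicted",
    rate = object$predicted_rate,
    low = object$predicted_rate_low, high = object$predicted_rate_high)
  dat <- pred
  if ("observed_rate" %in% names(object)) {
    obs <- tibble::tibble(
      year = object$year, series = "observed",
      rate = object$observed_rate,
      low = object$observed_rate_low, high = object$observed_rate_high)
    dat <- dplyr::bind_rows(pred, obs)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$rate,
                                    colour = .data$series)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$low, ymax = .data$high),
      position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = "Year",
                  y = "Infections per 1000 drainage days at risk",
                  colour = NULL,
                  title = "Observed vs predicted yearly infection rates") +
    ggplot2::theme_minimal()
}
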