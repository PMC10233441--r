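# ggplot2 display methods for the result types.

#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$fraction_positive)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), show.legend = FALSE) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Fraction of positives",
                  title = "Calibration") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cost_curve <- function(object, ...) {
  best <- object$threshold[which.min(abs(object$mean_cost))]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$mean_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::labs(x = "Threshold", y = "Mean cost-benefit",
                  title = sprintf("Cost-benefit curve (cutoff %.2f)", best)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.permutation_importance <- function(object, top_n = 15, ...) {
  d <- head(object, top_n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance,
                                  y = stats::reorder(.data$feature,
                                                     .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Normalized permutation importance", y = NULL,
                  title = "Feature impact") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hcal_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_hcal), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "Age (years)", y = "HCAL index",
                  title = "Health condition without activity limitation by age") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hly_result <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object), c("ex", "hly"),
                           names_to = "measure", values_to = "years")
  d$measure <- dplyr::recode(d$measure, ex = "Life expectancy",
                             hly = "Healthy life years")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$start, y = .data$years,
                                  colour = .data$measure)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Age (years)", y = "Expected years remaining",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve points
#'
#' Sensitivity / 1-specificity pairs over all distinct prediction
#' thresholds, for plotting.
#'
#' @param labels 0/1 outcome vector.
#' @param probabilities predicted probabilities.
#' @return a tibble of class `roc_curve` with `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(labels, probabilities) {
  y <- as.numeric(labels)
  ths <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  out <- tibble::tibble(
    threshold = ths,
    tpr = vapply(ths, function(t) sum(probabilities >= t & y == 1) / n1,
                 numeric(1)),
    fpr = vapply(ths, function(t) sum(probabilities >= t & y == 0) / n0,
                 numeric(1))
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}
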