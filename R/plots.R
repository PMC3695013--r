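#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_step geom_abline
#'   geom_boxplot geom_point labs theme_minimal coord_cartesian
NULL

#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A [roc_curve()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.brainage_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC (AUC = %.2f)", object$auc)) +
    theme_minimal()
}

#' Plot Kaplan-Meier cumulative incidence curves
#'
#' Cumulative AD incidence `1 - S(t)` per stratum; follow-up display is
#' truncated (default 1250 days).
#'
#' @param object A [kaplan_meier()] result.
#' @param truncate_days Right edge of the time axis.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.brainage_km <- function(object, truncate_days = 1250, ...) {
  ggplot(object$curves,
         aes(x = .data$time, y = .data$cumulative_incidence,
             colour = .data$stratum)) +
    geom_step() +
    coord_cartesian(xlim = c(0, truncate_days), ylim = c(0, 1)) +
    labs(x = "days from baseline", y = "cumulative AD incidence",
         colour = NULL) +
    theme_minimal()
}

#' Box plots of a baseline score across diagnostic groups
#'
#' @param data A cohort data frame.
#' @param value,group Columns (unquoted).
#' @return A ggplot.
#' @export
plot_group_scores <- function(data, value, group) {
  vq <- enquo(value); gq <- enquo(group)
  ggplot(data, aes(x = !!gq, y = !!vq)) +
    geom_boxplot() +
    theme_minimal()
}

#' Estimated versus chronological age
#'
#' @param data A tibble from [estimate_brain_age()].
#' @return A ggplot.
#' @export
plot_brainage <- function(data) {
  ggplot(data, aes(x = .data$chronological_age, y = .data$estimated_age)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(x = "chronological age (years)", y = "estimated brain age (years)") +
    theme_minimal()
}
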