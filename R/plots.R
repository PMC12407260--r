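#' Plot a biological-age clock's coefficients
#'
#' Bar chart of the clock's years-per-unit coefficients, the direct
#' reading of how a one-unit biomarker shift moves biological age.
#'
#' @param object A [bioage_clock].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bioage_clock <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(constant)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term, .data$estimate),
                                   y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "years of biological age per unit",
                  title = paste0("Clock coefficients (", object$provenance, ")")) +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves from km_quantile_groups()
#'
#' Step survival curves for the fast- and slow-ageing tails, faceted by
#' age stratum when present, with Greenwood log-log confidence ribbons.
#'
#' @param curves Tibble returned by [km_quantile_groups()].
#' @return A ggplot object.
#' @export
plot_km <- function(curves) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group, fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::labs(x = "years of follow-up", y = "survival probability",
                  colour = "age-gap group", fill = "age-gap group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (length(unique(curves$stratum)) > 1) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}

#' Plot the cross-validated C-index across the penalty path
#'
#' @param object A `selection_result` from [lasso_cox_select()].
#' @param ... Unused.
#' @return A ggplot object; the chosen penalty is marked with a dashed
#'   line.
#' @export
autoplot.selection_result <- function(object, ...) {
  cv <- object$cv_cindex
  ggplot2::ggplot(cv, ggplot2::aes(x = log(.data$lambda), y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$chosen_lambda),
                        linetype = "dashed") +
    ggplot2::labs(x = "log(lambda)", y = "cross-validated C-index",
                  title = "LASSO-Cox penalty path") +
    ggplot2::theme_minimal()
}

#' @rdname evaluate_clocks
#' @param object An `evaluation_report`.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("c_index", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$clock, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Discrimination (AUC horizon ",
                                 object$horizon, " y)")) +
    ggplot2::theme_minimal()
}
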