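#' Plot INR trajectories of a simulated cohort
#'
#' Spaghetti plot of per-patient INR over follow-up with the target band
#' shaded.
#'
#' @param object A `ptml_cohort`.
#' @param max_patients Cap on the number of trajectories drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ptml_cohort <- function(object, max_patients = 40, ...) {
  ids <- utils::head(unique(object$visits$patient_id), max_patients)
  v <- object$visits[object$visits$patient_id %in% ids, ]
  tgt <- object$params$target_inr
  ggplot2::ggplot(v, ggplot2::aes(x = .data$day, y = .data$inr,
                                  group = .data$patient_id)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = tgt[1], ymax = tgt[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "Days since first dose", y = "INR",
                  title = "Simulated INR trajectories",
                  subtitle = sprintf("target band [%g, %g]",
                                     tgt[1], tgt[2])) +
    ggplot2::theme_minimal()
}

#' Plot the coefficients of a linear IFPTML model
#'
#' @param object A `ptml_linear_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ptml_linear_model <- function(object, ...) {
  df <- tidy.ptml_linear_model(object)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Coefficient", y = NULL,
                  title = sprintf("Linear discriminant (%s level)",
                                  object$level)) +
    ggplot2::theme_minimal()
}

#' Predicted-bias plot for a regression model
#'
#' Histogram of `PB = 100 * (pred - obs) / obs` with the ideal band
#' (|PB| <= 20%) shaded.
#'
#' @param obs,pred Observed and predicted INR vectors.
#' @param binwidth Histogram bin width (%).
#' @return A ggplot object.
#' @export
plot_predicted_bias <- function(obs, pred, binwidth = 5) {
  df <- tibble::tibble(pb = predicted_bias(obs, pred))
  bins <- pb_bins(obs, pred)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pb)) +
    ggplot2::annotate("rect", xmin = -20, xmax = 20, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "forestgreen") +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::labs(x = "Predicted bias (%)", y = "Cases",
                  title = "Predicted bias",
                  subtitle = sprintf("ideal: %.1f%% of predictions",
                                     bins$pb_ideal)) +
    ggplot2::theme_minimal()
}
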