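# Diagnostic plots: per-unit significance, the null histogram behind a
# single branch or population, and the event-count likelihood path.

#' @describeIn test_differentiation Significance overview: -log10 p per
#'   tested unit, coloured by direction, with units at `q < 0.05`
#'   labelled.
#' @param object A `drift_test`.
#' @param q_threshold Highlight threshold.
#' @method autoplot drift_test
#' @export
autoplot.drift_test <- function(object, q_threshold = 0.05, ...) {
  res <- object$results
  unit <- if (object$mode == "branch") "branch" else "population"
  res$unit <- res[[unit]]
  ggplot2::ggplot(res, ggplot2::aes(
    x = stats::reorder(.data$unit, -.data$p),
    y = -log10(.data$p),
    fill = .data$direction
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_point(
      data = res[res$q < q_threshold, , drop = FALSE],
      ggplot2::aes(y = -log10(.data$p) + 0.1), shape = 8, show.legend = FALSE
    ) +
    ggplot2::scale_fill_manual(values = c(increased = "#c0392b",
                                          decreased = "#27ae60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = unit, y = expression(-log[10](p)),
      fill = "risk in descendants",
      title = sprintf("Risk differentiation vs drift (K = %d draws)", object$K),
      subtitle = sprintf("* marks q < %g", q_threshold)
    ) +
    ggplot2::theme_minimal()
}

#' Null distribution behind one tested unit
#'
#' Histogram of the matched-panel null deviations for a single branch or
#' population with the observed deviation marked: the expected amount of
#' risk difference under genetic drift versus what was seen.
#'
#' @param test A `drift_test` built with `keep_null = TRUE`.
#' @param unit Branch id (branch mode) or population (population mode).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(test, unit, bins = 60) {
  if (is.null(test$null)) abort("test was built with keep_null = FALSE")
  key <- if (test$mode == "branch") "branch" else "population"
  i <- match(unit, test$results[[key]])
  if (is.na(i)) abort(paste0("unknown unit: ", unit))
  df <- tibble::tibble(deviation = test$null[i, ])
  obs <- test$results$observed[i]
  ggplot2::ggplot(df, ggplot2::aes(.data$deviation)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs, colour = "#c0392b", linewidth = 1) +
    ggplot2::labs(
      x = "risk difference under matched random panels",
      y = "draws",
      title = sprintf("%s: observed %.3f, p = %.3g (K = %d)",
                      unit, obs, test$results$p[i], test$K)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn infer_events Log-likelihood path over candidate event
#'   counts with the supported count marked.
#' @param object An `event_model`.
#' @param ... Unused.
#' @method autoplot event_model
#' @export
autoplot.event_model <- function(object, ...) {
  df <- object$models
  ggplot2::ggplot(df, ggplot2::aes(.data$n_events, .data$log_lik)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$n_events == object$chosen_n),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey30")) +
    ggplot2::scale_x_continuous(breaks = df$n_events) +
    ggplot2::labs(
      x = "independent differentiation events",
      y = "log-likelihood",
      title = sprintf("%d event(s) supported (chi-squared LRT, alpha = %g)",
                      object$chosen_n, object$alpha)
    ) +
    ggplot2::theme_minimal()
}
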