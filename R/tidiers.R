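# broom-style accessors for the package's fitted objects.

#' @describeIn test_differentiation Per-unit results table of a
#'   `drift_test` (one row per branch or population).
#' @param x A `drift_test`.
#' @param ... Unused.
#' @method tidy drift_test
#' @export
tidy.drift_test <- function(x, ...) {
  x$results
}

#' @describeIn test_differentiation One-row summary of a `drift_test`:
#'   mode, units tested, draws, attained minimum p and q, seed.
#' @method glance drift_test
#' @export
glance.drift_test <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_units = nrow(x$results),
    K = x$K,
    n_panel_snps = nrow(x$panel),
    min_p = min(x$results$p),
    min_q = min(x$results$q),
    n_significant_q = sum(x$results$q < 0.05),
    seed = x$seed %||% NA_integer_
  )
}

#' @describeIn infer_events Per-model table of an `event_model`: one row
#'   per candidate event count with its log-likelihood, LRT p-value and
#'   event branches.
#' @param x An `event_model`.
#' @param ... Unused.
#' @method tidy event_model
#' @export
tidy.event_model <- function(x, ...) {
  x$models
}

#' @describeIn infer_events One-row summary of an `event_model`.
#' @method glance event_model
#' @export
glance.event_model <- function(x, ...) {
  chosen <- x$models[x$models$n_events == x$chosen_n, ]
  tibble::tibble(
    chosen_n = x$chosen_n,
    alpha = x$alpha,
    log_lik = chosen$log_lik,
    null_log_lik = x$null_log_lik,
    events = paste(chosen$events[[1]], collapse = ",")
  )
}
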