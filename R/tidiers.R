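#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a concordance result
#'
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble(
    term = sprintf("%s_c(%s)", x$method, x$score),
    estimate = x$c_index, std.error = x$se,
    conf.low = x$ci_lower, conf.high = x$ci_upper
  )
}

#' @rdname tidy.concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(
    c_index = x$c_index, method = x$method,
    truncation_time = x$truncation_time, n = x$n, n_events = x$n_events
  )
}

#' Tidy an NRI result
#'
#' @param x An `nri_result`.
#' @param ... Unused.
#' @return One row per component (`overall`, `event`, `nonevent`) with
#'   bootstrap bounds when present.
#' @export
tidy.nri_result <- function(x, ...) {
  out <- tibble(
    term = c("overall", "event", "nonevent"),
    estimate = c(x$overall, x$event_nri, x$nonevent_nri)
  )
  if (!is.null(x$ci)) {
    out$std.error <- x$ci$se
    out$conf.low <- x$ci$lower
    out$conf.high <- x$ci$upper
  }
  out
}

#' @rdname tidy.nri_result
#' @export
glance.nri_result <- function(x, ...) {
  tibble(
    overall = x$overall, event_nri = x$event_nri,
    nonevent_nri = x$nonevent_nri, variant = x$variant,
    tau = x$tau, recalibrated = x$recalibrated, n = x$n
  )
}

#' Tidy a calibration result
#'
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @return The per-partition observed/expected table.
#' @export
tidy.calibration_result <- function(x, ...) {
  x$table
}

#' @rdname tidy.calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble(
    chi_square = x$chi_square, n_partitions = x$n_partitions,
    threshold = x$threshold, lack_of_fit = x$lack_of_fit, tau = x$tau
  )
}

#' Tidy a recalibration result
#'
#' @param x A `recalibration_result`.
#' @param ... Unused.
#' @export
tidy.recalibration_result <- function(x, ...) {
  tibble(
    scale_factor = x$scale_factor,
    observed_incidence = x$observed_incidence,
    mean_predicted_before = x$mean_predicted_before,
    mean_predicted_after = x$mean_predicted_after
  )
}
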