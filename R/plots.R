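#' Scatterplot of updated versus baseline predicted risk
#'
#' Draws the `p_new` versus `p_old` scatter with the identity line
#' (points above it were moved up by the factor update) and optional
#' horizontal/vertical reference lines at risk thresholds, faceted by
#' outcome status.  Use `limits` to reproduce either the full-range or
#' the zoomed (e.g. 0-0.05) panels.
#'
#' @param object A `stroke_scatter` table from [scatter_data()].
#' @param thresholds Optional numeric risk thresholds drawn as reference
#'   lines on both axes.
#' @param limits Optional axis limit pair, e.g. `c(0, 0.05)`.
#' @param group_censored_with_events Plot censored subjects in the case
#'   panel (as in plots that pool cases and censored subjects) rather
#'   than in their own panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stroke_scatter <- function(object, thresholds = NULL, limits = NULL,
                                    group_censored_with_events = FALSE, ...) {
  d <- as_tibble(object)
  if (group_censored_with_events) {
    d$panel <- ifelse(d$status == "nonevent", "controls", "cases (incl. censored)")
  } else {
    d$panel <- as.character(d$status)
  }
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$p_old, y = .data$p_new)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(
      x = "baseline ten-year risk (p_old)",
      y = "updated ten-year risk (p_new)",
      title = sprintf(
        "Risk reclassification %s recalibration",
        if (isTRUE(attr(object, "recalibrated"))) "after" else "before"
      )
    )
  if (!is.null(thresholds)) {
    g <- g +
      ggplot2::geom_hline(yintercept = thresholds, linetype = "dotted") +
      ggplot2::geom_vline(xintercept = thresholds, linetype = "dotted")
  }
  if (!is.null(limits)) {
    g <- g + ggplot2::coord_cartesian(xlim = limits, ylim = limits)
  }
  g
}

#' @rdname autoplot.stroke_scatter
#' @param pairs Prediction pairs (see [make_prediction_pairs()]).
#' @param tau Horizon in years.
#' @param recalibrated Metadata flag for the title.
#' @export
plot_risk_scatter <- function(pairs, tau = 10, recalibrated = FALSE,
                              thresholds = NULL, limits = NULL, ...) {
  autoplot.stroke_scatter(
    scatter_data(pairs, tau = tau, recalibrated = recalibrated),
    thresholds = thresholds, limits = limits, ...
  )
}

#' Observed versus expected events per risk partition
#'
#' @param object A `calibration_result` from [hosmer_lemeshow()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_result <- function(object, ...) {
  d <- object$table
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "expected events (sum of predicted risks)",
      y = "observed events (n x KM incidence)",
      title = sprintf(
        "Hosmer-Lemeshow partitions (%s): chi-square = %.1f",
        object$score, object$chi_square
      )
    )
}
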