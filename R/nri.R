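#' Risk class scheme for the class NRI
#'
#' Three risk classes defined by two quantile cut points of each model's
#' own predicted-risk distribution (so the absolute thresholds differ
#' between models, as each model's quantiles are used).
#'
#' @param cut_points Two strictly increasing probabilities in (0, 1),
#'   e.g. `c(0.7, 0.9)` or `c(0.95, 0.99)`.
#' @return An object of class `risk_class_scheme`.
#' @export
risk_class_scheme <- function(cut_points = c(0.7, 0.9)) {
  if (length(cut_points) != 2 || is.unsorted(cut_points, strictly = TRUE) ||
    any(cut_points <= 0 | cut_points >= 1)) {
    stop_config("cut_points must be two strictly increasing probabilities in (0, 1)")
  }
  structure(list(cut_points = cut_points), class = "risk_class_scheme")
}

risk_classes <- function(p, thresholds) {
  1L + (p > thresholds[1]) + (p > thresholds[2])
}

# Kaplan-Meier-adjusted NRI from up/down movement indicators.  Event and
# non-event proportions among movers are estimated with the product-limit
# incidence at tau inside each movement group (risk-set weighting), rather
# than by deleting censored subjects, which would bias the components.
nri_from_moves <- function(up, down, time, event, tau) {
  n <- length(up)
  if (n == 0) stop_undefined("no subjects")
  p_all <- km_inc_at(time, event, tau)
  if (p_all <= 0) stop_undefined("no events by tau: event NRI undefined")
  if (p_all >= 1) stop_undefined("no non-events by tau: non-event NRI undefined")
  pi_up <- mean(up)
  pi_dn <- mean(down)
  p_up <- if (any(up)) km_inc_at(time[up], event[up], tau) else 0
  p_dn <- if (any(down)) km_inc_at(time[down], event[down], tau) else 0
  event_nri <- (p_up * pi_up - p_dn * pi_dn) / p_all
  nonevent_nri <- ((1 - p_dn) * pi_dn - (1 - p_up) * pi_up) / (1 - p_all)
  c(
    overall = event_nri + nonevent_nri,
    event = event_nri,
    nonevent = nonevent_nri
  )
}

nri_result <- function(pairs, moves_fn, variant, tau, thresholds = NULL,
                       recalibrated = NA, ci = FALSE, B = 1000, seed = 1) {
  require_columns(pairs, c("p_old", "p_new", "time", "event"), "prediction pairs")
  stat_one <- function(d) {
    mv <- moves_fn(d)
    nri_from_moves(mv$up, mv$down, d$time, d$event, tau)
  }
  est <- stat_one(pairs)
  cis <- NULL
  if (ci) cis <- bootstrap_ci(pairs, stat_one, B = B, seed = seed)
  structure(
    list(
      overall = est[["overall"]], event_nri = est[["event"]],
      nonevent_nri = est[["nonevent"]], variant = variant, tau = tau,
      thresholds = thresholds, recalibrated = recalibrated,
      ci = cis, n = nrow(pairs)
    ),
    class = "nri_result"
  )
}

#' Net reclassification improvement of one risk model over another
#'
#' `classless_nri()` treats the predicted probabilities as continuous:
#' any increase (`p_new > p_old`) is an upward move and any decrease a
#' downward move.  `class_nri()` counts movements across three risk
#' classes whose thresholds are the scheme's quantiles of each model's
#' own predicted risks.  For both variants the event NRI is
#' `P(up | event by tau) - P(down | event by tau)` and the non-event NRI
#' the same with directions reversed; the overall NRI is their sum, so
#' the additivity identity `overall = event + nonevent` holds by
#' construction.  Event status under censoring is estimated with the
#' Kaplan-Meier incidence at `tau` inside each movement group.
#'
#' @param pairs Prediction pairs (see [make_prediction_pairs()]).
#' @param tau Horizon in years.
#' @param scheme A [risk_class_scheme()] (class variant).
#' @param recalibrated Metadata flag recorded in the result.
#' @param ci Compute percentile-bootstrap intervals for all components?
#' @param B,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return An object of class `nri_result` with components `overall`,
#'   `event_nri`, `nonevent_nri` (each in \[-1, 1\], overall in \[-2, 2\]),
#'   and a `ci` tibble when requested.
#' @export
classless_nri <- function(pairs, tau = 10, recalibrated = NA,
                          ci = FALSE, B = 1000, seed = 1) {
  moves <- function(d) list(up = d$p_new > d$p_old, down = d$p_new < d$p_old)
  nri_result(pairs, moves,
    variant = "classless", tau = tau,
    recalibrated = recalibrated, ci = ci, B = B, seed = seed
  )
}

#' @rdname classless_nri
#' @export
class_nri <- function(pairs, scheme = risk_class_scheme(), tau = 10,
                      recalibrated = NA, ci = FALSE, B = 1000, seed = 1) {
  if (!inherits(scheme, "risk_class_scheme")) stop_config("scheme must be a risk_class_scheme")
  moves <- function(d) {
    thr_old <- quantile(d$p_old, scheme$cut_points, names = FALSE)
    thr_new <- quantile(d$p_new, scheme$cut_points, names = FALSE)
    cl_old <- risk_classes(d$p_old, thr_old)
    cl_new <- risk_classes(d$p_new, thr_new)
    list(up = cl_new > cl_old, down = cl_new < cl_old)
  }
  thresholds <- list(
    p_old = quantile(pairs$p_old, scheme$cut_points, names = FALSE),
    p_new = quantile(pairs$p_new, scheme$cut_points, names = FALSE)
  )
  nri_result(pairs, moves,
    variant = "class", tau = tau, thresholds = thresholds,
    recalibrated = recalibrated, ci = ci, B = B, seed = seed
  )
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "%s NRI (tau = %g, n = %d): overall %.4f  event %.4f  non-event %.4f\n",
    x$variant, x$tau, x$n, x$overall, x$event_nri, x$nonevent_nri
  ))
  if (!is.null(x$ci)) {
    for (i in seq_len(nrow(x$ci))) {
      cat(sprintf(
        "  %-9s 95%% CI [%.4f, %.4f]\n",
        x$ci$term[i], x$ci$lower[i], x$ci$upper[i]
      ))
    }
  }
  invisible(x)
}
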