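#' Kaplan-Meier cumulative incidence at a horizon
#'
#' Computes one minus the product-limit survival estimate at `horizon`,
#' the censoring-robust observed event probability used as the
#' recalibration target and as the "observed" quantity in the survival
#' Hosmer-Lemeshow statistic.
#'
#' @param time Follow-up times in years (all positive).
#' @param event Logical (or 0/1) event indicator.
#' @param horizon Time at which the cumulative incidence is evaluated.
#' @return A single probability in \[0, 1\].
#' @examples
#' km_incidence(c(1, 2, 3, 4, 11), c(TRUE, FALSE, TRUE, FALSE, FALSE), 10)
#' @export
km_incidence <- function(time, event, horizon) {
  if (length(time) == 0) stop_config("at least one subject is required")
  if (any(time <= 0)) stop_config("all follow-up times must be positive")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  s <- summary(fit, times = horizon, extend = TRUE)$surv
  1 - s
}

# Fast product-limit cumulative incidence at a single time point.  Same
# risk-set convention as survfit (ties: events precede censorings); used in
# bootstrap and replicate loops where a full survfit per call would dominate
# the runtime.  Cross-checked against survival::survfit in the test suite.
km_inc_at <- function(time, event, at) {
  n <- length(time)
  o <- order(time)
  t_s <- time[o]
  d_s <- event[o] != 0
  ev_t <- t_s[d_s & t_s <= at]
  if (!length(ev_t)) return(0)
  tk <- unique(ev_t)
  dk <- tabulate(match(ev_t, tk))
  nk <- n - findInterval(tk, t_s, left.open = TRUE) # subjects with time >= tk
  1 - prod(1 - dk / nk)
}

# Kaplan-Meier of the censoring distribution, evaluated as the left limit
# G(s-) at each time in `at_times` (censoring weights for Uno's C use the
# value just before the event time).  Ties: censorings act after events, so
# subjects with an event at t are still at risk for censoring at t.
censor_surv_before <- function(time, event, at_times) {
  n <- length(time)
  o <- order(time)
  t_s <- time[o]
  cens <- !(event[o] != 0)
  ct <- t_s[cens]
  if (!length(ct)) return(rep(1, length(at_times)))
  tk <- unique(ct)
  dk <- tabulate(match(ct, tk))
  nk <- n - findInterval(tk, t_s, left.open = TRUE)
  g_steps <- cumprod(1 - dk / nk)
  idx <- findInterval(at_times, tk, left.open = TRUE) # censoring times < s
  c(1, g_steps)[idx + 1L]
}
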