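#' Concordance statistics for censored survival predictions
#'
#' A pair of subjects is usable when the shorter observed time is an event
#' time (so the ordering of their survival times is known despite
#' censoring); the pair is concordant when that subject also has the
#' higher predicted risk.  `harrell_c()` is the classic proportion of
#' concordant usable pairs (score ties credited 1/2; tied event times
#' yield no usable pair).  `uno_c()` truncates usable pairs at `tau` and
#' weights each by the inverse squared Kaplan-Meier censoring survival
#' just before the event time (IPCW), which removes the dependence of the
#' estimand on the censoring distribution.  With no censoring before
#' `tau` every weight is exactly 1 and the two statistics coincide.
#'
#' @param pairs Prediction pairs from [make_prediction_pairs()].
#' @param score Column used to rank subjects, `"p_old"` or `"p_new"`.
#' @param tau Truncation time in years (Uno only).
#' @param ci Compute a percentile-bootstrap confidence interval?
#' @param B,seed Bootstrap resamples and seed (see [bootstrap_ci()]).
#' @return An object of class `concordance_result`: `c_index`, `se`,
#'   `ci_lower`, `ci_upper`, `method`, `truncation_time`, `n`, `n_events`.
#' @export
harrell_c <- function(pairs, score = "p_new", ci = FALSE, B = 1000, seed = 1) {
  concordance_result(pairs, score,
    method = "harrell", tau = Inf,
    ci = ci, B = B, seed = seed
  )
}

#' @rdname harrell_c
#' @export
uno_c <- function(pairs, score = "p_new", tau = 10, ci = FALSE, B = 1000, seed = 1) {
  concordance_result(pairs, score,
    method = "uno", tau = tau,
    ci = ci, B = B, seed = seed
  )
}

# shared pairwise engine; `weights` are per-subject IPCW weights applied to
# every usable pair led by that subject.  Keeping one code path (weights
# identically 1 for Harrell) makes the two statistics bitwise identical
# when no subject is censored before tau.
c_statistic <- function(time, event, score, tau = Inf, weights = NULL) {
  n <- length(time)
  if (n < 2) stop_undefined("concordance needs at least two subjects")
  ev <- which(event & time < tau)
  if (is.null(weights)) weights <- rep(1, n)
  num <- 0
  den <- 0
  for (i in ev) {
    later <- time > time[i]
    nj <- sum(later)
    if (nj == 0) next
    s <- score[later]
    conc <- sum(score[i] > s) + 0.5 * sum(score[i] == s)
    num <- num + weights[i] * conc
    den <- den + weights[i] * nj
  }
  if (den == 0) stop_undefined("no usable pairs: no event precedes another subject's follow-up")
  list(c_index = num / den, n_events = length(ev))
}

concordance_result <- function(pairs, score, method, tau, ci, B, seed) {
  require_columns(pairs, c(score, "time", "event"), "prediction pairs")
  stat_one <- function(d) {
    w <- NULL
    if (method == "uno") {
      g <- censor_surv_before(d$time, d$event, d$time)
      usable <- d$event & d$time < tau
      if (any(usable & g == 0)) {
        abort(paste(
          "censoring survival reaches 0 before an event inside tau;",
          "IPCW weights explode -- lower tau below the last censoring time"
        ), class = "strokesynth_weight_error")
      }
      w <- 1 / g^2
    }
    c_statistic(d$time, d$event, d[[score]], tau = tau, weights = w)
  }
  est <- stat_one(pairs)
  se <- NA_real_
  lo <- NA_real_
  hi <- NA_real_
  if (ci) {
    bs <- bootstrap_ci(pairs, function(d) c(c_index = stat_one(d)$c_index),
      B = B, seed = seed
    )
    se <- bs$se
    lo <- bs$lower
    hi <- bs$upper
  }
  structure(
    list(
      c_index = est$c_index, se = se, ci_lower = lo, ci_upper = hi,
      method = method, truncation_time = tau, n = nrow(pairs),
      n_events = est$n_events, score = score
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "%s C (%s%s): %.4f%s\n",
    if (x$method == "uno") "Uno's" else "Harrell's", x$score,
    if (is.finite(x$truncation_time)) sprintf(", tau = %g", x$truncation_time) else "",
    x$c_index,
    if (!is.na(x$ci_lower)) sprintf("  [%.4f, %.4f]", x$ci_lower, x$ci_upper) else ""
  ))
  invisible(x)
}
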