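#' Recalibrate predicted risks to an observed incidence
#'
#' Intercept-only recalibration on the cumulative-hazard scale: each
#' prediction is mapped to `p' = 1 - (1 - p)^c` with one scalar `c > 0`
#' solved (by geometric bisection, the mean being monotone in `c`) so that
#' `mean(p')` equals the observed cumulative incidence to within `tol`.
#' The transform is strictly monotone, so risk rankings -- and with them
#' the concordance statistics -- are unchanged.  If the mean already
#' matches the target within `tol`, `c` is exactly 1 and the predictions
#' are returned untouched, which makes the operation idempotent.
#'
#' @param predictions Probabilities in \[0, 1).
#' @param observed Target cumulative incidence in (0, 1), typically from
#'   [km_incidence()].
#' @param tol Tolerance on the matched mean (default 1e-8).
#' @return A list with `predictions` (recalibrated) and `result`, an
#'   object of class `recalibration_result` holding the scale factor and
#'   the before/after means.
#' @examples
#' r <- recalibrate(rep(0.10, 5), observed = 0.05)
#' r$result$scale_factor # log(0.95) / log(0.90)
#' @export
recalibrate <- function(predictions, observed, tol = 1e-8) {
  p <- predictions
  if (any(p < 0 | p >= 1)) stop_domain("predictions must lie in [0, 1)")
  if (length(observed) != 1 || observed <= 0 || observed >= 1) {
    stop_config("observed incidence must lie strictly in (0, 1)")
  }
  if (all(p == 0)) {
    abort("all predictions are zero; no hazard rescaling can reach a positive incidence",
      class = "strokesynth_calibration_error"
    )
  }
  fmean <- function(cc) mean(1 - (1 - p)^cc)
  before <- mean(p)
  if (abs(before - observed) <= tol) {
    cc <- 1
    pr <- p
  } else {
    lo <- 1e-6
    hi <- 1e6
    if (fmean(lo) - observed > 0 || fmean(hi) - observed < 0) {
      abort("observed incidence is outside the reachable range of the hazard rescaling",
        class = "strokesynth_calibration_error"
      )
    }
    for (i in seq_len(300)) {
      cc <- sqrt(lo * hi)
      fm <- fmean(cc)
      if (abs(fm - observed) <= tol) break
      if (fm < observed) lo <- cc else hi <- cc
    }
    pr <- 1 - (1 - p)^cc
  }
  result <- structure(
    list(
      scale_factor = cc, observed_incidence = observed,
      mean_predicted_before = before, mean_predicted_after = mean(pr)
    ),
    class = "recalibration_result"
  )
  list(predictions = pr, result = result)
}

#' Recalibrate score columns of a cohort against its Kaplan-Meier incidence
#'
#' Data-frame front end to [recalibrate()]: the observed incidence is the
#' Kaplan-Meier cumulative incidence of the table's own follow-up at
#' `tau` (the raw event fraction would be biased downward by censoring),
#' and each listed column is rescaled to match it.
#'
#' @param data Table with `time`, `event` and the score columns.
#' @param columns Score columns to recalibrate.
#' @param tau Horizon in years.
#' @return `data` with the columns replaced; the per-column
#'   `recalibration_result`s are attached as attribute `"recalibration"`.
#' @export
recalibrate_cohort <- function(data, columns = c("p_old", "p_new"), tau = 10) {
  require_columns(data, c("time", "event", columns), "scored cohort")
  observed <- km_incidence(data$time, data$event, tau)
  results <- list()
  for (cl in columns) {
    r <- recalibrate(data[[cl]], observed)
    data[[cl]] <- r$predictions
    results[[cl]] <- r$result
  }
  attr(data, "recalibration") <- results
  data
}

#' @export
print.recalibration_result <- function(x, ...) {
  cat(sprintf(
    "Recalibration: scale factor %.6g\n  mean predicted %.5f -> %.5f (observed %.5f)\n",
    x$scale_factor, x$mean_predicted_before, x$mean_predicted_after,
    x$observed_incidence
  ))
  invisible(x)
}
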