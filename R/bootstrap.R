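#' Percentile-bootstrap confidence interval for a pairs statistic
#'
#' Resamples subjects with replacement `B` times, applies `stat_fn` to
#' each resample, and returns the 2.5/97.5 percentile bounds (and the
#' bootstrap standard deviation as `se`) per statistic component.
#' Deterministic given `seed`.  Resamples on which the statistic is
#' undefined are dropped; the statistic is declared unstable if more than
#' 10% of resamples fail.
#'
#' @param pairs Prediction pairs (any per-subject table).
#' @param stat_fn Function of a resampled table returning a (named)
#'   numeric vector.
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per component: `term`, `se`, `lower`,
#'   `upper`, `n_failed`.
#' @export
bootstrap_ci <- function(pairs, stat_fn, B = 1000, seed = 1, conf = 0.95) {
  if (B < 100) stop_config("use at least 100 bootstrap resamples")
  n <- nrow(pairs)
  set.seed(seed)
  vals <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[[b]] <- tryCatch(
      stat_fn(pairs[idx, , drop = FALSE]),
      error = function(e) NULL
    )
  }
  ok <- !vapply(vals, is.null, logical(1))
  if (mean(!ok) > 0.10) {
    abort(sprintf(
      "statistic undefined on %d of %d bootstrap resamples; too unstable for a percentile interval",
      sum(!ok), B
    ), class = "strokesynth_unstable_error")
  }
  m <- do.call(rbind, vals[ok])
  if (is.null(colnames(m))) colnames(m) <- paste0("statistic", seq_len(ncol(m)))
  alpha <- (1 - conf) / 2
  tibble(
    term = colnames(m),
    se = apply(m, 2, sd),
    lower = apply(m, 2, quantile, probs = alpha, names = FALSE),
    upper = apply(m, 2, quantile, probs = 1 - alpha, names = FALSE),
    n_failed = sum(!ok)
  )
}
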