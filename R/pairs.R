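#' Assemble prediction pairs for model comparison
#'
#' The comparison metrics all consume one row per subject holding the two
#' competing ten-year risks alongside the censored outcome.  `sex` is kept
#' when present so results can be stratified with [subgroup()].
#'
#' @param data A scored cohort with `id`, `p_old`, `p_new`, `time`, `event`.
#' @return A tibble of prediction pairs.
#' @export
make_prediction_pairs <- function(data) {
  require_columns(data, c("id", "p_old", "p_new", "time", "event"), "scored cohort")
  out <- select(data, all_of(c("id", "p_old", "p_new", "time", "event")), any_of("sex"))
  if (any(out$p_old < 0 | out$p_old > 1 | out$p_new < 0 | out$p_new > 1)) {
    stop_domain("predicted risks must lie in [0, 1]")
  }
  if (any(out$time <= 0)) stop_domain("follow-up times must be positive")
  as_tibble(out)
}

#' Restrict prediction pairs to one sex
#'
#' @param pairs Prediction pairs carrying a `sex` column.
#' @param sex `"male"` or `"female"`.
#' @export
subgroup <- function(pairs, sex) {
  require_columns(pairs, "sex", "prediction pairs")
  sx <- sex
  out <- filter(pairs, .data$sex == sx)
  if (nrow(out) == 0) stop_config(sprintf("subgroup '%s' is empty", sex))
  out
}
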