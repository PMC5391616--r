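#' Survival Hosmer-Lemeshow calibration statistic
#'
#' Subjects are ranked by predicted risk into `n_partitions` equal-count
#' groups.  Per group, the expected event count is the sum of predicted
#' risks and the observed count is the group size times the group's
#' Kaplan-Meier cumulative incidence at `tau` (censoring-robust).  The
#' statistic is `sum((O - E)^2 / (E * (1 - E/n)))`; values above the
#' working threshold of 20 flag lack of fit.  Groups with a degenerate
#' expected count (0 or the full group) are merged into their neighbour
#' and the merge is reported.
#'
#' @param pairs Prediction pairs (see [make_prediction_pairs()]).
#' @param score Risk column to calibrate, `"p_old"` or `"p_new"`.
#' @param tau Horizon in years.
#' @param n_partitions Number of risk-ordered groups (default 10).
#' @param threshold Lack-of-fit flag threshold (default 20).
#' @return An object of class `calibration_result`: `chi_square`,
#'   `n_partitions` (after merges), `lack_of_fit` and the per-partition
#'   table.
#' @export
hosmer_lemeshow <- function(pairs, score = "p_new", tau = 10,
                            n_partitions = 10, threshold = 20) {
  require_columns(pairs, c(score, "time", "event"), "prediction pairs")
  if (n_partitions < 2) stop_config("n_partitions must be at least 2")
  p <- pairs[[score]]
  grp <- ntile(p, n_partitions)
  groups <- split(seq_along(p), grp)
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop_config("empty partition; reduce n_partitions")
  }

  cell <- function(idx) {
    e <- sum(p[idx])
    o <- length(idx) * km_inc_at(pairs$time[idx], pairs$event[idx], tau)
    c(n = length(idx), expected = e, observed = o)
  }
  degenerate <- function(idx) {
    e <- sum(p[idx])
    e <= 0 || e >= length(idx)
  }
  # merge degenerate groups (usually an all-zero-risk tail) into a neighbour
  i <- 1L
  while (i <= length(groups)) {
    if (length(groups) > 1 && degenerate(groups[[i]])) {
      j <- if (i == 1L) 2L else i - 1L
      inform(sprintf("merging degenerate risk partition %d into its neighbour", i))
      groups[[j]] <- c(groups[[j]], groups[[i]])
      groups[[i]] <- NULL
      i <- 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(groups) == 1 && degenerate(groups[[1]])) {
    stop_config("expected event counts are degenerate in every partition")
  }

  tab <- t(vapply(groups, cell, numeric(3)))
  tab <- as_tibble(tab)
  tab$partition <- seq_len(nrow(tab))
  tab$km_incidence <- tab$observed / tab$n
  chi <- sum((tab$observed - tab$expected)^2 /
    (tab$expected * (1 - tab$expected / tab$n)))
  structure(
    list(
      chi_square = chi, n_partitions = nrow(tab), threshold = threshold,
      lack_of_fit = chi > threshold, tau = tau, score = score,
      table = select(
        tab, all_of(c("partition", "n", "expected", "observed", "km_incidence"))
      )
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Hosmer-Lemeshow (%s, %d partitions, tau = %g): chi-square = %.2f%s\n",
    x$score, x$n_partitions, x$tau, x$chi_square,
    if (x$lack_of_fit) sprintf("  ** exceeds %g: lack of fit", x$threshold) else ""
  ))
  invisible(x)
}
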