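#' Define a literature-derived risk factor
#'
#' A literature factor carries a relative-risk function, the factor's
#' distribution in a reference population, and an optional applicability
#' predicate.  During synthesis each factor contributes the standardized
#' multiplier `rr(x) / E[rr(X)]`, where the expectation runs over the
#' reference distribution, so that the population-average update is
#' neutral (mean multiplier exactly 1).
#'
#' Three kinds are supported:
#' * `"binary"`: `rr` is the exposed relative risk, `reference` the exposure
#'   prevalence; the unexposed level is the reference (rr 1).
#' * `"categorical"`: `levels`, per-level `rr` (at least one level must have
#'   rr 1), `reference` the level prevalences (sum 1).
#' * `"continuous"`: inner `breaks` define left-closed bins covering the
#'   real line; `rr` and `reference` are per-bin (piecewise-constant
#'   relative risk, as literature values are usually reported per category).
#'
#' @param name Factor name.
#' @param kind `"binary"`, `"categorical"` or `"continuous"`.
#' @param rr Relative risk(s), all positive.
#' @param reference Reference-population distribution (prevalence, level
#'   probabilities, or per-bin masses).
#' @param levels Category labels (categorical only).
#' @param breaks Inner breakpoints (continuous only); bins are
#'   `[-Inf, b1), [b1, b2), ..., [bk, Inf)`.
#' @param column Cohort column the factor reads; defaults to `name`.
#' @param applies `NULL` (everyone), the string `"postmenopausal_female"`,
#'   or a predicate `function(data)` returning a logical vector.
#'   Inapplicable subjects receive multiplier exactly 1.
#' @return An object of class `literature_factor`.
#' @examples
#' f <- literature_factor("ethnicity_aa", "binary", rr = 1.8, reference = 0.2)
#' standardized_multiplier(f, c(TRUE, FALSE))
#' @export
literature_factor <- function(name, kind = c("binary", "categorical", "continuous"),
                              rr, reference, levels = NULL, breaks = NULL,
                              column = name, applies = NULL) {
  kind <- match.arg(kind)
  if (any(rr <= 0) || !all(is.finite(rr))) {
    stop_config(sprintf("factor '%s': all relative risks must be positive and finite", name))
  }
  if (kind == "binary") {
    if (length(rr) != 1 || length(reference) != 1) {
      stop_config(sprintf("factor '%s': binary factors take scalar rr and prevalence", name))
    }
    if (reference < 0 || reference > 1) {
      stop_config(sprintf("factor '%s': prevalence must lie in [0, 1]", name))
    }
  } else {
    k <- if (kind == "categorical") length(levels) else length(breaks) + 1L
    if (kind == "categorical" && (is.null(levels) || k < 2)) {
      stop_config(sprintf("factor '%s': categorical factors need >= 2 levels", name))
    }
    if (kind == "continuous" && (is.null(breaks) || is.unsorted(breaks, strictly = TRUE))) {
      stop_config(sprintf("factor '%s': breaks must be strictly increasing", name))
    }
    if (length(rr) != k || length(reference) != k) {
      stop_config(sprintf("factor '%s': rr and reference must have one entry per level/bin", name))
    }
    if (any(reference < 0) || abs(sum(reference) - 1) > 1e-8) {
      stop_config(sprintf("factor '%s': reference distribution must be non-negative and sum to 1", name))
    }
    if (sum(reference) == 0) {
      stop_config(sprintf("factor '%s': reference distribution has zero mass", name))
    }
    if (!any(rr == 1)) {
      stop_config(sprintf("factor '%s': some level/bin must be the reference (rr exactly 1)", name))
    }
  }
  structure(
    list(
      name = name, kind = kind, rr = unname(rr), reference = unname(reference),
      levels = levels, breaks = breaks, column = column, applies = applies
    ),
    class = "literature_factor"
  )
}

# mean relative risk over the reference distribution
expected_rr <- function(factor) {
  if (factor$kind == "binary") {
    (1 - factor$reference) + factor$reference * factor$rr
  } else {
    sum(factor$reference * factor$rr)
  }
}

rr_value <- function(factor, value) {
  switch(factor$kind,
    binary = ifelse(as.logical(value), factor$rr, 1),
    categorical = {
      i <- match(as.character(value), factor$levels)
      if (anyNA(i)) {
        stop_domain(sprintf(
          "factor '%s': value(s) outside levels %s",
          factor$name, paste(factor$levels, collapse = "/")
        ))
      }
      factor$rr[i]
    },
    continuous = {
      if (any(!is.finite(value))) {
        stop_domain(sprintf("factor '%s': non-finite value", factor$name))
      }
      factor$rr[findInterval(value, factor$breaks) + 1L]
    }
  )
}

factor_applicable <- function(factor, data) {
  ap <- factor$applies
  if (is.null(ap)) {
    rep(TRUE, nrow(data))
  } else if (is.function(ap)) {
    as.logical(ap(data))
  } else if (identical(ap, "postmenopausal_female")) {
    require_columns(data, c("sex", "postmenopausal"), "cohort table")
    data$sex == "female" & data$postmenopausal
  } else {
    stop_config(sprintf("factor '%s': unknown applicability rule '%s'", factor$name, ap))
  }
}

#' Standardized relative-risk multiplier of one factor
#'
#' Returns `rr(value) / E[rr(X)]` with the expectation over the factor's
#' reference distribution; subjects flagged inapplicable get exactly 1.
#'
#' @param factor A [literature_factor()].
#' @param value Covariate values.
#' @param applicable Optional logical vector; `FALSE` entries return 1.
#' @return Positive multipliers, mean 1 over the reference population.
#' @export
standardized_multiplier <- function(factor, value, applicable = NULL) {
  e <- expected_rr(factor)
  if (e <= 0) stop_config(sprintf("factor '%s': degenerate reference distribution", factor$name))
  if (is.null(applicable)) applicable <- rep(TRUE, length(value))
  m <- rep(1, length(value))
  if (any(applicable)) {
    m[applicable] <- rr_value(factor, value[applicable]) / e
  }
  m
}

factor_multiplier_column <- function(factor, data) {
  require_columns(data, factor$column, "cohort table")
  standardized_multiplier(factor, data[[factor$column]],
    applicable = factor_applicable(factor, data)
  )
}

#' Apply the synthesis-analysis update to baseline risks
#'
#' Multiplies each subject's baseline cumulative hazard by the product of
#' the factors' standardized multipliers: `H_new = H_old * prod(m_f)`,
#' `p_new = 1 - exp(-H_new)` with `H_old = -log(1 - p_old)`.  The hazard
#' scale keeps `p_new` inside \[0, 1\] for any multiplier product and agrees
#' with the proportional-hazards form of the baseline model.  Rows whose
#' total multiplier is exactly 1 keep `p_old` bit-for-bit.
#'
#' @param data Table containing a `p_old` column (see [score_cohort()]).
#' @param factors List of [literature_factor()] objects (names unique).
#' @param p_old Column holding the baseline ten-year risk.
#' @return `data` with `synthesis_multiplier` and `p_new` appended.
#' @export
synthesize_risk <- function(data, factors, p_old = "p_old") {
  require_columns(data, p_old, "scored table")
  nms <- vapply(factors, function(f) f$name, character(1))
  if (anyDuplicated(nms)) stop_config("factor names must be unique")
  p <- data[[p_old]]
  if (any(p < 0 | p >= 1)) stop_domain("baseline risks must lie in [0, 1)")
  m <- rep(1, nrow(data))
  for (f in factors) m <- m * factor_multiplier_column(f, data)
  h_new <- -log1p(-p) * m
  p_new <- 1 - exp(-h_new)
  keep <- m == 1
  p_new[keep] <- p[keep]
  mutate(data, synthesis_multiplier = m, p_new = p_new)
}

#' Read / write a literature-factor file
#'
#' Factor files are JSON arrays of factor records.  The packaged
#' `example_factors()` file carries illustrative relative risks for the
#' seven added stroke risk factors (African American ethnicity, exercise
#' level, BMI, waist circumference, height, HDL cholesterol, and hormone
#' replacement therapy in postmenopausal women); the values are synthetic
#' placeholders for literature estimates, packaged so the pipeline runs
#' end to end.
#'
#' @param path JSON file path.
#' @return A list of `literature_factor` objects.
#' @export
read_factors <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  map(raw, function(r) {
    literature_factor(
      name = r$name,
      kind = r$kind,
      rr = as.numeric(unlist(r$rr)),
      reference = as.numeric(unlist(r$reference)),
      levels = if (!is.null(r$levels)) as.character(unlist(r$levels)),
      breaks = if (!is.null(r$breaks)) as.numeric(unlist(r$breaks)),
      column = r$column %||% r$name,
      applies = r$applies
    )
  })
}

#' @rdname read_factors
#' @export
example_factors <- function() {
  read_factors(system.file("extdata", "synthetic_example_factors.json",
    package = "strokesynth", mustWork = TRUE
  ))
}

#' @rdname read_factors
#' @param factors List of `literature_factor` objects.
#' @export
write_factors <- function(factors, path) {
  recs <- map(factors, function(f) {
    r <- list(
      name = f$name, kind = f$kind, rr = f$rr, reference = f$reference,
      levels = f$levels, breaks = f$breaks, column = f$column,
      applies = if (is.character(f$applies)) f$applies
    )
    r[!vapply(r, is.null, logical(1))]
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Estimate a reference distribution from cohort data
#'
#' Empirical counterpart of a factor's reference distribution: exposure
#' prevalence (binary), level proportions (categorical), or bin masses for
#' a continuous factor (either at supplied `breaks`, or at quantile bins
#' via `probs`).
#'
#' @param data Cohort table.
#' @param column Column to summarise.
#' @param kind Factor kind; see [literature_factor()].
#' @param levels Level set (categorical); defaults to observed sorted levels.
#' @param breaks Inner breakpoints (continuous).
#' @param probs Quantile probabilities used to *derive* breaks (continuous).
#' @return A list with the estimated `reference` masses (and `levels` or
#'   `breaks` where relevant), suitable for rebuilding a factor.
#' @export
fit_reference_distribution <- function(data, column,
                                       kind = c("binary", "categorical", "continuous"),
                                       levels = NULL, breaks = NULL, probs = NULL) {
  kind <- match.arg(kind)
  if (nrow(data) == 0) stop_config("cannot fit a reference distribution on an empty table")
  require_columns(data, column, "cohort table")
  v <- data[[column]]
  switch(kind,
    binary = list(reference = mean(as.logical(v))),
    categorical = {
      levels <- levels %||% sort(unique(as.character(v)))
      tab <- table(factor(as.character(v), levels = levels))
      list(levels = levels, reference = as.numeric(tab) / length(v))
    },
    continuous = {
      if (is.null(breaks)) {
        if (is.null(probs)) stop_config("continuous factors need `breaks` or `probs`")
        breaks <- unname(quantile(v, probs = probs))
      }
      bin <- findInterval(v, breaks) + 1L
      list(
        breaks = breaks,
        reference = tabulate(bin, nbins = length(breaks) + 1L) / length(v)
      )
    }
  )
}

#' Replace a factor's reference distribution
#'
#' @param factor A [literature_factor()].
#' @param fit Output of [fit_reference_distribution()].
#' @export
set_reference_distribution <- function(factor, fit) {
  literature_factor(
    name = factor$name, kind = factor$kind, rr = factor$rr,
    reference = fit$reference,
    levels = fit$levels %||% factor$levels,
    breaks = fit$breaks %||% factor$breaks,
    column = factor$column, applies = factor$applies
  )
}
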