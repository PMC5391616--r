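#' Configuration for the full simulate-score-recalibrate-evaluate pipeline
#'
#' @param generator A [generator_config()].
#' @param model A `cox_risk_model` or a path to a model JSON file;
#'   defaults to the packaged baseline stroke score.
#' @param factors A list of [literature_factor()]s or a path to a factor
#'   JSON file; defaults to the packaged illustrative factors.
#' @param schemes List of quantile cut-point pairs for the class NRI.
#' @param tau Evaluation horizon; defaults to the generator horizon.
#' @param bootstrap_B Bootstrap resamples for every interval.
#' @param seed Master seed propagated (with fixed offsets) to every
#'   stochastic stage.
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @param exclude_flag Optional prevalent-condition column dropped before
#'   scoring (see [exclude_prevalent()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            model = NULL, factors = NULL,
                            schemes = list(c(0.7, 0.9), c(0.95, 0.99)),
                            tau = generator$horizon_years,
                            bootstrap_B = 1000, seed = 1,
                            out_dir = NULL, exclude_flag = NULL) {
  if (is.null(model)) model <- fsrs_model()
  if (is.character(model)) model <- read_risk_model(model)
  if (is.null(factors)) factors <- example_factors()
  if (is.character(factors)) factors <- read_factors(factors)
  structure(
    list(
      generator = generator, model = model, factors = factors,
      schemes = schemes, tau = tau, bootstrap_B = bootstrap_B,
      seed = as.integer(seed), out_dir = out_dir, exclude_flag = exclude_flag
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      parent = e
    )
  })
  inform(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
  out
}

groups_of <- function(pairs) {
  out <- list(overall = pairs)
  if ("sex" %in% names(pairs)) {
    for (sx in c("male", "female")) {
      if (any(pairs$sex == sx)) out[[sx]] <- subgroup(pairs, sx)
    }
  }
  out
}

#' Evaluate two risk models on prediction pairs
#'
#' Computes, per group (overall/male/female), Uno's C for both models
#' (with bootstrap CIs), the Hosmer-Lemeshow statistic before and after
#' recalibration, the classless NRI before and after recalibration, and
#' the class NRI per scheme (quantile-based classes and concordance are
#' invariant under the monotone recalibration map, so those need no
#' before/after split).
#'
#' @param pairs Prediction pairs before recalibration.
#' @param pairs_recal The same pairs after [recalibrate_cohort()].
#' @param schemes List of class-NRI quantile cut-point pairs.
#' @param tau Horizon.
#' @param B,seed Bootstrap settings.
#' @return A list of tibbles: `concordance`, `hosmer_lemeshow`,
#'   `classless_nri`, `class_nri`.
#' @export
evaluate_models <- function(pairs, pairs_recal, schemes = list(c(0.7, 0.9)),
                            tau = 10, B = 1000, seed = 1) {
  grp <- groups_of(pairs)
  grp_rc <- groups_of(pairs_recal)
  seed_i <- seed

  conc <- list()
  for (g in names(grp)) {
    for (sc in c("p_old", "p_new")) {
      seed_i <- seed_i + 1L
      r <- uno_c(grp[[g]], score = sc, tau = tau, ci = TRUE, B = B, seed = seed_i)
      conc[[length(conc) + 1L]] <- tibble(
        group = g, model = sc, c_index = r$c_index, se = r$se,
        lower95 = r$ci_lower, upper95 = r$ci_upper
      )
    }
  }

  hl <- list()
  for (g in names(grp)) {
    for (sc in c("p_old", "p_new")) {
      for (stage in c("before", "after")) {
        d <- if (stage == "before") grp[[g]] else grp_rc[[g]]
        r <- hosmer_lemeshow(d, score = sc, tau = tau)
        hl[[length(hl) + 1L]] <- tibble(
          group = g, model = sc, recalibrated = stage == "after",
          chi_square = r$chi_square, n_partitions = r$n_partitions,
          lack_of_fit = r$lack_of_fit
        )
      }
    }
  }

  cnl <- list()
  for (g in names(grp)) {
    for (stage in c("before", "after")) {
      d <- if (stage == "before") grp[[g]] else grp_rc[[g]]
      seed_i <- seed_i + 1L
      r <- classless_nri(d,
        tau = tau, recalibrated = stage == "after",
        ci = TRUE, B = B, seed = seed_i
      )
      cnl[[length(cnl) + 1L]] <- tibble(
        group = g, recalibrated = stage == "after",
        term = r$ci$term,
        estimate = c(r$overall, r$event_nri, r$nonevent_nri),
        lower95 = r$ci$lower, upper95 = r$ci$upper
      )
    }
  }

  ccl <- list()
  for (si in seq_along(schemes)) {
    scheme <- risk_class_scheme(schemes[[si]])
    for (g in names(grp)) {
      seed_i <- seed_i + 1L
      r <- class_nri(grp[[g]],
        scheme = scheme, tau = tau,
        ci = TRUE, B = B, seed = seed_i
      )
      ccl[[length(ccl) + 1L]] <- tibble(
        scheme = paste(schemes[[si]], collapse = "/"),
        group = g, term = r$ci$term,
        estimate = c(r$overall, r$event_nri, r$nonevent_nri),
        lower95 = r$ci$lower, upper95 = r$ci$upper
      )
    }
  }

  list(
    concordance = bind_rows(conc),
    hosmer_lemeshow = bind_rows(hl),
    classless_nri = bind_rows(cnl),
    class_nri = bind_rows(ccl)
  )
}

#' Scatterplot data for comparing two sets of predicted risks
#'
#' One row per subject with both risks and a three-way outcome status at
#' `tau`: `event` (event by tau), `censored` (lost before tau without an
#' event), `nonevent` (followed to tau event-free).  Keeping censored
#' subjects separate lets plots group them either with cases or apart.
#'
#' @param pairs Prediction pairs.
#' @param tau Horizon in years.
#' @param recalibrated Metadata flag carried on the result.
#' @return A tibble of class `stroke_scatter`.
#' @export
scatter_data <- function(pairs, tau = 10, recalibrated = FALSE) {
  require_columns(pairs, c("p_old", "p_new", "time", "event"), "prediction pairs")
  status <- dplyr::case_when(
    pairs$event & pairs$time <= tau ~ "event",
    pairs$time < tau ~ "censored",
    .default = "nonevent"
  )
  out <- mutate(
    select(pairs, any_of(c("id", "sex")), all_of(c("p_old", "p_new"))),
    status = factor(status, levels = c("event", "censored", "nonevent"))
  )
  attr(out, "recalibrated") <- recalibrated
  attr(out, "tau") <- tau
  class(out) <- c("stroke_scatter", class(out))
  out
}

#' Run the full pipeline
#'
#' Simulate a cohort, score it with the baseline model and the
#' synthesis-updated model, recalibrate both risk sets to the cohort's
#' Kaplan-Meier incidence, evaluate every comparison statistic, and build
#' the scatterplot datasets.  With `out_dir` set, the cohort, scores,
#' recalibrated scores, JSON report, plain-text tables, scatter data and
#' a manifest (package version, seed, row counts, file hashes) are
#' written; rerunning the same configuration reproduces the bundle
#' bit-for-bit.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `cohort`, `scores`, `scores_recalibrated`,
#'   `recalibration`, `report`, `scatter_before`, `scatter_after`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_config("config must be a pipeline_config")

  cohort <- run_stage("simulate", {
    ch <- generate_cohort(config$generator)
    if (!is.null(config$exclude_flag)) ch <- exclude_prevalent(ch, config$exclude_flag)
    ch
  })

  scores <- run_stage("score", {
    score_cohort(cohort, model = config$model, factors = config$factors)
  })
  pairs <- make_prediction_pairs(scores)

  scores_recal <- run_stage("recalibrate", {
    recalibrate_cohort(scores, columns = c("p_old", "p_new"), tau = config$tau)
  })
  pairs_recal <- make_prediction_pairs(scores_recal)
  recal_info <- attr(scores_recal, "recalibration")

  report <- run_stage("evaluate", {
    evaluate_models(pairs, pairs_recal,
      schemes = config$schemes, tau = config$tau,
      B = config$bootstrap_B, seed = config$seed
    )
  })

  scat_before <- scatter_data(pairs, tau = config$tau, recalibrated = FALSE)
  scat_after <- scatter_data(pairs_recal, tau = config$tau, recalibrated = TRUE)

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- run_stage("write", {
      write_bundle(
        config, cohort, scores, scores_recal, recal_info, report,
        scat_before, scat_after
      )
    })
  }

  invisible(list(
    cohort = cohort, scores = scores, scores_recalibrated = scores_recal,
    recalibration = recal_info, report = report,
    scatter_before = scat_before, scatter_after = scat_after,
    manifest = manifest
  ))
}

write_bundle <- function(config, cohort, scores, scores_recal, recal_info,
                         report, scat_before, scat_after) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)

  write_cohort(cohort, path("cohort.csv"))
  keep <- intersect(c("id", "sex", "time", "event", "lp", "p_old", "p_new"), names(scores))
  write_cohort(scores[keep], path("scores.csv"))
  write_cohort(scores_recal[keep], path("scores_recalibrated.csv"))
  write_cohort(as_tibble(scat_before), path("scatter_before.csv"))
  write_cohort(as_tibble(scat_after), path("scatter_after.csv"))

  report_out <- c(report, list(
    recalibration = imap(recal_info, function(r, nm) {
      list(
        column = nm, scale_factor = r$scale_factor,
        observed_incidence = r$observed_incidence,
        mean_predicted_before = r$mean_predicted_before,
        mean_predicted_after = r$mean_predicted_after
      )
    })
  ))
  jsonlite::write_json(report_out, path("report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  writeLines(format_report(report), path("tables.txt"))

  files <- c(
    "cohort.csv", "scores.csv", "scores_recalibrated.csv",
    "scatter_before.csv", "scatter_after.csv", "report.json", "tables.txt"
  )
  manifest <- list(
    package = "strokesynth",
    version = as.character(utils::packageVersion("strokesynth")),
    seed = config$seed,
    generator_seed = config$generator$seed,
    n_subjects = nrow(cohort),
    rows = setNames(
      lapply(files, function(f) length(readLines(path(f), warn = FALSE)) - 1L),
      files
    ),
    md5 = as.list(tools::md5sum(vapply(files, path, character(1))))
  )
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, path("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}

#' Format the evaluation report as aligned plain-text tables
#'
#' @param report Output of [evaluate_models()].
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  lines <- character()
  add <- function(...) lines <<- c(lines, sprintf(...))

  add("== Uno's C-statistic ==")
  add("%-8s %-6s %8s %8s %8s %8s", "group", "model", "c.index", "se", "Lower95", "Upper95")
  for (i in seq_len(nrow(report$concordance))) {
    r <- report$concordance[i, ]
    add(
      "%-8s %-6s %8.3f %8.3f %8.3f %8.3f", r$group, r$model,
      r$c_index, r$se, r$lower95, r$upper95
    )
  }

  add("")
  add("== Hosmer-Lemeshow test ==")
  add("%-8s %-6s %-18s %10s", "group", "model", "stage", "chi-square")
  for (i in seq_len(nrow(report$hosmer_lemeshow))) {
    r <- report$hosmer_lemeshow[i, ]
    add(
      "%-8s %-6s %-18s %10.1f", r$group, r$model,
      if (r$recalibrated) "after recal." else "before recal.", r$chi_square
    )
  }

  add("")
  add("== Classless NRI ==")
  add("%-8s %-18s %-9s %9s %9s %9s", "group", "stage", "term", "point est", "Lower95", "Upper95")
  for (i in seq_len(nrow(report$classless_nri))) {
    r <- report$classless_nri[i, ]
    add(
      "%-8s %-18s %-9s %9.3f %9.3f %9.3f", r$group,
      if (r$recalibrated) "after recal." else "before recal.",
      r$term, r$estimate, r$lower95, r$upper95
    )
  }

  add("")
  add("== Class NRI ==")
  add("%-11s %-8s %-9s %9s %9s %9s", "scheme", "group", "term", "point est", "Lower95", "Upper95")
  for (i in seq_len(nrow(report$class_nri))) {
    r <- report$class_nri[i, ]
    add(
      "%-11s %-8s %-9s %9.3f %9.3f %9.3f", r$scheme, r$group,
      r$term, r$estimate, r$lower95, r$upper95
    )
  }
  lines
}
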