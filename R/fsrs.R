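#' Load a sex-specific Cox-form ten-year risk model
#'
#' A risk model file stores, per sex, a named vector of per-unit log-hazard
#' coefficients, the covariate values at which the linear predictor is
#' centred, and the baseline (centred-profile) survival probability at the
#' model horizon.  The ten-year event probability for a subject is
#' `1 - S0 ^ exp(lp)` where `lp` is the centred linear predictor.
#'
#' `fsrs_model()` loads the packaged Framingham stroke risk score file,
#' a transcription of the revised (medication-window) stroke profile; its
#' centring values and baseline survivals are representative values chosen
#' for this package and any compatible JSON file can be substituted via
#' `read_risk_model()`.
#'
#' @param path Path to a model JSON file.
#' @return An object of class `cox_risk_model`.
#' @export
read_risk_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  model <- cox_risk_model(
    male = list(
      coefficients = unlist(raw$male$coefficients),
      center = unlist(raw$male$center),
      baseline_survival = raw$male$baseline_survival
    ),
    female = list(
      coefficients = unlist(raw$female$coefficients),
      center = unlist(raw$female$center),
      baseline_survival = raw$female$baseline_survival
    ),
    horizon_years = raw$horizon_years %||% 10,
    name = raw$name %||% basename(path),
    version = raw$version %||% "unversioned"
  )
  model
}

#' @rdname read_risk_model
#' @export
fsrs_model <- function() {
  read_risk_model(system.file("extdata", "fsrs_model.json",
    package = "strokesynth",
    mustWork = TRUE
  ))
}

#' Construct a Cox-form risk model object
#'
#' @param male,female Lists with elements `coefficients` (named numeric),
#'   `center` (named numeric, same names) and `baseline_survival`
#'   (probability in (0, 1)).
#' @param horizon_years Prediction horizon.
#' @param name,version Identification strings carried into manifests.
#' @export
cox_risk_model <- function(male, female, horizon_years = 10,
                           name = "risk-model", version = "unversioned") {
  for (sx in list(male = male, female = female)) {
    if (!is.numeric(sx$coefficients) || is.null(names(sx$coefficients))) {
      stop_config("each sex needs a named numeric coefficient vector")
    }
    if (!all(is.finite(sx$coefficients))) {
      stop_config("all model coefficients must be finite")
    }
    if (!setequal(names(sx$coefficients), names(sx$center))) {
      stop_config("coefficient and centring names must agree")
    }
    s0 <- sx$baseline_survival
    if (!is.numeric(s0) || length(s0) != 1 || s0 <= 0 || s0 >= 1) {
      stop_config("baseline survival must be a probability in (0, 1)")
    }
  }
  if (horizon_years <= 0) stop_config("horizon_years must be positive")
  structure(
    list(
      male = male, female = female, horizon_years = horizon_years,
      name = name, version = version
    ),
    class = "cox_risk_model"
  )
}

#' Write a risk model to JSON
#' @param model A `cox_risk_model`.
#' @param path Output file.
#' @export
write_risk_model <- function(model, path) {
  out <- list(
    name = model$name, version = model$version,
    horizon_years = model$horizon_years,
    male = list(
      coefficients = as.list(model$male$coefficients),
      center = as.list(model$male$center),
      baseline_survival = model$male$baseline_survival
    ),
    female = list(
      coefficients = as.list(model$female$coefficients),
      center = as.list(model$female$center),
      baseline_survival = model$female$baseline_survival
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Effective antihypertensive-medication indicator
#'
#' The revised stroke profile applies the medication coefficient only while
#' systolic blood pressure lies inside a stated window; outside it the term
#' contributes nothing.  Boundaries are treated as inclusive.
#'
#' @param sbp Systolic blood pressure in mmHg.
#' @param on_med Logical, on antihypertensive treatment.
#' @param lower,upper Window bounds in mmHg.
#' @return Logical vector: medication term active.
#' @examples
#' apply_med_window(c(150, 205, 150), c(TRUE, TRUE, FALSE))
#' @export
apply_med_window <- function(sbp, on_med, lower = 110, upper = 200) {
  as.logical(on_med) & sbp >= lower & sbp <= upper
}

# Derived design columns shared by the scorer and the cohort generator so
# that e.g. the medication window means the same thing in both places.
design_column <- function(data, col) {
  # bin indicators mirror the packaged factor file's piecewise-constant
  # relative-risk bins, so a generating model can carry the exact same
  # hazard shape the synthesis update assumes
  bins <- list(
    bmi_lt25 = c("bmi", -Inf, 25), bmi_30_35 = c("bmi", 30, 35),
    bmi_ge35 = c("bmi", 35, Inf),
    waist_lt88 = c("waist", -Inf, 88), waist_ge102 = c("waist", 102, Inf),
    height_lt160 = c("height", -Inf, 160), height_170_180 = c("height", 170, 180),
    height_ge180 = c("height", 180, Inf),
    hdl_lt40 = c("hdl", -Inf, 40), hdl_50_60 = c("hdl", 50, 60),
    hdl_ge60 = c("hdl", 60, Inf)
  )
  base_needed <- switch(col,
    htn_med_eff = c("sbp", "htn_med"),
    exercise_moderate = "exercise",
    exercise_high = "exercise",
    female = "sex",
    if (col %in% names(bins)) bins[[col]][1] else col
  )
  require_columns(data, base_needed, "covariate table")
  v <- if (col %in% names(bins)) {
    b <- bins[[col]]
    x <- data[[b[1]]]
    x >= as.numeric(b[2]) & x < as.numeric(b[3])
  } else {
    switch(col,
      htn_med_eff = apply_med_window(data$sbp, data$htn_med),
      exercise_moderate = data$exercise == "moderate",
      exercise_high = data$exercise == "high",
      female = data$sex == "female",
      data[[col]]
    )
  }
  if (is.logical(v)) v <- as.numeric(v)
  if (!is.numeric(v)) stop_schema(sprintf("column '%s' must be numeric or logical", col))
  v
}

design_matrix <- function(data, cols) {
  m <- vapply(cols, function(cl) design_column(data, cl), numeric(nrow(data)))
  if (nrow(data) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, cols))
  m
}

check_sex <- function(sex) {
  bad <- !sex %in% c("male", "female")
  if (any(bad)) {
    stop_schema("column 'sex' must be \"male\" or \"female\" for every row")
  }
}

#' Centred linear predictor of a Cox-form risk model
#'
#' Scores each row with the coefficient map of its own sex; the other
#' sex's coefficients are never touched.
#'
#' @param model A `cox_risk_model`.
#' @param data Covariate table including a `sex` column.
#' @return Numeric vector of centred linear predictors.
#' @export
linear_predictor <- function(model, data) {
  require_columns(data, "sex", "covariate table")
  check_sex(data$sex)
  lp <- rep(NA_real_, nrow(data))
  for (sx in c("male", "female")) {
    rows <- which(data$sex == sx)
    if (!length(rows)) next
    beta <- model[[sx]]$coefficients
    ctr <- model[[sx]]$center[names(beta)]
    x <- design_matrix(data[rows, , drop = FALSE], names(beta))
    lp[rows] <- drop(x %*% beta) - sum(beta * ctr)
  }
  lp
}

#' Ten-year event probability from a linear predictor
#'
#' Standard survival transform `p = 1 - S0 ^ exp(lp)` with the sex-specific
#' baseline survival at the model horizon.
#'
#' @inheritParams linear_predictor
#' @param lp Centred linear predictor(s).
#' @param sex `"male"`/`"female"`, recycled against `lp`.
#' @return Probabilities in (0, 1).
#' @examples
#' m <- fsrs_model()
#' ten_year_risk(m, 0, "male") # risk of the centred profile
#' @export
ten_year_risk <- function(model, lp, sex) {
  check_sex(sex)
  s0 <- ifelse(sex == "male",
    model$male$baseline_survival,
    model$female$baseline_survival
  )
  1 - s0^exp(lp)
}

#' Score a cohort with a baseline risk model (and optional factor update)
#'
#' Adds `lp` and `p_old` columns; when `factors` is supplied the synthesis
#' update is applied on top and `p_new` is added too.  Rows whose age falls
#' outside the model's development range are flagged (scored anyway), since
#' applying the score to younger cohorts is an extrapolation.
#'
#' @param data A cohort table (one row per subject).
#' @param model A `cox_risk_model`; defaults to the packaged stroke score.
#' @param factors Optional list of [literature_factor()] objects.
#' @param age_range Development age range used for the extrapolation flag.
#' @return `data` with columns `lp`, `p_old`, `fsrs_extrapolated` (and
#'   `synthesis_multiplier`, `p_new` when factors are given) appended.
#' @export
score_cohort <- function(data, model = fsrs_model(), factors = NULL,
                         age_range = c(55, 84)) {
  lp <- linear_predictor(model, data)
  out <- mutate(data,
    lp = lp,
    p_old = ten_year_risk(model, lp, .data$sex)
  )
  if ("age" %in% names(out)) {
    out$fsrs_extrapolated <- out$age < age_range[1] | out$age > age_range[2]
    n_out <- sum(out$fsrs_extrapolated)
    if (n_out > 0) {
      inform(sprintf(
        "%d of %d subjects are outside the model development age range %g-%g; scored by extrapolation",
        n_out, nrow(out), age_range[1], age_range[2]
      ))
    }
  }
  if (!is.null(factors)) out <- synthesize_risk(out, factors)
  out
}
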