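test_that("a null factor multiplies every subject by exactly one", {
  f <- literature_factor("x", "binary", rr = 1, reference = 0.3)
  expect_identical(standardized_multiplier(f, c(TRUE, FALSE, TRUE)), rep(1, 3))
  g <- literature_factor("e", "categorical",
    rr = c(1, 1, 1),
    reference = c(0.2, 0.5, 0.3), levels = c("a", "b", "c")
  )
  expect_identical(standardized_multiplier(g, c("a", "c")), rep(1, 2))
})

test_that("binary standardization matches the hand-computed expectation", {
  f <- literature_factor("x", "binary", rr = 2, reference = 0.2)
  m <- standardized_multiplier(f, c(TRUE, FALSE))
  expect_equal(m, c(2 / 1.2, 1 / 1.2), tolerance = 1e-12)
  # population mean of the multiplier is one
  expect_equal(0.2 * m[1] + 0.8 * m[2], 1, tolerance = 1e-12)
})

test_that("standardized multipliers average to one over any reference distribution", {
  set.seed(1)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    rr <- c(1, exp(runif(k - 1, -1, 1)))
    mass <- as.numeric(rmultinom(1, 1000, runif(k, 0.2, 1))) / 1000
    f <- literature_factor("f", "categorical",
      rr = rr, reference = mass,
      levels = letters[1:k]
    )
    m <- standardized_multiplier(f, letters[1:k])
    expect_equal(sum(mass * m), 1, tolerance = 1e-12)
  }
})

test_that("inapplicable subjects are left untouched by the factor", {
  f <- literature_factor("hrt", "binary",
    rr = 0.8, reference = 0.25,
    applies = "postmenopausal_female"
  )
  d <- tibble::tibble(
    sex = c("male", "female", "female"),
    postmenopausal = c(FALSE, TRUE, FALSE),
    hrt = c(TRUE, TRUE, TRUE), # male flag nonsensical on purpose
    p_old = rep(0.05, 3)
  )
  out <- synthesize_risk(d, list(f))
  expect_identical(out$p_new[1], out$p_old[1]) # male: multiplier exactly 1
  expect_identical(out$p_new[3], out$p_old[3]) # premenopausal: untouched
  expect_false(out$p_new[2] == out$p_old[2])
})

test_that("the hazard-scale update matches the closed-form hand computation", {
  f <- literature_factor("x", "binary", rr = 2, reference = 0.2)
  d <- tibble::tibble(x = c(TRUE, FALSE), p_old = c(0.05, 0.05))
  out <- synthesize_risk(d, list(f))
  # H = -ln(0.95) = 0.051293; exposed H' = H * 1.6667 = 0.085489
  expect_equal(out$p_new[1], 1 - 0.95^(2 / 1.2), tolerance = 1e-12)
  expect_equal(out$p_new[1], 0.08194, tolerance = 1e-4)
  expect_equal(out$p_new[2], 1 - 0.95^(1 / 1.2), tolerance = 1e-12)
})

test_that("null updates reproduce the baseline risk bit for bit", {
  sc <- scored_cohort(300, seed = 21, factors = NULL)
  out <- synthesize_risk(sc, null_factors())
  expect_identical(out$p_new, out$p_old)
})

test_that("the update is invariant to factor order and monotone in rr", {
  sc <- scored_cohort(200, seed = 8, factors = NULL)
  fs <- example_factors()
  a <- synthesize_risk(sc, fs)
  b <- synthesize_risk(sc, rev(fs))
  expect_equal(a$p_new, b$p_new, tolerance = 1e-13) # product commutes up to rounding

  f1 <- literature_factor("ethnicity_aa", "binary", rr = 1.5, reference = 0.2)
  f2 <- literature_factor("ethnicity_aa", "binary", rr = 2.0, reference = 0.2)
  exposed <- dplyr::filter(sc, ethnicity_aa)
  expect_true(all(
    synthesize_risk(exposed, list(f2))$p_new >
      synthesize_risk(exposed, list(f1))$p_new
  ))
})

test_that("the population-average updated risk stays near the baseline for small risks", {
  f <- literature_factor("x", "binary", rr = 1.8, reference = 0.3)
  d <- tibble::tibble(x = c(FALSE, TRUE), p_old = c(0.05, 0.05))
  out <- synthesize_risk(d, list(f))
  avg <- 0.7 * out$p_new[1] + 0.3 * out$p_new[2] # brute-force reference average
  expect_lt(abs(avg - 0.05), 5e-4)
})

test_that("reference distributions are estimated by counting and quantile binning", {
  d <- tibble::tibble(x = rep(c(TRUE, FALSE), c(3, 7)))
  expect_equal(fit_reference_distribution(d, "x", "binary")$reference, 0.3)
  dc <- tibble::tibble(y = as.numeric(1:100))
  q <- fit_reference_distribution(dc, "y", "continuous", probs = c(0.25, 0.5, 0.75))
  expect_equal(q$reference, rep(0.25, 4))
  expect_error(
    fit_reference_distribution(d[0, ], "x", "binary"),
    class = "strokesynth_config_error"
  )
})

test_that("refitting the reference on a resample moves multipliers only slightly", {
  set.seed(5)
  n <- 10000
  d <- tibble::tibble(x = runif(n) < 0.25)
  f <- literature_factor("x", "binary", rr = 1.6, reference = 0.25)
  f1 <- set_reference_distribution(f, fit_reference_distribution(d, "x", "binary"))
  boot <- d[sample.int(n, n, replace = TRUE), , drop = FALSE]
  f2 <- set_reference_distribution(f, fit_reference_distribution(boot, "x", "binary"))
  m1 <- standardized_multiplier(f1, c(TRUE, FALSE))
  m2 <- standardized_multiplier(f2, c(TRUE, FALSE))
  expect_lt(max(abs(m1 - m2)), 0.02) # O(n^-1/2) stability
})

test_that("invalid factors and out-of-domain values are rejected", {
  expect_error(
    literature_factor("x", "binary", rr = -2, reference = 0.2),
    class = "strokesynth_config_error"
  )
  expect_error(
    literature_factor("x", "categorical",
      rr = c(1.2, 2), reference = c(0.5, 0.5),
      levels = c("a", "b")
    ),
    class = "strokesynth_config_error" # no reference level with rr 1
  )
  expect_error(
    literature_factor("x", "categorical",
      rr = c(1, 2), reference = c(0.7, 0.7),
      levels = c("a", "b")
    ),
    class = "strokesynth_config_error" # masses do not sum to 1
  )
  f <- literature_factor("e", "categorical",
    rr = c(1, 2), reference = c(0.5, 0.5),
    levels = c("a", "b")
  )
  expect_error(
    standardized_multiplier(f, "z"),
    class = "strokesynth_domain_error"
  )
})

test_that("the packaged factor file loads with the documented structure", {
  fs <- example_factors()
  expect_length(fs, 7)
  nms <- vapply(fs, function(f) f$name, character(1))
  expect_setequal(
    nms,
    c("ethnicity_aa", "exercise", "bmi", "waist", "height", "hdl", "hrt")
  )
  for (f in fs) {
    # non-binary factors must name an explicit reference level/bin; binary
    # factors carry the exposed relative risk, the unexposed level is rr 1
    if (f$kind != "binary") expect_true(any(f$rr == 1))
    expect_true(all(f$rr > 0))
  }
})
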