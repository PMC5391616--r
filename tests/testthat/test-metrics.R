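pairs3 <- function(scores) {
  tibble::tibble(
    id = c("a", "b", "c"), p_old = scores, p_new = scores,
    time = c(2, 5, 10), event = c(TRUE, TRUE, FALSE)
  )
}

test_that("Harrell's C hits the exact endpoints on three-subject cohorts", {
  expect_equal(harrell_c(pairs3(c(0.9, 0.5, 0.1)), "p_new")$c_index, 1)
  expect_equal(harrell_c(pairs3(c(0.1, 0.5, 0.9)), "p_new")$c_index, 0)
  expect_equal(harrell_c(pairs3(c(0.4, 0.4, 0.4)), "p_new")$c_index, 0.5)
})

test_that("a cohort with no usable pair raises an undefined-statistic error", {
  d <- tibble::tibble(
    id = c("a", "b"), p_old = c(0.2, 0.4), p_new = c(0.2, 0.4),
    time = c(3, 7), event = c(FALSE, FALSE)
  )
  expect_error(harrell_c(d, "p_new"), class = "strokesynth_undefined_error")
})

test_that("a hand-built censored cohort matches brute-force IPCW enumeration", {
  d <- tibble::tibble(
    id = as.character(1:6),
    p_old = c(0.40, 0.10, 0.30, 0.25, 0.05, 0.20),
    p_new = c(0.35, 0.15, 0.30, 0.10, 0.20, 0.25),
    time = c(1, 3, 4, 4, 8, 10),
    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  for (sc in c("p_old", "p_new")) {
    expect_equal(
      uno_c(d, sc, tau = 9)$c_index,
      oracle_uno(d$time, d$event, d[[sc]], 9),
      tolerance = 1e-12
    )
    expect_equal(
      harrell_c(d, sc)$c_index,
      oracle_harrell(d$time, d$event, d[[sc]]),
      tolerance = 1e-12
    )
  }
})

test_that("an uninformative score concordances to one half", {
  set.seed(10)
  ch <- generate_cohort(generator_config(n = 5000, seed = 10))
  d <- tibble::tibble(
    id = ch$id, p_old = runif(5000), p_new = runif(5000),
    time = ch$time, event = ch$event
  )
  expect_lt(abs(uno_c(d, "p_new", tau = 10)$c_index - 0.5), 0.035)
})

test_that("concordance agrees with the survival package's IPCW estimator", {
  sc <- scored_cohort(600, seed = 14)
  fit <- survival::concordance(
    survival::Surv(time, event) ~ p_new,
    data = sc, reverse = TRUE, timewt = "n/G2", ymax = 10
  )
  expect_equal(uno_c(sc, "p_new", tau = 10)$c_index, unname(fit$concordance),
    tolerance = 0.02
  )
  fit_h <- survival::concordance(
    survival::Surv(time, event) ~ p_new,
    data = sc, reverse = TRUE
  )
  expect_equal(harrell_c(sc, "p_new")$c_index, unname(fit_h$concordance),
    tolerance = 1e-8
  )
})

test_that("concordance is invariant under strictly monotone rescoring", {
  sc <- scored_cohort(800, seed = 23)
  warped <- dplyr::mutate(sc, p_new = p_new^2) # strictly monotone on [0,1]
  expect_identical(
    uno_c(sc, "p_new", tau = 10)$c_index,
    uno_c(warped, "p_new", tau = 10)$c_index
  )
})

test_that("perfectly calibrated partitions give a zero statistic", {
  d <- tibble::tibble(
    id = as.character(1:20),
    p_old = rep(c(0.2, 0.4), each = 10),
    p_new = rep(c(0.2, 0.4), each = 10),
    time = rep(10, 20), event = FALSE
  )
  d$event[c(1, 2, 11, 12, 13, 14)] <- TRUE # 2/10 and 4/10 observed
  d$time[d$event] <- 5
  r <- hosmer_lemeshow(d, "p_new", tau = 10, n_partitions = 2)
  expect_equal(r$chi_square, 0, tolerance = 1e-12)
  expect_false(r$lack_of_fit)
})

test_that("one miscalibrated cell reproduces the hand-computed quadratic", {
  d <- tibble::tibble(
    id = as.character(1:20),
    p_old = rep(c(0.3, 0.5), each = 10),
    p_new = rep(c(0.3, 0.5), each = 10),
    time = 10, event = FALSE
  )
  d$event[c(1:5, 11:15)] <- TRUE # low group: O=5 vs E=3; high group exact
  d$time[d$event] <- 4
  r <- hosmer_lemeshow(d, "p_new", tau = 10, n_partitions = 2)
  expect_equal(r$chi_square, (5 - 3)^2 / (3 * 0.7), tolerance = 1e-10)
})

test_that("degenerate partitions are merged into a neighbour", {
  d <- tibble::tibble(
    id = as.character(1:30),
    p_old = c(rep(0, 10), rep(0.3, 20)),
    p_new = c(rep(0, 10), rep(0.3, 20)),
    time = 10, event = FALSE
  )
  d$event[15:20] <- TRUE
  d$time[d$event] <- 3
  expect_message(r <- hosmer_lemeshow(d, "p_new", tau = 10, n_partitions = 3), "merging")
  expect_lt(r$n_partitions, 3)
  expect_true(is.finite(r$chi_square))
})

test_that("classless NRI counts movement directions exactly", {
  # identical predictions: every component zero
  sc <- scored_cohort(150, seed = 3, factors = NULL)
  d <- dplyr::mutate(sc, p_new = p_old)
  r <- classless_nri(d, tau = 10)
  expect_identical(r$overall, 0)
  expect_identical(r$event_nri, 0)
  expect_identical(r$nonevent_nri, 0)

  # all events up, all non-events down, uncensored: maximal improvement
  d2 <- tibble::tibble(
    id = as.character(1:40),
    p_old = rep(0.2, 40),
    time = rep(c(4, 10), each = 20),
    event = rep(c(TRUE, FALSE), each = 20)
  )
  d2$p_new <- ifelse(d2$event, 0.3, 0.1)
  r2 <- classless_nri(d2, tau = 10)
  expect_equal(r2$overall, 2, tolerance = 1e-12)

  # events up/up, non-events down/up -> event 1, non-event 0, overall 1
  d3 <- tibble::tibble(
    id = as.character(1:4),
    p_old = rep(0.2, 4),
    p_new = c(0.3, 0.4, 0.1, 0.3),
    time = c(3, 5, 10, 10),
    event = c(TRUE, TRUE, FALSE, FALSE)
  )
  r3 <- classless_nri(d3, tau = 10)
  expect_equal(r3$event_nri, 1, tolerance = 1e-12)
  expect_equal(r3$nonevent_nri, 0, tolerance = 1e-12)
  expect_equal(r3$overall, 1, tolerance = 1e-12)
})

test_that("movement counts reproduce the hand-computed reclassification table", {
  # 10 events: 3 up / 1 down; 90 non-events: 5 up / 9 down; uncensored
  d <- tibble::tibble(
    id = as.character(1:100),
    p_old = rep(0.2, 100),
    p_new = rep(0.2, 100),
    time = rep(c(5, 10), c(10, 90)),
    event = rep(c(TRUE, FALSE), c(10, 90))
  )
  d$p_new[1:3] <- 0.3
  d$p_new[4] <- 0.1
  d$p_new[11:15] <- 0.3
  d$p_new[16:24] <- 0.1
  r <- classless_nri(d, tau = 10)
  expect_equal(r$event_nri, 0.2, tolerance = 1e-12)
  expect_equal(r$nonevent_nri, 0.04 / 0.9, tolerance = 1e-12)
  expect_equal(r$overall, 0.2 + 0.04 / 0.9, tolerance = 1e-12)
})

test_that("class NRI uses each model's own quantile thresholds", {
  set.seed(77)
  d <- tibble::tibble(
    id = as.character(1:1000),
    p_old = sample(seq(0.001, 0.999, length.out = 1000)),
    time = 10, event = FALSE
  )
  d$p_new <- d$p_old
  d$event[sample.int(1000, 80)] <- TRUE
  d$time[d$event] <- 5
  scheme <- risk_class_scheme(c(0.7, 0.9))
  r <- class_nri(d, scheme, tau = 10)
  expect_identical(r$overall, 0) # identical predictions
  for (thr in r$thresholds) {
    cls <- 1 + (d$p_old > thr[1]) + (d$p_old > thr[2])
    expect_equal(as.numeric(table(cls)), c(700, 200, 100))
  }
  expect_error(risk_class_scheme(c(0.9, 0.7)), class = "strokesynth_config_error")
})

test_that("bootstrap intervals are deterministic and collapse for constant statistics", {
  sc <- scored_cohort(300, seed = 40)
  stat <- function(d) c(c = uno_c(d, "p_new", tau = 10)$c_index)
  b1 <- bootstrap_ci(sc, stat, B = 100, seed = 99)
  b2 <- bootstrap_ci(sc, stat, B = 100, seed = 99)
  expect_identical(b1, b2)

  d <- dplyr::mutate(sc, p_new = p_old)[1:100, ]
  nri0 <- bootstrap_ci(d, function(x) {
    r <- classless_nri(x, tau = 10)
    c(overall = r$overall)
  }, B = 100, seed = 5)
  expect_identical(unname(c(nri0$lower, nri0$upper)), c(0, 0))
  expect_error(bootstrap_ci(sc, stat, B = 50), class = "strokesynth_config_error")
})

test_that("sex subgroups partition the prediction pairs", {
  sc <- scored_cohort(400, seed = 55)
  pr <- make_prediction_pairs(sc)
  m <- subgroup(pr, "male")
  f <- subgroup(pr, "female")
  expect_equal(nrow(m) + nrow(f), nrow(pr))
  expect_true(all(m$sex == "male"))
  expect_error(
    subgroup(dplyr::filter(pr, sex == "male"), "female"),
    class = "strokesynth_config_error"
  )
})

test_that("the calibration statistic is chi-square with one df per partition under the null", {
  # externally specified correct model: no parameters estimated in-sample,
  # so the 10-partition statistic behaves as chi-square(10), not chi-square(8)
  stats <- vapply(1:300, function(r) {
    cfg <- generator_config(n = 1500, seed = 50000 + r, censor_rate = 0)
    ch <- generate_cohort(cfg)
    p <- true_risk(cfg, ch)
    d <- tibble::tibble(id = ch$id, p_old = p, p_new = p, time = ch$time, event = ch$event)
    hosmer_lemeshow(d, "p_new", tau = 10)$chi_square
  }, numeric(1))
  exceed <- mean(stats > qchisq(0.95, df = 10))
  expect_gt(exceed, 0.02)
  expect_lt(exceed, 0.10)
  expect_gt(mean(stats), 9)
  expect_lt(mean(stats), 11.5)
})

test_that("tidiers expose estimates in broom shape", {
  sc <- scored_cohort(300, seed = 61)
  r <- uno_c(sc, "p_new", tau = 10, ci = TRUE, B = 100, seed = 1)
  td <- tidy(r)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_true(td$conf.low <= td$estimate && td$estimate <= td$conf.high)
  n <- classless_nri(sc, tau = 10, ci = TRUE, B = 100, seed = 2)
  tn <- tidy(n)
  expect_equal(tn$term, c("overall", "event", "nonevent"))
  g <- glance(hosmer_lemeshow(sc, "p_new", 10))
  expect_true(is.numeric(g$chi_square))
})
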