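# Independent brute-force reference implementations used to validate the
# package's metric engines.  Everything here is written as plain loops over
# the definitions, deliberately sharing no code with the package.

oracle_km_inc <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event & time <= at]))) {
    d <- sum(time == t & event)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  1 - s
}

# censoring Kaplan-Meier just before s (ties: events before censorings)
oracle_G_before <- function(time, event, s) {
  g <- 1
  for (t in sort(unique(time[!event]))) {
    if (t < s) {
      d <- sum(time == t & !event)
      r <- sum(time >= t)
      g <- g * (1 - d / r)
    }
  }
  g
}

oracle_harrell <- function(time, event, score) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i]) {
        den <- den + 1
        if (score[i] > score[j]) num <- num + 1
        if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_uno <- function(time, event, score, tau) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (!event[i] || time[i] >= tau) next
    w <- 1 / oracle_G_before(time, event, time[i])^2
    for (j in seq_len(n)) {
      if (i == j || time[j] <= time[i]) next
      den <- den + w
      if (score[i] > score[j]) num <- num + w
      if (score[i] == score[j]) num <- num + 0.5 * w
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

oracle_nri_from_moves <- function(up, down, time, event, tau) {
  p_all <- oracle_km_inc(time, event, tau)
  if (p_all <= 0 || p_all >= 1) return(NULL)
  pi_up <- mean(up)
  pi_dn <- mean(down)
  p_up <- if (any(up)) oracle_km_inc(time[up], event[up], tau) else 0
  p_dn <- if (any(down)) oracle_km_inc(time[down], event[down], tau) else 0
  ev <- (p_up * pi_up - p_dn * pi_dn) / p_all
  ne <- ((1 - p_dn) * pi_dn - (1 - p_up) * pi_up) / (1 - p_all)
  c(overall = ev + ne, event = ev, nonevent = ne)
}

oracle_classless_nri <- function(p_old, p_new, time, event, tau) {
  oracle_nri_from_moves(p_new > p_old, p_new < p_old, time, event, tau)
}

oracle_class_nri <- function(p_old, p_new, time, event, tau, cuts) {
  cls <- function(p) {
    thr <- stats::quantile(p, cuts, names = FALSE)
    1 + (p > thr[1]) + (p > thr[2])
  }
  co <- cls(p_old)
  cn <- cls(p_new)
  oracle_nri_from_moves(cn > co, cn < co, time, event, tau)
}

# tiny random cohorts with ties in both times and scores, and censoring
small_cohort <- function(seed) {
  set.seed(seed)
  n <- sample(4:8, 1)
  tibble::tibble(
    id = as.character(seq_len(n)),
    time = sample(c(1, 2, 2, 3, 5, 8, 9, 12), n, replace = TRUE),
    event = runif(n) < 0.6,
    p_old = sample(seq(0.05, 0.50, by = 0.05), n, replace = TRUE),
    p_new = sample(seq(0.05, 0.50, by = 0.05), n, replace = TRUE)
  )
}

quiet <- function(expr) suppressMessages(expr)

scored_cohort <- function(n, seed, censor_rate = 0.02, factors = example_factors()) {
  cfg <- generator_config(n = n, seed = seed, censor_rate = censor_rate)
  ch <- generate_cohort(cfg)
  quiet(score_cohort(ch, factors = factors))
}

null_factors <- function() {
  lapply(example_factors(), function(f) {
    f$rr <- rep(1, length(f$rr))
    f
  })
}
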