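test_that("product-limit estimate matches hand computation", {
  km <- km_estimate(c(2, 4, 6), c(1, 1, 0))
  expect_equal(km$event_times, c(2, 4))
  expect_equal(km$surv, c(2 / 3, 1 / 3))
  expect_equal(km$n_at_risk, c(3, 2))
  expect_equal(km$median_months, 4)

  # no events: flat curve, median undefined
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$event_times, 0)
  expect_true(is.na(km0$median_months))

  # everyone fails at t = 1
  km1 <- km_estimate(rep(1, 5), rep(1, 5))
  expect_equal(km1$surv, 0)
  expect_equal(km1$median_months, 1)

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("product-limit estimate matches the risk-set oracle on random fixtures", {
  set.seed(21)
  for (i in 1:25) {
    fx <- random_surv_fixture(sample(5:30, 1))
    if (sum(fx$events) == 0) next
    km <- km_estimate(fx$times, fx$events)
    oc <- km_oracle(fx$times, fx$events)
    expect_equal(km$event_times, oc$event_times)
    expect_equal(km$surv, oc$surv, tolerance = 1e-12)
    expect_equal(km$n_at_risk, oc$n_at_risk)
    expect_equal(km$median_months, oc$median)
  }
})

test_that("log-rank matches the observed-minus-expected oracle", {
  # small fixture, checked by hand via the O-E / V form
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 1, 1, 0, 1)
  group <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  got <- logrank_test(times, events, group)
  oc <- logrank_oracle(times, events, group)
  expect_equal(got$chi_square, oc$chi_square, tolerance = 1e-10)
  expect_equal(got$p, oc$p, tolerance = 1e-10)

  set.seed(22)
  for (i in 1:25) {
    fx <- random_surv_fixture(sample(8:40, 1))
    grp <- rbinom(length(fx$times), 1, 0.5)
    if (length(unique(grp)) < 2 || sum(fx$events) == 0) next
    got <- logrank_test(fx$times, fx$events, grp)
    oc <- logrank_oracle(fx$times, fx$events, grp)
    expect_equal(got$chi_square, oc$chi_square, tolerance = 1e-10)
  }
})

test_that("log-rank degenerate and symmetric cases", {
  expect_error(logrank_test(c(1, 2), c(1, 1), c(1, 1)), "two non-empty groups")
  # identical survival experience in both groups: statistic ~ 0
  times <- rep(c(1, 2, 3, 4), 2)
  events <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c(0, 1), each = 4)
  expect_lt(logrank_test(times, events, group)$chi_square, 1e-10)
})

test_that("log-rank p-values are roughly uniform under the null", {
  set.seed(23)
  n <- 60
  times <- rexp(n, 1 / 40) + runif(n)
  events <- rbinom(n, 1, 0.7)
  p <- replicate(400, logrank_test(times, events, sample(rep(0:1, n / 2)))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(p < 0.2) - 0.2), 0.08)
})

test_that("Cox fit recovers a known log hazard and flags bad designs", {
  set.seed(24)
  n <- 600
  x <- rnorm(n)
  t_event <- rexp(n, 0.02 * exp(-0.4 * x))
  cens <- rexp(n, 1 / 60)
  times <- pmin(t_event, cens)
  events <- as.integer(t_event <= cens)
  fit <- cox_fit(x, times, events)
  expect_lt(abs(fit$beta[[1]] + 0.4), 3 * fit$se[[1]])
  expect_equal(unname(fit$hr), unname(exp(fit$beta)))
  expect_true(all(fit$ci95[, "lower"] < fit$ci95[, "upper"]))
  expect_lte(fit$n_events, fit$n_used)

  expect_error(cox_fit(rep(1, n), times, events), "constant")
  expect_error(cox_fit(x, times, rep(0, n)), "at least one event")
  # perfect separation: covariate ordering all events before all censorings
  sep_t <- c(1:5, 11:15)
  sep_e <- c(rep(1, 5), rep(0, 5))
  sep_x <- c(rep(1, 5), rep(0, 5))
  expect_error(cox_fit(sep_x, sep_t, sep_e), "separation|non-convergence")
})

test_that("two-group Cox score statistic equals the log-rank chi-square", {
  set.seed(25)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    times <- round(rexp(n, 1 / 30), 6) + runif(n)   # tie-free
    events <- rbinom(n, 1, 0.7)
    grp <- rbinom(n, 1, 0.5)
    if (sum(events) < 2 || length(unique(grp)) < 2) next
    fit <- cox_fit(grp, times, events)
    oc <- logrank_oracle(times, events, grp)
    expect_equal(fit$score_chisq, oc$chi_square, tolerance = 1e-8)
  }
})

test_that("BH adjustment: identities and hand-computed step-up", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(26)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone in p-value rank
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cutoff scan matches exhaustive enumeration", {
  set.seed(27)
  for (i in 1:10) {
    fx <- random_surv_fixture(20)
    if (sum(fx$events) == 0) next
    # a log-rank-selected split can be Cox-inestimable; that only warns
    scan <- suppressWarnings(
      cutoff_scan(fx$scores, fx$times, fx$events, p_source = "logrank"))
    oc <- scan_oracle(fx$scores, fx$times, fx$events)
    expect_equal(scan$cutoffs, oc$cutoffs)
    expect_equal(scan$p_at, oc$p, tolerance = 1e-10)
    expect_equal(scan$selected_index, oc$selected_index)
  }
})

test_that("scan invariants: quartile bounds, BH family, selection rule", {
  set.seed(28)
  fx <- random_surv_fixture(60)
  scan <- cutoff_scan(fx$scores, fx$times, fx$events)
  qb <- quantile(fx$scores, c(0.25, 0.75), names = FALSE)
  expect_true(all(scan$cutoffs >= qb[1] & scan$cutoffs <= qb[2]))
  expect_equal(scan$p_at[scan$selected_index], min(scan$p_at, na.rm = TRUE))
  ok <- !scan$skipped
  expect_equal(scan$q_at[ok], bh_adjust(scan$p_at[ok]))
  expect_true(all(scan$q_at[ok] >= scan$p_at[ok]))
  expect_equal(scan$n_low + scan$n_high, rep(length(fx$scores),
                                             length(scan$cutoffs)))
})

test_that("tied minimum p-values resolve by |log HR| then lower cutoff", {
  # mirror-image design: the splits at cutoffs 1 and 2 swap the two group
  # compositions, so p and |log HR| tie and the lower cutoff must win;
  # cutoff 3 leaves the high group empty and is skipped
  scores <- c(1, 1, 2, 3, 3)
  times <- c(2, 2, 9, 2, 2)
  events <- c(1, 1, 0, 1, 1)
  scan <- cutoff_scan(scores, times, events)
  expect_equal(scan$cutoffs, c(1, 2, 3))
  expect_true(scan$skipped[3])
  expect_equal(scan$p_at[1], scan$p_at[2], tolerance = 1e-8)
  expect_equal(log(scan$hr_at[1]), -log(scan$hr_at[2]), tolerance = 1e-6)
  expect_equal(scan$selected_index, 1L)
  expect_equal(scan$selected_cutoff, 1)
})

test_that("scan rejects constant scores and honors monotone transforms", {
  times <- c(1, 2, 3, 4); events <- c(1, 1, 0, 1)
  expect_error(cutoff_scan(rep(5, 4), times, events), "fewer than 2 distinct")

  set.seed(29)
  fx <- random_surv_fixture(40)
  s1 <- cutoff_scan(fx$scores, fx$times, fx$events)
  s2 <- cutoff_scan(log(fx$scores) * 2 + 7, fx$times, fx$events)
  # same partitions, same p series, same selected split
  expect_equal(s1$p_at, s2$p_at, tolerance = 1e-9)
  expect_equal(s1$selected_index, s2$selected_index)
  expect_equal(sum(fx$scores > s1$selected_cutoff),
               s1$n_high[s1$selected_index])
})

test_that("KM and scan tables export plot-ready series", {
  set.seed(30)
  fx <- random_surv_fixture(50)
  scan <- cutoff_scan(fx$scores, fx$times, fx$events)
  st <- scan_table(scan)
  expect_equal(nrow(st), length(scan$cutoffs))
  expect_equal(sum(st$selected), 1L)
  kt <- km_table(scan)
  expect_setequal(unique(kt$group), c("low", "high"))
  expect_true(all(kt$surv >= 0 & kt$surv <= 1))
  # survival is non-increasing within each group
  for (g in c("low", "high")) {
    expect_true(all(diff(kt$surv[kt$group == g]) <= 1e-12))
  }
})
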