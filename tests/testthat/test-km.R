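test_that("product-limit estimate matches hand-computed cases", {
  # all censored: survival stays at 1
  km <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_length(km$event_times, 0)
  expect_equal(km_survival_at(km, c(1, 20)), c(1, 1))
  # three events among three patients
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$at_risk, c(3L, 2L, 1L))
  # single event among n
  km <- km_estimate(c(4, 6, 8, 10, 12), c(0, 1, 0, 0, 0))
  expect_equal(km_survival_at(km, 6), 1 - 1 / 4)
  expect_error(km_estimate(numeric(0), numeric(0)), "no observations")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("with no censoring the KM curve is the empirical survival function", {
  set.seed(5)
  t <- sample(1:40, 200, replace = TRUE)
  km <- km_estimate(t, rep(1, 200))
  grid <- 1:40
  expect_equal(km_survival_at(km, grid), vapply(grid, function(g) mean(t > g),
                                                numeric(1)))
})

test_that("survival and Greenwood variance agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(9)
  t <- rexp(300, 0.03)
  e <- rbinom(300, 1, 0.6)
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  idx <- match(km$event_times, sf$time)
  expect_equal(km$survival, sf$surv[idx], tolerance = 1e-12)
  ok <- is.finite(sf$std.err[idx]) & sf$surv[idx] > 0
  expect_equal(sqrt(km$greenwood_var)[ok], (sf$std.err * sf$surv)[idx][ok],
               tolerance = 1e-8)
})

test_that("log-rank statistic matches the survdiff oracle over random cases", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (k in c(2, 3, 4)) {
    n <- 150
    t <- sample(1:25, n, replace = TRUE)
    e <- rbinom(n, 1, 0.6)
    g <- sample(letters[1:k], n, replace = TRUE)
    lr <- logrank_test(t, e, g)
    sd <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$chi2, sd$chisq, tolerance = 1e-10)
    expect_equal(lr$df, k - 1)
    expect_equal(unname(lr$observed), unname(sd$obs), tolerance = 1e-12)
    expect_equal(unname(lr$expected), unname(sd$exp), tolerance = 1e-10)
  }
})

test_that("log-rank handles degenerate and powered designs", {
  # two identical groups: zero statistic, p = 1
  t <- c(2, 4, 6, 8, 10)
  e <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  expect_error(logrank_test(t, e, rep("a", 5)), "two groups")
  # a strong effect is detected essentially always
  set.seed(33)
  detected <- vapply(1:20, function(i) {
    d <- sim_two_group(250, hr = 4)
    logrank_test(d$time, d$event, d$x)$p < 0.001
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})
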