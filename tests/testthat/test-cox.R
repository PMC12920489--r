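test_that("null model has equal fitted and null likelihood", {
  set.seed(2)
  t <- rexp(100, 0.05)
  e <- rbinom(100, 1, 0.7)
  fit <- fit_cox(t, e, matrix(nrow = 100, ncol = 0))
  expect_equal(fit$loglik, fit$loglik_null)
  expect_equal(fit$aic, -2 * fit$loglik)
})

test_that("coefficients, errors and likelihood match coxph with Efron ties", {
  skip_if_not_installed("survival")
  set.seed(7)
  for (rep in 1:4) {
    n <- 250
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4), c = runif(n))
    t <- sample(1:20, n, replace = TRUE)   # heavy ties
    e <- rbinom(n, 1, 0.6)
    fit <- fit_cox(t, e, x)
    ref <- survival::coxph(survival::Surv(t, e) ~ x, ties = "efron")
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
    expect_equal(fit$loglik_null, ref$loglik[1], tolerance = 1e-8)
    expect_equal(fit$aic, 2 * length(coef(ref)) - 2 * ref$loglik[2],
                 tolerance = 1e-8)
    # Breslow route against its own oracle
    fitb <- fit_cox(t, e, x, ties = "breslow")
    refb <- survival::coxph(survival::Surv(t, e) ~ x, ties = "breslow")
    expect_equal(unname(fitb$coef), unname(coef(refb)), tolerance = 1e-6)
  }
})

test_that("without tied event times Efron and Breslow coincide", {
  set.seed(15)
  n <- 200
  x <- cbind(z = rnorm(n))
  t <- rexp(n, 0.04)
  e <- rbinom(n, 1, 0.7)
  fe <- fit_cox(t, e, x, ties = "efron")
  fb <- fit_cox(t, e, x, ties = "breslow")
  expect_equal(fe$coef, fb$coef, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
})

test_that("a known hazard ratio is recovered at large n", {
  set.seed(41)
  d <- sim_two_group(5000, hr = 2)
  fit <- fit_cox(d$time, d$event, cbind(arm = d$x))
  expect_lt(abs(unname(fit$coef) - log(2)), 0.08)
})

test_that("degenerate designs are rejected or flagged", {
  t <- rexp(50, 0.05); e <- rep(0, 50)
  expect_error(fit_cox(t, e, cbind(x = rnorm(50))), "no events")
  e <- rbinom(50, 1, 0.5); e[1] <- 1
  expect_error(fit_cox(t, e, cbind(x = rep(1, 50))), "constant")
  expect_error(fit_cox(t, e, cbind(a = 1:50, b = 2 * (1:50))),
               "rank deficient")
  # complete separation: all events carry the covariate
  ts <- c(rep(1:10, 1), rep(20:29, 1))
  ev <- c(rep(1, 10), rep(0, 10))
  xs <- cbind(s = c(rep(1, 10), rep(0, 10)))
  fit <- fit_cox(ts, ev, xs)
  expect_false(isTRUE(fit$converged) && is.null(fit$diagnostic))
})

test_that("Wald intervals cover the generating coefficient at nominal rate", {
  set.seed(55)
  beta <- log(2)
  hits <- vapply(1:200, function(i) {
    d <- sim_two_group(500, hr = exp(beta))
    f <- fit_cox(d$time, d$event, cbind(arm = d$x))
    abs(unname(f$coef) - beta) <= 1.96 * unname(f$se)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

test_that("likelihood-ratio test bookkeeping is correct", {
  set.seed(61)
  d <- sim_two_group(500, hr = 3)
  x2 <- cbind(arm = d$x, noise = rnorm(nrow(d)))
  f0 <- fit_cox(d$time, d$event, matrix(nrow = nrow(d), ncol = 0))
  f1 <- fit_cox(d$time, d$event, cbind(arm = d$x))
  f2 <- fit_cox(d$time, d$event, x2)
  same <- lrt(f1, f1)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  strong <- lrt(f0, f1)
  expect_equal(strong$df, 1)
  expect_lt(strong$p, 0.001)
  expect_error(lrt(f2, f1), "not nested")
  # chi-square is non-negative across random nested fits
  chis <- vapply(1:50, function(i) {
    dd <- sim_two_group(60, hr = 1)
    xx <- cbind(arm = dd$x, z = rnorm(nrow(dd)))
    lrt(fit_cox(dd$time, dd$event, xx[, 1, drop = FALSE]),
        fit_cox(dd$time, dd$event, xx))$chi2
  }, numeric(1))
  expect_true(all(chis >= 0))
})

test_that("Breslow baseline recovers the generating cumulative hazard", {
  set.seed(71)
  n <- 10000
  lambda <- 0.01
  t <- rexp(n, lambda)
  cens <- runif(n, 24, 72)
  time <- pmin(t, cens); ev <- as.integer(t <= cens)
  x <- cbind(z = rnorm(n))
  fit <- fit_cox(time, ev, x)
  bl <- breslow_baseline(fit, time, ev, x)
  for (h in c(12, 24, 48)) {
    H <- bl$cumhaz[max(which(bl$time <= h))]
    expect_lt(abs(H / (lambda * h) - 1), 0.1)
  }
})

test_that("survival predictions are proper and monotone in risk", {
  set.seed(81)
  d <- sim_two_group(300, hr = 2)
  x <- cbind(arm = d$x)
  fit <- fit_cox(d$time, d$event, x)
  bl <- breslow_baseline(fit, d$time, d$event, x)
  expect_equal(predict_survival(fit, bl, x[1:2, , drop = FALSE], horizon = 0),
               c(1, 1))
  s <- predict_survival(fit, bl, lp = c(0, 1, 2), horizon = 36)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
  expect_warning(predict_survival(fit, bl, lp = 0, horizon = 1000),
                 "beyond last")
})
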