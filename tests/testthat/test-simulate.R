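test_that("configuration validation rejects malformed inputs", {
  cfg <- training_sim_config()
  bad <- cfg$biomarker_marginals
  bad$tls_density <- c(0.5, 0.4, 0.2)
  expect_error(sim_config(10, bad, cfg$clinical_marginals, cfg$true_log_hr),
               "sum to 1")
  expect_error(training_sim_config(n_patients = 0), "positive integer")
  expect_error(sim_config(10, cfg$biomarker_marginals, cfg$clinical_marginals,
                          cfg$true_log_hr,
                          censoring = list(admin_min = 72, admin_max = 24,
                                          random_rate = 0)),
               "min < max")
  expect_error(sim_config(10, cfg$biomarker_marginals, cfg$clinical_marginals,
                          cfg$true_log_hr,
                          baseline = list(family = "exponential", rate = -1,
                                          target_event_rate = c(lrc = 0.2))),
               "positive")
})

test_that("degenerate marginals pin the sampled band", {
  cfg <- training_sim_config(n_patients = 50, seed = 3)
  cfg$biomarker_marginals$tls_density <- c(1, 0, 0)
  cfg$clinical_marginals$pathologic_response <- c(pCR = 1, mPR_not_pCR = 0,
                                                  no_mPR = 0)
  set.seed(3)
  bio <- sample_biomarkers(cfg)
  expect_true(all(bio$tls_density >= 3))
  expect_identical(unique(score_histopathology(bio$tls_density)), 0L)
  clin <- sample_clinical(cfg)
  expect_identical(unique(clin$pathologic_response), "pCR")
})

test_that("re-scoring sampled biomarkers recovers the drawn bands exactly", {
  cfg <- training_sim_config(n_patients = 1000, seed = 5)
  set.seed(5)
  bio <- sample_biomarkers(cfg)
  b <- attr(bio, "bands")
  expect_identical(score_histopathology(bio$tls_density),
                   as.integer(b$tls_density))
  expect_identical(score_tumor_burden(bio$panck_foci, bio$ki67_pct),
                   as.integer(pmax(b$panck_foci, b$ki67_pct)))
  expect_identical(score_molecular(bio$n_driver_mutations, bio$pdl1_fold),
                   as.integer(pmax(b$n_driver_mutations, b$pdl1_fold)))
  expect_identical(score_immune(bio$cd8_foxp3_ratio, bio$gzmb_density),
                   as.integer(pmax(b$cd8_foxp3_ratio, b$gzmb_density)))
})

test_that("sampled frequencies converge to the configured marginals", {
  n <- 10000
  cfg <- training_sim_config(n_patients = n, seed = 17)
  set.seed(17)
  bio <- sample_biomarkers(cfg)
  clin <- sample_clinical(cfg)
  check_marginal <- function(obs_prop, p) {
    se <- sqrt(p * (1 - p) / n)
    expect_true(all(abs(obs_prop - p) <= 3 * se + 1e-12))
  }
  tls_p <- c(51, 63, 30) / 144
  obs <- tabulate(score_histopathology(bio$tls_density) + 1L, 3) / n
  check_marginal(obs, tls_p)
  pr_p <- c(46, 58, 40) / 144
  obs <- tabulate(factor(clin$pathologic_response,
                         c("pCR", "mPR_not_pCR", "no_mPR")), 3) / n
  check_marginal(obs, pr_p)
})

test_that("linear predictor sums configured log hazard ratios", {
  lhr <- list(differentiation = log(c(moderate = 1.56, poor = 2.19)),
              mrix_category = log(c(intermediate = 1.89, high = 3.15)))
  ref_pt <- data.frame(differentiation = "well", mrix_category = "low")
  expect_equal(linear_predictor(ref_pt, lhr), 0)
  hi <- data.frame(differentiation = "well", mrix_category = "high")
  expect_equal(linear_predictor(hi, lhr), log(3.15))
  both <- data.frame(differentiation = "poor", mrix_category = "high")
  expect_equal(linear_predictor(both, lhr), log(2.19) + log(3.15))
  odd <- data.frame(differentiation = "unknown", mrix_category = "low")
  expect_error(linear_predictor(odd, lhr), "unknown")
})

test_that("event fraction matches the exponential closed form", {
  lambda <- 0.005
  cens <- list(admin_min = 59.999, admin_max = 60.001, random_rate = 0)
  expect_equal(expected_event_fraction(0, lambda, 1, cens),
               1 - exp(-lambda * 60), tolerance = 1e-6)
  set.seed(101)
  n <- 10000
  out <- simulate_event_times(rep(0, n), list(rate = lambda, shape = 1), cens)
  p <- 1 - exp(-lambda * 60)
  expect_lt(abs(mean(out$event) - p), 3 * sqrt(p * (1 - p) / n))
  # vanishing hazard gives vanishing event fraction
  out0 <- simulate_event_times(rep(-30, n), list(rate = lambda, shape = 1), cens)
  expect_lt(mean(out0$event), 0.001)
  expect_error(simulate_event_times(0, list(rate = 0)), "positive")
})

test_that("simulated data recover a known two-group hazard ratio", {
  set.seed(23)
  lp <- rep(c(0, log(2)), each = 5000)
  out <- simulate_event_times(lp, list(rate = 0.005, shape = 1),
                              list(admin_min = 24, admin_max = 72,
                                   random_rate = 0))
  fit <- fit_cox(out$time, out$event, cbind(arm = as.numeric(lp > 0)))
  expect_true(exp(fit$coef) >= 1.85 && exp(fit$coef) <= 2.15)
})

test_that("baseline calibration hits the target event fraction", {
  set.seed(31)
  lp <- rnorm(5000, 0, 0.7)
  cens <- list(admin_min = 24, admin_max = 72, random_rate = 0)
  rate <- calibrate_baseline_rate(lp, 0.181, 1, cens)
  expect_equal(expected_event_fraction(lp, rate, 1, cens), 0.181,
               tolerance = 1e-6)
})

test_that("generated cohorts are deterministic, schema-complete and on-rate", {
  cfg <- training_sim_config(n_patients = 500, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  sc <- cohort_schema()
  expect_true(all(sc$mandatory %in% names(a)))
  expect_true(all(sc$derived %in% names(a)))
  big <- generate_cohort(training_sim_config(n_patients = 10000, seed = 7))
  expect_lt(abs(mean(big$lrc_event) - 0.181), 0.05)
  expect_lt(abs(mean(big$dmfs_event) - 0.215), 0.05)
})

test_that("a null-effect cohort shows no separation between score strata", {
  cfg <- training_sim_config(n_patients = 600, seed = 13)
  cfg$true_log_hr$lrc <- list(mrix_category = c(intermediate = 0, high = 0))
  pvals <- vapply(1:40, function(i) {
    cfg$seed <- 1000L + i
    co <- generate_cohort(cfg)
    logrank_test(co$lrc_time_months, co$lrc_event, co$mrix_category)$p
  }, numeric(1))
  # under the null p-values are roughly uniform: no excess of small values
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.3)
})
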