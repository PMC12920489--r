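# Study-level analyses: cohort characterization, per-domain survival
# associations, the adjusted multivariable MRIx model, nested model
# comparison, and the frozen-score external-validation workflow.

.ENDPOINTS <- c("lrc", "dmfs")

.endpoint_cols <- function(endpoint) {
  endpoint <- match.arg(endpoint, .ENDPOINTS)
  c(time = paste0(endpoint, "_time_months"),
    event = paste0(endpoint, "_event"))
}

#' Display percentage, rounded half-up to one decimal
#'
#' @param count Numerator count(s).
#' @param total Denominator.
#' @return Numeric percentage(s) with one decimal, e.g. `fmt_pct(104, 144)`
#'   is `72.2`.
#' @export
fmt_pct <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  round_half_up(100 * count / total, 1)
}

.DESIGN_FACTORS <- list(
  differentiation = c("well", "moderate", "poor"),
  pathologic_response = c("pCR", "mPR_not_pCR", "no_mPR"),
  margin_class = c("clear", "close"),
  mrix_category = c("low", "intermediate", "high")
)

## 0/1 dummy design matrix with the first level of each factor as reference
.build_design <- function(df, factors) {
  cols <- list()
  for (cov in names(factors)) {
    levs <- factors[[cov]]
    if (is.null(df[[cov]])) stop("covariate column missing: ", cov)
    vals <- as.character(df[[cov]])
    unknown <- setdiff(unique(vals), levs)
    if (length(unknown)) {
      stop("unknown level(s) for ", cov, ": ", paste(unknown, collapse = ", "))
    }
    if (!any(vals == levs[1])) {
      stop("reference level '", levs[1], "' of ", cov, " is empty")
    }
    for (l in levs[-1]) {
      cols[[paste(cov, l, sep = "_")]] <- as.numeric(vals == l)
    }
  }
  do.call(cbind, cols)
}

.complete_rows <- function(cohort, cols) {
  keep <- complete.cases(cohort[, cols, drop = FALSE])
  if (!all(keep)) {
    message(sum(!keep), " row(s) excluded for missing values (complete-case)")
  }
  cohort[keep, , drop = FALSE]
}

#' Baseline characteristics table with between-cohort tests
#'
#' Per-covariate category counts and percentages (half-up, one decimal) for
#' two cohorts, with a Pearson chi-squared test of the 2 x k contingency
#' table (Fisher's exact test when any expected cell count is below 5).
#'
#' @param cohort_a,cohort_b Cohort data frames (e.g. training and
#'   validation) holding the clinical covariate columns.
#' @param covariates Named list of category vocabularies, in display order;
#'   defaults to the full clinical registry of [cohort_schema()].
#' @return Data frame with one row per category: `variable`, `level`,
#'   `n_a`, `pct_a`, `n_b`, `pct_b`, and on each variable's first row the
#'   test `p` and `method` (`"chisq"` or `"fisher"`).
#' @export
baseline_table <- function(cohort_a, cohort_b,
                           covariates = cohort_schema()$clinical_vocab) {
  if (nrow(cohort_a) == 0 || nrow(cohort_b) == 0) stop("empty cohort")
  out <- list()
  for (v in names(covariates)) {
    levs <- covariates[[v]]
    na <- vapply(levs, function(l) sum(cohort_a[[v]] == l), numeric(1))
    nb <- vapply(levs, function(l) sum(cohort_b[[v]] == l), numeric(1))
    tab <- rbind(na, nb)
    keep <- colSums(tab) > 0
    p <- NA_real_; method <- NA_character_
    if (sum(keep) >= 2) {
      m <- tab[, keep, drop = FALSE]
      cs <- suppressWarnings(chisq.test(m, correct = FALSE))
      if (any(cs$expected < 5)) {
        p <- fisher.test(m)$p.value
        method <- "fisher"
      } else {
        p <- cs$p.value
        method <- "chisq"
      }
    }
    out[[v]] <- data.frame(
      variable = v, level = levs,
      n_a = unname(na), pct_a = fmt_pct(unname(na), nrow(cohort_a)),
      n_b = unname(nb), pct_b = fmt_pct(unname(nb), nrow(cohort_b)),
      p = c(p, rep(NA_real_, length(levs) - 1)),
      method = c(method, rep(NA_character_, length(levs) - 1)),
      row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Per-domain survival associations
#'
#' For each of the four margin domains, Kaplan-Meier curves by score level
#' (0/1/2) and the log-rank test for each endpoint, with Benjamini-Hochberg
#' adjustment across the resulting family of tests. Levels with no patients
#' are dropped with a warning.
#'
#' @param scored A scored cohort (see [score_cohort()]) with both endpoint
#'   outcome column pairs.
#' @return List with `tests` (data frame: domain, endpoint, chi2, df, p,
#'   p_adj) and `km` (nested list of per-level [km_estimate()]s).
#' @export
domain_outcome_analysis <- function(scored) {
  domains <- c("histopathology_score", "tumor_burden_score",
               "molecular_score", "immune_score")
  rows <- list()
  kms <- list()
  for (dom in domains) {
    for (ep in .ENDPOINTS) {
      oc <- .endpoint_cols(ep)
      lev_present <- sort(unique(scored[[dom]]))
      if (length(lev_present) < length(0:2)) {
        warning("domain ", dom, ": score level(s) ",
                paste(setdiff(0:2, lev_present), collapse = ", "),
                " absent; dropped")
      }
      kms[[dom]][[ep]] <- lapply(setNames(lev_present, lev_present),
        function(l) {
          sel <- scored[[dom]] == l
          km_estimate(scored[[oc["time"]]][sel], scored[[oc["event"]]][sel])
        })
      res <- if (length(lev_present) >= 2) {
        lr <- logrank_test(scored[[oc["time"]]], scored[[oc["event"]]],
                           scored[[dom]])
        data.frame(domain = dom, endpoint = ep, chi2 = lr$chi2, df = lr$df,
                   p = lr$p)
      } else {
        data.frame(domain = dom, endpoint = ep, chi2 = NA_real_,
                   df = NA_integer_, p = NA_real_)
      }
      rows[[paste(dom, ep)]] <- res
    }
  }
  tests <- do.call(rbind, c(rows, make.row.names = FALSE))
  ok <- !is.na(tests$p)
  tests$p_adj <- NA_real_
  tests$p_adj[ok] <- bh_adjust(tests$p[ok])
  list(tests = tests, km = kms)
}

#' Adjusted multivariable MRIx Cox model
#'
#' The training-cohort model: differentiation (reference well), pathologic
#' response (reference pCR) and MRIx category (reference low) for one
#' endpoint, fitted by [fit_cox()] on complete cases.
#'
#' @param scored A scored cohort with outcome columns.
#' @param endpoint `"lrc"` or `"dmfs"`.
#' @param extra_factors Optional named list of additional factor vocabularies
#'   (reference first) to adjust for, e.g. the traditional margin class.
#' @return A `cox_fit` with terms named `<covariate>_<level>`.
#' @export
fit_adjusted_mrix_model <- function(scored, endpoint = c("lrc", "dmfs"),
                                    extra_factors = NULL) {
  endpoint <- match.arg(endpoint)
  oc <- .endpoint_cols(endpoint)
  factors <- c(.DESIGN_FACTORS[c("differentiation", "pathologic_response")],
               extra_factors,
               .DESIGN_FACTORS["mrix_category"])
  dat <- .complete_rows(scored, c(names(factors), oc))
  x <- .build_design(dat, factors)
  fit_cox(dat[[oc["time"]]], dat[[oc["event"]]], x)
}

#' Nested Cox model comparison
#'
#' Fits, on the identical complete-case row set, the three models of the
#' model-performance comparison: Clinical (differentiation + pathologic
#' response), Clinical + traditional margin (binary close/clear), and
#' Clinical + MRIx category. Reports per-model C-index (of the model linear
#' predictor), AIC, and likelihood-ratio statistics against the clinical
#' reference and against the previous model in the chain. The MRIx model
#' does not contain the margin term, so its "versus previous" comparison is
#' a log-likelihood difference between non-nested models of equal clinical
#' content; it is reported with `nested = FALSE`.
#'
#' @param scored A scored cohort with outcome columns.
#' @param endpoint `"lrc"` or `"dmfs"`.
#' @param boot_ci Number of bootstrap resamples for a percentile CI on each
#'   C-index (0 = no CI, the default; uses the current RNG state).
#' @return Object of class `model_comparison`: `models` (data frame with
#'   label, k, c_index, ci bounds, aic, loglik) and `lrt` (data frame with
#'   comparison, chi2, df, p, nested).
#' @export
compare_models <- function(scored, endpoint = c("lrc", "dmfs"),
                           boot_ci = 0) {
  endpoint <- match.arg(endpoint)
  oc <- .endpoint_cols(endpoint)
  specs <- list(
    clinical = .DESIGN_FACTORS[c("differentiation", "pathologic_response")],
    clinical_margin = .DESIGN_FACTORS[c("differentiation",
                                        "pathologic_response",
                                        "margin_class")],
    clinical_mrix = .DESIGN_FACTORS[c("differentiation",
                                      "pathologic_response",
                                      "mrix_category")]
  )
  all_cols <- unique(c(unlist(lapply(specs, names)), oc))
  dat <- .complete_rows(scored, all_cols)
  fits <- list()
  cstat <- list()
  for (nm in names(specs)) {
    x <- .build_design(dat, specs[[nm]])
    fit <- tryCatch(fit_cox(dat[[oc["time"]]], dat[[oc["event"]]], x),
                    error = function(e) {
                      stop("model '", nm, "' failed to fit: ",
                           conditionMessage(e))
                    })
    lp <- drop(x %*% fit$coef)
    ci <- c(NA_real_, NA_real_)
    cidx <- harrell_c(lp, dat[[oc["time"]]], dat[[oc["event"]]])$c_index
    if (boot_ci > 0) {
      bs <- replicate(boot_ci, {
        idx <- sample.int(nrow(dat), replace = TRUE)
        harrell_c(lp[idx], dat[[oc["time"]]][idx],
                  dat[[oc["event"]]][idx])$c_index
      })
      ci <- unname(quantile(bs, c(0.025, 0.975)))
    }
    fits[[nm]] <- fit
    cstat[[nm]] <- c(cidx, ci)
  }
  models <- data.frame(
    label = names(specs),
    k = vapply(fits, function(f) length(f$coef), numeric(1)),
    c_index = vapply(cstat, `[`, numeric(1), 1),
    c_lower = vapply(cstat, `[`, numeric(1), 2),
    c_upper = vapply(cstat, `[`, numeric(1), 3),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    row.names = NULL)
  lr12 <- lrt(fits$clinical, fits$clinical_margin)
  lr13 <- lrt(fits$clinical, fits$clinical_mrix)
  # non-nested pair: plain twice-log-likelihood difference
  chi23 <- 2 * (fits$clinical_mrix$loglik - fits$clinical_margin$loglik)
  df23 <- length(fits$clinical_mrix$coef) - length(fits$clinical_margin$coef)
  lrtab <- data.frame(
    comparison = c("clinical_margin vs clinical",
                   "clinical_mrix vs clinical",
                   "clinical_mrix vs clinical_margin"),
    chi2 = c(lr12$chi2, lr13$chi2, chi23),
    df = c(lr12$df, lr13$df, df23),
    p = c(lr12$p, lr13$p,
          pchisq(max(chi23, 0), max(df23, 1), lower.tail = FALSE)),
    nested = c(TRUE, TRUE, FALSE),
    row.names = NULL)
  structure(list(endpoint = endpoint, n = nrow(dat),
                 n_events = sum(dat[[oc["event"]]]),
                 models = models, lrt = lrtab, fits = fits),
            class = "model_comparison")
}

#' Frozen-score external validation workflow
#'
#' Applies a frozen scoring configuration (no re-estimation of thresholds,
#' weights or cuts) to an independent cohort and produces, per endpoint:
#' three-group Kaplan-Meier curves with the log-rank test over the MRIx
#' categories, Harrell's C-index of the continuous MRIx score, the adjusted
#' Cox model (differentiation, pathologic response, traditional margin
#' class, MRIx category), and fixed-horizon calibration with the
#' Hosmer-Lemeshow test, where predicted event probabilities come from the
#' adjusted model's Breslow baseline.
#'
#' @param frozen_config A [mrix_scoring_config()] (the frozen thresholds).
#' @param cohort An unscored (or scored; columns are recomputed) validation
#'   cohort with biomarker, clinical and outcome columns.
#' @param horizon Calibration horizon in months (default 36, i.e. 3-year
#'   outcomes).
#' @param n_groups Hosmer-Lemeshow group count.
#' @return List with `scored_n`, and per endpoint: `km` (per-category),
#'   `logrank`, `c_index`, `cox` (`cox_fit`), `calibration`
#'   (`calibration_result`).
#' @export
validate_external <- function(frozen_config, cohort, horizon = 36,
                              n_groups = 10) {
  stopifnot(inherits(frozen_config, "mrix_scoring_config"))
  scored <- score_cohort(cohort, frozen_config)
  factors <- .DESIGN_FACTORS[c("differentiation", "pathologic_response",
                               "margin_class", "mrix_category")]
  out <- list(scored_n = nrow(scored))
  for (ep in .ENDPOINTS) {
    oc <- .endpoint_cols(ep)
    dat <- .complete_rows(scored, c(names(factors), oc, "mrix_score"))
    km <- lapply(setNames(mrix_levels(), mrix_levels()), function(l) {
      sel <- dat$mrix_category == l
      if (!any(sel)) return(NULL)
      km_estimate(dat[[oc["time"]]][sel], dat[[oc["event"]]][sel])
    })
    lr <- logrank_test(dat[[oc["time"]]], dat[[oc["event"]]],
                       as.character(dat$mrix_category))
    cidx <- harrell_c(dat$mrix_score, dat[[oc["time"]]], dat[[oc["event"]]])
    x <- .build_design(dat, factors)
    fit <- fit_cox(dat[[oc["time"]]], dat[[oc["event"]]], x)
    bl <- breslow_baseline(fit, dat[[oc["time"]]], dat[[oc["event"]]], x)
    pred_event <- 1 - predict_survival(fit, bl, x, horizon = horizon)
    cal <- hosmer_lemeshow_survival(pred_event, dat[[oc["time"]]],
                                    dat[[oc["event"]]], horizon, n_groups)
    out[[ep]] <- list(km = km, logrank = lr, c_index = cidx$c_index,
                      cox = fit, calibration = cal)
  }
  out
}

#' Run the full study analysis
#'
#' Convenience orchestration: baseline comparison of the two cohorts,
#' per-domain survival associations, the adjusted MRIx model and nested
#' model comparison per endpoint on the training cohort, and the
#' frozen-score external validation on the validation cohort.
#'
#' @param training,validation Scored (or scorable) cohort data frames.
#' @param scoring_config The frozen [mrix_scoring_config()].
#' @param horizon Calibration horizon (months).
#' @return A `study_report` list with elements `baseline_table`,
#'   `domain_km`, `table3_analog`, `table4_analog`, `validation_block`.
#' @export
run_study <- function(training, validation,
                      scoring_config = mrix_scoring_config(), horizon = 36) {
  training <- score_cohort(training, scoring_config)
  report <- list(
    baseline_table = baseline_table(training, validation),
    domain_km = domain_outcome_analysis(training),
    table3_analog = lapply(setNames(.ENDPOINTS, .ENDPOINTS), function(ep) {
      fit_adjusted_mrix_model(training, ep)
    }),
    table4_analog = lapply(setNames(.ENDPOINTS, .ENDPOINTS), function(ep) {
      compare_models(training, ep)
    }),
    validation_block = validate_external(scoring_config, validation, horizon)
  )
  class(report) <- "study_report"
  report
}
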