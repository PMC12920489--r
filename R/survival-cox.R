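# Cox proportional-hazards regression on the partial likelihood with Efron
# handling of tied event times, fitted by Newton-Raphson with step-halving.
# Standard errors come from the inverse observed information.

## reverse cumulative sums down each column (sum over the risk set when rows
## are sorted by increasing time)
.revcumsum <- function(x) {
  if (is.matrix(x)) {
    x[rev(seq_len(nrow(x))), , drop = FALSE] |>
      apply(2, cumsum) |>
      (\(m) m[rev(seq_len(nrow(m))), , drop = FALSE])()
  } else {
    rev(cumsum(rev(x)))
  }
}

## partial log-likelihood, score vector and observed information at beta;
## what = "ll" skips the score/information work (used during step-halving).
## Untied event times are handled fully vectorized; tie groups (Efron or
## Breslow with d > 1) go through an explicit loop.
.cox_llk <- function(beta, time, event, x, ties, groups, what = "all") {
  p <- ncol(x)
  eta <- drop(x %*% beta)
  eta <- pmin(eta, 500)   # overflow guard; never binds for sane designs
  w <- exp(eta)
  rc0 <- .revcumsum(w)
  d_per <- lengths(groups$deaths)
  one <- d_per == 1 | (ties == "breslow" & rep(TRUE, length(d_per)))
  s1 <- groups$start[one]
  # Breslow treats each of the d tied deaths with the full risk set
  s1 <- rep(s1, d_per[one])
  D1 <- unlist(groups$deaths[one], use.names = FALSE)
  Dall <- unlist(groups$deaths, use.names = FALSE)
  ll <- sum(eta[Dall]) - sum(log(rc0[s1]))
  if (what == "ll" && !any(!one)) return(list(ll = ll))
  pr <- groups$pairs
  grad <- NULL; info <- NULL
  if (what != "ll") {
    rc1 <- .revcumsum(w * x)
    xx <- x[, pr[, 1], drop = FALSE] * x[, pr[, 2], drop = FALSE]
    rc2 <- .revcumsum(w * xx)
    mu <- rc1[s1, , drop = FALSE] / rc0[s1]
    grad <- colSums(x[D1, , drop = FALSE]) - colSums(mu)
    expand <- function(v) {
      m <- matrix(0, p, p)
      m[cbind(pr[, 1], pr[, 2])] <- v
      m[cbind(pr[, 2], pr[, 1])] <- v
      m
    }
    info <- expand(colSums(rc2[s1, , drop = FALSE] / rc0[s1])) -
      crossprod(mu)
  }
  # Efron tie groups
  for (gi in which(!one)) {
    s <- groups$start[gi]
    D <- groups$deaths[[gi]]
    d <- length(D)
    S0 <- rc0[s]
    xD <- x[D, , drop = FALSE]
    wD <- w[D]
    W0 <- sum(wD)
    f <- (0:(d - 1)) / d
    S0l <- S0 - f * W0
    ll <- ll - sum(log(S0l))
    if (what != "ll") {
      S1 <- rc1[s, ]
      S2 <- expand(rc2[s, ])
      W1 <- colSums(wD * xD)
      W2 <- expand(colSums(wD * xx[D, , drop = FALSE]))
      grad <- grad + colSums(xD)
      for (l in seq_len(d)) {
        mul <- (S1 - f[l] * W1) / S0l[l]
        grad <- grad - mul
        info <- info + (S2 - f[l] * W2) / S0l[l] - outer(mul, mul)
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

## index death-time groups once: rows sorted by increasing time; for each
## distinct event time, the first row of its risk set and the death rows
.cox_groups <- function(time, event, p) {
  ut <- unique(time[event == 1])
  start <- match(ut, time)   # time sorted ascending: first index with t >= ut
  deaths <- lapply(ut, function(t_i) which(time == t_i & event == 1))
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  list(start = start, deaths = deaths, pairs = pairs)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood with Efron's approximation for tied event
#' times (Breslow optionally) by Newton-Raphson from `coef = 0`, with
#' step-halving, to a score-vector norm below `tol` or `max_iter` iterations.
#' Standard errors are square roots of the diagonal of the inverse observed
#' information; hazard-ratio confidence intervals are Wald intervals
#' `exp(coef +/- 1.96 se)`.
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators (at least one event required).
#' @param x Design matrix (numeric, full rank, no constant column); column
#'   names label the coefficients.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Convergence tolerance on the score-vector norm.
#' @param max_iter Maximum Newton-Raphson iterations.
#' @return Object of class `cox_fit`: `coef`, `se`, `loglik`, `loglik_null`,
#'   `aic` (`-2 loglik + 2k`), `hr` (data frame of hazard ratios with 95%
#'   Wald bounds and p-values), `n`, `n_events`, `ties_method`, `converged`,
#'   `iterations` and the observed information `info`.
#' @export
fit_cox <- function(time, event, x, ties = c("efron", "breslow"),
                    tol = 1e-8, max_iter = 100) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  if (ncol(x) > 0 && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (length(time) != nrow(x) || length(event) != nrow(x)) {
    stop("time, event and design matrix dimensions disagree")
  }
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) == 0) stop("no events observed; cannot fit a Cox model")
  if (ncol(x) > 0) {
    if (any(apply(x, 2, function(col) max(col) == min(col)))) {
      stop("design matrix contains a constant column")
    }
    if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  }
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  x <- x[ord, , drop = FALSE]
  p <- ncol(x)
  if (p == 0) {
    groups <- .cox_groups(time, event, 1)
    ll0 <- .cox_llk(matrix(0), time, event,
                    matrix(0, nrow = length(time)), ties, groups)$ll
    return(structure(list(coef = numeric(0), se = numeric(0), loglik = ll0,
                          loglik_null = ll0, aic = -2 * ll0,
                          hr = data.frame(), n = length(time),
                          n_events = sum(event), ties_method = ties,
                          converged = TRUE, iterations = 0L,
                          info = matrix(0, 0, 0)),
                     class = "cox_fit"))
  }
  groups <- .cox_groups(time, event, p)
  beta <- numeric(p)
  cur <- .cox_llk(beta, time, event, x, ties, groups)
  ll_null <- cur$ll
  converged <- FALSE
  iter <- 0L
  flag <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    if (sqrt(sum(cur$grad^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) {
      flag <- "singular information matrix (possible separation)"
      break
    }
    # step-halving keeps the partial likelihood non-decreasing
    h <- 1
    repeat {
      cand <- beta + h * step
      ll_cand <- .cox_llk(cand, time, event, x, ties, groups, what = "ll")$ll
      if (is.finite(ll_cand) && ll_cand >= cur$ll - 1e-12) break
      h <- h / 2
      if (h < 1e-10) {
        flag <- "step-halving failed to improve the likelihood"
        break
      }
    }
    if (!is.null(flag)) break
    beta <- cand
    cur <- .cox_llk(beta, time, event, x, ties, groups)
    if (any(abs(beta) > 50)) {
      flag <- "coefficients diverging (possible separation)"
      break
    }
  }
  if (!converged && is.null(flag) && sqrt(sum(cur$grad^2)) < tol) {
    converged <- TRUE
  }
  if (!converged && is.null(flag)) flag <- "maximum iterations reached"
  if (is.null(flag) && any(abs(beta) > 15)) {
    flag <- "very large coefficients; possible separation or monotone likelihood"
  }
  vcv <- tryCatch(solve(cur$info), error = function(e) {
    matrix(NA_real_, p, p)
  })
  se <- sqrt(pmax(diag(vcv), 0))
  names(beta) <- names(se) <- colnames(x)
  z <- beta / se
  hr <- data.frame(term = colnames(x),
                   hr = exp(beta),
                   lower = exp(beta - 1.96 * se),
                   upper = exp(beta + 1.96 * se),
                   p = 2 * pnorm(abs(z), lower.tail = FALSE),
                   row.names = NULL)
  structure(list(coef = beta, se = se, loglik = cur$ll, loglik_null = ll_null,
                 aic = -2 * cur$ll + 2 * p, hr = hr, n = length(time),
                 n_events = sum(event), ties_method = ties,
                 converged = converged, diagnostic = flag,
                 iterations = iter, info = cur$info, vcov = vcv),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties_method, " ties)\n", sep = "")
  cat("n =", x$n, ", events =", x$n_events,
      ", loglik =", format(x$loglik, digits = 6),
      ", AIC =", format(x$aic, digits = 6), "\n")
  if (length(x$coef)) {
    tab <- cbind(coef = x$coef, se = x$se, x$hr[c("hr", "lower", "upper", "p")])
    print(format(tab, digits = 3))
  }
  if (!isTRUE(x$converged)) cat("WARNING:", x$diagnostic, "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param nested,full `cox_fit` objects on the same data, with the nested
#'   model's terms a subset of the full model's.
#' @return List with `chi2 = 2 * (loglik_full - loglik_nested)`,
#'   `df = k_full - k_nested` and the chi-squared p-value.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "cox_fit"), inherits(full, "cox_fit"))
  if (nested$n != full$n || nested$n_events != full$n_events) {
    stop("models were not fitted on the same data")
  }
  if (!all(names(nested$coef) %in% names(full$coef))) {
    stop("models are not nested: nested terms ",
         paste(setdiff(names(nested$coef), names(full$coef)), collapse = ", "),
         " absent from the full model")
  }
  df <- length(full$coef) - length(nested$coef)
  if (df < 0) stop("full model has fewer parameters than the nested model")
  chi2 <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Breslow cumulative baseline hazard
#'
#' Nonparametric estimate `H0(t) = sum_{t_k <= t} d_k / S0(t_k)` over distinct
#' event times, where `S0` is the risk-set sum of `exp(lp)` at the fitted
#' coefficients.
#'
#' @param fit A [fit_cox()] result.
#' @param time,event The outcome vectors the model was fitted on.
#' @param x The design matrix the model was fitted on.
#' @return Data frame with `time`, `hazard` (increment) and `cumhaz`.
#' @export
breslow_baseline <- function(fit, time, event, x) {
  x <- as.matrix(x)
  eta <- if (length(fit$coef)) drop(x %*% fit$coef) else numeric(nrow(x))
  w <- exp(eta)
  ut <- sort(unique(time[event == 1]))
  inc <- vapply(ut, function(t_i) {
    sum(time == t_i & event == 1) / sum(w[time >= t_i])
  }, numeric(1))
  data.frame(time = ut, hazard = inc, cumhaz = cumsum(inc))
}

#' Predicted survival probability at a horizon
#'
#' `S(t | x) = exp(-H0(t) exp(lp))` from a fitted Cox model and its Breslow
#' baseline. Horizons beyond the last observed event time carry the last
#' baseline value forward with a warning.
#'
#' @param fit A [fit_cox()] result.
#' @param baseline A [breslow_baseline()] result.
#' @param x Design matrix of new observations (or a numeric vector of linear
#'   predictors via `lp`).
#' @param horizon Time (months) at which to predict; `0` returns 1.
#' @param lp Optional precomputed linear predictors (overrides `x`).
#' @return Numeric vector of survival probabilities in `(0, 1]`.
#' @export
predict_survival <- function(fit, baseline, x = NULL, horizon, lp = NULL) {
  if (horizon < 0) stop("horizon must be non-negative")
  if (is.null(lp)) {
    x <- as.matrix(x)
    lp <- if (length(fit$coef)) drop(x %*% fit$coef) else numeric(nrow(x))
  }
  if (horizon > max(baseline$time)) {
    warning("horizon beyond last observed event time; ",
            "carrying the last baseline value forward")
  }
  idx <- which(baseline$time <= horizon)
  H0 <- if (length(idx) == 0) 0 else baseline$cumhaz[max(idx)]
  exp(-H0 * exp(lp))
}
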