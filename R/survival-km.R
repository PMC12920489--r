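# Kaplan-Meier product-limit estimation and the k-sample log-rank test.

#' Kaplan-Meier estimate with Greenwood variance
#'
#' @param time Positive event/censoring times (months).
#' @param event 0/1 event indicators (1 = event observed).
#' @return Object of class `km_estimate`: a list with `event_times` (sorted
#'   distinct times at which at least one event occurred), `survival` (the
#'   product-limit step values), `at_risk`, `n_events` and `greenwood_var`
#'   (variance of the survival estimate at each step).
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("no observations")
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time[event == 1])
  n <- length(time)
  surv <- numeric(length(ut))
  atrisk <- integer(length(ut))
  nev <- integer(length(ut))
  gw <- numeric(length(ut))
  s <- 1
  gsum <- 0
  for (i in seq_along(ut)) {
    t_i <- ut[i]
    r <- sum(time >= t_i)
    d <- sum(time == t_i & event == 1)
    s <- s * (1 - d / r)
    if (r > d) gsum <- gsum + d / (r * (r - d))
    surv[i] <- s
    atrisk[i] <- r
    nev[i] <- d
    gw[i] <- s^2 * gsum
  }
  structure(list(event_times = ut, survival = surv, at_risk = atrisk,
                 n_events = nev, greenwood_var = gw, n = n),
            class = "km_estimate")
}

#' Evaluate a Kaplan-Meier estimate at given times
#'
#' Step-function evaluation; times before the first event return 1, times
#' beyond the last step carry the last value.
#'
#' @param km A [km_estimate()].
#' @param times Times at which to evaluate the survival function.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(t) {
    idx <- which(km$event_times <= t)
    if (length(idx) == 0) 1 else km$survival[max(idx)]
  }, numeric(1))
}

#' k-sample log-rank test
#'
#' Observed-minus-expected event counts per group accumulated over distinct
#' event times, with the hypergeometric variance-covariance; the statistic is
#' the quadratic form over k - 1 groups and is chi-squared with k - 1 degrees
#' of freedom under the null of identical hazards.
#'
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param group Group labels (>= 2 non-empty groups).
#' @return List with `chi2`, `df`, `p`, `observed` and `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.character(group)
  levs <- sort(unique(group))
  k <- length(levs)
  if (k < 2) stop("log-rank test needs at least two groups")
  if (any(time <= 0)) stop("times must be positive")
  g <- match(group, levs)
  ut <- sort(unique(time[event == 1]))
  O <- numeric(k); E <- numeric(k)
  V <- matrix(0, k, k)
  for (t_i in ut) {
    at <- time >= t_i
    n_i <- sum(at)
    d_i <- sum(time == t_i & event == 1)
    n_ij <- tabulate(g[at], nbins = k)
    d_ij <- tabulate(g[time == t_i & event == 1], nbins = k)
    O <- O + d_ij
    E <- E + d_i * n_ij / n_i
    if (n_i > 1) {
      f <- d_i * (n_i - d_i) / (n_i - 1)
      p_ij <- n_ij / n_i
      V <- V + f * (diag(p_ij, k) - outer(p_ij, p_ij))
    }
  }
  ome <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  # pseudo-inverse guards degenerate designs (e.g. duplicated groups)
  sv <- svd(Vk)
  pos <- sv$d > max(sv$d[1], 0) * 1e-12
  chi2 <- if (!any(pos) || all(abs(ome) < 1e-12)) {
    0
  } else {
    vinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    as.numeric(t(ome) %*% vinv %*% ome)
  }
  chi2 <- max(chi2, 0)
  df <- k - 1
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       observed = setNames(O, levs), expected = setNames(E, levs))
}
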