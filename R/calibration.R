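# Fixed-horizon calibration (Hosmer-Lemeshow on grouped predicted event
# probabilities, observed rates from within-group Kaplan-Meier) and the
# Benjamini-Hochberg step-up adjustment.

#' Hosmer-Lemeshow calibration test for survival predictions
#'
#' Groups patients by predicted event probability at the horizon (decile
#' groups by default), takes the observed group event probability as
#' `1 - KM(horizon)` within the group (which accounts for censoring), and
#' forms `chi2 = sum n_g (obs_g - pred_g)^2 / (pred_g (1 - pred_g))` with
#' `df = g - 2` per the Hosmer-Lemeshow convention.
#'
#' @param predicted Predicted event probabilities at the horizon, in `[0, 1]`.
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param horizon Months at which calibration is assessed.
#' @param n_groups Number of probability groups (>= 2; default 10).
#' @return Object of class `calibration_result`: `horizon`, `groups` (data
#'   frame with `n`, `mean_predicted`, `observed`), `hl_chi2`, `hl_df`,
#'   `hl_p`, and `merged` (number of degenerate groups merged, with a note).
#' @export
hosmer_lemeshow_survival <- function(predicted, time, event, horizon,
                                     n_groups = 10) {
  if (n_groups < 2) stop("n_groups must be at least 2")
  if (any(predicted < 0 | predicted > 1)) {
    stop("predicted probabilities must be in [0, 1]")
  }
  if (length(predicted) != length(time)) stop("input lengths disagree")
  br <- unique(quantile(predicted, probs = seq(0, 1, length.out = n_groups + 1)))
  if (length(br) < 3) stop("predicted probabilities too concentrated to group")
  grp <- cut(predicted, breaks = br, include.lowest = TRUE, labels = FALSE)
  stats_g <- lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    km <- km_estimate(time[sel], event[sel])
    data.frame(n = sum(sel),
               mean_predicted = mean(predicted[sel]),
               observed = 1 - km_survival_at(km, horizon))
  })
  tab <- do.call(rbind, stats_g)
  # merge groups with degenerate mean predictions into their neighbor
  merged <- 0L
  repeat {
    bad <- which(tab$mean_predicted <= 0 | tab$mean_predicted >= 1)
    if (!length(bad) || nrow(tab) <= 2) break
    i <- bad[1]
    j <- if (i == 1) 2L else i - 1L
    wsum <- tab$n[i] + tab$n[j]
    tab$mean_predicted[j] <- (tab$n[i] * tab$mean_predicted[i] +
                                tab$n[j] * tab$mean_predicted[j]) / wsum
    tab$observed[j] <- (tab$n[i] * tab$observed[i] +
                          tab$n[j] * tab$observed[j]) / wsum
    tab$n[j] <- wsum
    tab <- tab[-i, , drop = FALSE]
    merged <- merged + 1L
  }
  chi2 <- sum(tab$n * (tab$observed - tab$mean_predicted)^2 /
                (tab$mean_predicted * (1 - tab$mean_predicted)))
  df <- max(nrow(tab) - 2, 1)
  structure(list(horizon = horizon, groups = tab, hl_chi2 = chi2,
                 hl_df = df, hl_p = pchisq(chi2, df, lower.tail = FALSE),
                 merged = merged),
            class = "calibration_result")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' the adjusted value is `min_{k >= i} m p_(k) / k`, capped at 1. Output is
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  adj[order(o)]
}
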