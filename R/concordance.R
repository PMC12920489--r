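# Harrell's concordance index for censored survival data.
#
# Pair convention (documented because variants differ): an ordered pair
# (i, j) is usable when subject i's time is strictly shorter and an event
# (t_i < t_j, e_i = 1), or when the times are equal and i is the event while
# j is censored (the event precedes the censoring). Pairs tied on time with
# both events are unusable, as are pairs whose shorter time is censored.
# A usable pair is concordant when the higher risk score belongs to the
# earlier event (risk_i > risk_j); ties in risk score count 0.5.

.harrell_brute <- function(risk, time, event) {
  n <- length(risk)
  conc <- disc <- tied <- 0
  ev <- which(event == 1)
  for (i in ev) {
    usable <- (time > time[i]) | (time == time[i] & event == 0)
    usable[i] <- FALSE
    if (!any(usable)) next
    r <- risk[usable]
    conc <- conc + sum(risk[i] > r)
    disc <- disc + sum(risk[i] < r)
    tied <- tied + sum(risk[i] == r)
  }
  c(conc = conc, disc = disc, tied = tied)
}

## Fenwick (binary indexed) tree counting previously inserted risk ranks
.harrell_fast <- function(risk, time, event) {
  rk <- match(risk, sort(unique(risk)))
  m <- max(rk)
  tree <- numeric(m)
  add <- function(i) {
    while (i <= m) {
      tree[i] <<- tree[i] + 1
      i <- i + bitwAnd(i, -i)
    }
  }
  prefix <- function(i) {   # count of inserted ranks <= i
    s <- 0
    while (i > 0) {
      s <- s + tree[i]
      i <- i - bitwAnd(i, -i)
    }
    s
  }
  conc <- disc <- tied <- 0
  inserted <- 0
  ord <- order(-time)
  groups <- split(ord, time[ord])
  # process distinct times in decreasing order; everything already inserted
  # has a strictly longer time
  for (idx in rev(seq_along(groups))) {
    g <- groups[[idx]]
    evg <- g[event[g] == 1]
    ceng <- g[event[g] == 0]
    for (i in evg) {
      le <- prefix(rk[i]);  lt <- prefix(rk[i] - 1)
      conc <- conc + lt
      tied <- tied + (le - lt)
      disc <- disc + (inserted - le)
      if (length(ceng)) {   # same-time censored subjects are usable partners
        rc <- rk[ceng]
        conc <- conc + sum(rc < rk[i])
        tied <- tied + sum(rc == rk[i])
        disc <- disc + sum(rc > rk[i])
      }
    }
    for (i in g) add(rk[i])
    inserted <- inserted + length(g)
  }
  c(conc = conc, disc = disc, tied = tied)
}

#' Harrell's concordance index
#'
#' Probability that, over usable patient pairs, the higher risk score is
#' assigned to the patient with the earlier event; ties in risk score count
#' one half. Computed by explicit pair enumeration for `n <= 2000` and by an
#' order-statistics (Fenwick tree) path above, both implementing the same
#' pair convention.
#'
#' @param risk Numeric risk scores (higher = riskier).
#' @param time Positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param method `"auto"` (default; brute force up to n = 2000), `"brute"`,
#'   or `"fast"`.
#' @return List with `c_index`, `concordant`, `discordant`, `tied` and
#'   `usable` pair counts.
#' @export
harrell_c <- function(risk, time, event, method = c("auto", "brute", "fast")) {
  method <- match.arg(method)
  n <- length(risk)
  if (length(time) != n || length(event) != n) {
    stop("risk, time and event lengths disagree")
  }
  if (anyNA(risk) || anyNA(time) || anyNA(event)) stop("missing values")
  counts <- switch(method,
                   brute = .harrell_brute(risk, time, event),
                   fast = .harrell_fast(risk, time, event),
                   auto = if (n <= 2000) .harrell_brute(risk, time, event)
                          else .harrell_fast(risk, time, event))
  usable <- sum(counts)
  if (usable == 0) stop("no usable pairs (no events, or all times tied)")
  list(c_index = (counts[["conc"]] + 0.5 * counts[["tied"]]) / usable,
       concordant = counts[["conc"]], discordant = counts[["disc"]],
       tied = counts[["tied"]], usable = usable)
}
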