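# Kaplan-Meier product-limit estimation and the two-group log-rank test.

#' Kaplan-Meier estimate of the survival function
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicators; censored subjects leave the risk
#'   set without producing a step.
#' @return object of class `km_curve`: event `times`, `surv`
#'   probabilities after each event time, `n_risk` and `n_event` at each.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)),
            all(time > 0))
  tev <- sort(unique(time[event == 1]))
  if (!length(tev)) {
    return(structure(list(times = numeric(0), surv = numeric(0),
                          n_risk = integer(0), n_event = integer(0), n = length(time)),
                     class = "km_curve"))
  }
  n_risk <- vapply(tev, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(tev, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(times = tev, surv = surv, n_risk = n_risk,
                 n_event = n_event, n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n=%d, %d event time(s)\n",
              x$n, length(x$times)))
  print(head(data.frame(time = x$times, n_risk = x$n_risk,
                        n_event = x$n_event, surv = x$surv), 10))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a `km_curve`.
#' @param t times at which to evaluate S(t).
#' @return numeric vector of survival probabilities (right-continuous
#'   step function, S(t) = 1 before the first event).
#' @export
km_surv_at <- function(km, t) {
  if (!length(km$times)) return(rep(1, length(t)))
  idx <- findInterval(t, km$times)
  c(1, km$surv)[idx + 1L]
}

#' Two-group log-rank test
#'
#' Standard log-rank with hypergeometric variance at each event time;
#' the statistic is compared to chi-square with 1 df.
#'
#' @param time,event as in [km_estimate()].
#' @param group vector with exactly two distinct values.
#' @return list with `chi2`, `p`, observed/expected events per group.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(group))
  g <- unique(group)
  if (length(g) != 2) stop("log-rank test needs exactly 2 groups, got ",
                           length(g))
  inA <- group == g[1]
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); nA <- sum(at_risk & inA)
    d <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & inA)
    O <- O + dA
    E <- E + d * nA / n
    if (n > 1) V <- V + d * (n - d) * nA * (n - nA) / (n^2 * (n - 1))
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) pchisq(chi2, df = 1, lower.tail = FALSE) else 1
  list(chi2 = chi2, p = p, observed = O, expected = E, var = V,
       groups = g)
}
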