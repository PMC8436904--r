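# Time-dependent ROC at a horizon t with the cumulative-case /
# dynamic-control definition: cases are subjects with an event by t,
# controls are event-free past t. Censoring before t is handled with
# the Kaplan-Meier redistribution estimator (Heagerty-style "KM"
# method): for a threshold c,
#   Se(c) = (1 - S_{>c}(t)) P(score > c) / (1 - S(t))
#   Sp(c) =        S_{<=c}(t) (1 - P(score > c)) / S(t)
# where S_{>c}, S_{<=c} are KM curves within the score strata and
# S(t) is their mixture. With no censoring before t this reduces
# exactly to the empirical ROC of cases versus controls.

#' Time-dependent ROC curve at a horizon
#'
#' @param scores named numeric risk scores (higher = higher risk).
#' @param time,event survival outcome aligned with `scores` (or pass a
#'   clinical data.frame via `clinical` with matching sample ids).
#' @param horizon evaluation time t in the same unit as `time`.
#' @param clinical optional clinical data.frame (sample_id/time/event);
#'   used when `time`/`event` are missing.
#' @return object of class `roc_curve`: `horizon`, `thresholds`
#'   (including -Inf for the all-positive corner), `sens`, `spec`,
#'   `auc` (trapezoid over the (1-spec, sens) polyline).
#' @export
time_dependent_roc <- function(scores, time = NULL, event = NULL,
                               horizon, clinical = NULL) {
  if (is.null(time)) {
    stopifnot(!is.null(clinical), !is.null(names(scores)))
    i <- match(names(scores), clinical$sample_id)
    if (anyNA(i)) stop("clinical data missing for some scored samples")
    time <- clinical$time[i]; event <- clinical$event[i]
  }
  stopifnot(length(scores) == length(time), length(time) == length(event))
  if (!any(time <= horizon & event == 1))
    stop("horizon precedes the first event: no cases by t = ", horizon)
  if (!any(time > horizon))
    stop("no subjects at risk past the horizon t = ", horizon)

  thr <- c(-Inf, sort(unique(scores)))
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pos <- scores > thr[i]
    p_pos <- mean(pos)
    s_pos <- if (any(pos)) km_surv_at(km_estimate(time[pos], event[pos]),
                                      horizon) else 1
    s_neg <- if (any(!pos)) km_surv_at(km_estimate(time[!pos], event[!pos]),
                                       horizon) else 1
    s_all <- p_pos * s_pos + (1 - p_pos) * s_neg
    sens[i] <- if (s_all < 1) (1 - s_pos) * p_pos / (1 - s_all) else 0
    spec[i] <- if (s_all > 0) s_neg * (1 - p_pos) / s_all else 1
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  roc_curve(thresholds = thr, sens = sens, spec = spec, horizon = horizon)
}

#' Construct an ROC curve object
#'
#' Mostly internal; exported so hand-built curves can be fed to
#' [optimal_cutoff()].
#'
#' @param thresholds,sens,spec parallel vectors of cutpoints and the
#'   sensitivity/specificity attained by predicting positive above each.
#' @param horizon evaluation time (NA for a plain ROC).
#' @param auc area under the curve; computed by trapezoid if NULL.
#' @return `roc_curve` object.
#' @export
roc_curve <- function(thresholds, sens, spec, horizon = NA_real_,
                      auc = NULL) {
  stopifnot(length(thresholds) == length(sens),
            length(sens) == length(spec))
  fpr <- 1 - spec
  # walk the curve by decreasing threshold (both coordinates are then
  # non-decreasing); ordering by fpr instead is unstable when float
  # noise perturbs ties in 1 - spec
  ord <- if (!anyNA(thresholds)) order(thresholds, decreasing = TRUE)
         else order(fpr, sens)
  xs <- c(0, fpr[ord], 1)
  ys <- c(0, sens[ord], 1)
  if (is.null(auc))
    auc <- sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  structure(list(horizon = horizon, thresholds = thresholds,
                 sens = sens, spec = spec, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve%s: AUC = %.4f (%d thresholds)\n",
              if (is.na(x$horizon)) "" else
                sprintf(" at t = %g", x$horizon),
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Youden-optimal cutoff on an ROC curve
#'
#' Maximizes the Youden index (sensitivity + specificity - 1) over the
#' finite thresholds of the curve; ties are broken toward the cutoff
#' with the higher sensitivity. When the survival outcome is supplied,
#' the AIC of the implied two-group Cox model (high vs low risk) is
#' reported alongside for transparency.
#'
#' @param roc a `roc_curve`.
#' @param scores,time,event optional; used for the two-group AIC.
#' @return list of class `cutoff_result`: `cutoff`, `youden`, `sens`,
#'   `spec`, `aic` (NA when outcome not supplied).
#' @export
optimal_cutoff <- function(roc, scores = NULL, time = NULL, event = NULL) {
  stopifnot(inherits(roc, "roc_curve"))
  finite <- is.finite(roc$thresholds)
  if (!any(finite)) stop("no finite thresholds on the curve")
  youden <- roc$sens + roc$spec - 1
  cand <- which(finite)
  best_y <- max(youden[cand])
  at_max <- cand[youden[cand] == best_y]
  best <- at_max[which.max(roc$sens[at_max])]
  aic <- NA_real_
  if (!is.null(scores) && !is.null(time)) {
    grp <- as.numeric(scores > roc$thresholds[best])
    if (length(unique(grp)) == 2)
      aic <- fit_cox(grp, time, event)$aic
  }
  structure(list(cutoff = roc$thresholds[best], youden = best_y,
                 sens = roc$sens[best], spec = roc$spec[best], aic = aic),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff = %g (Youden = %.4f, sens = %.3f, spec = %.3f%s)\n",
              x$cutoff, x$youden, x$sens, x$spec,
              if (is.na(x$aic)) "" else sprintf(", 2-group AIC = %.2f",
                                                x$aic)))
  invisible(x)
}

#' Assign risk groups at a cutoff
#'
#' High risk strictly above the cutoff, low risk otherwise.
#'
#' @param scores named numeric risk scores.
#' @param cutoff numeric cutoff (or a `cutoff_result`).
#' @return named character vector "high"/"low" with attribute `cutoff`.
#' @export
assign_groups <- function(scores, cutoff) {
  if (inherits(cutoff, "cutoff_result")) cutoff <- cutoff$cutoff
  g <- ifelse(scores > cutoff, "high", "low")
  attr(g, "cutoff") <- cutoff
  g
}
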