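# Downstream validation of a fitted signature: risk-group survival
# comparison, independence from clinical covariates, and association
# with clinicopathological categories.

#' Compare survival between risk groups
#'
#' Kaplan-Meier curve per group plus the two-group log-rank test.
#'
#' @param groups named "high"/"low" vector (from [assign_groups()]).
#' @param clinical clinical data.frame covering the grouped samples.
#' @return list: `km` (named list of `km_curve`), `chi2`, `p`,
#'   `n_per_group`.
#' @export
compare_groups_survival <- function(groups, clinical) {
  i <- match(names(groups), clinical$sample_id)
  if (anyNA(i)) stop("clinical data missing for some grouped samples")
  time <- clinical$time[i]; event <- clinical$event[i]
  lev <- unique(groups)
  if (length(lev) < 2)
    stop("need two risk groups, got only: ", paste(lev, collapse = ", "))
  km <- lapply(setNames(lev, lev), function(g)
    km_estimate(time[groups == g], event[groups == g]))
  lr <- logrank_test(time, event, groups)
  list(km = km, chi2 = lr$chi2, p = lr$p,
       n_per_group = table(groups))
}

#' Independence analysis of the risk score
#'
#' Univariate Cox per covariate (risk score entered continuously) and
#' one multivariate Cox over all of them. Ordered categorical
#' covariates (stage I-IV, T/N/M) are coded ordinally by the rank of
#' their sorted levels, giving a single hazard ratio per covariate;
#' two-level categories (sex) become 0/1.
#'
#' @param scores named risk scores.
#' @param clinical clinical data.frame with the covariate columns.
#' @param covariates clinical column names to include alongside the
#'   risk score (defaults to the intersection of
#'   c("age","sex","stage","T","N","M") with the table).
#' @return list: `univariate` and `multivariate` data.frames
#'   (covariate, hr, ci_lower, ci_upper, p), plus the `fits`.
#' @export
independence_analysis <- function(scores, clinical,
                                  covariates = NULL) {
  covariates <- covariates %||%
    intersect(c("age", "sex", "stage", "T", "N", "M"), colnames(clinical))
  i <- match(names(scores), clinical$sample_id)
  if (anyNA(i)) stop("clinical data missing for some scored samples")
  cl <- clinical[i, , drop = FALSE]
  X <- cbind(risk_score = as.numeric(scores))
  for (cv in covariates) X <- cbind(X, encode_ordinal(cl[[cv]], cv))
  colnames(X) <- c("risk_score", covariates)
  dup_cols <- which(duplicated(t(X)))
  if (length(dup_cols))
    warning("collinear covariate(s) duplicated in the design: ",
            paste(colnames(X)[dup_cols], collapse = ", "))
  uni <- lapply(colnames(X), function(nm)
    fit_cox(X[, nm], cl$time, cl$event))
  names(uni) <- colnames(X)
  multi <- fit_cox(X, cl$time, cl$event)
  fit_row <- function(f, nm, j = 1L)
    data.frame(covariate = nm, hr = unname(f$hr[j]),
               ci_lower = unname(f$ci_lower[j]),
               ci_upper = unname(f$ci_upper[j]), p = unname(f$p[j]),
               stringsAsFactors = FALSE)
  list(
    univariate = do.call(rbind, lapply(names(uni), function(nm)
      fit_row(uni[[nm]], nm))),
    multivariate = do.call(rbind, lapply(seq_along(colnames(X)),
      function(j) fit_row(multi, colnames(X)[j], j))),
    fits = list(univariate = uni, multivariate = multi))
}

encode_ordinal <- function(v, name) {
  if (is.numeric(v)) return(v)
  lev <- sort(unique(as.character(v)))
  out <- match(as.character(v), lev)
  if (anyNA(out)) stop("cannot encode covariate ", name)
  out
}

#' Association of risk groups/scores with clinical categories
#'
#' Per categorical covariate: a chi-square test (no continuity
#' correction) on the risk-group x category contingency table, with a
#' flag when any expected count falls below 5; and, when `scores` are
#' supplied and the covariate has exactly two levels, a Wilcoxon
#' rank-sum comparison of the scores between the levels (exact
#' enumeration for total n <= 25 without ties, normal approximation
#' with tie correction otherwise).
#'
#' @param clinical clinical data.frame.
#' @param categories column names of the categorical covariates.
#' @param groups named "high"/"low" vector (for the chi-square tests).
#' @param scores named risk scores (for the rank-sum tests).
#' @return data.frame: covariate, test, statistic, p, stars,
#'   low_expected.
#' @export
association_tests <- function(clinical, categories, groups = NULL,
                              scores = NULL) {
  if (is.null(groups) && is.null(scores))
    stop("supply at least one of groups/scores")
  rows <- list()
  for (cat_col in categories) {
    if (!cat_col %in% colnames(clinical))
      stop("no such clinical column: ", cat_col)
    if (!is.null(groups)) {
      i <- match(names(groups), clinical$sample_id)
      v <- as.character(clinical[[cat_col]][i])
      tab <- table(groups, v)
      if (all(dim(tab) >= 2)) {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cat_col, test = "chi-square",
          statistic = unname(ct$statistic), p = unname(ct$p.value),
          stars = p_stars(unname(ct$p.value)),
          low_expected = any(ct$expected < 5), stringsAsFactors = FALSE)
      }
    }
    if (!is.null(scores)) {
      i <- match(names(scores), clinical$sample_id)
      v <- as.character(clinical[[cat_col]][i])
      lev <- sort(unique(v))
      if (length(lev) == 2) {
        a <- scores[v == lev[1]]; b <- scores[v == lev[2]]
        wt <- rank_sum_test(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cat_col, test = "wilcoxon-rank-sum",
          statistic = wt$statistic, p = wt$p, stars = p_stars(wt$p),
          low_expected = NA, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is <= 25 and there
#' are no ties; otherwise the normal approximation with tie-corrected
#' variance (no continuity correction).
#'
#' @param a,b numeric vectors.
#' @return list with `statistic` (Mann-Whitney U of `a`) and two-sided
#'   `p`.
#' @export
rank_sum_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 > 0, n2 > 0)
  v <- c(a, b)
  ties <- anyDuplicated(v) > 0
  r <- rank(v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && n1 + n2 <= 25) {
    p <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(v)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) /
         ((n1 + n2) * (n1 + n2 - 1)))
    if (sig2 == 0) return(list(statistic = U, p = 1))
    z <- (U - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = U, p = min(p, 1))
}
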