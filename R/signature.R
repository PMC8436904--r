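# Prognostic signature construction over pair indicators:
#   univariate Cox screen (p < 0.05)
#   -> repeated cross-validated LASSO-Cox, selection counted over cycles
#   -> multivariate Cox with backward AIC reduction
#   -> risk score = sum_i Coef(i) * E(i).

#' Univariate Cox screen of pair indicators
#'
#' Each pair enters a one-covariate Cox model against overall survival;
#' pairs with Wald p below `p_thresh` and an unflagged (converged,
#' non-separating) fit are retained.
#'
#' @param pm a `pair_matrix`.
#' @param clinical clinical data.frame with sample_id, time, event
#'   covering the pair-matrix samples.
#' @param p_thresh retention threshold (strict).
#' @return character vector of retained pair ids, with attribute
#'   `table` holding the full per-pair results (pair_id, beta, hr, p,
#'   flagged).
#' @export
univariate_screen <- function(pm, clinical, p_thresh = 0.05) {
  stopifnot(inherits(pm, "pair_matrix"))
  cl <- align_clinical(clinical, pm$sample_ids)
  const <- apply(pm$values, 1, function(v) length(unique(v)) == 1)
  if (any(const))
    stop("constant pair(s) (apply filter_pairs first): ",
         paste(pm$pair_ids[const], collapse = ", "))
  res <- lapply(seq_along(pm$pair_ids), function(i) {
    f <- fit_cox(pm$values[i, cl$idx], cl$time, cl$event)
    data.frame(pair_id = pm$pair_ids[i], beta = unname(f$beta),
               hr = unname(f$hr), p = unname(f$p), flagged = f$flagged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  keep <- tab$pair_id[!tab$flagged & tab$p < p_thresh]
  attr(keep, "table") <- tab
  keep
}

align_clinical <- function(clinical, sample_ids) {
  miss <- setdiff(sample_ids, clinical$sample_id)
  if (length(miss))
    stop("clinical data missing for sample(s): ",
         paste(head(miss, 5), collapse = ", "))
  i <- match(sample_ids, clinical$sample_id)
  list(idx = seq_along(sample_ids), time = clinical$time[i],
       event = clinical$event[i])
}

#' Repeated cross-validated LASSO-Cox selection by occurrence frequency
#'
#' Runs `n_cycles` cycles; each cycle draws a fresh random fold
#' assignment, fits the cross-validated L1-penalized Cox path
#' (glmnet backend, 100-value log-spaced lambda grid), takes the model
#' at the lambda minimizing mean CV partial-likelihood deviance, and
#' records which pairs have nonzero coefficients. Pairs selected in
#' strictly more than `freq_thresh` cycles are returned.
#'
#' The reference protocol ran 1000 cycles and kept pairs above
#' frequency 100, i.e. above 10% of cycles; `freq_thresh` therefore
#' defaults to `n_cycles / 10` so the rule scales with the cycle count.
#'
#' @param pm a `pair_matrix` restricted to the screened pairs (>= 2).
#' @param clinical clinical data.frame.
#' @param n_cycles number of cross-validation cycles.
#' @param n_folds folds per cycle; must not exceed the event count.
#' @param freq_thresh strict selection threshold on occurrence counts.
#' @param seed integer seed; identical seeds give identical frequencies.
#' @return list of class `lasso_selection`: `frequency` (named counts),
#'   `selected` (pair ids with frequency > freq_thresh), `n_cycles`,
#'   `freq_thresh`, `lambda_rule` ("lambda.min"), `no_signal` (TRUE when
#'   nothing was ever selected).
#' @export
repeated_lasso <- function(pm, clinical, n_cycles = 1000, n_folds = 10,
                           freq_thresh = n_cycles / 10, seed = 1L) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (length(pm$pair_ids) < 2) stop("need >= 2 screened pairs")
  cl <- align_clinical(clinical, pm$sample_ids)
  if (n_cycles > 0 && sum(cl$event) < n_folds)
    stop("need at least n_folds events")
  freq <- setNames(integer(length(pm$pair_ids)), pm$pair_ids)
  if (n_cycles == 0) {
    return(structure(list(frequency = freq, selected = character(0),
                          n_cycles = 0L, freq_thresh = freq_thresh,
                          lambda_rule = "lambda.min", no_signal = TRUE),
                     class = "lasso_selection"))
  }
  X <- t(pm$values)
  y <- survival::Surv(cl$time, cl$event)
  nobs <- nrow(X)
  set.seed(as.integer(seed))
  for (cycle in seq_len(n_cycles)) {
    foldid <- sample(rep(seq_len(n_folds), length.out = nobs))
    sel <- tryCatch({
      cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                              foldid = foldid, nlambda = 100)
      b <- as.matrix(glmnet::coef.glmnet(cv$glmnet.fit, s = cv$lambda.min))
      rownames(b)[b[, 1] != 0]
    }, error = function(e) {
      warning("LASSO cycle ", cycle, " failed: ", conditionMessage(e))
      character(0)
    })
    freq[sel] <- freq[sel] + 1L
  }
  selected <- names(freq)[freq > freq_thresh]
  structure(list(frequency = freq, selected = selected,
                 n_cycles = as.integer(n_cycles), freq_thresh = freq_thresh,
                 lambda_rule = "lambda.min",
                 no_signal = all(freq == 0L)),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf(
    "LASSO selection: %d cycles, threshold > %g; %d pair(s) selected%s\n",
    x$n_cycles, x$freq_thresh, length(x$selected),
    if (x$no_signal) " [no signal: nothing ever selected]" else ""))
  invisible(x)
}

#' Fit the final pair signature
#'
#' Multivariate Cox on the selected pairs followed by backward stepwise
#' elimination: while removing some pair lowers the AIC, remove the one
#' giving the lowest AIC. Duplicate (collinear) pair columns are
#' dropped with a warning before fitting, as are pairs whose presence
#' makes the fit diverge.
#'
#' @param pm a `pair_matrix` containing at least the selected pairs.
#' @param clinical clinical data.frame.
#' @param pairs pair ids to start from (default: all pairs in `pm`).
#' @param provenance optional list (screen table, LASSO frequencies)
#'   stored on the model.
#' @return object of class `signature_model`: `pairs`, `coef` (the
#'   Coef(i) of the risk-score formula), the final `fit` (a `cox_fit`),
#'   and `provenance`.
#' @export
fit_signature <- function(pm, clinical, pairs = NULL, provenance = list()) {
  stopifnot(inherits(pm, "pair_matrix"))
  pairs <- pairs %||% pm$pair_ids
  if (!length(pairs)) stop("no pairs to fit")
  pm <- subset_pairs(pm, pairs = pairs)
  cl <- align_clinical(clinical, pm$sample_ids)
  X <- t(pm$values)

  # identical columns, and complementary ones (1 - A), are collinear in
  # a Cox model; canonicalize so both show up as duplicates
  canon <- apply(X, 2, function(v) if (v[1] == 1) 1 - v else v)
  dup <- duplicated(t(canon))
  if (any(dup)) {
    warning("dropping collinear pair column(s): ",
            paste(colnames(X)[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
  }

  fit <- fit_cox(X, cl$time, cl$event)
  while (fit$flagged && ncol(X) > 1) {
    worst <- which.max(abs(fit$beta))
    warning("dropping separating pair: ", colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
    fit <- fit_cox(X, cl$time, cl$event)
  }

  # backward elimination on AIC
  while (ncol(X) > 1) {
    aics <- vapply(seq_len(ncol(X)), function(j) {
      fit_cox(X[, -j, drop = FALSE], cl$time, cl$event)$aic
    }, numeric(1))
    if (min(aics) < fit$aic) {
      j <- which.min(aics)
      X <- X[, -j, drop = FALSE]
      fit <- fit_cox(X, cl$time, cl$event)
    } else break
  }

  structure(list(pairs = colnames(X), coef = fit$beta, fit = fit,
                 provenance = provenance),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("Pair signature: %d pair(s)\n", length(x$pairs)))
  print(data.frame(pair = x$pairs, coef = unname(x$coef),
                   HR = unname(x$fit$hr), p = unname(x$fit$p)))
  invisible(x)
}

#' Risk scores: sum of Coef(i) x E(i)
#'
#' The exact linear combination of the model coefficients with the
#' sample's pair-indicator values; no intercept, no rescaling.
#'
#' @param model a `signature_model`.
#' @param pm a `pair_matrix` containing every model pair (error
#'   otherwise).
#' @return named numeric vector of risk scores per sample.
#' @export
score_samples <- function(model, pm) {
  stopifnot(inherits(model, "signature_model"), inherits(pm, "pair_matrix"))
  miss <- setdiff(model$pairs, pm$pair_ids)
  if (length(miss))
    stop("pair matrix is missing model pair(s): ",
         paste(miss, collapse = ", "))
  E <- pm$values[model$pairs, , drop = FALSE]
  setNames(drop(crossprod(E, model$coef)), pm$sample_ids)
}
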