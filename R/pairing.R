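# The 0/1 pair matrix: for an ordered pair (X, Y) and sample s, the
# indicator is 0 when expression of X is lower than Y in that sample,
# and 1 otherwise (ties map to 1). Being a within-sample rank statistic
# it is invariant to any strictly increasing per-sample transform of
# the expression values, which is what makes the signature portable
# across normalization schemes.

#' Build the binary pair-indicator matrix
#'
#' All C(n, 2) unordered gene pairs are emitted in canonical order:
#' pair id "X|Y" with X preceding Y lexicographically, value
#' `1{expr(X, s) >= expr(Y, s)}` per sample (ties count as 1).
#'
#' @param expr an [expression_matrix()] (or plain matrix with dimnames)
#'   restricted to the genes to pair; >= 2 genes required.
#' @param genes optional subset of gene ids to pair.
#' @return object of class `pair_matrix`: binary `values`
#'   (pairs x samples, rownames = pair ids), `pair_ids`, `sample_ids`,
#'   `ones_frac` (per-pair frequency of ones), `n_ties` (tie count).
#' @export
build_pair_matrix <- function(expr, genes = NULL) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(m))
    if (length(missing_g))
      stop("gene id(s) not in matrix: ", paste(missing_g, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("need >= 2 genes to build pairs")
  if (anyNA(m)) stop("expression values must be complete")
  m <- m[order(rownames(m)), , drop = FALSE]   # canonical lexicographic order
  n <- nrow(m)
  idx <- combn(n, 2)
  values <- (m[idx[1, ], , drop = FALSE] >= m[idx[2, ], , drop = FALSE]) * 1
  pair_ids <- paste(rownames(m)[idx[1, ]], rownames(m)[idx[2, ]], sep = "|")
  rownames(values) <- pair_ids
  n_ties <- sum(m[idx[1, ], , drop = FALSE] == m[idx[2, ], , drop = FALSE])
  if (n_ties > 0)
    msg("%d tie(s) in pair construction mapped to 1", n_ties)
  structure(list(values = values, pair_ids = pair_ids,
                 sample_ids = colnames(m),
                 ones_frac = rowMeans(values), n_ties = n_ties),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples\n",
              length(x$pair_ids), length(x$sample_ids)))
  invisible(x)
}

#' Drop low-information pairs
#'
#' A pair whose rarer value (0 or 1) occurs in fewer than
#' `min_frac` of the samples carries (almost) no grouping information
#' and cannot stratify prognosis; it is excluded. The boundary is kept:
#' a pair is dropped only when the rarer-value frequency is strictly
#' below `min_frac`. Idempotent; pair order preserved.
#'
#' @param pm a `pair_matrix`.
#' @param min_frac minimum frequency of the rarer value (default 0.2).
#' @return filtered `pair_matrix`.
#' @export
filter_pairs <- function(pm, min_frac = 0.2) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (!length(pm$pair_ids)) stop("empty pair matrix")
  rarer <- pmin(pm$ones_frac, 1 - pm$ones_frac)
  keep <- rarer >= min_frac
  structure(list(values = pm$values[keep, , drop = FALSE],
                 pair_ids = pm$pair_ids[keep],
                 sample_ids = pm$sample_ids,
                 ones_frac = pm$ones_frac[keep], n_ties = pm$n_ties),
            class = "pair_matrix")
}

#' Restrict a pair matrix to given pairs and/or samples
#'
#' @param pm a `pair_matrix`.
#' @param pairs,samples ids to keep (NULL keeps all).
#' @return a `pair_matrix`.
#' @export
subset_pairs <- function(pm, pairs = NULL, samples = NULL) {
  stopifnot(inherits(pm, "pair_matrix"))
  pairs <- pairs %||% pm$pair_ids
  samples <- samples %||% pm$sample_ids
  mp <- setdiff(pairs, pm$pair_ids)
  ms <- setdiff(samples, pm$sample_ids)
  if (length(mp)) stop("pair id(s) not present: ", paste(mp, collapse = ", "))
  if (length(ms)) stop("sample id(s) not present: ", paste(ms, collapse = ", "))
  v <- pm$values[pairs, samples, drop = FALSE]
  structure(list(values = v, pair_ids = pairs, sample_ids = samples,
                 ones_frac = rowMeans(v), n_ties = pm$n_ties),
            class = "pair_matrix")
}
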