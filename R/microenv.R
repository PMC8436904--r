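# Tumor microenvironment scoring and immune correlates of the risk
# score. Stromal/immune scores are single-sample gene-set enrichment
# (ssGSEA) statistics: a weighted running sum over the sample's gene
# ranking (Barbie-style, weight = rank^alpha for set members, uniform
# steps for non-members), with no cross-sample normalization.

#' Single-sample gene-set enrichment scores
#'
#' Per sample, genes are ranked by expression (descending; ties get
#' average ranks). Walking down the ranking, the score accumulates
#' `P_in(i) - P_out(i)` at every position, where `P_in` is the
#' cumulative rank^alpha weight of set members normalized over all set
#' members and `P_out` is the cumulative uniform step over
#' non-members.
#'
#' @param expr an [expression_matrix()] or plain matrix with dimnames.
#' @param gene_set character vector of member gene ids.
#' @param alpha rank-weighting exponent (0.25 default).
#' @param min_size minimum required overlap between the set and the
#'   matrix genes.
#' @return named numeric vector of enrichment scores per sample.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, min_size = 10) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  present <- intersect(gene_set, rownames(m))
  if (!length(present))
    stop("gene set has no overlap with the matrix; missing: ",
         paste(head(setdiff(gene_set, rownames(m)), 10), collapse = ", "))
  if (length(present) < min_size)
    stop(sprintf("gene set overlap %d below min_size %d",
                 length(present), min_size))
  if (length(present) >= nrow(m))
    stop("gene set covers the whole matrix; no outside genes")
  in_set <- rownames(m) %in% present
  apply(m, 2, function(x) ssgsea_one(x, in_set, alpha))
}

ssgsea_one <- function(x, in_set, alpha) {
  r <- rank(x)                       # ties -> average ranks
  ord <- order(r, decreasing = TRUE) # walk from the top of the ranking
  inq <- in_set[ord]
  w <- r[ord]^alpha
  p_in <- cumsum(ifelse(inq, w, 0)) / sum(w[inq])
  p_out <- cumsum(!inq) / sum(!inq)
  sum(p_in - p_out)
}

#' Stromal, immune and combined microenvironment scores
#'
#' @param expr an [expression_matrix()] (mRNA expression).
#' @param stromal_set,immune_set gene id vectors (e.g. from a GMT via
#'   [read_gene_sets()]).
#' @param alpha,min_size passed to [ssgsea_score()].
#' @return data.frame: sample_id, stromal_score, immune_score,
#'   estimate_score (= stromal + immune exactly).
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25,
                            min_size = 10) {
  s <- ssgsea_score(expr, stromal_set, alpha = alpha, min_size = min_size)
  i <- ssgsea_score(expr, immune_set, alpha = alpha, min_size = min_size)
  data.frame(sample_id = names(s), stromal_score = unname(s),
             immune_score = unname(i), estimate_score = unname(s + i),
             stringsAsFactors = FALSE)
}

#' Spearman correlation of risk scores with immune-cell abundances
#'
#' Tie-corrected Spearman rho per cell type; p-value by the t
#' approximation, or exact (via the null permutation distribution of
#' rho) for n < 10 without ties.
#'
#' @param scores named risk scores.
#' @param abundance data.frame from [read_abundance()] (sample_id +
#'   one numeric column per cell type, optional method column).
#' @return data.frame: cell_type, method, n, rho, p, stars.
#' @export
correlate_risk <- function(scores, abundance) {
  stopifnot(!is.null(names(scores)))
  methods <- if ("method" %in% colnames(abundance))
    unique(abundance$method) else NA_character_
  rows <- list()
  for (mth in methods) {
    ab <- if (is.na(mth)) abundance else abundance[abundance$method == mth, ]
    common <- intersect(names(scores), ab$sample_id)
    if (length(common) < 3) next
    i <- match(common, ab$sample_id)
    for (ct in setdiff(colnames(ab), c("sample_id", "method"))) {
      ok <- stats::complete.cases(ab[[ct]][i])
      x <- scores[common][ok]; y <- ab[[ct]][i][ok]
      n <- length(x)
      if (n < 3 || sd(y) == 0 || sd(x) == 0) next
      st <- spearman_test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, method = mth, n = n, rho = st$rho, p = st$p,
        stars = p_stars(st$p), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no overlapping samples between scores and table")
  do.call(rbind, rows)
}

spearman_test <- function(x, y) {
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 10 && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else if (abs(rho) == 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = min(p, 1))
}

#' Expression of named genes between risk groups
#'
#' Wilcoxon rank-sum test per gene (e.g. immune-checkpoint genes)
#' between high- and low-risk samples; direction is the sign of the
#' median difference (high minus low).
#'
#' @param expr an [expression_matrix()].
#' @param genes gene ids to test; an absent gene is an error naming it.
#' @param groups named "high"/"low" vector over the matrix samples.
#' @return data.frame: gene, direction ("up"/"down"/"none" in high
#'   risk), statistic, p, stars.
#' @export
group_expression_test <- function(expr, genes, groups) {
  m <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  miss <- setdiff(genes, rownames(m))
  if (length(miss))
    stop("gene(s) absent from the matrix: ", paste(miss, collapse = ", "))
  common <- intersect(names(groups), colnames(m))
  if (length(common) < 4) stop("too few samples with group labels")
  g <- groups[common]
  if (length(unique(g)) != 2) stop("need both risk groups present")
  rows <- lapply(genes, function(gene) {
    hi <- m[gene, common[g == "high"]]
    lo <- m[gene, common[g == "low"]]
    wt <- rank_sum_test(hi, lo)
    dmed <- median(hi) - median(lo)
    data.frame(gene = gene,
               direction = if (dmed > 0) "up" else if (dmed < 0) "down"
                           else "none",
               statistic = wt$statistic, p = wt$p, stars = p_stars(wt$p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
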