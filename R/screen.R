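# Immune-related lncRNA identification: co-expression screen against an
# immune gene list, then tumor-vs-normal differential expression on the
# retained lncRNAs.

#' Screen lncRNAs for co-expression with immune genes
#'
#' A lncRNA is retained when its best immune partner (maximum |Pearson
#' r| over the immune genes present in the matrix) satisfies |r| >
#' `r_thresh` AND that pair's two-sided p-value is below `p_thresh`
#' (both strict). The p-value uses the exact t transform of r with
#' n - 2 degrees of freedom. Zero-variance genes cannot enter a
#' correlation and are skipped with a note.
#'
#' @param expr an [expression_matrix()] containing lncRNA-class genes
#'   and the immune genes (mRNA class).
#' @param immune_genes character vector of immune gene ids.
#' @param r_thresh,p_thresh strict retention thresholds.
#' @return data.frame (one row per retained lncRNA): `lnc_id`,
#'   `partner`, `r`, `p`, plus attribute `n_tested`.
#' @export
correlation_screen <- function(expr, immune_genes, r_thresh = 0.4,
                               p_thresh = 0.001) {
  stopifnot(inherits(expr, "expr_matrix"))
  n <- ncol(expr$values)
  if (n < 3) stop("need >= 3 samples for the correlation screen")
  lnc <- genes_of_class(expr, "lncRNA")
  if (!length(lnc)) stop("no lncRNA-class genes in the matrix")
  imm <- intersect(immune_genes, rownames(expr$values))
  if (!length(imm)) stop("none of the immune genes are in the matrix")

  lv <- expr$values[lnc, , drop = FALSE]
  iv <- expr$values[imm, , drop = FALSE]
  sd_l <- apply(lv, 1, sd)
  sd_i <- apply(iv, 1, sd)
  if (any(sd_i == 0)) {
    msg("skipping %d zero-variance immune gene(s)", sum(sd_i == 0))
    iv <- iv[sd_i > 0, , drop = FALSE]
    imm <- rownames(iv)
    if (!length(imm)) stop("all immune genes have zero variance")
  }
  keep_l <- sd_l > 0
  if (any(!keep_l))
    msg("skipping %d zero-variance lncRNA(s)", sum(!keep_l))
  lv <- lv[keep_l, , drop = FALSE]
  lnc <- rownames(lv)
  if (!length(lnc)) return(empty_screen_result(0L))

  r <- cor(t(lv), t(iv))               # lnc x immune Pearson matrix
  best <- max.col(abs(r), ties.method = "first")
  r_best <- r[cbind(seq_along(lnc), best)]
  tt <- abs(r_best) * sqrt((n - 2) / pmax(1 - r_best^2, .Machine$double.eps))
  p_best <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  retained <- abs(r_best) > r_thresh & p_best < p_thresh
  out <- data.frame(lnc_id = lnc[retained],
                    partner = imm[best[retained]],
                    r = r_best[retained], p = p_best[retained],
                    stringsAsFactors = FALSE)
  attr(out, "n_tested") <- length(lnc)
  out
}

empty_screen_result <- function(n_tested) {
  out <- data.frame(lnc_id = character(0), partner = character(0),
                    r = numeric(0), p = numeric(0))
  attr(out, "n_tested") <- n_tested
  out
}

#' Tumor-vs-normal differential expression of lncRNAs
#'
#' Fold change is computed on group means with a pseudo-count:
#' log2fc = log2((mean_tumor + eps) / (mean_normal + eps)). The p-value
#' is a two-sided Welch t-test on log2(x + eps); FDR is
#' Benjamini-Hochberg over all tested genes. A gene is retained when
#' |log2fc| > `lfc_thresh` and fdr < `fdr_thresh` (both strict).
#'
#' The original workflow used limma's moderated t; the Welch t on the
#' log scale is a deliberate, documented substitution that preserves the
#' meaning of the thresholds without the empirical-Bayes machinery.
#'
#' @param expr an [expression_matrix()].
#' @param tumor_ids,normal_ids sample id vectors (each >= 2).
#' @param genes genes to test; default all lncRNA-class genes.
#' @param lfc_thresh,fdr_thresh strict retention thresholds.
#' @param eps pseudo-count.
#' @return data.frame per tested gene: `lnc_id`, `log2fc`, `p`, `fdr`,
#'   `direction` ("up"/"down"), `retained`.
#' @export
differential_expression <- function(expr, tumor_ids, normal_ids,
                                    genes = NULL, lfc_thresh = 1,
                                    fdr_thresh = 0.05, eps = 0.001) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(tumor_ids) < 2 || length(normal_ids) < 2)
    stop("both groups need >= 2 samples")
  genes <- genes %||% genes_of_class(expr, "lncRNA")
  if (!length(genes)) stop("no genes to test")
  xt <- expr$values[genes, tumor_ids, drop = FALSE]
  xn <- expr$values[genes, normal_ids, drop = FALSE]
  log2fc <- log2((rowMeans(xt) + eps) / (rowMeans(xn) + eps))
  lt <- log2(xt + eps); ln <- log2(xn + eps)
  p <- vapply(seq_along(genes), function(g) {
    welch_t_p(lt[g, ], ln[g, ])
  }, numeric(1))
  fdr <- p.adjust(p, method = "BH")
  out <- data.frame(lnc_id = genes, log2fc = log2fc, p = p, fdr = fdr,
                    direction = ifelse(log2fc >= 0, "up", "down"),
                    retained = abs(log2fc) > lfc_thresh & fdr < fdr_thresh,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

welch_t_p <- function(a, b) {
  va <- var(a); vb <- var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) return(if (mean(a) == mean(b)) 1 else 0)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(abs(t), df = df, lower.tail = FALSE)
}
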