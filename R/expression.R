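#' Expression matrix with gene class labels
#'
#' A light container for a genes x samples matrix of non-negative
#' normalized expression values, carrying a per-gene class label in
#' `{"lncRNA", "mRNA", "other"}`. The pair-indicator transform downstream
#' is a within-sample rank statistic, so the expression unit (FPKM, TPM,
#' ...) does not matter; values only need to be comparable between genes
#' of the same sample.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Must be non-negative
#'   with unique, non-empty dimnames.
#' @param gene_class character vector, one of "lncRNA", "mRNA", "other"
#'   per gene; either named by gene id or in row order. Defaults to
#'   "other" for every gene.
#' @return an object of class `expr_matrix`: a list with elements
#'   `values` and `gene_class` (named by gene id).
#' @export
expression_matrix <- function(values, gene_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene id(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  if (is.null(gene_class)) {
    gene_class <- setNames(rep("other", nrow(values)), gid)
  } else {
    if (is.null(names(gene_class))) {
      if (length(gene_class) != nrow(values))
        stop("'gene_class' length does not match number of genes")
      names(gene_class) <- gid
    }
    gene_class <- setNames(rep("other", nrow(values)), gid) |>
      replace_named(gene_class)
  }
  bad <- setdiff(unique(gene_class), c("lncRNA", "mRNA", "other"))
  if (length(bad))
    stop("unknown gene class label(s): ", paste(bad, collapse = ", "))
  structure(list(values = values, gene_class = gene_class),
            class = "expr_matrix")
}

replace_named <- function(base, upd) {
  common <- intersect(names(base), names(upd))
  base[common] <- upd[common]
  base
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$gene_class)
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or sample ids
#'
#' @param x an `expr_matrix`.
#' @param genes,samples character vectors of ids to keep (NULL keeps all).
#' @return an `expr_matrix` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  genes <- genes %||% rownames(x$values)
  samples <- samples %||% colnames(x$values)
  missing_g <- setdiff(genes, rownames(x$values))
  missing_s <- setdiff(samples, colnames(x$values))
  if (length(missing_g))
    stop("gene id(s) not in matrix: ", paste(missing_g, collapse = ", "))
  if (length(missing_s))
    stop("sample id(s) not in matrix: ", paste(missing_s, collapse = ", "))
  expression_matrix(x$values[genes, samples, drop = FALSE],
                    x$gene_class[genes])
}

#' Gene ids of a given class
#'
#' @param x an `expr_matrix`.
#' @param class one of "lncRNA", "mRNA", "other".
#' @return character vector of gene ids.
#' @export
genes_of_class <- function(x, class) {
  stopifnot(inherits(x, "expr_matrix"))
  names(x$gene_class)[x$gene_class == class]
}
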