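# Gene-class annotation from a GTF file (Ensembl attribute dialect).
# Only `gene` feature lines are consulted; biotype comes from the
# gene_biotype attribute with gene_type as a GENCODE-dialect fallback.

#' Classify genes as lncRNA / mRNA / other from a GTF file
#'
#' Reads `gene` feature lines and maps `gene_biotype` (fallback
#' `gene_type`) to the class labels used throughout the package:
#' `"lncRNA"` for biotype lncRNA, `"mRNA"` for protein_coding, and
#' `"other"` for everything else (pseudogenes, miRNA, ...). Lines whose
#' attribute column cannot be parsed are skipped with a warning count.
#'
#' @param gtf_path path to a GTF file.
#' @return named character vector gene_id -> class.
#' @export
classify_genes_from_gtf <- function(gtf_path) {
  lines <- readLines(gtf_path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene",
                 logical(1))
  fields <- fields[keep]
  if (!length(fields)) stop("no 'gene' feature lines found in ", gtf_path)
  ids <- character(length(fields))
  cls <- character(length(fields))
  n_skipped <- 0L
  for (i in seq_along(fields)) {
    attr <- fields[[i]][9]
    gid <- gtf_attr(attr, "gene_id")
    bt <- gtf_attr(attr, "gene_biotype")
    if (is.na(bt)) bt <- gtf_attr(attr, "gene_type")
    if (is.na(gid) || is.na(bt)) {
      n_skipped <- n_skipped + 1L
      next
    }
    ids[i] <- gid
    cls[i] <- switch(bt, lncRNA = "lncRNA", protein_coding = "mRNA", "other")
  }
  if (n_skipped > 0)
    warning(sprintf("%d gene line(s) with unparseable attributes skipped",
                    n_skipped))
  ok <- nzchar(ids)
  out <- setNames(cls[ok], ids[ok])
  out[!duplicated(names(out))]
}

gtf_attr <- function(attr, key) {
  m <- regmatches(attr,
                  regexpr(sprintf('%s "([^"]*)"', key), attr, perl = TRUE))
  if (!length(m)) return(NA_character_)
  sub(sprintf('%s "([^"]*)"', key), "\\1", m, perl = TRUE)
}

#' Write a minimal GTF-like annotation for a set of genes
#'
#' Emits one `gene` line per id with a `gene_biotype` attribute, enough
#' for [classify_genes_from_gtf()] to reconstruct the class labels.
#' Used by the synthetic-cohort writer.
#'
#' @param gene_class named character vector gene_id -> class
#'   ("lncRNA"/"mRNA"/"other").
#' @param path output path.
#' @export
write_annotation_gtf <- function(gene_class, path) {
  biotype <- c(lncRNA = "lncRNA", mRNA = "protein_coding",
               other = "pseudogene")[gene_class]
  lines <- sprintf(
    'chr1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_biotype "%s";',
    seq_along(gene_class) * 1000L, seq_along(gene_class) * 1000L + 500L,
    names(gene_class), biotype)
  writeLines(lines, path)
  invisible(path)
}
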