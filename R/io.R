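# Readers/writers for the plain-text formats the pipeline touches.
# All tables are TSV, UTF-8, '.' decimal. Readers either return a valid
# object or raise a diagnostic error; silent truncation is never allowed.

#' Read a genes x samples expression TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path file path.
#' @param gene_class optional named class vector passed through to
#'   [expression_matrix()].
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, gene_class = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed expression file (need gene id column + >=1 sample): ", path)
  gid <- as.character(df[[1]])
  if (anyDuplicated(gid)) {
    dup <- unique(gid[duplicated(gid)])
    first_line <- which(duplicated(gid))[1] + 1L  # +1 for header
    stop(sprintf("duplicated gene id(s) %s (first at line %d) in %s",
                 paste(dup, collapse = ", "), first_line, path))
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !all(is.na(v) == is.na(vn))) {
        bad <- which(is.na(vn) & !is.na(v))[1]
        stop(sprintf("non-numeric cell at line %d, column '%s' in %s",
                     bad + 1L, colnames(vals)[j], path))
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gid
  expression_matrix(m, gene_class = gene_class)
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' Inverse of [read_expression()] up to float formatting.
#'
#' @param x an `expr_matrix` or plain numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_expression <- function(x, path) {
  m <- if (inherits(x, "expr_matrix")) x$values else x
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' Read a clinical table
#'
#' Mandatory columns: `sample_id`, `time` (days), `event` (0/1). Rows
#' with follow-up time <= 0 are dropped and duplicated sample ids are
#' dropped keeping the first occurrence; both removals are reported.
#' Any further columns (age, sex, stage, T, N, M, ...) pass through.
#'
#' @param path file path.
#' @return data.frame with unique sample ids and strictly positive time.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_clinical(df, src = path)
}

#' Validate (and clean) a clinical data.frame
#'
#' @param df data.frame with at least sample_id, time, event.
#' @param src label used in messages.
#' @return cleaned data.frame.
#' @export
validate_clinical <- function(df, src = "clinical table") {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing mandatory clinical column(s): ", paste(miss, collapse = ", "),
         " in ", src)
  df$time <- as.numeric(df$time)
  df$event <- as.numeric(df$event)
  if (anyNA(df$time) || anyNA(df$event))
    stop("non-numeric time/event value in ", src)
  if (!all(df$event %in% c(0, 1)))
    stop("event column must be 0/1 in ", src, " (found: ",
         paste(setdiff(unique(df$event), c(0, 1)), collapse = ", "), ")")
  n0 <- sum(df$time <= 0)
  if (n0 > 0) {
    msg("dropping %d sample(s) with follow-up time <= 0", n0)
    df <- df[df$time > 0, , drop = FALSE]
  }
  ndup <- sum(duplicated(df$sample_id))
  if (ndup > 0) {
    msg("dropping %d duplicated sample id(s), keeping first occurrence", ndup)
    df <- df[!duplicated(df$sample_id), , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no usable clinical rows in ", src)
  rownames(df) <- NULL
  df
}

#' Write a clinical table as TSV
#' @param df clinical data.frame.
#' @param path output path.
#' @export
write_clinical <- function(df, path) write_tsv(df, path)

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, fields tab-separated: name,
#' description, then member gene ids. Blank member fields are skipped;
#' duplicated members are deduplicated with a warning; an empty set is
#' an error.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> member ids).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d (need name, description, members)", i))
    members <- f[-(1:2)]
    members <- members[nzchar(trimws(members))]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s': duplicated members deduplicated", f[1]))
      members <- unique(members)
    }
    if (!length(members))
      stop(sprintf("gene set '%s' (line %d) has no members", f[1], i))
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a samples x cell-types immune abundance table
#'
#' First column holds sample ids; an optional `method` column labels the
#' deconvolution tool that produced the row block. Remaining columns are
#' non-negative abundances.
#'
#' @param path TSV path.
#' @return data.frame with `sample_id`, optional `method`, and one
#'   numeric column per cell type.
#' @export
read_abundance <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("abundance table needs sample column + >=1 cell type")
  colnames(df)[1] <- "sample_id"
  num_cols <- setdiff(colnames(df), c("sample_id", "method"))
  for (cc in num_cols) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (anyNA(df[[cc]])) stop("non-numeric abundance in column ", cc)
  }
  key <- if ("method" %in% colnames(df))
    paste(df$sample_id, df$method) else df$sample_id
  if (anyDuplicated(key)) stop("duplicated (sample, method) row in ", path)
  df
}
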