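# shared internal helpers

#' Significance stars at the conventional thresholds
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise "".
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
p_stars <- function(p) {
  out <- character(length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[pairsig] ", sprintf(...))

stop_field <- function(field, ...) {
  stop(sprintf("invalid '%s': %s", field, sprintf(...)), call. = FALSE)
}

# deterministic text table writer used by all TSV outputs
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
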