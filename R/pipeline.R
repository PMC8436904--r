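# End-to-end pipeline: expression + clinical + immune gene list
# -> immune-related lncRNA screen -> differential expression -> pair
# matrix + filter -> univariate Cox screen -> repeated LASSO-Cox
# selection -> signature fit -> risk scores -> ROC / cutoff / groups /
# log-rank. All outputs are plain text and byte-reproducible for a
# fixed seed.

#' Run the full pair-signature pipeline
#'
#' @param expr an [expression_matrix()] over tumor and normal samples.
#' @param clinical clinical data.frame (tumor samples; cleaned with
#'   [validate_clinical()]).
#' @param immune_genes character vector of immune gene ids.
#' @param tumor_ids,normal_ids sample id vectors for the two classes.
#' @param seed integer seed driving every stochastic step.
#' @param n_cycles,n_folds,freq_thresh LASSO selection controls (see
#'   [repeated_lasso()]).
#' @param r_thresh,p_corr co-expression screen thresholds.
#' @param lfc_thresh,fdr_thresh differential-expression thresholds.
#' @param min_frac pair-filter threshold.
#' @param p_uni univariate Cox screen threshold.
#' @param horizons ROC horizons in days (1/2/3 years by default).
#' @param outdir when non-NULL, write all result tables there.
#' @return list with every intermediate and final result: `irlnc`,
#'   `de`, `pairs` (filtered `pair_matrix`), `screened`, `selection`,
#'   `model`, `scores`, `rocs` (one `roc_curve` per horizon), `cutoff`
#'   (on the first horizon), `groups`, `km_logrank`, and `counts`.
#' @export
run_pair_pipeline <- function(expr, clinical, immune_genes, tumor_ids,
                              normal_ids, seed = 1L, n_cycles = 1000,
                              n_folds = 10, freq_thresh = n_cycles / 10,
                              r_thresh = 0.4, p_corr = 0.001,
                              lfc_thresh = 1, fdr_thresh = 0.05,
                              min_frac = 0.2, p_uni = 0.05,
                              horizons = c(365, 730, 1095),
                              outdir = NULL) {
  clinical <- validate_clinical(clinical)
  irlnc <- correlation_screen(expr, immune_genes, r_thresh = r_thresh,
                              p_thresh = p_corr)
  if (!nrow(irlnc)) stop("no immune-related lncRNAs pass the screen")
  de <- differential_expression(expr, tumor_ids, normal_ids,
                                genes = irlnc$lnc_id,
                                lfc_thresh = lfc_thresh,
                                fdr_thresh = fdr_thresh)
  de_ids <- de$lnc_id[de$retained]
  if (length(de_ids) < 2)
    stop("fewer than 2 differentially expressed immune-related lncRNAs")
  tumor_ids <- intersect(tumor_ids, clinical$sample_id)
  pm_all <- build_pair_matrix(subset_expression(expr, genes = de_ids,
                                                samples = tumor_ids))
  pm <- filter_pairs(pm_all, min_frac = min_frac)
  if (!length(pm$pair_ids)) stop("no pairs survive the frequency filter")
  screened <- univariate_screen(pm, clinical, p_thresh = p_uni)
  if (length(screened) < 2) stop("fewer than 2 pairs pass the Cox screen")
  selection <- repeated_lasso(subset_pairs(pm, pairs = screened), clinical,
                              n_cycles = n_cycles, n_folds = n_folds,
                              freq_thresh = freq_thresh, seed = seed)
  final_pairs <- if (length(selection$selected)) selection$selected
                 else screened
  model <- fit_signature(pm, clinical, pairs = final_pairs,
                         provenance = list(
                           screen = attr(screened, "table"),
                           frequency = selection$frequency))
  scores <- score_samples(model, pm)
  rocs <- lapply(horizons, function(h)
    time_dependent_roc(scores, clinical = clinical, horizon = h))
  names(rocs) <- paste0("t", horizons)
  cl_i <- match(names(scores), clinical$sample_id)
  cutoff <- optimal_cutoff(rocs[[1]], scores = scores,
                           time = clinical$time[cl_i],
                           event = clinical$event[cl_i])
  groups <- assign_groups(scores, cutoff)
  km_lr <- compare_groups_survival(groups, clinical)
  counts <- list(n_irlnc = nrow(irlnc), n_de = length(de_ids),
                 n_pairs_total = length(pm_all$pair_ids),
                 n_pairs_valid = length(pm$pair_ids),
                 n_screened = length(screened),
                 n_selected = length(selection$selected),
                 n_model = length(model$pairs))
  res <- list(irlnc = irlnc, de = de, pairs = pm, screened = screened,
              selection = selection, model = model, scores = scores,
              rocs = rocs, cutoff = cutoff, groups = groups,
              km_logrank = km_lr, counts = counts, seed = seed)
  if (!is.null(outdir)) write_pipeline_outputs(res, clinical, outdir)
  res
}

#' Write pipeline result tables
#'
#' Deterministic plain-text outputs: `irlncRNAs.tsv`,
#' `deirlncRNAs.tsv`, `pairs.tsv`, `pair_stats.tsv`, `selection.tsv`,
#' `model.json`, `risk_scores.tsv`, `roc_t<h>.tsv` per horizon,
#' `cutoff.json`, `groups.tsv`, `km_logrank.json`, `counts.json`.
#'
#' @param res result list from [run_pair_pipeline()].
#' @param clinical the clinical table used.
#' @param outdir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_pipeline_outputs <- function(res, clinical, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  write_tsv(res$irlnc, out("irlncRNAs.tsv"))
  write_tsv(res$de, out("deirlncRNAs.tsv"))
  write_tsv(data.frame(pair_id = res$pairs$pair_ids, res$pairs$values,
                       check.names = FALSE), out("pairs.tsv"))
  write_tsv(data.frame(pair_id = res$pairs$pair_ids,
                       ones_frac = res$pairs$ones_frac), out("pair_stats.tsv"))
  write_tsv(data.frame(pair_id = names(res$selection$frequency),
                       frequency = unname(res$selection$frequency)),
            out("selection.tsv"))
  f <- res$model$fit
  jsonlite::write_json(list(
    pairs = res$model$pairs, coef = unname(res$model$coef),
    hr = unname(f$hr), ci_lower = unname(f$ci_lower),
    ci_upper = unname(f$ci_upper), p = unname(f$p), aic = f$aic),
    out("model.json"), auto_unbox = FALSE, digits = NA, pretty = TRUE)
  write_tsv(data.frame(sample_id = names(res$scores),
                       risk_score = unname(res$scores)),
            out("risk_scores.tsv"))
  for (nm in names(res$rocs)) {
    r <- res$rocs[[nm]]
    write_tsv(data.frame(threshold = r$thresholds, sens = r$sens,
                         spec = r$spec, auc = r$auc),
              out(sprintf("roc_%s.tsv", nm)))
  }
  jsonlite::write_json(unclass(res$cutoff), out("cutoff.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_tsv(data.frame(sample_id = names(res$groups),
                       risk_group = as.character(res$groups)),
            out("groups.tsv"))
  jsonlite::write_json(list(chi2 = res$km_logrank$chi2,
                            p = res$km_logrank$p,
                            n_per_group = as.list(res$km_logrank$n_per_group)),
                       out("km_logrank.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(res$counts, out("counts.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}
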