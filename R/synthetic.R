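# Synthetic survival cohorts with the statistical structure the pair
# signature pipeline assumes: tumor/normal classes, immune-gene
# co-expression among a subset of lncRNAs, class-differential lncRNAs,
# and survival driven by planted pair indicators.
#
# Expression is log-normal per gene (non-negative by construction, and
# the differential shift ln(2)*target_log2fc makes log2 fold-change
# calls consistent with the usual |log2FC| > 1 threshold). Survival is
# Weibull baseline with hazard multiplier exp(sum beta_k * I_k) where
# I_k is the pair indicator recomputed from the emitted matrix, so the
# planted signal is exactly what the pipeline models. Censoring is
# exponential with the rate calibrated by root finding so the expected
# censored fraction matches `censor_rate`.

#' Specify a synthetic cohort
#'
#' Defaults describe the stated verification world: 500 tumors + 50
#' normals, 30 differentially expressed immune-related lncRNAs carrying
#' 6 planted prognostic pairs with |beta| in \[0.8, 1.2\] and 30%
#' censoring.
#'
#' @param n_tumor,n_normal sample counts per class.
#' @param n_lnc,n_mrna gene counts per class.
#' @param n_immune_mrna number of mRNAs on the immune list (first block
#'   of the mRNAs).
#' @param n_corr_lnc number of lncRNAs co-expressed with an immune
#'   partner gene (first block of the lncRNAs).
#' @param n_de_lnc number of those that are differentially expressed
#'   tumor vs normal (alternating up/down, target |log2FC| =
#'   `target_log2fc`).
#' @param planted_pairs data.frame with columns `i`, `j` (1-based
#'   indices into the DE lncRNA block, all distinct across pairs) and
#'   `beta` (log hazard ratio acting on the canonical pair indicator).
#'   NULL gives 6 pairs on DE lncRNAs 1..12 with betas
#'   +-\{0.8, 0.88, 0.96, 1.04, 1.12, 1.2\}, alternating sign.
#' @param baseline_shape,baseline_scale Weibull baseline hazard
#'   parameters (days; defaults give a median baseline survival of
#'   about 2 years).
#' @param censor_rate target fraction censored, in \[0, 1).
#' @param noise_sd log-scale expression noise standard deviation.
#' @param corr_load log-scale loading of a correlated lncRNA on its
#'   immune partner. The raw-scale Pearson r is attenuated both by the
#'   log-normal transform and, for DE lncRNAs, by the tumor-class shift
#'   inflating the marginal variance; 0.95 keeps every planted
#'   correlation comfortably above the 0.4 screen threshold.
#' @param target_log2fc planted log2 fold change magnitude for DE
#'   lncRNAs.
#' @param seed integer RNG seed; the whole cohort comes from a single
#'   seeded stream.
#' @return validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_tumor = 500, n_normal = 50, n_lnc = 80,
                        n_mrna = 200, n_immune_mrna = 40, n_corr_lnc = 40,
                        n_de_lnc = 30, planted_pairs = NULL,
                        baseline_shape = 1.2, baseline_scale = 1000,
                        censor_rate = 0.3, noise_sd = 0.5,
                        corr_load = 0.95, target_log2fc = 2, seed = 1L) {
  if (is.null(planted_pairs)) {
    # pair members share the DE direction (odd indices are up, even are
    # down) so the class shift cancels inside the pair and the
    # indicator stays balanced / informative
    planted_pairs <- data.frame(
      i = c(1, 5, 9, 2, 6, 10), j = c(3, 7, 11, 4, 8, 12),
      beta = seq(0.8, 1.2, length.out = 6) * c(1, -1))
  }
  spec <- list(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
               n_mrna = n_mrna, n_immune_mrna = n_immune_mrna,
               n_corr_lnc = n_corr_lnc, n_de_lnc = n_de_lnc,
               planted_pairs = planted_pairs,
               baseline_shape = baseline_shape,
               baseline_scale = baseline_scale,
               censor_rate = censor_rate, noise_sd = noise_sd,
               corr_load = corr_load, target_log2fc = target_log2fc,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
}

#' Validate a cohort specification
#'
#' Errors name the violated field.
#'
#' @param spec list as built by [cohort_spec()].
#' @return the spec, invisibly usable, with class `cohort_spec`.
#' @export
validate_cohort_spec <- function(spec) {
  counts <- c("n_tumor", "n_normal", "n_lnc", "n_mrna", "n_immune_mrna",
              "n_corr_lnc", "n_de_lnc")
  for (f in counts) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v != round(v))
      stop_field(f, "must be a single positive integer")
  }
  if (spec$n_de_lnc > spec$n_corr_lnc)
    stop_field("n_de_lnc", "must be <= n_corr_lnc")
  if (spec$n_corr_lnc > spec$n_lnc)
    stop_field("n_corr_lnc", "must be <= n_lnc")
  if (spec$n_immune_mrna > spec$n_mrna)
    stop_field("n_immune_mrna", "must be <= n_mrna")
  pp <- spec$planted_pairs
  if (!is.data.frame(pp) || !all(c("i", "j", "beta") %in% colnames(pp)))
    stop_field("planted_pairs", "must be a data.frame with columns i, j, beta")
  if (nrow(pp)) {
    idx <- c(pp$i, pp$j)
    if (any(idx < 1 | idx > spec$n_de_lnc | idx != round(idx)))
      stop_field("planted_pairs", "indices must lie in 1..n_de_lnc")
    if (anyDuplicated(idx))
      stop_field("planted_pairs", "every pair must index distinct DE lncRNAs")
    if (any(!is.finite(pp$beta)))
      stop_field("planted_pairs", "betas must be finite")
  }
  if (!is.numeric(spec$censor_rate) || spec$censor_rate < 0 ||
      spec$censor_rate >= 1)
    stop_field("censor_rate", "must be in [0, 1)")
  if (spec$baseline_shape <= 0) stop_field("baseline_shape", "must be > 0")
  if (spec$baseline_scale <= 0) stop_field("baseline_scale", "must be > 0")
  if (spec$noise_sd <= 0) stop_field("noise_sd", "must be > 0")
  if (abs(spec$corr_load) >= 1) stop_field("corr_load", "must be in (-1, 1)")
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic cohort
#'
#' @param spec a `cohort_spec`.
#' @return list with elements `expr` (an [expression_matrix()] over all
#'   tumor + normal samples), `clinical` (tumor samples only: sample_id,
#'   time, event, age, sex, stage, T, N, M), `immune_genes` (the immune
#'   mRNA id list), `tumor_ids`, `normal_ids`, and `truth` (ground
#'   truth: DE lncRNA ids with direction, lncRNA-immune partner map,
#'   planted pairs in canonical id order with betas, the per-sample true
#'   linear predictor, and the realized censoring fraction). Identical
#'   seeds give bit-identical output.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(unclass(spec))
  set.seed(spec$seed)
  lnc_ids <- sprintf("LNC%04d", seq_len(spec$n_lnc))
  mrna_ids <- sprintf("PCG%04d", seq_len(spec$n_mrna))
  immune_ids <- mrna_ids[seq_len(spec$n_immune_mrna)]
  tumor_ids <- sprintf("TUM%04d", seq_len(spec$n_tumor))
  normal_ids <- sprintf("NRM%04d", seq_len(spec$n_normal))
  sample_ids <- c(tumor_ids, normal_ids)
  n <- length(sample_ids)
  is_tumor <- c(rep(TRUE, spec$n_tumor), rep(FALSE, spec$n_normal))

  gene_ids <- c(lnc_ids, mrna_ids)
  mu <- runif(length(gene_ids), 1.0, 3.0)
  names(mu) <- gene_ids
  # planted pairs are matched on baseline mean: with equal baselines
  # (and equal class shifts, since members share DE direction) the pair
  # indicator is near-balanced, hence informative and filter-proof
  pp <- spec$planted_pairs
  if (nrow(pp)) mu[lnc_ids[pp$j]] <- mu[lnc_ids[pp$i]]
  logx <- matrix(rnorm(length(gene_ids) * n, mean = mu, sd = spec$noise_sd),
                 nrow = length(gene_ids), ncol = n,
                 dimnames = list(gene_ids, sample_ids))

  # co-expression: correlated lncRNAs load on an immune partner's
  # centered log expression; marginal sd preserved
  partner <- setNames(rep(NA_character_, spec$n_lnc), lnc_ids)
  rho <- spec$corr_load
  for (k in seq_len(spec$n_corr_lnc)) {
    p <- immune_ids[(k - 1L) %% spec$n_immune_mrna + 1L]
    partner[lnc_ids[k]] <- p
    z <- (logx[p, ] - mu[p]) / spec$noise_sd
    logx[lnc_ids[k], ] <- mu[lnc_ids[k]] + spec$noise_sd *
      (rho * z + sqrt(1 - rho^2) * rnorm(n))
  }

  # differential expression: tumor-class shift on the first n_de_lnc
  # correlated lncRNAs, alternating direction
  de_ids <- lnc_ids[seq_len(spec$n_de_lnc)]
  de_dir <- rep(c(1, -1), length.out = spec$n_de_lnc)
  shift <- log(2) * spec$target_log2fc
  for (k in seq_len(spec$n_de_lnc))
    logx[de_ids[k], is_tumor] <- logx[de_ids[k], is_tumor] + de_dir[k] * shift

  values <- exp(logx)
  gene_class <- setNames(c(rep("lncRNA", spec$n_lnc),
                           rep("mRNA", spec$n_mrna)), gene_ids)
  expr <- expression_matrix(values, gene_class)

  # planted pairs: betas act on the canonical pair indicator
  # 1{expr[X,] >= expr[Y,]} with X < Y lexicographically
  pp <- spec$planted_pairs
  lp <- rep(0, spec$n_tumor)
  planted <- NULL
  if (nrow(pp)) {
    a <- de_ids[pp$i]; b <- de_ids[pp$j]
    x_id <- pmin(a, b); y_id <- pmax(a, b)
    planted <- data.frame(pair_id = paste(x_id, y_id, sep = "|"),
                          lnc_x = x_id, lnc_y = y_id, beta = pp$beta,
                          stringsAsFactors = FALSE)
    for (k in seq_len(nrow(planted))) {
      ind <- as.numeric(values[planted$lnc_x[k], tumor_ids] >=
                          values[planted$lnc_y[k], tumor_ids])
      lp <- lp + planted$beta[k] * ind
    }
  }

  # Weibull event times: S(t) = exp(-(t/scale)^shape * exp(lp))
  u <- runif(spec$n_tumor)
  t_event <- spec$baseline_scale * (-log(u) / exp(lp))^(1 / spec$baseline_shape)
  if (spec$censor_rate == 0) {
    time <- t_event
    event <- rep(1, spec$n_tumor)
  } else {
    rate <- calibrate_censor_rate(t_event, spec$censor_rate)
    c_time <- rexp(spec$n_tumor, rate = rate)
    time <- pmin(t_event, c_time)
    event <- as.numeric(t_event <= c_time)
  }

  clinical <- data.frame(
    sample_id = tumor_ids, time = time, event = event,
    age = pmin(pmax(round(rnorm(spec$n_tumor, 65, 10)), 30), 90),
    sex = sample(c("female", "male"), spec$n_tumor, replace = TRUE),
    stage = sample(c("I", "II", "III", "IV"), spec$n_tumor, replace = TRUE,
                   prob = c(0.5, 0.25, 0.15, 0.10)),
    T = sample(c("T1", "T2", "T3", "T4"), spec$n_tumor, replace = TRUE,
               prob = c(0.3, 0.45, 0.15, 0.10)),
    N = sample(c("N0", "N1", "N2"), spec$n_tumor, replace = TRUE,
               prob = c(0.6, 0.25, 0.15)),
    M = sample(c("M0", "M1"), spec$n_tumor, replace = TRUE,
               prob = c(0.95, 0.05)),
    stringsAsFactors = FALSE, check.names = FALSE)

  truth <- list(
    de_lnc_ids = de_ids, de_direction = setNames(de_dir, de_ids),
    partner = partner[!is.na(partner)],
    planted_pairs = planted,
    linear_predictor = setNames(lp, tumor_ids),
    event = setNames(event, tumor_ids),
    censor_rate_realized = mean(event == 0),
    target_log2fc = spec$target_log2fc)

  list(expr = expr, clinical = clinical, immune_genes = immune_ids,
       tumor_ids = tumor_ids, normal_ids = normal_ids, truth = truth,
       spec = spec)
}

# exponential censoring rate such that the expected censored fraction
# over the realized event times equals `target`
calibrate_censor_rate <- function(t_event, target) {
  f <- function(log_rate) mean(1 - exp(-exp(log_rate) * t_event)) - target
  uniroot(f, lower = log(1e-10), upper = log(1e4), tol = 1e-10)$root |> exp()
}

#' Write a synthetic cohort to disk
#'
#' Emits `expression.tsv` (genes x samples), `clinical.tsv`,
#' `annotation.gtf` (gene lines with gene_biotype), `immune_genes.txt`
#' (one id per line), and `truth.json`.
#'
#' @param cohort output of [generate_cohort()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("expression.tsv", "clinical.tsv",
                               "annotation.gtf", "immune_genes.txt",
                               "truth.json"))
  write_expression(cohort$expr, paths[1])
  write_clinical(cohort$clinical, paths[2])
  write_annotation_gtf(cohort$expr$gene_class, paths[3])
  writeLines(cohort$immune_genes, paths[4])
  truth <- cohort$truth
  truth$partner <- as.list(truth$partner)
  jsonlite::write_json(truth, paths[5], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
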