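# pairsig

Rank-based immune lncRNA **pair** signatures for survival prognosis in
tumor cohorts.

## What it does, and for whom

Expression-level prognostic signatures are tied to the normalization
of the data they were trained on. `pairsig` implements the
alternative: build the signature on **binary rank indicators of gene
pairs**. For an ordered pair of immune-related lncRNAs (X, Y) and a
sample *s*,

    E(X|Y, s) = 0  if expr(X, s) < expr(Y, s),   1 otherwise

so every covariate is a within-sample comparison, invariant to any
strictly increasing per-sample transform of expression (FPKM vs TPM,
log scale, quantile shifts). The package is for computational
oncologists and biostatisticians who want this class of signature as
a tested, reusable pipeline rather than a one-off script.

The pipeline, given a genes × samples expression matrix, a GTF for
lncRNA/mRNA classification, an immune gene list and a clinical table:

1. immune-related lncRNA screen: best immune partner with
   |Pearson r| > 0.4 and p < 0.001;
2. tumor-vs-normal differential expression on those lncRNAs
   (|log2FC| > 1, BH FDR < 0.05);
3. 0/1 pair matrix over all C(n, 2) pairs; pairs whose rarer value
   occurs in < 20% of samples are dropped;
4. univariate Cox screen (Wald p < 0.05; first-principles
   Newton–Raphson fitter with Efron ties and separation detection);
5. repeated cross-validated LASSO-Cox (fresh fold assignment per
   cycle, λ_min, glmnet backend), pairs kept by occurrence frequency
   (> `n_cycles / 10`);
6. multivariate Cox with backward AIC elimination; risk score
   = Σ Coef(i)·E(i);
7. time-dependent ROC at 1/2/3 years (KM-corrected
   cumulative/dynamic estimator), Youden-index cutoff, risk groups,
   Kaplan–Meier + log-rank, independence and association analyses;
8. microenvironment add-ons: ssGSEA stromal/immune/combined scores,
   Spearman correlation with external immune-cell abundance tables,
   checkpoint-gene comparisons between risk groups.

A synthetic-cohort generator (`cohort_spec()` / `generate_cohort()`)
produces the world the pipeline assumes — immune co-expression,
DE lncRNAs, survival driven by planted pair indicators, calibrated
censoring — with ground truth, so the whole chain is verifiable at
desk scale. See `vignettes/pair-signature-methods.Rmd` for the
models, parameter choices and limitations.

## Worked example

```r
library(pairsig)

co  <- generate_cohort(cohort_spec(n_tumor = 300, n_normal = 50, seed = 7))
res <- run_pair_pipeline(co$expr, co$clinical, co$immune_genes,
                         co$tumor_ids, co$normal_ids,
                         seed = 7, n_cycles = 50)

res$counts
#> $n_irlnc: 40   $n_de: 30   $n_pairs_total: 435   $n_pairs_valid: 90
#> $n_screened: 26   $n_selected: 14   $n_model: 7

res$model
#> Pair signature: 7 pair(s)
#>              pair       coef        HR            p
#> 1 LNC0001|LNC0003  0.6971985 2.0081190 4.412852e-06
#> 2 LNC0002|LNC0004 -1.3050047 0.2711713 6.124693e-14
#> 3 LNC0002|LNC0012 -0.2838592 0.7528726 9.347185e-02
#> 4 LNC0005|LNC0007 -1.0368139 0.3545826 2.131019e-11
#> 5 LNC0006|LNC0008  1.0794974 2.9432000 1.374484e-11
#> 6 LNC0009|LNC0011  1.1181366 3.0591484 2.406720e-12
#> 7 LNC0010|LNC0012 -1.2620538 0.2830721 1.721258e-14

res$rocs[["t365"]]
#> ROC curve at t = 365: AUC = 0.8498 (108 thresholds)
res$cutoff
#> cutoff = 0 (Youden = 0.5620, sens = 0.781, spec = 0.781,
#>             2-group AIC = 1779.92)
table(res$groups)
#> high  low
#>  115  185
res$km_logrank$p
#> 3.894167e-37
```

Reading: 40 of 80 lncRNAs pass the immune co-expression screen, 30
are differentially expressed, and of the 435 possible pairs 90 are
informative enough to keep. The final 7-pair model contains all 6
planted prognostic pairs with the correct coefficient signs (the
seventh is a correlated passenger); a 1-year AUC of 0.85 and a
log-rank p of ~4e-37 between the Youden-split risk groups reflect
the planted effect sizes (|β| between 0.8 and 1.2), not a claim
about any real cohort. Risk scores are exactly Σ Coef(i)·E(i) and
survive any per-sample monotone rescaling of the input matrix.

With `outdir =` set, every table is written as deterministic TSV/JSON
(`irlncRNAs.tsv`, `pairs.tsv`, `selection.tsv`, `model.json`,
`risk_scores.tsv`, `roc_t365.tsv`, `cutoff.json`, `groups.tsv`,
`km_logrank.json`, ...). A command-line wrapper with `simulate` and
`run` subcommands is installed at `inst/cli/pairsig`.

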