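---
title: "Rank-based immune lncRNA pair signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based immune lncRNA pair signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modeling idea

Prognostic signatures built on absolute expression levels of single
genes are fragile: they inherit every normalization, platform and
batch artifact of the expression unit they were trained on. The
pipeline in this package instead works on *pairs* of immune-related
long noncoding RNAs (lncRNAs). For an ordered pair (X, Y) and a
sample s, the covariate is the binary indicator

> E(X|Y, s) = 0 if expression of X is **lower** than Y in s, and 1
> otherwise (ties count as 1).

This is a within-sample rank statistic: any strictly increasing
per-sample transform of the expression values (FPKM vs TPM, log
scaling, quantile shifts) leaves every indicator unchanged, so the
fitted signature transfers across normalization schemes. That
invariance is asserted bit-for-bit in the test suite, both at the
pair-matrix level and end-to-end on risk scores.

The full pipeline:

1. **Immune-related lncRNA screen.** A lncRNA is immune-related when
   its best partner among a user-supplied immune gene list satisfies
   |Pearson r| > 0.4 with p < 0.001 (strict inequalities; p from the
   exact t transform of r with n − 2 df). The "best partner via max
   |r|" rule is equivalent to "any partner" for a strict maximum; it
   is fixed here for determinism.
2. **Differential expression.** Tumor vs normal on the retained
   lncRNAs: log2 fold change of group means with pseudo-count
   ε = 0.001, two-sided Welch t on log2(x + ε), Benjamini–Hochberg
   FDR; retained iff |log2FC| > 1 and FDR < 0.05. The original
   workflow used limma's moderated t; Welch t on the log scale is a
   deliberate substitution that keeps the thresholds' meaning without
   the empirical-Bayes machinery. At the cohort sizes this pipeline
   targets (dozens to hundreds per class) the moderation matters
   little; at very small n the moderated test is more powerful, which
   is a known limitation.
3. **Pair matrix and filter.** All C(n, 2) pairs in canonical
   lexicographic order. A pair whose rarer value occurs in fewer than
   20% of samples cannot stratify the cohort and is dropped; the
   boundary (exactly 20%) is kept, because the exclusion rule is a
   strict "< 20%". Ties map to 1 by the "otherwise" reading of the
   rule; tie counts are logged since ties are measure-zero for
   continuous data but common in integer fixtures.
4. **Univariate Cox screen** (Wald p < 0.05), excluding fits flagged
   for monotone likelihood — binary covariates at modest n make
   risk-set separation a real possibility, and a diverging coefficient
   must not masquerade as a strong signal.
5. **Repeated cross-validated LASSO-Cox.** Each cycle draws a fresh
   10-fold assignment, fits the L1-penalized Cox path (glmnet
   backend, 100-value log-spaced λ grid) and records the pairs with
   nonzero coefficients at λ_min (minimum mean CV partial-likelihood
   deviance). Fold re-assignment is the only randomness
   cross-validated LASSO has, so "random stimulation per cycle" is
   read as exactly that; no bootstrap resampling. λ_min rather than
   λ_1se because frequency counting wants the denser end of the path.
   The reference protocol ran 1000 cycles and kept pairs with
   frequency > 100; the threshold is therefore expressed as
   `n_cycles / 10` so the rule scales when the cycle count is scaled.
6. **Final model.** Multivariate Cox on the selected pairs with
   backward stepwise elimination minimizing AIC (stop when no removal
   lowers AIC). The published workflow reduced eight selected pairs to
   six without stating the mechanism; backward-AIC reproduces that
   reduction structurally and is the package's explicit choice.
7. **Risk score** = Σ Coef(i)·E(i), the exact linear predictor — no
   rescaling, so scores are recomputable from the model table and the
   pair matrix alone.
8. **Evaluation.** Time-dependent ROC at 1/2/3 years (365/730/1095
   days by default — day counts, not calendar years) with the
   cumulative-case / dynamic-control definition and Kaplan–Meier
   censoring correction; Youden-maximal cutoff on the 1-year curve
   (ties broken toward higher sensitivity, the AIC of the implied
   two-group Cox model reported alongside); strict ">" group
   assignment; Kaplan–Meier + log-rank between groups; independence
   analysis with ordinally coded stage/T/N/M; chi-square and
   Wilcoxon rank-sum association tests. The source protocol names a
   "signed-rank" test for what are independent groups; the rank-sum
   (Mann–Whitney) test is what that comparison can mean, and the
   naming discrepancy is recorded here.

## Survival statistics from first principles

`fit_cox()` maximizes the log partial likelihood by Newton–Raphson
with step-halving, Efron tie correction by default (Breslow available
for cross-checks), convergence at max |score| < 1e−8 within 100
iterations. Monotone likelihood is detected when a coefficient runs
away (|β| > 15) or the information matrix becomes singular; such fits
are returned flagged and excluded from screens. Tie-free data takes a
vectorized prefix-cumsum path; any duplicated time routes to the
general risk-set path. Wald p-values are reported because the
downstream forest-plot convention is HR with a 95% CI; the score test
at β = 0 is exposed separately (`cox_score_test()`), and on tie-free
data it coincides with the log-rank statistic — one of the
cross-route identities in the test suite. AIC is exactly
−2·loglik + 2k.

The time-dependent ROC uses stratified Kaplan–Meier estimates above
and below each threshold and their mixture as the marginal survival,
which guarantees sensitivity and specificity stay in [0, 1] and makes
the uncensored case reduce *exactly* to the empirical ROC (and the
AUC to the Mann–Whitney statistic with the ½ tie convention). Curve
vertices are walked in decreasing-threshold order when integrating;
ordering by false-positive rate is numerically unstable when float
noise perturbs ties.

## Microenvironment scoring

Stromal/immune scores are single-sample gene-set enrichment values:
rank genes within a sample (average ranks on ties), then accumulate
`P_in − P_out` down the ranking, with set members weighted by
rank^α (α = 0.25) and non-members stepping uniformly. The combined
score is stromal + immune, an exact identity. No cross-sample
normalization is applied, so scores are comparable within a cohort
run but not across gene sets of different sizes. The published
stromal/immune gene sets are not bundled — the module takes any GMT,
and the tests use synthetic sets; published-set scores will differ by
the set contents only. Spearman correlations with externally supplied
immune-cell abundance tables use tie-corrected ranks with a
t-approximate p (exact for n < 10 without ties).

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` produces the world the pipeline assumes, with
ground truth for recovery testing:

- **Expression**: per-gene log-normal, log-mean ~ U(1, 3), log-sd
  `noise_sd = 0.5`. Non-negative by construction. This is *not* an
  RNA-seq count model: no negative binomial, no library-size or batch
  artifacts. A green recovery test therefore establishes correctness
  of the statistical machinery on its stated model, not robustness to
  sequencing artifacts (the rank-pair transform removes a large class
  of those by design, but that removal is only demonstrated for
  monotone per-sample distortions).
- **Immune co-expression**: the first `n_corr_lnc` lncRNAs load on a
  distinct immune mRNA partner with log-scale loading
  `corr_load = 0.95`. The value looks high, but the raw-scale Pearson
  correlation the screen actually computes is attenuated twice: by
  the log-normal transform and, for DE lncRNAs, by the tumor-class
  shift inflating the marginal variance. 0.95 leaves the weakest
  planted correlation near 0.44 at n = 400 — above the 0.4 screen
  threshold with margin, which is what the generator contracts to
  provide. At 0.8 the weakest planted correlation lands near 0.36 and
  the generator would violate its own contract.
- **Differential expression**: the first `n_de_lnc` correlated
  lncRNAs get a tumor-class shift of ln(2)·`target_log2fc`
  (default |log2FC| = 2), alternating up/down.
- **Planted prognostic pairs**: betas act on the *canonical pair
  indicator recomputed from the emitted matrix*, so the planted
  signal is exactly what the pipeline models and the truth linear
  predictor is reproducible to machine precision. The default six
  pairs use same-direction DE lncRNAs matched on baseline log-mean:
  with opposite-direction members or mismatched baselines the
  indicator is nearly constant in tumors and the 20% filter removes
  it — the planted world would be unrecoverable by construction, not
  by algorithmic failure.
- **Survival**: Weibull baseline (shape 1.2, scale 1000 days; median
  baseline survival ≈ 2 years, a realistic scale for 1/2/3-year
  horizons) with hazard multiplier exp(Σ βk·Ik). Censoring is
  exponential, its rate calibrated by root finding so the expected
  censored fraction equals `censor_rate` (default 0.3); `censor_rate
  = 0` disables censoring entirely.
- **Determinism**: one seeded RNG stream per cohort; identical seeds
  give bit-identical outputs, and the full pipeline writes
  byte-identical files on reruns.

Default sizes (500 tumors, 50 normals, 80 lncRNAs, 200 mRNAs, 30 DE
lncRNAs, 6 planted pairs with |β| ∈ [0.8, 1.2], 30% censoring) are
the stated verification world; unit tests scale them down for speed
and say so where they do.

## Numerical choices and degenerate inputs

- Strict inequalities throughout where the screening rules state
  them: |r| > 0.4, p < 0.001, |log2FC| > 1, FDR < 0.05, frequency
  filter "< 20%" (boundary kept), selection frequency "> threshold",
  score "> cutoff".
- Zero-variance genes cannot enter a correlation; they are skipped
  and counted, never silently imputed.
- Constant pair columns are an error at the univariate screen (they
  should have been filtered) and collinear/complementary columns are
  dropped with a warning at the multivariate step (a pair and its
  complement differ by a constant in the linear predictor, which a
  Cox model cannot distinguish).
- The LASSO backend is an established coordinate-descent
  implementation (glmnet); its contract here is fixed (penalized Cox
  path on a 100-value log-spaced λ grid, CV deviance minimization) so
  backends are interchangeable, and a failed cycle counts as an empty
  selection with a warning rather than aborting the run.
- ROC horizons must have events before and subjects at risk after
  them; both violations produce immediate, named errors.

## Known limitations

- Welch-t DE is less powerful than moderated-t at very small group
  sizes.
- The ssGSEA scores are unnormalized running sums; comparing scores
  across differently sized gene sets requires care.
- No time-varying covariates, stratified Cox, frailty or competing
  risks.
- The synthetic world does not model counts, library size, batch, or
  dependence between censoring and covariates.
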