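test_that("time-dependent ROC guards its preconditions", {
  set.seed(41)
  tm <- c(10, 20, 30, 40); ev <- c(1, 1, 0, 0)
  expect_error(time_dependent_roc(rnorm(4), tm, ev, horizon = 5),
               "precedes")
  expect_error(time_dependent_roc(rnorm(4), tm, ev, horizon = 50),
               "past the horizon")
})

test_that("perfect ranking gives AUC 1; uncensored case reduces to Mann-Whitney", {
  sc <- 1:20
  tm <- c(rep(100, 10), rep(5, 10))     # high scores die early
  roc1 <- time_dependent_roc(sc, tm, rep(1, 20), horizon = 50)
  expect_equal(roc1$auc, 1)

  set.seed(42)
  for (r in 1:10) {
    n <- 30
    sc <- rnorm(n)
    tm <- rexp(n, exp(0.8 * sc))
    t0 <- median(tm)
    roc <- time_dependent_roc(sc, tm, rep(1, n), horizon = t0)
    case <- tm <= t0
    u <- (sum(outer(sc[case], sc[!case], ">")) +
            0.5 * sum(outer(sc[case], sc[!case], "=="))) /
      (sum(case) * sum(!case))
    expect_equal(roc$auc, u, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(43)
  n <- 80
  sc <- rnorm(n)
  tm <- rexp(n, exp(0.5 * sc)) * 100
  cens <- rexp(n, 0.004)
  time <- pmin(tm, cens); ev <- as.numeric(tm <= cens)
  t0 <- quantile(time, 0.4)
  a1 <- time_dependent_roc(sc, time, ev, horizon = t0)$auc
  a2 <- time_dependent_roc(exp(2 * sc) + 5, time, ev, horizon = t0)$auc
  expect_equal(a1, a2)
})

test_that("Youden cutoff selection follows the stated rules", {
  # hand example: youden = 0, 0.7, 0.35 -> middle point wins
  roc <- roc_curve(thresholds = c(1, 2, 3),
                   sens = c(1.0, 0.9, 0.4), spec = c(0.0, 0.8, 0.95))
  cut <- optimal_cutoff(roc)
  expect_equal(cut$cutoff, 2)
  expect_equal(cut$youden, 0.7)

  # tie on youden -> higher sensitivity wins
  roc2 <- roc_curve(thresholds = c(1, 2),
                    sens = c(0.9, 0.6), spec = c(0.6, 0.9))
  expect_equal(optimal_cutoff(roc2)$cutoff, 1)

  # perfect separation -> youden 1
  sc <- 1:20; tm <- c(rep(100, 10), rep(5, 10))
  roc3 <- time_dependent_roc(sc, tm, rep(1, 20), horizon = 50)
  expect_equal(optimal_cutoff(roc3)$youden, 1)
})

test_that("group assignment is strict at the cutoff", {
  sc <- setNames(c(1, 2, 3), c("a", "b", "c"))
  g <- assign_groups(sc, 2)
  expect_equal(as.character(g), c("low", "low", "high"))  # == cutoff -> low
  expect_true(all(assign_groups(sc, 10) == "low"))
  expect_equal(sum(table(g)), 3)
})

test_that("group survival comparison behaves at the null and under signal", {
  # identical survival in both groups: p = 1
  cl <- data.frame(sample_id = sprintf("s%02d", 1:20),
                   time = rep(c(5, 10, 15, 20, 25), 4),
                   event = rep(c(1, 1, 0, 1, 0), 4))
  g <- setNames(rep(c("high", "low"), each = 10), cl$sample_id)
  res <- compare_groups_survival(g, cl)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_named(res$km, c("high", "low"))

  expect_error(compare_groups_survival(
    setNames(rep("high", 20), cl$sample_id), cl), "two risk groups")

  # planted signal: strongly separated groups
  set.seed(44)
  d <- sim_surv(300, beta = 1.2)
  cl2 <- data.frame(sample_id = sprintf("t%03d", 1:300),
                    time = d$time, event = d$event)
  g2 <- setNames(ifelse(d$x == 1, "high", "low"), cl2$sample_id)
  expect_lt(compare_groups_survival(g2, cl2)$p, 0.001)
})

test_that("independence analysis reports one HR per covariate", {
  co <- generate_cohort(cohort_spec(n_tumor = 200, n_normal = 30,
                                    seed = 45))
  sc <- setNames(co$truth$linear_predictor, co$tumor_ids)
  res <- independence_analysis(sc, co$clinical)
  covs <- c("risk_score", "age", "sex", "stage", "T", "N", "M")
  expect_equal(res$univariate$covariate, covs)
  expect_equal(res$multivariate$covariate, covs)
  expect_equal(nrow(res$multivariate), length(covs))
  # the true linear predictor must be prognostic
  expect_lt(res$univariate$p[1], 0.001)

  # duplicated risk score as a covariate triggers a collinearity warning
  cl2 <- co$clinical
  cl2$copy <- as.numeric(sc)
  expect_warning(independence_analysis(sc, cl2, covariates = "copy"),
                 "collinear")
})

test_that("null covariate CIs cover HR = 1 at the nominal rate", {
  set.seed(46)
  cover <- replicate(200, {
    d <- sim_surv(80, beta = 0)
    f <- fit_cox(d$x, d$time, d$event)
    f$ci_lower <= 1 && 1 <= f$ci_upper
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("chi-square association matches the hand-computed table", {
  # contingency [[10,20],[20,10]]: expected all 15, chi2 = 20/3
  cl <- data.frame(sample_id = sprintf("s%02d", 1:60),
                   grade = rep(c("g1", "g2", "g1", "g2"),
                               c(10, 20, 20, 10)))
  g <- setNames(rep(c("high", "low"), each = 30), cl$sample_id)
  res <- association_tests(cl, "grade", groups = g)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$p, pchisq(20 / 3, 1, lower.tail = FALSE))
  expect_equal(res$stars, "**")
  expect_false(res$low_expected)

  # identical distributions: chi2 = 0, no star
  cl0 <- data.frame(sample_id = sprintf("s%02d", 1:40),
                    grade = rep(c("g1", "g2"), 20))
  g0 <- setNames(rep(c("high", "low"), each = 20), cl0$sample_id)
  res0 <- association_tests(cl0, "grade", groups = g0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$stars, "")
})

test_that("rank-sum score comparisons use exact enumeration at small n", {
  # extreme ordering of 3 vs 3: two-sided exact p = 2 / C(6,3) = 0.1
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p, 0.1)

  cl <- data.frame(sample_id = paste0("s", 1:6),
                   sex = rep(c("f", "m"), each = 3))
  sc <- setNames(c(1, 2, 3, 4, 5, 6), cl$sample_id)
  res <- association_tests(cl, "sex", scores = sc)
  expect_equal(res$p, 0.1)
  expect_equal(res$test, "wilcoxon-rank-sum")

  # large-sample path agrees with the normal approximation direction
  set.seed(47)
  a <- rnorm(40); b <- rnorm(40) + 2
  expect_lt(rank_sum_test(a, b)$p, 1e-6)
})
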