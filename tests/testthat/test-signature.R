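clin_df <- function(time, event, ids) {
  data.frame(sample_id = ids, time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("univariate screen keeps a strong planted pair", {
  set.seed(31)
  d <- sim_surv(400, beta = 1)
  pm <- one_pair_matrix(d$x)
  cl <- clin_df(d$time, d$event, pm$sample_ids)
  kept <- univariate_screen(pm, cl)
  expect_equal(kept, "A|B", ignore_attr = TRUE)
  tab <- attr(kept, "table")
  expect_equal(tab$beta, 1, tolerance = 0.35)   # ~2 se at n=400
})

test_that("univariate screen rejects constant pairs by name", {
  pm <- one_pair_matrix(c(0, 1, 0, 1))
  pm$values["A|B", ] <- 1
  cl <- clin_df(c(3, 1, 4, 2), c(1, 1, 1, 1), pm$sample_ids)
  expect_error(univariate_screen(pm, cl), "A|B")
})

test_that("repeated_lasso honors the vacuous and determinism contracts", {
  set.seed(32)
  co <- generate_cohort(cohort_spec(
    n_tumor = 120, n_normal = 20, n_lnc = 20, n_mrna = 30,
    n_immune_mrna = 10, n_corr_lnc = 14, n_de_lnc = 12, seed = 5))
  pm <- filter_pairs(build_pair_matrix(
    subset_expression(co$expr, genes = co$truth$de_lnc_ids,
                      samples = co$tumor_ids)))
  s0 <- repeated_lasso(pm, co$clinical, n_cycles = 0)
  expect_true(s0$no_signal)
  expect_length(s0$selected, 0)
  expect_true(all(s0$frequency == 0))

  s1 <- repeated_lasso(pm, co$clinical, n_cycles = 5, seed = 99)
  s2 <- repeated_lasso(pm, co$clinical, n_cycles = 5, seed = 99)
  expect_identical(s1$frequency, s2$frequency)
})

test_that("planted pairs dominate null pairs in selection frequency", {
  # scaled-down recovery world: 400 tumors, 40 cycles, 60 candidate
  # pairs of which 6 are planted
  co <- generate_cohort(cohort_spec(n_tumor = 400, n_normal = 40, seed = 33))
  pm <- filter_pairs(build_pair_matrix(
    subset_expression(co$expr, genes = co$truth$de_lnc_ids,
                      samples = co$tumor_ids)))
  planted <- intersect(co$truth$planted_pairs$pair_id, pm$pair_ids)
  expect_length(planted, 6)
  set.seed(34)
  nulls <- sample(setdiff(pm$pair_ids, planted), 54)
  sel <- repeated_lasso(subset_pairs(pm, pairs = c(planted, nulls)),
                        co$clinical, n_cycles = 40, seed = 34)
  null_freq <- sel$frequency[nulls]
  expect_true(all(sel$frequency[planted] > median(null_freq)))
})

test_that("backward AIC removes a pure-noise pair from a strong model", {
  set.seed(35)
  removed <- vapply(1:5, function(r) {
    n <- 400
    x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
    noise <- rbinom(n, 1, 0.5)
    tm <- rexp(n, 0.01 * exp(1.0 * x1 - 0.9 * x2))
    ev <- rep(1, n)
    m <- rbind(A1 = x1 + 1, A2 = rep(1.5, n),
               B1 = x2 + 1, B2 = rep(1.5, n),
               C1 = noise + 1, C2 = rep(1.5, n))
    colnames(m) <- sprintf("S%03d", 1:n)
    pm <- build_pair_matrix(m)
    pm <- subset_pairs(pm, pairs = c("A1|A2", "B1|B2", "C1|C2"))
    cl <- clin_df(tm, ev, pm$sample_ids)
    model <- fit_signature(pm, cl)
    !"C1|C2" %in% model$pairs
  }, logical(1))
  expect_gte(sum(removed), 3)
})

test_that("single-pair signature reduces to the univariate fit", {
  set.seed(36)
  d <- sim_surv(100, beta = 0.8)
  pm <- one_pair_matrix(d$x)
  cl <- clin_df(d$time, d$event, pm$sample_ids)
  model <- fit_signature(pm, cl)
  uni <- fit_cox(d$x, d$time, d$event)
  expect_equal(model$pairs, "A|B")
  expect_equal(unname(model$coef), unname(uni$beta))
  expect_equal(model$fit$aic, uni$aic)
})

test_that("collinear pair columns are dropped with a warning", {
  set.seed(37)
  d <- sim_surv(120, beta = 0.8)
  m <- rbind(A1 = d$x + 1, A2 = rep(1.5, 120),
             B1 = d$x + 1, B2 = rep(1.5, 120))   # B1|B2 duplicates A1|A2
  colnames(m) <- sprintf("S%03d", 1:120)
  pm <- subset_pairs(build_pair_matrix(m), pairs = c("A1|A2", "B1|B2"))
  cl <- clin_df(d$time, d$event, pm$sample_ids)
  expect_warning(model <- fit_signature(pm, cl), "collinear")
  expect_length(model$pairs, 1)
})

test_that("risk scores follow the stated linear formula", {
  set.seed(38)
  d <- sim_surv(50, beta = 0.5)
  pm <- one_pair_matrix(d$x)
  cl <- clin_df(d$time, d$event, pm$sample_ids)
  model <- fit_signature(pm, cl)

  # hand arithmetic on a fabricated two-pair model
  m2 <- model
  m2$pairs <- c("A|B", "A|B")   # degenerate but exercises the sum
  expect_error(score_samples(m2, subset_pairs(pm, pairs = character(0))),
               "missing")

  sc <- score_samples(model, pm)
  expect_equal(unname(sc), unname(model$coef * pm$values["A|B", ]))
  # all-zero pair values give score 0; doubling coefs doubles scores
  zero_idx <- pm$values["A|B", ] == 0
  expect_true(all(sc[zero_idx] == 0))
  m3 <- model; m3$coef <- 2 * model$coef
  expect_equal(score_samples(m3, pm), 2 * sc)
})

test_that("Coef x E arithmetic: (0.5, -0.2) . (1, 1) = 0.3", {
  m <- rbind(A1 = c(2, 2), A2 = c(1.5, 1.5),
             B1 = c(2, 1), B2 = c(1.5, 1.5))
  colnames(m) <- c("s1", "s2")
  pm <- subset_pairs(build_pair_matrix(m), pairs = c("A1|A2", "B1|B2"))
  model <- structure(list(pairs = c("A1|A2", "B1|B2"),
                          coef = c("A1|A2" = 0.5, "B1|B2" = -0.2)),
                     class = "signature_model")
  sc <- score_samples(model, pm)
  expect_equal(unname(sc), c(0.3, 0.5))
})

test_that("risk scores inherit rank invariance from the pair matrix", {
  set.seed(39)
  m <- matrix(abs(rnorm(6 * 40, 5)), 6, 40,
              dimnames = list(letters[1:6], sprintf("S%03d", 1:40)))
  pm1 <- build_pair_matrix(m)
  pm2 <- build_pair_matrix(exp(m / 2))     # strictly increasing transform
  model <- structure(list(pairs = pm1$pair_ids,
                          coef = setNames(rnorm(length(pm1$pair_ids)),
                                          pm1$pair_ids)),
                     class = "signature_model")
  expect_identical(score_samples(model, pm1), score_samples(model, pm2))
})
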