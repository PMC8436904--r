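rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_samples, 5, 2)) + 0.01,
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  m
}

test_that("enrichment score is positive for top-ranked sets, negative for bottom", {
  m <- rand_expr(50, 6, seed = 51)
  for (s in colnames(m)) {
    ord <- order(m[, s], decreasing = TRUE)
    top <- rownames(m)[ord[1:8]]
    bottom <- rownames(m)[ord[43:50]]
    expect_gt(ssgsea_score(m[, s, drop = FALSE], top, min_size = 1)[[1]], 0)
    expect_lt(ssgsea_score(m[, s, drop = FALSE], bottom, min_size = 1)[[1]], 0)
  }
})

test_that("running sum matches the brute-force oracle on 5-gene fixtures", {
  m <- rand_expr(5, 4, seed = 52)
  # the stated single-member case: the top-ranked gene of a sample
  s1 <- colnames(m)[1]
  top_gene <- rownames(m)[which.max(m[, s1])]
  expect_equal(ssgsea_score(m[, s1, drop = FALSE], top_gene,
                            min_size = 1)[[1]],
               brute_ssgsea(m[, s1], top_gene, alpha = 0.25))
  # every proper non-empty subset, every sample
  subsets <- unlist(lapply(1:4, function(k)
    combn(rownames(m), k, simplify = FALSE)), recursive = FALSE)
  for (set in subsets) {
    sc <- ssgsea_score(m, set, min_size = 1)
    for (s in colnames(m))
      expect_equal(sc[[s]], brute_ssgsea(m[, s], set, alpha = 0.25))
  }
})

test_that("scores are rank-based: per-sample monotone invariance", {
  m <- rand_expr(40, 8, seed = 53)
  set <- rownames(m)[c(2, 9, 17, 25, 33)]
  s1 <- ssgsea_score(m, set, min_size = 1)
  s2 <- ssgsea_score(exp(m / 3), set, min_size = 1)
  expect_equal(s1, s2)
})

test_that("reversing the ranking reverses the score ordering", {
  m <- rand_expr(40, 30, seed = 54)
  set <- rownames(m)[1:8]
  fwd <- ssgsea_score(m, set, min_size = 1)
  rev <- ssgsea_score(max(m) - m + 0.01, set, min_size = 1)
  expect_lt(cor(rank(fwd), rank(rev)), 0)
})

test_that("complement set negates the unweighted score (alpha = 0)", {
  m <- rand_expr(12, 5, seed = 55)
  set <- rownames(m)[c(1, 4, 7, 10)]
  comp <- setdiff(rownames(m), set)
  for (s in colnames(m)) {
    a <- brute_ssgsea(m[, s], set, alpha = 0)
    b <- brute_ssgsea(m[, s], comp, alpha = 0)
    expect_equal(a, -b, tolerance = 1e-12)
    expect_equal(ssgsea_score(m[, s, drop = FALSE], set, alpha = 0,
                              min_size = 1)[[1]], a)
  }
})

test_that("ESTIMATE-style scores: sum identity and permutation equivariance", {
  m <- rand_expr(60, 12, seed = 56)
  stromal <- rownames(m)[1:12]
  immune <- rownames(m)[21:32]
  sc <- estimate_scores(m, stromal, immune)
  expect_identical(sc$estimate_score, sc$stromal_score + sc$immune_score)

  perm <- sample(ncol(m))
  sc2 <- estimate_scores(m[, perm], stromal, immune)
  expect_equal(sc2$stromal_score,
               sc$stromal_score[match(sc2$sample_id, sc$sample_id)])
})

test_that("disjoint random sets on null data give uncorrelated scores", {
  # sets small relative to the gene universe, as in real signatures;
  # with sets covering a large share of a tiny matrix the compositional
  # coupling of the running sums induces spurious negative correlation
  rhos <- vapply(1:20, function(s) {
    m <- rand_expr(300, 200, seed = 500 + s)
    a <- ssgsea_score(m, rownames(m)[1:20], min_size = 10)
    b <- ssgsea_score(m, rownames(m)[150:169], min_size = 10)
    abs(cor(rank(a), rank(b)))
  }, numeric(1))
  expect_lt(mean(rhos), 0.2)
})

test_that("gene-set preconditions are enforced", {
  m <- rand_expr(20, 3, seed = 57)
  expect_error(ssgsea_score(m, c("nope1", "nope2")), "nope1")
  expect_error(ssgsea_score(m, rownames(m)[1:4], min_size = 10),
               "min_size")
  expect_error(ssgsea_score(m, rownames(m)), "whole matrix")
})

test_that("Spearman correlation with abundances matches the rank formula", {
  sc <- setNames(c(3.1, 1.2, 5.5, 2.2, 4.9), paste0("s", 1:5))
  ab <- data.frame(sample_id = paste0("s", 1:5),
                   Tcell = c(10, 2, 50, 8, 30),       # same ordering
                   Bcell = 10 - c(3.1, 1.2, 5.5, 2.2, 4.9))  # reversed
  res <- correlate_risk(sc, ab)
  expect_equal(res$rho[res$cell_type == "Tcell"], 1)
  expect_equal(res$rho[res$cell_type == "Bcell"], -1)

  # hand fixture: rho from the rank formula 1 - 6 sum(d^2)/(n(n^2-1))
  ab2 <- data.frame(sample_id = paste0("s", 1:5),
                    NK = c(2, 1, 4, 5, 3))
  d <- rank(sc) - rank(ab2$NK)
  expect_equal(correlate_risk(sc, ab2)$rho,
               1 - 6 * sum(d^2) / (5 * 24))
})

test_that("checkpoint-gene comparisons behave at the null and under shift", {
  m <- rand_expr(10, 200, seed = 58)
  g <- setNames(rep(c("high", "low"), 100), colnames(m))
  # identical groups built by duplication: p = 1
  m2 <- m
  m2["g001", ] <- rep(m["g001", 1:100], 2)
  g2 <- setNames(rep(c("high", "low"), each = 100), colnames(m))
  res0 <- group_expression_test(m2, "g001", g2)
  expect_equal(res0$p, 1)
  expect_equal(res0$direction, "none")

  # 2-sigma shift at n = 100/group
  m3 <- m
  m3["g002", g == "high"] <- m3["g002", g == "high"] + 4
  res1 <- group_expression_test(m3, "g002", g)
  expect_lt(res1$p, 0.001)
  expect_equal(res1$direction, "up")

  expect_error(group_expression_test(m, "ABSENT", g), "ABSENT")
})
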