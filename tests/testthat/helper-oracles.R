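# Independent oracles and small fixture builders. These deliberately
# reimplement the operations under test by the most literal route
# available (double loops, grid search, step-by-step running sums) and
# must stay independent of the package internals.

# literal double-loop evaluation of the pair rule: 0 iff X < Y, else 1,
# pairs in lexicographic canonical order
naive_pair_matrix <- function(m) {
  m <- m[order(rownames(m)), , drop = FALSE]
  ids <- rownames(m)
  n <- nrow(m)
  rows <- list()
  rn <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      row <- numeric(ncol(m))
      for (s in seq_len(ncol(m)))
        row[s] <- if (m[i, s] < m[j, s]) 0 else 1
      rows[[length(rows) + 1]] <- row
      rn <- c(rn, paste(ids[i], ids[j], sep = "|"))
    }
  }
  out <- do.call(rbind, rows)
  dimnames(out) <- list(rn, colnames(m))
  out
}

# grid search of the 1-covariate log partial likelihood (no ties):
# returns the grid argmax of sum_events [ b x_i - log sum_{risk} e^{b x_j} ]
grid_cox_beta <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  stopifnot(anyDuplicated(time) == 0)
  grid <- seq(lo, hi, by = step)
  ord <- order(time)
  x <- x[ord]; event <- event[ord]
  n <- length(x)
  M <- outer(grid, x)
  E <- exp(M)
  Ecum <- E
  for (j in seq(n - 1, 1)) Ecum[, j] <- Ecum[, j + 1] + E[, j]
  ev <- which(event == 1)
  ll <- rowSums(M[, ev, drop = FALSE] - log(Ecum[, ev, drop = FALSE]))
  grid[which.max(ll)]
}

# step-by-step scalar evaluation of the weighted running-sum enrichment
# statistic for one sample
brute_ssgsea <- function(x, set, alpha) {
  stopifnot(!is.null(names(x)))
  r <- rank(x)
  ord <- order(r, decreasing = TRUE)
  genes <- names(x)[ord]
  inset <- genes %in% set
  w <- r[ord]^alpha
  wsum <- sum(w[inset])
  nout <- sum(!inset)
  score <- 0; pin <- 0; pout <- 0
  for (i in seq_along(genes)) {
    if (inset[i]) pin <- pin + w[i] / wsum else pout <- pout + 1 / nout
    score <- score + (pin - pout)
  }
  unname(score)
}

# minimal survival fixture: exponential event times with a log hazard
# ratio `beta` on a binary covariate, exponential censoring
sim_surv <- function(n, beta = 0, censor_rate = 0.3, x = NULL) {
  if (is.null(x)) x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.01 * exp(beta * x))
  if (censor_rate > 0) {
    cens <- rexp(n, rate = 0.01 * censor_rate / (1 - censor_rate))
    list(x = x, time = pmin(t_ev, cens), event = as.numeric(t_ev <= cens))
  } else {
    list(x = x, time = t_ev, event = rep(1, n))
  }
}

# wrap a plain binary vector as a one-pair pair_matrix via the public
# constructor route: gene A carries the indicator, gene B a constant
# reference level between the two A values
one_pair_matrix <- function(v, sample_ids = sprintf("S%03d", seq_along(v))) {
  m <- rbind(A = v + 1, B = rep(1.5, length(v)))
  colnames(m) <- sample_ids
  build_pair_matrix(m)
}

# tiny immune co-expression matrix fixture
small_expr <- function(seed = 1, n_samples = 20) {
  set.seed(seed)
  imm <- rnorm(n_samples, 5, 1)
  m <- rbind(
    LNC_LIN = 2 * imm + 1,        # exact linear dependence
    LNC_NOISE = rnorm(n_samples, 5, 1),
    PCG_IMM = imm,
    PCG_OTHER = rnorm(n_samples, 5, 1))
  m <- m - min(m) + 0.1           # keep non-negative
  colnames(m) <- sprintf("S%02d", seq_len(n_samples))
  expression_matrix(m, c(LNC_LIN = "lncRNA", LNC_NOISE = "lncRNA",
                         PCG_IMM = "mRNA", PCG_OTHER = "mRNA"))
}
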