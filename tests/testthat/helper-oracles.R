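# Independent oracles used across the suite. These are deliberately naive
# re-derivations (loops, enumeration, brute force) kept separate from the
# package's own code paths.

# Brute-force GSEA running sum: explicit loop, no cumsum/vector tricks.
oracle_gsea_es <- function(gene_ids, scores, members, weight = 1) {
  n <- length(gene_ids)
  hit <- gene_ids %in% members
  nh <- sum(hit)
  denom <- 0
  for (i in seq_len(n)) if (hit[i]) denom <- denom + abs(scores[i])^weight
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      acc <- acc + if (denom > 0) abs(scores[i])^weight / denom else 0
    } else {
      acc <- acc - 1 / (n - nh)
    }
    running[i] <- acc
  }
  mx <- running[1]; mn <- running[1]
  for (i in seq_len(n)) {
    if (running[i] > mx) mx <- running[i]
    if (running[i] < mn) mn <- running[i]
  }
  if (mx >= -mn) mx else mn
}

# Compare two enrichment scores, accepting a sign flip only when the
# positive and negative maximal deviations tie in magnitude (the sign is
# then ill-defined and implementations may resolve the tie differently at
# the last floating-point digit).
expect_es_equal <- function(actual, expected, tol = 1e-12) {
  ok <- abs(actual - expected) <= tol ||
    abs(abs(actual) - abs(expected)) <= tol
  testthat::expect_true(ok, label = sprintf(
    "enrichment scores %.15g and %.15g agree up to a magnitude tie",
    actual, expected))
}

# Efron log partial likelihood for a single continuous covariate, coded
# from the definition (no survival:: calls).
oracle_efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d_idx <- which(time == t & event == 1)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    eta_d <- sum(x[d_idx] * beta)
    s_risk <- sum(exp(beta * x[r_idx]))
    s_tied <- sum(exp(beta * x[d_idx]))
    ll <- ll + eta_d
    for (l in seq_len(d) - 1) {
      ll <- ll - log(s_risk - (l / d) * s_tied)
    }
  }
  ll
}

# Grid + golden-section maximization of the oracle partial likelihood.
oracle_cox_beta <- function(time, event, x, lower = -5, upper = 5) {
  grid <- seq(lower, upper, length.out = 201)
  ll <- vapply(grid, oracle_efron_loglik, 1.0, time = time, event = event,
               x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(oracle_efron_loglik, c(b0 - 0.1, b0 + 0.1),
                  time = time, event = event, x = x,
                  maximum = TRUE, tol = 1e-9)$maximum
}

# Hand hypergeometric O-E tabulation of the two-group log-rank statistic.
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(as.factor(group)) # 1 / 2
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    e1 <- d * n1 / n
    oe <- oe + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

make_ranked <- function(ids, scores) {
  df <- data.frame(gene_id = ids, log2fc = scores, stringsAsFactors = FALSE)
  rank_by_log2fc(df)
}

# Small deterministic expression matrix builder for toy tests.
toy_expr <- function(values, condition, scale = "log2cpm") {
  expr_matrix(values, condition = condition, scale = scale)
}
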