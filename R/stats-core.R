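#' Rank a vector with tie-averaging
#'
#' Average ranks are assigned to tied values, so ranks always sum to
#' `n*(n+1)/2`. This is the rank convention used by every rank-based test in
#' the package.
#'
#' @param values non-empty numeric vector without missing values.
#' @return numeric vector of (possibly fractional) ranks.
#' @export
#' @examples
#' rank_with_ties(c(5, 5, 7)) # 1.5 1.5 3
rank_with_ties <- function(values) {
  if (length(values) == 0) stopf("rank_with_ties: empty input")
  if (anyNA(values)) stopf("rank_with_ties: missing values not allowed")
  rank(values, ties.method = "average")
}

#' Spearman rank correlation with p-value
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' tie-averaged ranks. The default two-sided p-value uses the t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n-2` degrees of
#' freedom; for `n <= 8` an exact permutation p-value (all `n!` permutations)
#' is available via `method = "exact"`.
#'
#' Pairs with a missing value in either vector are removed before anything
#' else. A constant vector leaves the coefficient undefined: the result is
#' flagged (`degenerate = TRUE`) with `rho = NA`, never silently zero.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"approx"` (t approximation, default) or `"exact"`
#'   (permutation, only for n <= 8).
#' @return object of class `cs_cor` with fields `rho`, `p`, `n`, `method`,
#'   `degenerate`.
#' @export
#' @examples
#' spearman(1:4, c(2, 4, 6, 8))$rho # 1
spearman <- function(x, y, method = c("approx", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("spearman: unequal lengths")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stopf("spearman: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(rho = NA_real_, p = NA_real_, n = n, method = method,
                degenerate = TRUE)
    class(out) <- "cs_cor"
    return(out)
  }
  rx <- rank_with_ties(x)
  ry <- rank_with_ties(y)
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (method == "exact") {
    if (n > 8) stopf("spearman: exact permutation p only for n <= 8")
    p <- spearman_exact_p(rx, ry)
  } else {
    if (abs(rho) == 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  out <- list(rho = rho, p = p, n = n, method = method, degenerate = FALSE)
  class(out) <- "cs_cor"
  out
}

# Exact two-sided permutation p for Spearman on rank vectors (n <= 8):
# proportion of the n! permutations of y-ranks whose |rho| >= |observed|.
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  perms <- all_permutations(n)
  rho_obs <- stats::cor(rx, ry)
  # Pearson on ranks: center once, correlate against every permutation.
  cx <- rx - mean(rx)
  denom_x <- sqrt(sum(cx^2))
  rho_all <- apply(perms, 1, function(idx) {
    yy <- ry[idx]
    cy <- yy - mean(yy)
    sum(cx * cy) / (denom_x * sqrt(sum(cy^2)))
  })
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

# All permutations of 1..n as a matrix (n! rows). Recursive; n <= 8 only.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

new_test_result <- function(statistic, p, method, note = NULL) {
  out <- list(statistic = statistic, p = min(1, max(0, p)), method = method,
              note = note)
  class(out) <- "cs_test"
  out
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test for a location difference between two independent groups.
#' When the combined sample size is at most 12 the null distribution of the
#' Mann-Whitney U statistic is enumerated exactly over all assignments of
#' ranks to groups (ties handled by average ranks); otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used (delegated to [stats::wilcox.test()]).
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates when `length(a) + length(b) <= 12`.
#' @param correct continuity correction in the approximate mode.
#' @return `cs_test` with the U statistic (named `W` as in base R) and p.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL, correct = TRUE) {
  if (length(a) == 0 || length(b) == 0) {
    stopf("wilcoxon_rank_sum: both groups must be non-empty")
  }
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(new_test_result(na * nb / 2, 1, "wilcoxon_rank_sum",
                           note = "all values identical"))
  }
  r <- rank_with_ties(pooled)
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2 # Mann-Whitney U of group a
  if (is.null(exact)) exact <- (na + nb) <= 12
  if (exact) {
    combs <- utils::combn(na + nb, na)
    wnull <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    m <- length(wnull)
    eps <- 1e-9
    p_lo <- sum(wnull <= w + eps) / m
    p_hi <- sum(wnull >= w - eps) / m
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = correct)$p.value
    )
  }
  new_test_result(w, p, "wilcoxon_rank_sum")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon convention). `V` is the sum of the
#' ranks of positive differences among the absolute differences. Exact
#' enumeration over all `2^m` sign assignments is used for at most 12
#' non-zero pairs; otherwise the tie-corrected normal approximation with
#' continuity correction (via [stats::wilcox.test()]).
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @param exact force/suppress exact enumeration; default `NULL` enumerates
#'   for m <= 12 non-zero differences.
#' @return `cs_test` with statistic `V` and two-sided p.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact = NULL) {
  if (length(paired_a) != length(paired_b)) {
    stopf("wilcoxon_signed_rank: unequal lengths")
  }
  d <- paired_a - paired_b
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(new_test_result(0, 1, "wilcoxon_signed_rank",
                           note = "all differences zero"))
  }
  r <- rank_with_ties(abs(d))
  v <- sum(r[d > 0])
  if (is.null(exact)) exact <- m <= 12
  if (exact) {
    # All 2^m sign assignments; V null distribution given the tied ranks.
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    vnull <- as.numeric(signs %*% r)
    eps <- 1e-9
    p_lo <- mean(vnull <= v + eps)
    p_hi <- mean(vnull >= v - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
    )
  }
  new_test_result(v, p, "wilcoxon_signed_rank",
                  note = if (n_zero > 0) sprintf("%d zero differences dropped",
                                                 n_zero))
}

#' Kruskal-Wallis rank test for k groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k-1 degrees of freedom (delegated to [stats::kruskal.test()]). The fully
#' degenerate case (every value identical) is reported as H = 0, p = 1
#' rather than the indeterminate 0/0 of the tie correction.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return `cs_test` with statistic `H` and p.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stopf("kruskal_wallis: need a list of >= 2 groups")
  }
  if (any(vapply(groups, length, 1L) == 0)) {
    stopf("kruskal_wallis: empty group")
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3) stopf("kruskal_wallis: total n must be >= 3")
  if (length(unique(pooled)) == 1) {
    return(new_test_result(0, 1, "kruskal_wallis",
                           note = "all values identical"))
  }
  kt <- stats::kruskal.test(groups)
  new_test_result(unname(kt$statistic), kt$p.value, "kruskal_wallis")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment ([stats::p.adjust()] with
#' `method = "BH"`). Output order matches input order; adjusted values never
#' exceed 1 and are monotone along the sorted p-values.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed,
#'   propagated).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stopf("bh_adjust: p-values outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' @export
print.cs_cor <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Spearman correlation: undefined (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("Spearman rho = %.4f, p = %.4g, n = %d (%s)\n",
                x$rho, x$p, x$n, x$method))
  }
  invisible(x)
}

#' @export
print.cs_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n", x$method, x$statistic, x$p))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
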