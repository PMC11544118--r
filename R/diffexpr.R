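#' Moderated-t differential expression between tumor and normal
#'
#' Per-gene two-group comparison on the log2(CPM+1) scale. The log2 fold
#' change is the difference of group means. The statistic is a moderated t:
#' gene-wise residual variances are shrunk toward a pooled scale `s0^2` with
#' prior degrees of freedom `d0`, both estimated by method of moments from
#' the observed variance distribution (matching the mean and variance of a
#' scaled F law). The moderated variance is
#' `s_tilde^2 = (d0*s0^2 + d*s^2) / (d0 + d)` and the statistic is referred
#' to a t distribution on `d0 + d` degrees of freedom. In the limit
#' `d0 -> Inf` every gene uses the pooled scale; at `d0 = 0` the statistic
#' is the ordinary two-sample t.
#'
#' Genes with zero variance in both groups have an undefined statistic and
#' are reported with `p = 1` and `degenerate = TRUE`. BH adjustment is
#' applied across all tested genes.
#'
#' @param expr `expr_matrix` on the `log2cpm` scale with >= 2 samples per
#'   condition.
#' @param genes optional subset of gene ids to test (e.g. lncRNAs only).
#' @param prior_df override for the prior degrees of freedom `d0` (numeric,
#'   may be `Inf` or `0`); `NULL` estimates it from the data.
#' @param lfc_threshold,p_threshold thresholds used to annotate `direction`.
#' @return data.frame with columns `gene_id`, `log2fc`, `statistic`, `p`,
#'   `adj_p`, `direction`, `degenerate`; attribute `prior` holds the fitted
#'   `(d0, s02)`.
#' @export
differential_expression <- function(expr, genes = NULL, prior_df = NULL,
                                    lfc_threshold = 1, p_threshold = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "log2cpm") {
    stopf("differential_expression: expression must be log2cpm (see cpm_log_normalize)")
  }
  is_t <- expr$condition == "tumor"
  n1 <- sum(is_t); n2 <- sum(!is_t)
  if (n1 < 2 || n2 < 2) {
    stopf("differential_expression: need >= 2 samples per condition")
  }
  v <- expr$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) > 0) {
      stopf("differential_expression: gene '%s' not in matrix", missing[1])
    }
    v <- v[genes, , drop = FALSE]
  }
  xt <- v[, is_t, drop = FALSE]
  xn <- v[, !is_t, drop = FALSE]
  m1 <- rowMeans(xt)
  m2 <- rowMeans(xn)
  lfc <- m1 - m2
  ss1 <- rowSums((xt - m1)^2)
  ss2 <- rowSums((xn - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  degenerate <- s2 <= 0

  prior <- fit_variance_prior(s2[!degenerate], d)
  if (!is.null(prior_df)) prior$d0 <- prior_df
  d0 <- prior$d0; s02 <- prior$s02

  if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_tilde <- s2
    df_total <- d
  } else {
    s2_tilde <- (d0 * s02 + d * s2) / (d0 + d)
    df_total <- d0 + d
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  tstat[degenerate] <- NA_real_
  p[degenerate] <- 1
  adj <- bh_adjust(p)
  direction <- rep("ns", length(p))
  direction[lfc > lfc_threshold & adj < p_threshold] <- "up"
  direction[lfc < -lfc_threshold & adj < p_threshold] <- "down"
  out <- data.frame(gene_id = rownames(v), log2fc = unname(lfc),
                    statistic = unname(tstat), p = unname(p),
                    adj_p = unname(adj), direction = direction,
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior") <- prior
  out
}

# Method-of-moments fit of the scaled-F variance prior: if s^2 ~ s0^2 *
# F(d, d0) then m1 = E[s^2] = s0^2 d0/(d0-2) and
# Var[s^2]/m1^2 = 2 (d + d0 - 2) / (d (d0 - 4)). Solving the variance ratio
# for d0 gives d0 = (4 r d + 2 d - 4) / (r d - 2) with r the observed
# squared coefficient of variation; r d <= 2 means no excess spread over a
# chi-square, i.e. d0 = Inf.
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 4) return(list(d0 = Inf, s02 = mean(s2)))
  m1 <- mean(s2)
  r <- stats::var(s2) / m1^2
  if (r * d <= 2) {
    d0 <- Inf
    s02 <- m1
  } else {
    d0 <- (4 * r * d + 2 * d - 4) / (r * d - 2)
    s02 <- m1 * (d0 - 2) / d0
    if (d0 <= 2 || s02 <= 0) { # extremely heavy spread: fall back to no shrinkage
      d0 <- 0
      s02 <- m1
    }
  }
  list(d0 = d0, s02 = s02)
}

#' Filter differential-expression records into up / down sets
#'
#' Strict inequalities on both axes: up requires `log2fc > lfc_threshold`
#' and `adj_p < p_threshold`; down is symmetric with `log2fc <
#' -lfc_threshold`. A record sitting exactly on a threshold is excluded.
#'
#' @param records data.frame from [differential_expression()] (needs
#'   `gene_id`, `log2fc`, `adj_p`).
#' @param lfc_threshold,p_threshold screening thresholds.
#' @return list with character vectors `up` and `down`.
#' @export
filter_de <- function(records, lfc_threshold = 1, p_threshold = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "adj_p") %in% names(records)))
  up <- records$gene_id[records$log2fc > lfc_threshold &
                          records$adj_p < p_threshold]
  down <- records$gene_id[records$log2fc < -lfc_threshold &
                            records$adj_p < p_threshold]
  list(up = up, down = down)
}

#' Write a differential-expression table to TSV
#'
#' @param records data.frame from [differential_expression()].
#' @param path output path.
#' @param seed,config_hash optional provenance fields.
#' @export
write_de_tsv <- function(records, path, seed = NULL, config_hash = NULL) {
  write_tsv(records, path, seed = seed, config_hash = config_hash)
}
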