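#' Test a marker's association with a clinical factor
#'
#' Two-level factors use the Wilcoxon rank-sum test, factors with more
#' levels the Kruskal-Wallis test. Per-level medians are attached.
#'
#' @param values per-sample marker values.
#' @param factor_var factor (or coercible) of the same length.
#' @return `cs_test` with extra fields `levels` and `medians`.
#' @export
clinical_association <- function(values, factor_var) {
  f <- droplevels(as.factor(factor_var))
  keep <- !is.na(values) & !is.na(f)
  values <- values[keep]; f <- droplevels(f[keep])
  if (nlevels(f) < 2) stopf("clinical_association: factor has a single level")
  groups <- split(values, f)
  res <- if (nlevels(f) == 2) {
    wilcoxon_rank_sum(groups[[1]], groups[[2]])
  } else {
    kruskal_wallis(groups)
  }
  res$levels <- levels(f)
  res$medians <- vapply(groups, stats::median, 1.0)
  res
}

#' Compare immune cell fractions between two expression groups
#'
#' One Wilcoxon rank-sum test per cell type between the `high` and `low`
#' groups, BH-adjusted across the cell types (one family per call). The
#' direction records which group has the larger median fraction. A cell
#' type constant across both groups is reported with p = 1 and flagged.
#'
#' @param fractions numeric matrix, cell types x samples (columns sum to
#'   1).
#' @param groups named factor/character of `high`/`low` per sample; only
#'   samples present in both inputs are used.
#' @return data.frame: `cell_type`, `statistic`, `p`, `adj_p`,
#'   `higher_in`, `degenerate`; attribute `bh_family` documents the
#'   adjustment family.
#' @export
fraction_group_compare <- function(fractions, groups) {
  check_fraction_table(fractions)
  shared <- intersect(colnames(fractions), names(groups))
  groups <- as.character(groups[shared])
  if (!all(groups %in% c("high", "low"))) {
    stopf("fraction_group_compare: groups must be 'high'/'low'")
  }
  if (!all(c("high", "low") %in% groups)) {
    stopf("fraction_group_compare: both groups must be non-empty")
  }
  fr <- fractions[, shared, drop = FALSE]
  rows <- lapply(rownames(fr), function(ct) {
    hi <- fr[ct, groups == "high"]
    lo <- fr[ct, groups == "low"]
    if (length(unique(c(hi, lo))) == 1) {
      return(data.frame(cell_type = ct, statistic = NA_real_, p = 1,
                        higher_in = NA_character_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    t <- wilcoxon_rank_sum(hi, lo)
    dir <- if (stats::median(hi) > stats::median(lo)) "high"
           else if (stats::median(hi) < stats::median(lo)) "low"
           else NA_character_
    data.frame(cell_type = ct, statistic = t$statistic, p = t$p,
               higher_in = dir, degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[, c("cell_type", "statistic", "p", "adj_p", "higher_in",
                 "degenerate")]
  attr(out, "bh_family") <-
    sprintf("BH across the %d cell types of this comparison", nrow(out))
  out
}

#' Correlate immune cell fractions with a marker's expression
#'
#' Spearman correlation per cell type over the shared samples, BH-adjusted
#' across cell types.
#'
#' @param fractions numeric matrix, cell types x samples.
#' @param values named per-sample marker values.
#' @return data.frame: `cell_type`, `rho`, `p`, `adj_p`, `n`; attribute
#'   `bh_family` documents the adjustment family.
#' @export
fraction_expression_correlation <- function(fractions, values) {
  check_fraction_table(fractions)
  shared <- intersect(colnames(fractions), names(values))
  if (length(shared) < 3) {
    stopf("fraction_expression_correlation: fewer than 3 shared samples")
  }
  v <- values[shared]
  rows <- lapply(rownames(fractions), function(ct) {
    cr <- spearman(fractions[ct, shared], v)
    data.frame(cell_type = ct, rho = cr$rho, p = cr$p, n = cr$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[, c("cell_type", "rho", "p", "adj_p", "n")]
  attr(out, "bh_family") <-
    sprintf("BH across the %d cell types of this correlation screen",
            nrow(out))
  out
}

check_fraction_table <- function(fractions) {
  if (!is.matrix(fractions) || !is.numeric(fractions)) {
    stopf("fraction table must be a numeric matrix (cell types x samples)")
  }
  if (any(fractions < -1e-9)) stopf("fraction table has negative entries")
  sums <- colSums(fractions)
  if (any(abs(sums - 1) > 1e-6)) {
    stopf("fraction table columns must sum to 1 (sample '%s' sums to %.4f)",
          colnames(fractions)[which.max(abs(sums - 1))],
          sums[which.max(abs(sums - 1))])
  }
  invisible(TRUE)
}

# Per-sample, per-gene delta-Ct against the reference gene: replicate Ct
# values are averaged per (sample, condition, gene) before differencing.
mean_ct_table <- function(ct) {
  stopifnot(all(c("sample_id", "gene", "condition", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stopf("Ct values must be > 0")
  agg <- stats::aggregate(ct ~ sample_id + condition + gene, data = ct,
                          FUN = mean)
  agg
}

#' Relative quantification by 2^-deltaCt
#'
#' For every non-reference gene and sample: `deltaCt = mean Ct(target
#' replicates) - mean Ct(reference replicates)` within the same sample and
#' condition, reported as `2^-deltaCt`.
#'
#' @param ct data.frame of wells with columns `sample_id`, `gene`,
#'   `condition`, `replicate`, `ct`.
#' @param reference_gene the normalizer (e.g. `"ACTB"`); must be measured
#'   for every (sample, condition).
#' @return data.frame: `sample_id`, `condition`, `gene`, `delta_ct`,
#'   `rel_expr` (= 2^-deltaCt).
#' @export
delta_ct <- function(ct, reference_gene) {
  agg <- mean_ct_table(ct)
  ref <- agg[agg$gene == reference_gene, ]
  if (nrow(ref) == 0) stopf("delta_ct: reference gene '%s' not measured",
                            reference_gene)
  tgt <- agg[agg$gene != reference_gene, ]
  key <- function(df) paste(df$sample_id, df$condition, sep = "\r")
  ref_ct <- stats::setNames(ref$ct, key(ref))
  miss <- setdiff(unique(key(tgt)), names(ref_ct))
  if (length(miss) > 0) {
    stopf("delta_ct: reference missing for sample/condition '%s'",
          gsub("\r", "/", miss[1]))
  }
  dct <- tgt$ct - ref_ct[key(tgt)]
  out <- data.frame(sample_id = tgt$sample_id, condition = tgt$condition,
                    gene = tgt$gene, delta_ct = unname(dct),
                    rel_expr = 2^(-unname(dct)), stringsAsFactors = FALSE)
  out[order(out$gene, out$condition, out$sample_id), , drop = FALSE]
}

#' Relative quantification by 2^-deltadeltaCt (Livak)
#'
#' deltaCt values (per [delta_ct()]) are further normalized to the mean
#' deltaCt of the control condition per gene:
#' `deltadeltaCt = deltaCt - mean(deltaCt | control)`, fold change
#' `2^-deltadeltaCt`. The geometric mean fold of the control condition is
#' 1 by construction.
#'
#' @param ct Ct well table as in [delta_ct()].
#' @param reference_gene the normalizer gene.
#' @param control_condition the baseline condition (e.g. `"adjacent"` or
#'   `"siNC"`).
#' @return data.frame: `sample_id`, `condition`, `gene`, `ddct`, `fold`.
#' @export
delta_delta_ct <- function(ct, reference_gene, control_condition) {
  d <- delta_ct(ct, reference_gene)
  if (!control_condition %in% d$condition) {
    stopf("delta_delta_ct: control condition '%s' absent", control_condition)
  }
  ctrl_mean <- tapply(d$delta_ct[d$condition == control_condition],
                      d$gene[d$condition == control_condition], mean)
  miss <- setdiff(unique(d$gene), names(ctrl_mean))
  if (length(miss) > 0) {
    stopf("delta_delta_ct: gene '%s' has no control-condition wells",
          miss[1])
  }
  ddct <- d$delta_ct - ctrl_mean[d$gene]
  data.frame(sample_id = d$sample_id, condition = d$condition,
             gene = d$gene, ddct = unname(ddct), fold = 2^(-unname(ddct)),
             stringsAsFactors = FALSE)
}

#' Paired tumor-vs-adjacent comparison (Wilcoxon signed-rank)
#'
#' Matches the two vectors by pair identifier and tests the paired
#' differences.
#'
#' @param tumor,adjacent named numeric vectors; names are pair ids.
#' @param pair_ids optional explicit pair ids (used when the vectors are
#'   unnamed and already aligned).
#' @return `cs_test` with extra field `direction` (`"tumor_higher"`,
#'   `"adjacent_higher"` or `"none"` by median difference).
#' @export
paired_expression_compare <- function(tumor, adjacent, pair_ids = NULL) {
  if (!is.null(pair_ids)) {
    names(tumor) <- pair_ids
    names(adjacent) <- pair_ids
  }
  if (is.null(names(tumor)) || is.null(names(adjacent))) {
    stopf("paired_expression_compare: pair ids required")
  }
  shared <- intersect(names(tumor), names(adjacent))
  if (length(shared) < length(tumor) || length(shared) < length(adjacent)) {
    stopf("paired_expression_compare: unmatched pair ids")
  }
  t <- tumor[shared]; a <- adjacent[shared]
  res <- wilcoxon_signed_rank(t, a)
  md <- stats::median(t - a)
  res$direction <- if (md > 0) "tumor_higher"
                   else if (md < 0) "adjacent_higher" else "none"
  res
}
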