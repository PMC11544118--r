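#' Build a ranked list from differential-expression records
#'
#' All expressed genes (no DE filter) ordered descending by log2 fold
#' change; ties are broken lexicographically by gene id so the order is
#' deterministic.
#'
#' @param de_records data.frame with `gene_id` and `log2fc`, one row per
#'   gene.
#' @return object of class `ranked_list`: list with `gene_ids` and
#'   `scores` in ranked order.
#' @export
rank_by_log2fc <- function(de_records) {
  stopifnot(all(c("gene_id", "log2fc") %in% names(de_records)))
  if (anyDuplicated(de_records$gene_id)) {
    stopf("rank_by_log2fc: duplicate gene id '%s'",
          de_records$gene_id[duplicated(de_records$gene_id)][1])
  }
  ord <- order(-de_records$log2fc, de_records$gene_id)
  structure(list(gene_ids = de_records$gene_id[ord],
                 scores = de_records$log2fc[ord]),
            class = "ranked_list")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic preranked GSEA running sum: walking down the ranked list, a
#' set member ("hit") at position i increments the sum by
#' `|score_i|^weight / sum_j(|score_j|^weight)` (sum over set members), a
#' non-member decrements it by `1 / (N - Nh)`. The enrichment score is the
#' value of the running sum at its maximum absolute deviation from zero.
#' If every set member has zero weighted score the hit increments are
#' defined as zero.
#'
#' @param ranked `ranked_list`.
#' @param set character vector of member gene ids (or a `gene_set`).
#' @param weight exponent on the scores (1 = classic weighted; 0 =
#'   unweighted KS).
#' @return list with `es` and the full `running` sum vector.
#' @export
gsea_es <- function(ranked, set, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  members <- if (inherits(set, "gene_set")) set$genes else set
  hit <- ranked$gene_ids %in% members
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0) stopf("gsea_es: no set member in the ranked list")
  if (nh == n) stopf("gsea_es: set covers every ranked gene")
  w <- abs(ranked$scores)^weight
  denom <- sum(w[hit])
  inc <- rep(-1 / (n - nh), n)
  inc[hit] <- if (denom > 0) w[hit] / denom else 0
  running <- cumsum(inc)
  mx <- max(running)
  mn <- min(running)
  # signed maximal deviation; an exact magnitude tie resolves positive
  es <- if (mx >= -mn) mx else mn
  list(es = es, running = running)
}

#' Permutation significance for a preranked enrichment score
#'
#' Null enrichment scores are obtained by permuting the set-membership
#' labels over the ranked list (preranked mode), keeping the set size. The
#' normalized score is `NES = es / mean(|null ES| of matching sign)` and
#' the p-value is `(1 + #{null at least as extreme, matching sign}) /
#' (1 + #{null of matching sign})`. When no null sample matches the sign
#' the p-value is reported at its resolution bound `1 / (n_perm + 1)`.
#'
#' @param ranked `ranked_list`.
#' @param set member gene ids (or `gene_set`).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param weight score exponent, as in [gsea_es()].
#' @return object of class `gsea_result`: `es`, `nes`, `p`,
#'   `leading_edge` (member genes up to the running-sum extremum on the
#'   enriched side), `n_perm`, `set_size`.
#' @export
gsea_significance <- function(ranked, set, n_perm = 1000, seed = 1,
                              weight = 1) {
  if (n_perm < 100) stopf("gsea_significance: n_perm must be >= 100")
  obs <- gsea_es(ranked, set, weight = weight)
  members <- if (inherits(set, "gene_set")) set$genes else set
  hit <- ranked$gene_ids %in% members
  n <- length(hit); nh <- sum(hit)
  w <- abs(ranked$scores)^weight
  base_inc <- -1 / (n - nh)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sample.int(n, nh)
      inc <- rep(base_inc, n)
      wh <- w[pos]
      s <- sum(wh)
      inc[pos] <- if (s > 0) wh / s else 0
      r <- cumsum(inc)
      rmx <- max(r)
      rmn <- min(r)
      if (rmx >= -rmn) rmx else rmn
    }, 1.0)
  })
  same_sign <- null_es * sign(obs$es) > 0
  m <- sum(same_sign)
  if (m == 0) {
    nes <- sign(obs$es)
    p <- 1 / (n_perm + 1)
  } else {
    nes <- obs$es / mean(abs(null_es[same_sign]))
    extreme <- sum(abs(null_es[same_sign]) >= abs(obs$es) - 1e-12)
    p <- (1 + extreme) / (1 + m)
  }
  peak <- if (obs$es >= 0) which.max(obs$running) else which.min(obs$running)
  leading <- if (obs$es >= 0) {
    ranked$gene_ids[seq_len(peak)][hit[seq_len(peak)]]
  } else {
    ranked$gene_ids[peak:n][hit[peak:n]]
  }
  structure(list(es = obs$es, nes = nes, p = p, leading_edge = leading,
                 n_perm = n_perm, set_size = nh),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, NES = %.3f, p = %.4g (set size %d, %d perms)\n",
              x$es, x$nes, x$p, x$set_size, x$n_perm))
  invisible(x)
}

#' Run preranked GSEA over several gene sets with BH adjustment
#'
#' One permutation test per set (seeds derived deterministically from
#' `seed`), with BH adjustment across all sets tested in the call.
#'
#' @param ranked `ranked_list`.
#' @param sets named list of gene sets (character vectors or `gene_set`s).
#' @param n_perm,weight,seed as in [gsea_significance()].
#' @return data.frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p`, `adj_p`, `leading_edge_size`.
#' @export
gsea_batch <- function(ranked, sets, n_perm = 1000, weight = 1, seed = 1) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  rows <- lapply(seq_along(sets), function(i) {
    r <- gsea_significance(ranked, sets[[i]], n_perm = n_perm,
                           seed = seed + i, weight = weight)
    data.frame(set = names(sets)[i], size = r$set_size, es = r$es,
               nes = r$nes, p = r$p,
               leading_edge_size = length(r$leading_edge),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out[, c("set", "size", "es", "nes", "p", "adj_p", "leading_edge_size")]
}

#' Geometric-mean signature score
#'
#' Per-sample score `exp(mean(log(count + pseudocount)))` over the set
#' members present in the matrix; absent members are reported in the
#' `absent` attribute. For counts well above the pseudocount the score is
#' scale-equivariant.
#'
#' @param expr `expr_matrix` on the `counts` scale.
#' @param set member gene ids (or `gene_set`).
#' @param pseudocount added before the log (default 1).
#' @return named numeric vector of per-sample scores; attribute `absent`
#'   lists the set members missing from the matrix.
#' @export
signature_score_geomean <- function(expr, set, pseudocount = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "counts") {
    stopf("signature_score_geomean: expression must be on the counts scale")
  }
  members <- if (inherits(set, "gene_set")) set$genes else set
  members <- normalize_gene_ids(members)
  rows <- stats::setNames(rownames(expr$values),
                          normalize_gene_ids(rownames(expr$values)))
  present <- intersect(members, names(rows))
  absent <- setdiff(members, names(rows))
  if (length(present) == 0) {
    stopf("signature_score_geomean: no set member present in the matrix")
  }
  sub <- expr$values[rows[present], , drop = FALSE]
  scores <- exp(colMeans(log(sub + pseudocount)))
  attr(scores, "absent") <- absent
  scores
}

#' Correlate a per-sample signature score with a gene's expression
#'
#' Delegates to [spearman()] on the shared samples and records the sample
#' count and a provenance fingerprint of the sample set used.
#'
#' @param scores named per-sample scores.
#' @param expr_values named per-sample expression of the gene.
#' @return `cs_cor` with extra fields `sample_hash`.
#' @export
score_correlation <- function(scores, expr_values) {
  shared <- intersect(names(scores), names(expr_values))
  if (length(shared) < 3) {
    stopf("score_correlation: fewer than 3 shared samples")
  }
  shared <- sort(shared)
  out <- spearman(scores[shared], expr_values[shared])
  out$sample_hash <- string_fingerprint(shared)
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-separated GMT dialect: field 1 the set name, field 2 a description
#' (dropped), remaining fields the member genes. Duplicate members are
#' collapsed. A line with fewer than 3 fields is an error.
#'
#' @param path GMT file.
#' @return named list of `gene_set` objects (`name`, `genes`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("read_gmt: line %d has fewer than 3 fields", i)
    }
    genes <- unique(fields[-(1:2)])
    out[[fields[1]]] <- structure(list(name = fields[1], genes = genes),
                                  class = "gene_set")
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors or `gene_set` objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    genes <- sets[[nm]]
    if (inherits(genes, "gene_set")) genes <- genes$genes
    paste(c(nm, "na", genes), collapse = "\t")
  }, "")
  writeLines(unname(lines), path)
  invisible(path)
}
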