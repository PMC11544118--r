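#' Construct an interaction table
#'
#' A set of predicted regulatory edges from one prediction source, either
#' lncRNA -> miRNA (`edge_class = "lnc_mi"`) or miRNA -> mRNA
#' (`"mi_mrna"`). Identifiers are normalized ([normalize_gene_ids()]),
#' self-edges are rejected, and the inferred class of each endpoint must
#' match the edge class.
#'
#' @param edges data.frame with columns `regulator_id` and `target_id`
#'   (`source_id` is accepted as an alias of `regulator_id`).
#' @param edge_class `"lnc_mi"` or `"mi_mrna"`.
#' @param source_db label of the prediction source (e.g. `"targetscan"`).
#' @return object of class `interaction_table`.
#' @export
interaction_table <- function(edges, edge_class = c("lnc_mi", "mi_mrna"),
                              source_db) {
  edge_class <- match.arg(edge_class)
  if ("source_id" %in% names(edges) && !"regulator_id" %in% names(edges)) {
    names(edges)[names(edges) == "source_id"] <- "regulator_id"
  }
  stopifnot(all(c("regulator_id", "target_id") %in% names(edges)))
  reg <- normalize_gene_ids(edges$regulator_id)
  tgt <- normalize_gene_ids(edges$target_id)
  if (any(reg == tgt)) stopf("interaction_table: self-edge '%s'", reg[reg == tgt][1])
  reg_class <- infer_gene_class(reg)
  tgt_class <- infer_gene_class(tgt)
  want <- if (edge_class == "lnc_mi") c("lncRNA", "miRNA") else c("miRNA", "mRNA")
  bad <- which(reg_class != want[1] | tgt_class != want[2])
  if (length(bad) > 0) {
    stopf("interaction_table: edge '%s' -> '%s' inconsistent with class %s",
          reg[bad[1]], tgt[bad[1]], edge_class)
  }
  keep <- !duplicated(paste(reg, tgt))
  structure(list(edges = data.frame(regulator_id = reg[keep],
                                    target_id = tgt[keep],
                                    stringsAsFactors = FALSE),
                 edge_class = edge_class,
                 source_db = source_db),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("interaction_table [%s] %s: %d edges\n", x$edge_class,
              x$source_db, nrow(x$edges)))
  invisible(x)
}

#' Read an interaction table from TSV
#'
#' Expects columns `source_id` (or `regulator_id`), `target_id` and
#' optionally `source_db`.
#'
#' @param path TSV file.
#' @param edge_class `"lnc_mi"` or `"mi_mrna"`.
#' @param source_db override for the source label; default uses the file's
#'   `source_db` column (must be constant) or the file name.
#' @return `interaction_table`.
#' @export
read_interaction_tsv <- function(path, edge_class, source_db = NULL) {
  if (!file.exists(path)) {
    stopf("read_interaction_tsv: file '%s' not found", path)
  }
  df <- read_tsv(path)
  if (is.null(source_db)) {
    source_db <- if ("source_db" %in% names(df) && nrow(df) > 0) {
      unique(df$source_db)[1]
    } else {
      sub("\\.tsv$", "", basename(path))
    }
  }
  interaction_table(df, edge_class = edge_class, source_db = source_db)
}

#' Write an interaction table to TSV
#' @param tab `interaction_table`.
#' @param path output path.
#' @param seed,config_hash optional provenance fields.
#' @export
write_interaction_tsv <- function(tab, path, seed = NULL, config_hash = NULL) {
  df <- data.frame(source_id = tab$edges$regulator_id,
                   target_id = tab$edges$target_id,
                   source_db = tab$source_db, stringsAsFactors = FALSE)
  write_tsv(df, path, seed = seed, config_hash = config_hash)
}

#' Screen differentially expressed lncRNAs for ligand co-expression
#'
#' Retains the lncRNAs whose Spearman correlation with a ligand mRNA (e.g.
#' CD274 / PDCD1LG2) exceeds `rho_min` with `p < p_max`. The correlation is
#' computed on tumor samples by default, on the analysis (log2cpm) scale.
#' P-values here are deliberately raw, not BH-adjusted.
#'
#' @param expr `expr_matrix` (log2cpm).
#' @param de_lncs character vector of candidate lncRNA ids.
#' @param ligand id of the ligand gene; must be in the matrix.
#' @param rho_min,p_max strict screening thresholds (rho > rho_min, p <
#'   p_max).
#' @param samples `"tumor"` (default) or `"all"`.
#' @return data.frame (`gene_id`, `rho`, `p`, `n`) of the retained
#'   lncRNAs, sorted by id; the unfiltered screen is in attribute `"all"`.
#' @export
ligand_correlated_lncs <- function(expr, de_lncs, ligand, rho_min = 0.4,
                                   p_max = 0.001,
                                   samples = c("tumor", "all")) {
  samples <- match.arg(samples)
  stopifnot(inherits(expr, "expr_matrix"))
  rows <- stats::setNames(rownames(expr$values),
                          normalize_gene_ids(rownames(expr$values)))
  ligand_n <- normalize_gene_ids(ligand)
  if (!ligand_n %in% names(rows)) {
    stopf("ligand_correlated_lncs: ligand '%s' absent from matrix", ligand)
  }
  de_n <- normalize_gene_ids(de_lncs)
  missing <- setdiff(de_n, names(rows))
  if (length(missing) > 0) {
    stopf("ligand_correlated_lncs: candidate '%s' absent from matrix",
          missing[1])
  }
  v <- expr$values
  if (samples == "tumor") v <- v[, tumor_samples(expr), drop = FALSE]
  y <- v[rows[ligand_n], ]
  de_n <- sort(de_n)
  res <- lapply(de_n, function(g) {
    cr <- spearman(v[rows[g], ], y)
    data.frame(gene_id = g, rho = cr$rho, p = cr$p, n = cr$n,
               stringsAsFactors = FALSE)
  })
  all_res <- do.call(rbind, res)
  keep <- !is.na(all_res$rho) & all_res$rho > rho_min & all_res$p < p_max
  out <- all_res[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- all_res
  out
}

#' Intersect two gene sets
#'
#' Exact set intersection after identifier normalization; output is sorted
#' for determinism.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return sorted character vector.
#' @export
#' @examples
#' intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D"))
intersect_gene_sets <- function(set_a, set_b) {
  sort(intersect(normalize_gene_ids(set_a), normalize_gene_ids(set_b)))
}

#' Intersect interaction prediction sources
#'
#' Keeps only the edges present in every source table; the combined source
#' label records all contributing databases. All tables must share the same
#' edge class.
#'
#' @param tables list of `interaction_table` objects.
#' @return `interaction_table` of the shared edges.
#' @export
intersect_interaction_sources <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "interaction_table")))
  classes <- unique(vapply(tables, `[[`, "", "edge_class"))
  if (length(classes) != 1) {
    stopf("intersect_interaction_sources: mixed edge_class (%s)",
          paste(classes, collapse = ", "))
  }
  keys <- lapply(tables, function(t) paste(t$edges$regulator_id,
                                           t$edges$target_id, sep = "\t"))
  shared <- sort(Reduce(intersect, keys))
  parts <- strsplit(shared, "\t", fixed = TRUE)
  edges <- data.frame(
    regulator_id = vapply(parts, `[`, "", 1L),
    target_id = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  if (length(shared) == 0) edges <- edges[0, ]
  interaction_table(edges, edge_class = classes,
                    source_db = paste(vapply(tables, `[[`, "", "source_db"),
                                      collapse = "+"))
}

#' Assemble co-expressed competing triplets
#'
#' The core screening rule: a lncRNA-mRNA pair is a target pair when its
#' Spearman correlation exceeds `rho_pos_min` with `p < p_max`; for every
#' miRNA predicted to bind both members (edges present in the supplied,
#' typically source-intersected, tables), a triplet is emitted when both the
#' lncRNA and the mRNA are negatively correlated with that miRNA
#' (`rho < 0`, `p < neg_p_max`). All correlations are computed on tumor
#' samples by default.
#'
#' @param expr `expr_matrix` (log2cpm).
#' @param candidate_lncs lncRNA candidates (e.g. the DE screen survivors).
#' @param lnc_mi `interaction_table` of lncRNA -> miRNA predictions.
#' @param mi_mrna `interaction_table` of miRNA -> mRNA predictions.
#' @param targets mRNA targets to consider; default: every target in
#'   `mi_mrna`.
#' @param rho_pos_min,p_max positive-pair thresholds (strict).
#' @param neg_p_max p threshold for the two negative correlations.
#' @param samples `"tumor"` (default) or `"all"`.
#' @return data.frame of class `cerna_triplets`, one row per
#'   (lncRNA, miRNA, mRNA) triplet with all three correlations, p-values
#'   and supporting sources; sorted by the triplet key.
#' @export
assemble_triplets <- function(expr, candidate_lncs, lnc_mi, mi_mrna,
                              targets = NULL, rho_pos_min = 0.5,
                              p_max = 0.001, neg_p_max = 0.05,
                              samples = c("tumor", "all")) {
  samples <- match.arg(samples)
  stopifnot(inherits(expr, "expr_matrix"),
            inherits(lnc_mi, "interaction_table"),
            inherits(mi_mrna, "interaction_table"))
  if (lnc_mi$edge_class != "lnc_mi" || mi_mrna$edge_class != "mi_mrna") {
    stopf("assemble_triplets: interaction tables have wrong edge classes")
  }
  rows <- stats::setNames(rownames(expr$values),
                          normalize_gene_ids(rownames(expr$values)))
  v <- expr$values
  if (samples == "tumor") v <- v[, tumor_samples(expr), drop = FALSE]

  lncs <- sort(unique(normalize_gene_ids(candidate_lncs)))
  miss_lnc <- setdiff(lncs, names(rows))
  if (length(miss_lnc) > 0) {
    warnf("assemble_triplets: %d candidate lncRNA(s) absent from matrix (e.g. '%s'), skipped",
          length(miss_lnc), miss_lnc[1])
    lncs <- setdiff(lncs, miss_lnc)
  }
  if (is.null(targets)) targets <- unique(mi_mrna$edges$target_id)
  targets <- sort(unique(normalize_gene_ids(targets)))
  miss_t <- setdiff(targets, names(rows))
  if (length(miss_t) > 0) {
    warnf("assemble_triplets: %d target gene(s) absent from matrix (e.g. '%s'), skipped",
          length(miss_t), miss_t[1])
    targets <- setdiff(targets, miss_t)
  }

  # precompute rank transforms once per used gene
  ranks <- new.env(parent = emptyenv())
  get_ranks <- function(g) {
    if (is.null(ranks[[g]])) ranks[[g]] <- v[rows[g], ]
    ranks[[g]]
  }

  out <- list()
  for (lnc in lncs) {
    mis_of_lnc <- lnc_mi$edges$target_id[lnc_mi$edges$regulator_id == lnc]
    if (length(mis_of_lnc) == 0) next
    for (mrna in targets) {
      pos <- spearman(get_ranks(lnc), get_ranks(mrna))
      if (is.na(pos$rho) || !(pos$rho > rho_pos_min && pos$p < p_max)) next
      mis <- intersect(mis_of_lnc,
                       mi_mrna$edges$regulator_id[mi_mrna$edges$target_id == mrna])
      mis <- sort(intersect(mis, names(rows)))
      for (mi in mis) {
        c_lm <- spearman(get_ranks(lnc), get_ranks(mi))
        if (is.na(c_lm$rho) || !(c_lm$rho < 0 && c_lm$p < neg_p_max)) next
        c_mm <- spearman(get_ranks(mi), get_ranks(mrna))
        if (is.na(c_mm$rho) || !(c_mm$rho < 0 && c_mm$p < neg_p_max)) next
        out[[length(out) + 1L]] <- data.frame(
          lnc_id = lnc, mi_id = mi, mrna_id = mrna,
          rho_lnc_mrna = pos$rho, p_lnc_mrna = pos$p,
          rho_lnc_mi = c_lm$rho, p_lnc_mi = c_lm$p,
          rho_mi_mrna = c_mm$rho, p_mi_mrna = c_mm$p,
          sources_lnc_mi = lnc_mi$source_db,
          sources_mi_mrna = mi_mrna$source_db,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out) == 0) {
    data.frame(lnc_id = character(), mi_id = character(),
               mrna_id = character(), rho_lnc_mrna = numeric(),
               p_lnc_mrna = numeric(), rho_lnc_mi = numeric(),
               p_lnc_mi = numeric(), rho_mi_mrna = numeric(),
               p_mi_mrna = numeric(), sources_lnc_mi = character(),
               sources_mi_mrna = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
  res <- res[order(res$lnc_id, res$mi_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cerna_triplets", "data.frame")
  res
}

#' Rank candidate hub lncRNAs by mean ligand correlation
#'
#' Candidates are ordered by the mean of their Spearman correlations with
#' the two ligand mRNAs, descending; ties are broken lexicographically by
#' gene id. Every candidate must appear in both correlation tables.
#'
#' @param candidates character vector of lncRNA ids.
#' @param cor_a,cor_b data.frames with `gene_id` and `rho` (e.g. the
#'   `"all"` attribute of [ligand_correlated_lncs()]), one per ligand.
#' @return data.frame sorted by `mean_rho` descending with columns
#'   `gene_id`, `rho_a`, `rho_b`, `mean_rho`, `rank`.
#' @export
rank_hub_lnc <- function(candidates, cor_a, cor_b) {
  cand <- normalize_gene_ids(candidates)
  ia <- match(cand, normalize_gene_ids(cor_a$gene_id))
  ib <- match(cand, normalize_gene_ids(cor_b$gene_id))
  if (anyNA(ia) || anyNA(ib)) {
    miss <- cand[is.na(ia) | is.na(ib)][1]
    stopf("rank_hub_lnc: candidate '%s' missing a ligand correlation", miss)
  }
  df <- data.frame(gene_id = cand, rho_a = cor_a$rho[ia],
                   rho_b = cor_b$rho[ib], stringsAsFactors = FALSE)
  df$mean_rho <- (df$rho_a + df$rho_b) / 2
  df <- df[order(-df$mean_rho, df$gene_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Export a triplet network as SIF and GraphML
#'
#' Writes the lncRNA-miRNA-mRNA network in Cytoscape's SIF dialect (one
#' `lnc sponge miRNA` or `miRNA targets mRNA` line per unique edge) and as
#' GraphML with node `class` and edge `rho` attributes. Node and edge order
#' is deterministic (sorted). An empty triplet table yields an empty SIF
#' and a valid empty GraphML.
#'
#' @param triplets data.frame from [assemble_triplets()].
#' @param sif_path,graphml_path output paths (`NULL` skips that format).
#' @return invisibly, a list with the node and edge tables.
#' @export
export_network <- function(triplets, sif_path = NULL, graphml_path = NULL) {
  edges <- if (nrow(triplets) == 0) {
    data.frame(from = character(), interaction = character(),
               to = character(), rho = numeric(), stringsAsFactors = FALSE)
  } else {
    rbind(
      unique(data.frame(from = triplets$lnc_id, interaction = "sponge",
                        to = triplets$mi_id, rho = triplets$rho_lnc_mi,
                        stringsAsFactors = FALSE)),
      unique(data.frame(from = triplets$mi_id, interaction = "targets",
                        to = triplets$mrna_id, rho = triplets$rho_mi_mrna,
                        stringsAsFactors = FALSE))
    )
  }
  edges <- edges[!duplicated(edges[, c("from", "interaction", "to")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(triplets$lnc_id, triplets$mi_id,
                            triplets$mrna_id)))
  nodes <- data.frame(id = node_ids, class = infer_gene_class(node_ids),
                      stringsAsFactors = FALSE)
  if (!is.null(sif_path)) {
    writeLines(if (nrow(edges)) paste(edges$from, edges$interaction,
                                      edges$to, sep = "\t") else character(),
               sif_path)
  }
  if (!is.null(graphml_path)) {
    g <- if (nrow(nodes) == 0) {
      igraph::make_empty_graph(directed = TRUE)
    } else {
      igraph::graph_from_data_frame(
        edges[, c("from", "to", "interaction", "rho")],
        directed = TRUE, vertices = nodes)
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(list(nodes = nodes, edges = edges))
}

#' Write the triplet table to TSV
#' @param triplets data.frame from [assemble_triplets()].
#' @param path output path.
#' @param seed,config_hash optional provenance fields.
#' @export
write_triplets_tsv <- function(triplets, path, seed = NULL,
                               config_hash = NULL) {
  write_tsv(as.data.frame(triplets), path, seed = seed,
            config_hash = config_hash)
}
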