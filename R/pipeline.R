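#' Pipeline configuration
#'
#' Collects the input file paths, every stage threshold and the seed for
#' an end-to-end run. Unknown keys and out-of-range thresholds are
#' rejected.
#'
#' @param expression expression TSV (genes x samples, counts, condition
#'   row).
#' @param clinical clinical TSV (`sample_id`, `time`, `event`,
#'   covariates).
#' @param lnc_mi two lncRNA->miRNA interaction TSVs (one per prediction
#'   source).
#' @param mi_mrna two miRNA->mRNA interaction TSVs.
#' @param fractions immune cell-fraction TSV (cell types x samples),
#'   optional.
#' @param gmt gene-set GMT file, optional.
#' @param ligands ids of the two ligand mRNAs (e.g. `CD274`,
#'   `PDCD1LG2`).
#' @param out_dir output directory.
#' @param lfc_threshold,p_threshold DE screen thresholds.
#' @param rho_min,p_max ligand-correlation screen thresholds.
#' @param rho_pos_min,neg_p_max triplet assembly thresholds.
#' @param univ_p_enter univariate Cox entry threshold.
#' @param n_perm,weight GSEA settings.
#' @param pseudocount signature-score pseudocount.
#' @param seed integer seed used by every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical = NULL, lnc_mi,
                            mi_mrna, fractions = NULL, gmt = NULL,
                            ligands, out_dir, lfc_threshold = 1,
                            p_threshold = 0.05, rho_min = 0.4,
                            p_max = 0.001, rho_pos_min = 0.5,
                            neg_p_max = 0.05, univ_p_enter = 0.05,
                            n_perm = 1000, weight = 1, pseudocount = 1,
                            seed = 1) {
  cfg <- list(expression = expression, clinical = clinical,
              lnc_mi = lnc_mi, mi_mrna = mi_mrna, fractions = fractions,
              gmt = gmt, ligands = normalize_gene_ids(ligands),
              out_dir = out_dir, lfc_threshold = lfc_threshold,
              p_threshold = p_threshold, rho_min = rho_min, p_max = p_max,
              rho_pos_min = rho_pos_min, neg_p_max = neg_p_max,
              univ_p_enter = univ_p_enter, n_perm = n_perm,
              weight = weight, pseudocount = pseudocount, seed = seed)
  if (length(cfg$ligands) != 2) {
    stopf("pipeline_config: exactly two ligands required")
  }
  if (length(cfg$lnc_mi) != 2 || length(cfg$mi_mrna) != 2) {
    stopf("pipeline_config: two interaction files per edge class required")
  }
  probs <- c("p_threshold", "p_max", "neg_p_max", "univ_p_enter")
  for (k in probs) {
    if (!(cfg[[k]] > 0 && cfg[[k]] <= 1)) {
      stopf("pipeline_config: %s must be in (0, 1]", k)
    }
  }
  if (!(cfg$rho_min >= -1 && cfg$rho_min <= 1) ||
      !(cfg$rho_pos_min >= -1 && cfg$rho_pos_min <= 1)) {
    stopf("pipeline_config: correlation thresholds must be in [-1, 1]")
  }
  if (cfg$lfc_threshold < 0) stopf("pipeline_config: lfc_threshold must be >= 0")
  if (cfg$n_perm < 100) stopf("pipeline_config: n_perm must be >= 100")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Build a pipeline configuration from a named list
#'
#' Validating counterpart for configurations read from JSON/YAML-style
#' files: unknown keys are an error.
#'
#' @param x named list of [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
pipeline_config_from_list <- function(x) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stopf("pipeline_config: unknown key '%s'", unknown[1])
  }
  do.call(pipeline_config, x)
}

config_hash <- function(config) {
  # out_dir does not affect the analysis and must not perturb reruns
  cfg <- config[setdiff(names(config), "out_dir")]
  flat <- vapply(cfg, function(v) paste(format(v, digits = 15),
                                        collapse = ","), "")
  string_fingerprint(paste(names(cfg), flat, sep = "=", collapse = ";"))
}

#' Run the full screening pipeline
#'
#' Executes, in order: log2(CPM+1) normalization; the lncRNA
#' differential-expression screen; the ligand-correlation screens for both
#' ligands and their intersection; prediction-source intersection; triplet
#' assembly over all differentially expressed lncRNAs; hub ranking of the
#' ligand-intersected candidates; median-split survival screening
#' (Kaplan-Meier, log-rank, univariate-to-multivariate Cox) when a
#' clinical table is supplied; preranked GSEA between hub-high and
#' hub-low tumors plus geometric-mean signature scoring when a GMT is
#' supplied; and clinical/immune-fraction association tests when fractions
#' are supplied. Every stage's table is written to the output directory
#' with a provenance header (package version, config hash, seed), and the
#' resolved configuration is written as `config.json`. A rerun with the
#' same configuration and seed produces byte-identical outputs.
#'
#' @param config `pipeline_config`.
#' @return invisibly, a named list with every stage's in-memory result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  chash <- config_hash(config)
  seed <- config$seed
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  res <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  counts <- stage("read_expression", {
    if (!file.exists(config$expression)) {
      stopf("expression file '%s' not found", config$expression)
    }
    read_expression_tsv(config$expression, scale = "counts")
  })
  expr <- stage("normalize", cpm_log_normalize(counts))
  res$expr <- expr

  lnc_ids <- names(expr$gene_class[expr$gene_class == "lncRNA"])
  de <- stage("differential_expression",
              differential_expression(expr, genes = lnc_ids,
                                      lfc_threshold = config$lfc_threshold,
                                      p_threshold = config$p_threshold))
  de_sets <- filter_de(de, config$lfc_threshold, config$p_threshold)
  de_lncs <- sort(c(de_sets$up, de_sets$down))
  res$de <- de
  res$de_lncs <- de_lncs
  write_de_tsv(de, file.path(out, "de_lncRNA.tsv"), seed = seed,
               config_hash = chash)

  lig <- config$ligands
  scr_a <- stage("ligand_screen",
                 ligand_correlated_lncs(expr, de_lncs, lig[1],
                                        rho_min = config$rho_min,
                                        p_max = config$p_max))
  scr_b <- stage("ligand_screen",
                 ligand_correlated_lncs(expr, de_lncs, lig[2],
                                        rho_min = config$rho_min,
                                        p_max = config$p_max))
  candidates <- intersect_gene_sets(scr_a$gene_id, scr_b$gene_id)
  res$ligand_screens <- list(scr_a, scr_b)
  res$candidates <- candidates
  write_tsv(data.frame(gene_id = candidates),
            file.path(out, "ligand_intersect.tsv"), seed = seed,
            config_hash = chash)

  lnc_mi <- stage("interactions", intersect_interaction_sources(
    lapply(config$lnc_mi, read_interaction_tsv, edge_class = "lnc_mi")))
  mi_mrna <- stage("interactions", intersect_interaction_sources(
    lapply(config$mi_mrna, read_interaction_tsv, edge_class = "mi_mrna")))
  res$lnc_mi <- lnc_mi
  res$mi_mrna <- mi_mrna

  triplets <- stage("assemble_triplets", suppressWarnings(
    assemble_triplets(expr, de_lncs, lnc_mi, mi_mrna,
                      rho_pos_min = config$rho_pos_min,
                      p_max = config$p_max,
                      neg_p_max = config$neg_p_max)))
  res$triplets <- triplets
  write_triplets_tsv(triplets, file.path(out, "triplets.tsv"), seed = seed,
                     config_hash = chash)
  export_network(triplets, sif_path = file.path(out, "network.sif"),
                 graphml_path = file.path(out, "network.graphml"))

  hub_rank <- if (length(candidates) > 0) {
    rank_hub_lnc(candidates, attr(scr_a, "all"), attr(scr_b, "all"))
  } else {
    data.frame(gene_id = character(), rho_a = numeric(), rho_b = numeric(),
               mean_rho = numeric(), rank = integer())
  }
  res$hub_rank <- hub_rank
  write_tsv(hub_rank, file.path(out, "hub_ranking.tsv"), seed = seed,
            config_hash = chash)
  hub <- if (nrow(hub_rank) > 0) hub_rank$gene_id[1] else NULL
  res$hub <- hub

  hub_expr <- if (!is.null(hub)) {
    rows <- stats::setNames(rownames(expr$values),
                            normalize_gene_ids(rownames(expr$values)))
    expr$values[rows[hub], tumor_samples(expr)]
  } else {
    NULL
  }

  if (!is.null(config$clinical) && !is.null(hub)) {
    clin <- stage("survival", {
      if (!file.exists(config$clinical)) {
        stopf("clinical file '%s' not found", config$clinical)
      }
      read_tsv(config$clinical)
    })
    shared <- intersect(clin$sample_id, names(hub_expr))
    clin <- clin[match(shared, clin$sample_id), , drop = FALSE]
    grp <- median_split(hub_expr[shared])
    clin$expression_group <- grp
    res$logrank <- stage("survival",
                         logrank_test(clin$time, clin$event, grp))
    km <- do.call(rbind, lapply(levels(grp), function(g) {
      sub <- clin[grp == g, ]
      cbind(group = g, kaplan_meier(sub$time, sub$event))
    }))
    res$km <- km
    write_tsv(km, file.path(out, "km_curves.tsv"), seed = seed,
              config_hash = chash)
    covs <- intersect(c("expression_group", "age", "sex", "stage", "grade",
                        "t_stage", "n_stage", "m_stage", "msi", "ebv"),
                      names(clin))
    for (cv in covs) {
      if (is.character(clin[[cv]])) clin[[cv]] <- factor(clin[[cv]])
    }
    res$cox <- stage("survival",
                     cox_screen(clin, covs,
                                univ_p_enter = config$univ_p_enter))
    write_cox_tsv(res$cox, file.path(out, "cox_univariate.tsv"),
                  file.path(out, "cox_multivariate.tsv"), seed = seed,
                  config_hash = chash)
    res$clinical <- clin
  }

  if (!is.null(config$gmt) && !is.null(hub)) {
    sets <- stage("enrichment", read_gmt(config$gmt))
    grp_all <- median_split(hub_expr)
    mrna_ids <- names(expr$gene_class[expr$gene_class == "mRNA"])
    # tumor-only high-vs-low comparison, reusing the moderated-t machinery
    tum_expr <- expr_subset_samples(expr, tumor_samples(expr))
    tum_expr$condition[] <- ifelse(grp_all[colnames(tum_expr$values)] ==
                                     "high", "tumor", "normal")
    de_mrna <- stage("enrichment",
                     differential_expression(tum_expr, genes = mrna_ids))
    ranked <- rank_by_log2fc(de_mrna)
    res$gsea <- stage("enrichment",
                      gsea_batch(ranked, sets, n_perm = config$n_perm,
                                 weight = config$weight, seed = seed))
    write_tsv(res$gsea, file.path(out, "gsea.tsv"), seed = seed,
              config_hash = chash)
    scores <- stage("enrichment",
                    signature_score_geomean(counts, sets[[1]],
                                            pseudocount = config$pseudocount))
    res$signature_scores <- scores
    res$score_cor <- score_correlation(scores, stats::setNames(
      as.numeric(hub_expr), names(hub_expr)))
    write_tsv(data.frame(sample_id = names(scores),
                         score = as.numeric(scores)),
              file.path(out, "signature_scores.tsv"), seed = seed,
              config_hash = chash)
  }

  if (!is.null(config$fractions) && !is.null(hub)) {
    fr <- stage("fractions", {
      df <- read_tsv(config$fractions)
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- df[[1]]
      m
    })
    grp_all <- median_split(hub_expr)
    res$fraction_compare <- stage("fractions",
                                  fraction_group_compare(fr, grp_all))
    res$fraction_cor <- stage("fractions",
                              fraction_expression_correlation(fr, hub_expr))
    write_tsv(res$fraction_compare, file.path(out, "fraction_compare.tsv"),
              seed = seed, config_hash = chash)
    write_tsv(res$fraction_cor, file.path(out, "fraction_correlation.tsv"),
              seed = seed, config_hash = chash)
  }

  cfg_out <- config
  class(cfg_out) <- NULL
  jsonlite::write_json(c(cfg_out, list(config_hash = chash)),
                       file.path(out, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(res)
}
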