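toy_matrix <- function() {
  # 6 tumor samples; lnc1 tracks the ligand, lnc2 anti-tracks it
  v <- rbind(
    LNC0001 = c(1, 2, 3, 4, 5, 6),
    LNC0002 = c(6, 5, 4, 3, 2, 1),
    MIR0001 = c(6, 5, 4, 3, 2, 1),
    MR0001  = c(1.1, 2.2, 2.9, 4.3, 5.1, 6.2)
  )
  colnames(v) <- sprintf("T%02d", 1:6)
  expr_matrix(v, condition = rep("tumor", 6), scale = "log2cpm")
}

test_that("identifier normalization strips versions and upper-cases", {
  expect_equal(normalize_gene_ids("ENSG00000245532.8"), "ENSG00000245532")
  expect_equal(normalize_gene_ids("linc01094"), "LINC01094")
  expect_equal(infer_gene_class(c("LINC01094", "hsa-miR-17-5p", "CD274")),
               c("lncRNA", "miRNA", "mRNA"))
})

test_that("ligand screen keeps monotone partners and drops anti-monotone ones", {
  expr <- toy_matrix()
  res <- ligand_correlated_lncs(expr, c("LNC0001", "LNC0002"), "MR0001",
                                rho_min = 0.4, p_max = 0.05)
  expect_equal(res$gene_id, "LNC0001")
  expect_equal(res$rho, 1)
  all_res <- attr(res, "all")
  expect_equal(nrow(all_res), 2)
  expect_lt(all_res$rho[all_res$gene_id == "LNC0002"], 0)
  expect_error(ligand_correlated_lncs(expr, "LNC0001", "ABSENT"), "ABSENT")
})

test_that("gene-set intersection is exact, sorted and dialect-insensitive", {
  expect_equal(intersect_gene_sets(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(intersect_gene_sets(c("A"), c("B")), character())
  expect_equal(intersect_gene_sets(c("linc01094.4"), c("LINC01094")),
               "LINC01094")
})

test_that("source intersection keeps shared edges only and records all dbs", {
  t1 <- interaction_table(
    data.frame(regulator_id = c("MIR0001", "MIR0002"),
               target_id = c("MR0001", "MR0002")),
    edge_class = "mi_mrna", source_db = "targetscan")
  t2 <- interaction_table(
    data.frame(regulator_id = c("MIR0001", "MIR0003"),
               target_id = c("MR0001", "MR0003")),
    edge_class = "mi_mrna", source_db = "mirdb")
  out <- intersect_interaction_sources(list(t1, t2))
  expect_equal(nrow(out$edges), 1)
  expect_equal(out$edges$regulator_id, "MIR0001")
  expect_equal(out$source_db, "targetscan+mirdb")
  # identical tables pass through unchanged
  same <- intersect_interaction_sources(list(t1, t1))
  expect_equal(same$edges, t1$edges)
  # an empty table empties the intersection
  t0 <- interaction_table(data.frame(regulator_id = character(),
                                     target_id = character()),
                          edge_class = "mi_mrna", source_db = "empty")
  expect_equal(nrow(intersect_interaction_sources(list(t1, t0))$edges), 0)
  # mixed edge classes are a named error
  tl <- interaction_table(data.frame(regulator_id = "LNC0001",
                                     target_id = "MIR0001"),
                          edge_class = "lnc_mi", source_db = "mircode")
  expect_error(intersect_interaction_sources(list(t1, tl)), "mixed")
})

test_that("interaction_table validates endpoint classes and self-edges", {
  expect_error(interaction_table(
    data.frame(regulator_id = "MR0001", target_id = "MIR0001"),
    edge_class = "lnc_mi", source_db = "x"), "inconsistent")
  expect_error(interaction_table(
    data.frame(regulator_id = "MIR0001", target_id = "MIR0001"),
    edge_class = "mi_mrna", source_db = "x"), "self-edge")
})

test_that("triplet assembly enforces the sign rules on a perfect-rank toy", {
  v <- rbind(LNC0001 = 1:5, MIR0001 = 5:1, MR0001 = 1:5)
  colnames(v) <- sprintf("T%02d", 1:5)
  expr <- expr_matrix(v, condition = rep("tumor", 5), scale = "log2cpm")
  lnc_mi <- interaction_table(
    data.frame(regulator_id = "LNC0001", target_id = "MIR0001"),
    edge_class = "lnc_mi", source_db = "mircode")
  mi_mrna <- interaction_table(
    data.frame(regulator_id = "MIR0001", target_id = "MR0001"),
    edge_class = "mi_mrna", source_db = "targetscan")
  tr <- assemble_triplets(expr, "LNC0001", lnc_mi, mi_mrna,
                          rho_pos_min = 0.5, p_max = 1, neg_p_max = 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$rho_lnc_mrna, 1)
  expect_equal(tr$rho_lnc_mi, -1)
  expect_equal(tr$rho_mi_mrna, -1)
  # positively co-expressed miRNA violates the sign rule: no triplet
  v2 <- v; v2["MIR0001", ] <- 1:5
  expr2 <- expr_matrix(v2, condition = rep("tumor", 5), scale = "log2cpm")
  tr2 <- assemble_triplets(expr2, "LNC0001", lnc_mi, mi_mrna,
                           rho_pos_min = 0.5, p_max = 1, neg_p_max = 1)
  expect_equal(nrow(tr2), 0)
  # absent target is a warning, not a failure
  mi_mrna2 <- interaction_table(
    data.frame(regulator_id = c("MIR0001", "MIR0001"),
               target_id = c("MR0001", "MR0099")),
    edge_class = "mi_mrna", source_db = "targetscan")
  expect_warning(
    tr3 <- assemble_triplets(expr, "LNC0001", lnc_mi, mi_mrna2,
                             rho_pos_min = 0.5, p_max = 1, neg_p_max = 1),
    "absent")
  expect_equal(nrow(tr3), 1)
})

test_that("emitted triplets re-validate against the raw matrix and thresholds are monotone", {
  cfg <- sim_config(n_tumor = 80, n_normal = 20, n_lnc = 60, n_mi = 25,
                    n_mrna = 50, n_triplets = 5, fp_edges = 100, seed = 31)
  sim <- simulate_expression(cfg)
  expr <- cpm_log_normalize(sim$expr)
  tabs <- simulate_interaction_tables(sim$truth, cfg)
  lnc_mi <- intersect_interaction_sources(tabs$lnc_mi)
  mi_mrna <- intersect_interaction_sources(tabs$mi_mrna)
  cands <- unique(sim$truth$planted_triplets$lnc_id)
  tr <- assemble_triplets(expr, cands, lnc_mi, mi_mrna)
  expect_gt(nrow(tr), 0)
  tum <- expr$values[, tumor_samples(expr)]
  for (i in seq_len(nrow(tr))) {
    # independent re-check of all three rules straight from the matrix
    r1 <- cor.test(tum[tr$lnc_id[i], ], tum[tr$mrna_id[i], ],
                   method = "spearman", exact = FALSE)
    expect_gt(r1$estimate, 0.5)
    expect_lt(r1$p.value, 0.001)
    expect_lt(cor(tum[tr$lnc_id[i], ], tum[tr$mi_id[i], ],
                  method = "spearman"), 0)
    expect_lt(cor(tum[tr$mi_id[i], ], tum[tr$mrna_id[i], ],
                  method = "spearman"), 0)
    expect_true(paste(tr$lnc_id[i], tr$mi_id[i]) %in%
                  paste(lnc_mi$edges$regulator_id, lnc_mi$edges$target_id))
    expect_true(paste(tr$mi_id[i], tr$mrna_id[i]) %in%
                  paste(mi_mrna$edges$regulator_id, mi_mrna$edges$target_id))
  }
  # raising the positive threshold never adds triplets
  tr_strict <- assemble_triplets(expr, cands, lnc_mi, mi_mrna,
                                 rho_pos_min = 0.7)
  key <- function(d) paste(d$lnc_id, d$mi_id, d$mrna_id)
  expect_true(all(key(tr_strict) %in% key(tr)))
  # input order invariance
  tr_perm <- assemble_triplets(expr, rev(cands), lnc_mi, mi_mrna)
  expect_equal(key(tr_perm), key(tr))
})

test_that("hub ranking orders by mean ligand correlation with recorded tie-break", {
  cor_a <- data.frame(gene_id = c("X", "Y", "Z"), rho = c(0.58, 0.34, 0.44))
  cor_b <- data.frame(gene_id = c("X", "Y", "Z"), rho = c(0.51, 0.46, 0.51))
  r <- rank_hub_lnc(c("Y", "Z", "X"), cor_a, cor_b)
  expect_equal(r$gene_id[1], "X")
  expect_equal(r$rank, 1:3)
  # permuting input order leaves the ranking unchanged
  r2 <- rank_hub_lnc(c("X", "Y", "Z"), cor_a, cor_b)
  expect_equal(r$gene_id, r2$gene_id)
  # single candidate ranks itself
  expect_equal(rank_hub_lnc("Y", cor_a, cor_b)$gene_id, "Y")
  # ties break lexicographically
  cor_t <- data.frame(gene_id = c("B", "A"), rho = c(0.5, 0.5))
  expect_equal(rank_hub_lnc(c("B", "A"), cor_t, cor_t)$gene_id, c("A", "B"))
  expect_error(rank_hub_lnc("Q", cor_a, cor_b), "missing")
})

test_that("network export writes SIF and round-trips through GraphML", {
  dir <- withr::local_tempdir()
  tr <- data.frame(lnc_id = "LNC0001", mi_id = "MIR0001", mrna_id = "MR0001",
                   rho_lnc_mrna = 0.8, p_lnc_mrna = 1e-5,
                   rho_lnc_mi = -0.6, p_lnc_mi = 1e-3,
                   rho_mi_mrna = -0.5, p_mi_mrna = 1e-3,
                   sources_lnc_mi = "a+b", sources_mi_mrna = "c+d")
  sif <- file.path(dir, "net.sif"); gml <- file.path(dir, "net.graphml")
  net <- export_network(tr, sif, gml)
  expect_equal(length(readLines(sif)), 2)
  expect_equal(nrow(net$nodes), 3)
  g <- igraph::read_graph(gml, format = "graphml")
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]),
                  c("LNC0001 MIR0001", "MIR0001 MR0001"))
  expect_setequal(igraph::vertex_attr(g, "class"),
                  c("lncRNA", "miRNA", "mRNA"))
  # empty network: empty SIF, valid empty GraphML
  empty <- tr[0, ]
  export_network(empty, sif, gml)
  expect_equal(length(readLines(sif)), 0)
  g0 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g0), 0)
})

test_that("synthetic supplementary lists intersect to the expected 22 ids", {
  a <- readLines(system.file("extdata", "pdl1_correlated_lncRNAs_synthetic.txt",
                             package = "cernascreen"))
  b <- readLines(system.file("extdata", "pdl2_correlated_lncRNAs_synthetic.txt",
                             package = "cernascreen"))
  expect_length(a, 29)
  expect_length(b, 85)
  shared <- intersect_gene_sets(a, b)
  expect_length(shared, 22)
  expect_true(all(c("LINC01094", "LINC01272", "LINC00877", "PIK3CD-AS1",
                    "SIRPG-AS1") %in% shared))
})
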