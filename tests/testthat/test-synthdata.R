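test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_tumor = 0), "integer >= 1")
  expect_error(sim_config(sponge_strength = 1), "sponge_strength")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_triplets = 200, n_mi = 100), "smallest gene class")
  expect_error(sim_config(libsize_range = c(2e6, 5e5)), "libsize_range")
})

test_that("same seed gives identical output; planted ids exist in the matrix", {
  cfg <- sim_config(n_tumor = 30, n_normal = 10, n_lnc = 50, n_mi = 20,
                    n_mrna = 40, n_triplets = 4, seed = 7)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)
  genes <- rownames(a$expr$values)
  pt <- a$truth$planted_triplets
  expect_true(all(unlist(pt) %in% genes))
  expect_true(all(a$truth$de_genes$gene_id %in% genes))
  # gene classes carried by prefix
  expect_equal(unname(a$expr$gene_class[pt$lnc_id[1]]), "lncRNA")
  expect_equal(unname(a$expr$gene_class[pt$mi_id[1]]), "miRNA")
  expect_equal(unname(a$expr$gene_class[pt$mrna_id[1]]), "mRNA")
})

test_that("sponge correlation and fold change calibrate to the configured values", {
  cfg <- sim_config(seed = 5) # 200 tumor, sponge 0.8, de_lfc 2
  sim <- simulate_expression(cfg)
  expr <- cpm_log_normalize(sim$expr)
  tum <- expr$values[, expr$condition == "tumor"]
  pt <- sim$truth$planted_triplets
  for (i in seq_len(nrow(pt))) {
    r_lm <- spearman(tum[pt$lnc_id[i], ], tum[pt$mi_id[i], ])$rho
    r_mm <- spearman(tum[pt$mi_id[i], ], tum[pt$mrna_id[i], ])$rho
    expect_lt(abs(r_lm - (-0.8)), 0.1)
    expect_lt(abs(r_mm - (-0.8)), 0.1)
  }
  de <- sim$truth$de_genes$gene_id
  lfc <- rowMeans(expr$values[de, expr$condition == "tumor"]) -
    rowMeans(expr$values[de, expr$condition == "normal"])
  expect_lt(abs(mean(lfc) - 2), 0.3)
  # decoy genes carry no planted structure
  set.seed(1)
  decoys <- sample(setdiff(rownames(tum), unlist(pt)), 40)
  rhos <- sapply(seq_len(20), function(i) {
    spearman(tum[decoys[2 * i - 1], ], tum[decoys[2 * i], ])$rho
  })
  # null sd of Spearman is ~1/sqrt(n-1) = 0.071 at n = 200
  expect_lt(max(abs(rhos)), 4 / sqrt(199))
})

test_that("interaction tables contain planted edges in all sources plus decoys", {
  cfg0 <- sim_config(n_tumor = 20, n_normal = 10, n_lnc = 50, n_mi = 20,
                     n_mrna = 40, n_triplets = 4, fp_edges = 0, seed = 2)
  sim <- simulate_expression(cfg0)
  tabs <- simulate_interaction_tables(sim$truth, cfg0)
  pt <- sim$truth$planted_triplets
  planted_lm <- unique(paste(pt$lnc_id, pt$mi_id))
  # fp_edges = 0: tables contain exactly the planted edges
  for (t in tabs$lnc_mi) {
    expect_setequal(paste(t$edges$regulator_id, t$edges$target_id), planted_lm)
  }
  planted_mm <- unique(paste(pt$mi_id, pt$mrna_id))
  for (t in tabs$mi_mrna) {
    expect_setequal(paste(t$edges$regulator_id, t$edges$target_id), planted_mm)
  }
  # with decoys, the source intersection still contains every planted edge
  cfg1 <- sim_config(n_tumor = 20, n_normal = 10, n_lnc = 50, n_mi = 20,
                     n_mrna = 40, n_triplets = 4, fp_edges = 300, seed = 3)
  tabs1 <- simulate_interaction_tables(sim$truth, cfg1)
  inter <- intersect_interaction_sources(tabs1$mi_mrna)
  got <- paste(inter$edges$regulator_id, inter$edges$target_id)
  expect_true(all(planted_mm %in% got))
})

test_that("decoy overlap between two sources matches the birthday expectation", {
  # fp^2 / universe expected shared decoys, averaged over replicates
  cfg <- sim_config(n_tumor = 20, n_normal = 10, n_lnc = 100, n_mi = 50,
                    n_mrna = 200, n_triplets = 2, fp_edges = 1000, seed = 5)
  sim <- simulate_expression(cfg)
  universe <- cfg$n_mi * cfg$n_mrna
  expected <- 1000^2 / universe # = 100
  overlaps <- sapply(1:20, function(s) {
    cfg_s <- sim_config(n_tumor = 20, n_normal = 10, n_lnc = 100, n_mi = 50,
                        n_mrna = 200, n_triplets = 2, fp_edges = 1000,
                        seed = s)
    tabs <- simulate_interaction_tables(sim$truth, cfg_s)
    inter <- intersect_interaction_sources(tabs$mi_mrna)
    nrow(inter$edges) - nrow(unique(sim$truth$planted_triplets[, c("mi_id", "mrna_id")]))
  })
  expect_lt(abs(mean(overlaps) - expected), 0.25 * expected)
})

test_that("clinical simulation hits the censoring target and degenerates correctly", {
  cfg <- sim_config(n_tumor = 300, n_normal = 20, n_lnc = 30, n_mi = 10,
                    n_mrna = 20, n_triplets = 3, seed = 11)
  sim <- simulate_expression(cfg)
  clin <- simulate_clinical(sim$expr, sim$truth, cfg)
  expect_equal(nrow(clin), 300)
  expect_true(all(clin$time > 0))
  expect_true(all(clin$event %in% 0:1))
  expect_lt(abs(mean(1 - clin$event) - cfg$censor_rate), 0.08)
  # censor_rate = 0: every record is an event
  cfg0 <- sim_config(n_tumor = 100, n_normal = 20, n_lnc = 30, n_mi = 10,
                     n_mrna = 20, n_triplets = 3, censor_rate = 0, seed = 12)
  sim0 <- simulate_expression(cfg0)
  clin0 <- simulate_clinical(sim0$expr, sim0$truth, cfg0)
  expect_true(all(clin0$event == 1))
})

test_that("hazard coefficient is recoverable from simulated survival", {
  cfg <- sim_config(n_tumor = 400, n_normal = 20, n_lnc = 30, n_mi = 10,
                    n_mrna = 20, n_triplets = 3, censor_rate = 0.2, seed = 13)
  sim <- simulate_expression(cfg)
  betas <- sapply(1:20, function(i) {
    cfg_i <- cfg; cfg_i$seed <- cfg$seed + i
    clin <- simulate_clinical(sim$expr, sim$truth, cfg_i)
    clin$z <- as.numeric(scale(clin$expression))
    cox_fit(clin, "z")$table$beta
  })
  expect_lt(abs(mean(betas) - log(1.74)), 0.1)
})

test_that("fractions lie on the simplex with the configured hub coupling", {
  cfg <- sim_config(n_tumor = 375, n_normal = 25, n_lnc = 30, n_mi = 10,
                    n_mrna = 20, n_triplets = 3, seed = 17)
  sim <- simulate_expression(cfg)
  fr <- simulate_fractions(sim$expr, sim$truth, cfg)
  expect_equal(dim(fr), c(22, 400))
  expect_true(all(fr >= 0))
  expect_lt(max(abs(colSums(fr) - 1)), 1e-9)
  expr <- cpm_log_normalize(sim$expr)
  hub <- expr$values[sim$truth$hub_lnc, ]
  rho <- spearman(fr[sim$truth$coupled_celltype, names(hub)], hub)$rho
  expect_lt(abs(rho - 0.47), 0.1)
  # uncoupled generator: correlation CI covers zero
  cfg0 <- sim_config(n_tumor = 375, n_normal = 25, n_lnc = 30, n_mi = 10,
                     n_mrna = 20, n_triplets = 3, frac_coupling = 0,
                     seed = 18)
  fr0 <- simulate_fractions(sim$expr, sim$truth, cfg0)
  r0 <- spearman(fr0[sim$truth$coupled_celltype, names(hub)], hub)
  expect_gt(r0$p, 0.05 / 20) # no detectable coupling
})

test_that("the written bundle round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_tumor = 20, n_normal = 8, n_lnc = 40, n_mi = 15,
                    n_mrna = 30, n_triplets = 3, fp_edges = 20, seed = 23)
  bundle <- simulate_bundle(cfg, dir)
  expr2 <- read_expression_tsv(bundle$paths$expression, scale = "counts")
  expect_equal(expr2$values, bundle$expr$values)
  expect_equal(expr2$condition, bundle$expr$condition)
  tab <- read_interaction_tsv(bundle$paths$lnc_mi[1], edge_class = "lnc_mi")
  expect_equal(tab$edges, bundle$interactions$lnc_mi$mircode$edges)
  truth <- jsonlite::read_json(bundle$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$hub_lnc, bundle$truth$hub_lnc)
  sets <- read_gmt(bundle$paths$gmt)
  expect_equal(sets[[1]]$genes,
               sort(unique(bundle$truth$planted_triplets$mrna_id)))
})
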