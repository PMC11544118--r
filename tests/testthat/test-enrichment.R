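test_that("rank_by_log2fc orders by score with deterministic tie-breaks", {
  rec <- data.frame(gene_id = c("A", "B", "C"), log2fc = c(2, -1, 0.5))
  r <- rank_by_log2fc(rec)
  expect_equal(r$gene_ids, c("A", "C", "B"))
  # input order irrelevant
  r2 <- rank_by_log2fc(rec[c(3, 1, 2), ])
  expect_equal(r$gene_ids, r2$gene_ids)
  # ties break by gene id
  r3 <- rank_by_log2fc(data.frame(gene_id = c("B", "A"), log2fc = c(1, 1)))
  expect_equal(r3$gene_ids, c("A", "B"))
  expect_error(rank_by_log2fc(data.frame(gene_id = c("A", "A"),
                                         log2fc = c(1, 2))), "duplicate")
})

test_that("gsea_es reproduces hand running sums", {
  ranked <- make_ranked(c("g1", "g2", "g3", "g4"), c(3, 2, 1, 0))
  # set = top gene: hit adds 3/3 = 1 at position 1
  expect_equal(gsea_es(ranked, "g1")$es, 1)
  # set = bottom gene with score 0, weight 1: three misses of -1/3 reach
  # -1, the zero-weight hit adds nothing
  r <- gsea_es(ranked, "g4")
  expect_equal(r$running, c(-1 / 3, -2 / 3, -1, -1))
  expect_equal(r$es, -1)
  # appending zero-score genes outside the set changes es (documented
  # N-dependence of the miss decrement): 2/3 -> 4/5 for the set {g2}
  expect_equal(gsea_es(ranked, "g2")$es, 2 / 3)
  ranked6 <- make_ranked(c("g1", "g2", "g3", "g4", "g5", "g6"),
                         c(3, 2, 1, 0, 0, 0))
  expect_equal(gsea_es(ranked6, "g2")$es, 4 / 5)
  # degenerate sets are named errors
  expect_error(gsea_es(ranked, c("g1", "g2", "g3", "g4")), "covers")
  expect_error(gsea_es(ranked, "absent"), "no set member")
})

test_that("gsea_es equals the brute-force running-sum oracle on random fixtures", {
  set.seed(33)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    ids <- sprintf("G%03d", seq_len(n))
    scores <- round(rnorm(n), 2)
    ranked <- make_ranked(ids, scores)
    nh <- sample(seq_len(n - 1), 1)
    members <- sample(ids, nh)
    w <- sample(c(0, 1), 1)
    # agreement to double-precision rounding (the two implementations
    # accumulate in different internal precisions; magnitude ties may
    # resolve with opposite sign)
    expect_es_equal(gsea_es(ranked, members, weight = w)$es,
                    oracle_gsea_es(ranked$gene_ids, ranked$scores,
                                   members, weight = w))
  }
})

test_that("reversing the ranking negates the unweighted enrichment score", {
  set.seed(35)
  n <- 30
  ids <- sprintf("G%03d", 1:n)
  scores <- seq(3, -3, length.out = n)
  ranked <- make_ranked(ids, scores)
  rev_ranked <- structure(list(gene_ids = rev(ranked$gene_ids),
                               scores = rev(ranked$scores)),
                          class = "ranked_list")
  for (i in 1:10) {
    members <- sample(ids, 6)
    expect_equal(gsea_es(ranked, members, weight = 0)$es,
                 -gsea_es(rev_ranked, members, weight = 0)$es,
                 tolerance = 1e-12)
  }
})

test_that("permutation significance is seeded, powered, and sign-consistent", {
  set.seed(40)
  n <- 100
  ids <- sprintf("G%03d", 1:n)
  scores <- seq(4, -4, length.out = n)
  ranked <- make_ranked(ids, scores)
  planted <- ids[1:10] # top decile of a strong ranking
  r1 <- gsea_significance(ranked, planted, n_perm = 1000, seed = 5)
  r2 <- gsea_significance(ranked, planted, n_perm = 1000, seed = 5)
  expect_identical(r1[c("es", "nes", "p")], r2[c("es", "nes", "p")])
  expect_lte(r1$p, 0.01)
  expect_equal(sign(r1$nes), sign(r1$es))
  expect_true(all(r1$leading_edge %in% planted))
  # a bottom-of-list set is enriched with negative sign
  rneg <- gsea_significance(ranked, ids[91:100], n_perm = 500, seed = 6)
  expect_lt(rneg$es, 0)
  expect_lt(rneg$nes, 0)
  expect_error(gsea_significance(ranked, planted, n_perm = 50), "100")
})

test_that("gsea_batch adjusts across sets", {
  set.seed(44)
  n <- 80
  ids <- sprintf("G%03d", 1:n)
  ranked <- make_ranked(ids, seq(3, -3, length.out = n))
  sets <- list(TOP = ids[1:8], RANDOM = sample(ids, 8), RANDOM2 = sample(ids, 8))
  out <- gsea_batch(ranked, sets, n_perm = 300, seed = 2)
  expect_equal(nrow(out), 3)
  expect_equal(out$adj_p, bh_adjust(out$p))
  expect_lt(out$p[out$set == "TOP"], 0.05)
})

test_that("geometric-mean signature score: constant case, zero counts, symmetry, scaling", {
  m <- rbind(MR0001 = c(0, 7), MR0002 = c(3, 3))
  colnames(m) <- c("s1", "s2")
  expr <- expr_matrix(m, condition = c("tumor", "tumor"), scale = "counts")
  # one member, counts [0, 7], pseudocount 1 -> scores [1, 8]
  expect_equal(as.numeric(signature_score_geomean(expr, "MR0001")), c(1, 8))
  # constant counts c with pseudocount 1 -> c + 1; pseudocount 0 -> c
  expect_equal(as.numeric(signature_score_geomean(expr, "MR0002")), c(4, 4))
  expect_equal(as.numeric(signature_score_geomean(expr, "MR0002",
                                                  pseudocount = 0)),
               c(3, 3))
  # member order irrelevant
  s1 <- signature_score_geomean(expr, c("MR0001", "MR0002"))
  s2 <- signature_score_geomean(expr, c("MR0002", "MR0001"))
  expect_equal(s1, s2)
  # absent members reported, all-absent is an error
  s3 <- signature_score_geomean(expr, c("MR0002", "MR9999"))
  expect_equal(attr(s3, "absent"), "MR9999")
  expect_error(signature_score_geomean(expr, "MR9999"), "no set member")
  # approximate scale equivariance for counts >> pseudocount
  set.seed(50)
  big <- matrix(rpois(40, 5000), 4,
                dimnames = list(sprintf("MR%04d", 1:4), sprintf("s%d", 1:10)))
  e1 <- expr_matrix(big, rep("tumor", 10), scale = "counts")
  e2 <- expr_matrix(big * 7, rep("tumor", 10), scale = "counts")
  r <- as.numeric(signature_score_geomean(e2, rownames(big))) /
    as.numeric(signature_score_geomean(e1, rownames(big)))
  expect_equal(r, rep(7, 10), tolerance = 1e-3)
})

test_that("score_correlation recovers identity and the planted fraction coupling", {
  s <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  r <- score_correlation(s, s)
  expect_equal(r$rho, 1)
  expect_match(r$sample_hash, "^[0-9a-f]+$")
  # independent vectors: CI covers zero (p not small)
  set.seed(55)
  x <- setNames(rnorm(100), sprintf("s%03d", 1:100))
  y <- setNames(rnorm(100), sprintf("s%03d", 1:100))
  expect_gt(score_correlation(x, y)$p, 0.001)
  expect_error(score_correlation(s[1:2], s[1:2]), "3")
})

test_that("GMT parsing collapses duplicates and rejects short lines", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tdesc\tA\tA\tC"), path)
  sets <- read_gmt(path)
  expect_equal(sets$S1$genes, c("A", "B"))
  expect_equal(sets$S2$genes, c("A", "C"))
  writeLines("BAD\tonly-desc", path)
  expect_error(read_gmt(path), "fewer than 3")
  writeLines(character(), path)
  expect_equal(length(read_gmt(path)), 0)
  # write/read round trip
  write_gmt(list(X = c("G1", "G2")), path)
  expect_equal(read_gmt(path)$X$genes, c("G1", "G2"))
})
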