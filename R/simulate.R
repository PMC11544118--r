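#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the planted-truth simulator. Defaults describe the
#' reference synthetic study: 200 tumor / 50 normal samples, 1000 genes
#' (500 lncRNA, 100 miRNA, 400 mRNA), 10 planted sponge triplets with
#' target rank correlation 0.8, hub log2 fold change 2 in tumors,
#' negative-binomial dispersion 0.2, log-uniform library sizes between
#' 5e5 and 2e6, a true log-hazard of `log(1.74)` per standard deviation of
#' hub expression, 30% censoring, 500 decoy edges per prediction table and
#' an M2-macrophage coupling of 0.47.
#'
#' @param n_tumor,n_normal sample counts per condition.
#' @param n_lnc,n_mi,n_mrna gene counts per class.
#' @param n_triplets number of planted sponge triplets (the first two share
#'   the hub lncRNA and its miRNA, making their two mRNAs the planted
#'   ligand pair).
#' @param sponge_strength target absolute Spearman correlation, in (0, 1),
#'   between the miRNA and its sponged partners (and between lncRNA and
#'   mRNA of a triplet).
#' @param de_lfc planted tumor-vs-normal log2 fold change of hub genes.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param libsize_range two-element interval for log-uniform per-sample
#'   library sizes.
#' @param beta_hazard true Cox log-hazard per unit of z-scored hub
#'   expression.
#' @param censor_rate target fraction of censored survival records, in
#'   \[0, 1).
#' @param fp_edges decoy (false-positive) edges per interaction table.
#' @param frac_coupling target Spearman correlation between the coupled
#'   immune cell fraction and hub expression.
#' @param stage_coupling latent coupling of ordinal tumor stage with hub
#'   expression (no published effect size exists for this association; 0.5
#'   gives a clearly detectable but not deterministic shift).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_tumor = 200, n_normal = 50, n_lnc = 500,
                       n_mi = 100, n_mrna = 400, n_triplets = 10,
                       sponge_strength = 0.8, de_lfc = 2,
                       nb_dispersion = 0.2, libsize_range = c(5e5, 2e6),
                       beta_hazard = log(1.74), censor_rate = 0.3,
                       fp_edges = 500, frac_coupling = 0.47,
                       stage_coupling = 0.5, seed = 1) {
  cfg <- list(n_tumor = n_tumor, n_normal = n_normal, n_lnc = n_lnc,
              n_mi = n_mi, n_mrna = n_mrna, n_triplets = n_triplets,
              sponge_strength = sponge_strength, de_lfc = de_lfc,
              nb_dispersion = nb_dispersion, libsize_range = libsize_range,
              beta_hazard = beta_hazard, censor_rate = censor_rate,
              fp_edges = fp_edges, frac_coupling = frac_coupling,
              stage_coupling = stage_coupling, seed = seed)
  counts <- c("n_tumor", "n_normal", "n_lnc", "n_mi", "n_mrna", "n_triplets")
  for (k in counts) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1 || cfg[[k]] != round(cfg[[k]])) {
      stopf("sim_config: %s must be an integer >= 1", k)
    }
  }
  if (!(sponge_strength > 0 && sponge_strength < 1)) {
    stopf("sim_config: sponge_strength must be in (0, 1)")
  }
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stopf("sim_config: censor_rate must be in [0, 1)")
  }
  if (n_triplets > min(n_lnc, n_mi, n_mrna)) {
    stopf("sim_config: n_triplets exceeds the smallest gene class")
  }
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      libsize_range[1] > libsize_range[2]) {
    stopf("sim_config: libsize_range must be a positive increasing interval")
  }
  if (nb_dispersion <= 0) stopf("sim_config: nb_dispersion must be > 0")
  if (fp_edges < 0) stopf("sim_config: fp_edges must be >= 0")
  if (abs(frac_coupling) >= 1) stopf("sim_config: |frac_coupling| must be < 1")
  class(cfg) <- "sim_config"
  cfg
}

# Gaussian-copula correlation that yields a target Spearman correlation for
# bivariate normal latents: rho_G = 2 sin(pi * rho_S / 6).
spearman_to_gaussian <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Sample ids and gene ids used by every generator.
sim_sample_ids <- function(config) {
  c(sprintf("T%03d", seq_len(config$n_tumor)),
    sprintf("N%03d", seq_len(config$n_normal)))
}
sim_gene_ids <- function(config) {
  c(sprintf("LNC%04d", seq_len(config$n_lnc)),
    sprintf("MIR%04d", seq_len(config$n_mi)),
    sprintf("MR%04d", seq_len(config$n_mrna)))
}

# Planted triplet layout. The first two triplets share the hub lncRNA and
# its miRNA; their mRNAs are the two planted "ligand" genes, so the hub is
# the unique lncRNA correlated with both ligands.
sim_triplet_layout <- function(config) {
  k <- config$n_triplets
  if (k >= 2) {
    lnc_idx <- c(1L, 1L, seq_len(k - 2) + 1L)
    mi_idx <- lnc_idx
    mrna_idx <- seq_len(k)
  } else {
    lnc_idx <- 1L; mi_idx <- 1L; mrna_idx <- 1L
  }
  data.frame(
    lnc_id = sprintf("LNC%04d", lnc_idx),
    mi_id = sprintf("MIR%04d", mi_idx),
    mrna_id = sprintf("MR%04d", mrna_idx),
    group = pmax(1L, seq_len(k) - 1L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a count matrix with planted sponge triplets
#'
#' Counts are negative-binomial with per-gene abundances, log-uniform
#' library sizes and a Gaussian copula planting the sponge structure: each
#' triplet group has a shared latent factor loading positively on its
#' lncRNA and mRNA(s) and negatively on its miRNA, with per-gene loading
#' `sqrt(2*sin(pi*sponge_strength/6))`, so every planted pair attains
#' an absolute Spearman correlation of about `sponge_strength` on the
#' normalized scale. Latent normals are mapped to counts by the
#' negative-binomial quantile transform, which preserves rank correlation.
#' Planted lncRNAs and mRNAs additionally carry a `de_lfc` mean shift in
#' tumor samples. All other genes are independent noise.
#'
#' @param config `sim_config`.
#' @return list with `expr` (an `expr_matrix` of counts) and `truth`
#'   (class `sim_truth`: planted triplets, DE genes with true log2 fold
#'   change, hub lncRNA, ligand pair, hazard coefficient, coupled cell
#'   type).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_s <- config$n_tumor + config$n_normal
    sample_ids <- sim_sample_ids(config)
    condition <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
    gene_ids <- sim_gene_ids(config)
    n_g <- length(gene_ids)
    layout <- sim_triplet_layout(config)
    planted <- unique(c(layout$lnc_id, layout$mi_id, layout$mrna_id))
    de_genes <- unique(c(layout$lnc_id, layout$mrna_id))

    # abundance weights: planted genes drawn from a tighter, well-expressed
    # regime so the screen is not confounded by detection limits, but kept
    # a small share of the library so their fold change does not displace
    # the relative abundance of null genes (CPM is zero-sum)
    w <- stats::rlnorm(n_g, meanlog = log(50), sdlog = 1.5)
    names(w) <- gene_ids
    w[planted] <- stats::rlnorm(length(planted), meanlog = log(100),
                                sdlog = 0.4)
    libsize <- exp(stats::runif(n_s, log(config$libsize_range[1]),
                                log(config$libsize_range[2])))

    # the planted fold change is defined on the CPM (relative-abundance)
    # scale, so the count-space multiplier m must over-shoot to compensate
    # for the library share the DE genes gain: solving
    # (m w / S_t) / (w / S) = fold with S_t = S + (m - 1) W_de gives
    # m = fold (S - W_de) / (S - fold W_de)
    fold <- 2^config$de_lfc
    S <- sum(w)
    W_de <- sum(w[de_genes])
    if (S - fold * W_de <= 0) {
      stopf("simulate_expression: planted DE mass too large for de_lfc = %g",
            config$de_lfc)
    }
    m <- fold * (S - W_de) / (S - fold * W_de)
    w_tum <- w
    w_tum[de_genes] <- w_tum[de_genes] * m
    comp <- cbind(tumor = w_tum / sum(w_tum), normal = w / S)
    mu <- comp[, condition] * rep(libsize, each = n_g)
    dimnames(mu) <- list(gene_ids, sample_ids)

    # latent normals: shared factor within each triplet group
    lambda <- sqrt(spearman_to_gaussian(config$sponge_strength))
    n_groups <- max(layout$group)
    f <- matrix(stats::rnorm(n_groups * n_s), n_groups, n_s)
    z <- matrix(stats::rnorm(n_g * n_s), n_g, n_s,
                dimnames = list(gene_ids, sample_ids))
    for (i in seq_len(nrow(layout))) {
      g <- layout$group[i]
      for (gene in c(layout$lnc_id[i], layout$mrna_id[i])) {
        z[gene, ] <- lambda * f[g, ] +
          sqrt(1 - lambda^2) * stats::rnorm(n_s)
      }
      z[layout$mi_id[i], ] <- -lambda * f[g, ] +
        sqrt(1 - lambda^2) * stats::rnorm(n_s)
    }

    size <- 1 / config$nb_dispersion
    counts <- matrix(stats::qnbinom(stats::pnorm(z), size = size, mu = mu),
                     n_g, n_s, dimnames = list(gene_ids, sample_ids))

    truth <- structure(list(
      planted_triplets = layout[, c("lnc_id", "mi_id", "mrna_id")],
      de_genes = data.frame(gene_id = de_genes,
                            true_log2fc = config$de_lfc,
                            stringsAsFactors = FALSE),
      hub_lnc = layout$lnc_id[1],
      ligands = unique(layout$mrna_id[seq_len(min(2, nrow(layout)))]),
      beta_hazard = config$beta_hazard,
      coupled_celltype = "Macrophages M2"
    ), class = "sim_truth")

    list(expr = expr_matrix(counts, condition = condition, scale = "counts"),
         truth = truth)
  })
}

#' Simulate interaction prediction tables with planted edges and decoys
#'
#' Two lncRNA->miRNA sources (`mircode`, `rnahybrid`) and two miRNA->mRNA
#' sources (`targetscan`, `mirdb`). Every planted edge appears in both
#' sources of its class; each source additionally carries `fp_edges`
#' uniformly random decoy edges, drawn independently per source (so decoys
#' are mostly removed by source intersection).
#'
#' @param truth `sim_truth` from [simulate_expression()].
#' @param config `sim_config` used for the simulation.
#' @return list with elements `lnc_mi` and `mi_mrna`, each a named list of
#'   two `interaction_table`s.
#' @export
simulate_interaction_tables <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lnc))
    mi_ids <- sprintf("MIR%04d", seq_len(config$n_mi))
    mrna_ids <- sprintf("MR%04d", seq_len(config$n_mrna))
    pt <- truth$planted_triplets

    make_source <- function(regs, tgts, planted_reg, planted_tgt, db,
                            edge_class) {
      planted_idx <- (match(planted_tgt, tgts) - 1L) * length(regs) +
        match(planted_reg, regs)
      planted_idx <- unique(planted_idx)
      pool <- setdiff(seq_len(length(regs) * length(tgts)), planted_idx)
      decoy_idx <- if (config$fp_edges > 0) {
        sample(pool, min(config$fp_edges, length(pool)))
      } else {
        integer()
      }
      idx <- c(planted_idx, decoy_idx)
      reg <- regs[((idx - 1L) %% length(regs)) + 1L]
      tgt <- tgts[((idx - 1L) %/% length(regs)) + 1L]
      interaction_table(data.frame(regulator_id = reg, target_id = tgt,
                                   stringsAsFactors = FALSE),
                        edge_class = edge_class, source_db = db)
    }

    list(
      lnc_mi = list(
        mircode = make_source(lnc_ids, mi_ids, pt$lnc_id, pt$mi_id,
                              "mircode", "lnc_mi"),
        rnahybrid = make_source(lnc_ids, mi_ids, pt$lnc_id, pt$mi_id,
                                "rnahybrid", "lnc_mi")
      ),
      mi_mrna = list(
        targetscan = make_source(mi_ids, mrna_ids, pt$mi_id, pt$mrna_id,
                                 "targetscan", "mi_mrna"),
        mirdb = make_source(mi_ids, mrna_ids, pt$mi_id, pt$mrna_id,
                            "mirdb", "mi_mrna")
      )
    )
  })
}

#' Simulate a clinical table with hub-driven survival
#'
#' Tumor samples receive exponential survival times with log-hazard
#' `beta_hazard * z`, where `z` is the z-scored log2(CPM+1) expression of
#' the hub lncRNA. Censoring is independent exponential with its rate
#' solved numerically so the expected censored fraction equals
#' `censor_rate` (hazards stay proportional). Ordinal stage (and, more
#' weakly, grade and T stage) is coupled to hub expression through a latent
#' Gaussian; N/M stage and the MSI/EBV subtype flags are sampled with
#' realistic marginal rates.
#'
#' @param expr `expr_matrix` (counts or log2cpm) containing the hub gene.
#' @param truth `sim_truth`.
#' @param config `sim_config`.
#' @return data.frame with columns `sample_id`, `time`, `event`,
#'   `expression`, `age`, `sex`, `stage`, `grade`, `t_stage`, `n_stage`,
#'   `m_stage`, `msi`, `ebv` (tumor samples only).
#' @export
simulate_clinical <- function(expr, truth, config) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  if (expr$scale == "counts") expr <- cpm_log_normalize(expr)
  tum <- tumor_samples(expr)
  hub <- expr$values[truth$hub_lnc, tum]
  x <- as.numeric(scale(hub))
  n <- length(x)
  with_seed(config$seed + 202L, {
    lambda0 <- 1 / 1000 # baseline hazard per day
    rate <- lambda0 * exp(config$beta_hazard * x)
    t_event <- stats::rexp(n, rate)
    if (config$censor_rate > 0) {
      f <- function(theta) mean(theta / (theta + rate)) - config$censor_rate
      theta <- stats::uniroot(f, lower = 1e-12, upper = 1e6,
                              tol = 1e-12)$root
      t_cens <- stats::rexp(n, theta)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    ordinal_from_latent <- function(coupling, breaks, labels) {
      latent <- coupling * x + stats::rnorm(n)
      cut(latent, breaks = stats::quantile(latent, c(0, breaks, 1)),
          labels = labels, include.lowest = TRUE)
    }
    stage <- ordinal_from_latent(config$stage_coupling, c(0.20, 0.55, 0.85),
                                 c("I", "II", "III", "IV"))
    grade <- ordinal_from_latent(0.3 * config$stage_coupling, c(0.10, 0.50),
                                 c("G1", "G2", "G3"))
    t_stage <- ordinal_from_latent(0.8 * config$stage_coupling,
                                   c(0.05, 0.25, 0.70),
                                   c("T1", "T2", "T3", "T4"))
    n_stage <- ordinal_from_latent(0.4 * config$stage_coupling,
                                   c(0.30, 0.55, 0.75),
                                   c("N0", "N1", "N2", "N3"))
    m_stage <- factor(ifelse(stats::runif(n) <
                               stats::plogis(stats::qlogis(0.10) + 0.3 * x),
                             "M1", "M0"), levels = c("M0", "M1"))
    data.frame(
      sample_id = tum,
      time = time,
      event = event,
      expression = as.numeric(hub),
      age = round(stats::rnorm(n, 65, 10)),
      sex = factor(sample(c("male", "female"), n, replace = TRUE,
                          prob = c(0.65, 0.35)),
                   levels = c("male", "female")),
      stage = stage, grade = grade, t_stage = t_stage,
      n_stage = n_stage, m_stage = m_stage,
      msi = stats::rbinom(n, 1, 0.22),
      ebv = stats::rbinom(n, 1, 0.09),
      stringsAsFactors = FALSE
    )
  })
}

lm22_cell_types <- function() {
  c("B cells naive", "B cells memory", "Plasma cells", "T cells CD8",
    "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta",
    "NK cells resting", "NK cells activated", "Monocytes",
    "Macrophages M0", "Macrophages M1", "Macrophages M2",
    "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells resting", "Mast cells activated", "Eosinophils",
    "Neutrophils")
}

#' Simulate immune cell fractions coupled to hub expression
#'
#' Per-sample fractions over the 22 leukocyte subsets of the LM22
#' signature. The coupled cell type (M2 macrophages) is drawn from a Beta
#' marginal through a Gaussian copula against the rank-transformed hub
#' expression, targeting a Spearman correlation of `frac_coupling`; the
#' remaining 21 types are Dirichlet and rescaled so every sample's
#' fractions sum to exactly 1.
#'
#' @param expr `expr_matrix` containing the hub gene.
#' @param truth `sim_truth`.
#' @param config `sim_config`.
#' @return numeric matrix, 22 cell types x samples, columns summing to 1.
#' @export
simulate_fractions <- function(expr, truth, config) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(truth, "sim_truth"),
            inherits(config, "sim_config"))
  if (expr$scale == "counts") expr <- cpm_log_normalize(expr)
  hub <- expr$values[truth$hub_lnc, ]
  n <- length(hub)
  cells <- lm22_cell_types()
  coupled <- truth$coupled_celltype
  stopifnot(coupled %in% cells)
  alpha <- c(0.6, 0.4, 1.2, 1.5, 0.6, 2.5, 0.8, 0.6, 0.6, 0.3, 0.6, 0.9,
             1.2, 2.2, 1.2, 3.0, 0.4, 0.4, 0.9, 0.3, 0.2, 0.6)
  names(alpha) <- cells
  with_seed(config$seed + 303L, {
    zhub <- stats::qnorm((rank_with_ties(hub) - 0.5) / n)
    rho_g <- spearman_to_gaussian(config$frac_coupling)
    zc <- rho_g * zhub + sqrt(1 - rho_g^2) * stats::rnorm(n)
    f_c <- stats::qbeta(stats::pnorm(zc), shape1 = 3, shape2 = 17)
    others <- setdiff(cells, coupled)
    g <- matrix(stats::rgamma(length(others) * n, shape = alpha[others]),
                nrow = length(others), dimnames = list(others, names(hub)))
    g <- sweep(g, 2, colSums(g), "/")
    g <- sweep(g, 2, 1 - f_c, "*")
    out <- rbind(g, matrix(f_c, 1, n, dimnames = list(coupled, names(hub))))
    out[cells, , drop = FALSE]
  })
}

#' Simulate a qPCR Ct plate for paired tumor/adjacent specimens
#'
#' Triplicate cycle-threshold values for a target transcript and a
#' reference gene in matched tumor and adjacent-normal tissue, with the
#' target amplifying `delta` cycles earlier (i.e. 2^delta-fold higher) in
#' tumors.
#'
#' @param n_pairs number of specimen pairs.
#' @param target,reference gene labels.
#' @param delta planted tumor-vs-adjacent Ct shift of the target (cycles).
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `gene`, `condition`,
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(n_pairs = 23, target = "LINC01094",
                          reference = "ACTB", delta = 2, seed = 1) {
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_pairs)) {
      sid <- sprintf("P%02d", i)
      ref_base <- stats::rnorm(1, 18, 0.3)
      tgt_adj <- stats::rnorm(1, 26, 0.8)
      tgt_tum <- tgt_adj - delta + stats::rnorm(1, 0, 0.5)
      for (cond in c("tumor", "adjacent")) {
        tgt_ct <- if (cond == "tumor") tgt_tum else tgt_adj
        for (r in 1:3) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, gene = c(target, reference), condition = cond,
            replicate = r,
            ct = c(tgt_ct, ref_base) + stats::rnorm(2, 0, 0.15),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs every generator under `config` and writes the pipeline's input
#' files to `dir`: `expression.tsv`, `clinical.tsv`, four interaction
#' tables, `fractions.tsv`, `genesets.gmt` (one planted set of the sponge
#' target mRNAs plus one random decoy set) and `truth.json`.
#'
#' @param config `sim_config`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_expression(config)
  tabs <- simulate_interaction_tables(sim$truth, config)
  clin <- simulate_clinical(sim$expr, sim$truth, config)
  fracs <- simulate_fractions(sim$expr, sim$truth, config)

  seed <- config$seed
  chash <- string_fingerprint(paste(names(config), unlist(lapply(config, paste,
                                                      collapse = ",")),
                         sep = "=", collapse = ";"))
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    lnc_mi = file.path(dir, c("lnc_mi_mircode.tsv", "lnc_mi_rnahybrid.tsv")),
    mi_mrna = file.path(dir, c("mi_mrna_targetscan.tsv",
                               "mi_mrna_mirdb.tsv")),
    fractions = file.path(dir, "fractions.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(sim$expr, paths$expression, seed = seed,
                       config_hash = chash)
  write_tsv(clin, paths$clinical, seed = seed, config_hash = chash)
  write_interaction_tsv(tabs$lnc_mi$mircode, paths$lnc_mi[1], seed = seed,
                        config_hash = chash)
  write_interaction_tsv(tabs$lnc_mi$rnahybrid, paths$lnc_mi[2], seed = seed,
                        config_hash = chash)
  write_interaction_tsv(tabs$mi_mrna$targetscan, paths$mi_mrna[1],
                        seed = seed, config_hash = chash)
  write_interaction_tsv(tabs$mi_mrna$mirdb, paths$mi_mrna[2], seed = seed,
                        config_hash = chash)
  frac_df <- data.frame(cell_type = rownames(fracs),
                        as.data.frame(fracs, check.names = FALSE),
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(frac_df, paths$fractions, seed = seed, config_hash = chash)

  decoy_pool <- setdiff(sprintf("MR%04d", seq_len(config$n_mrna)),
                        sim$truth$planted_triplets$mrna_id)
  decoy_set <- with_seed(config$seed + 404L,
                         sort(sample(decoy_pool, min(10, length(decoy_pool)))))
  sets <- list(
    PLANTED_SPONGE_TARGETS = sort(unique(sim$truth$planted_triplets$mrna_id)),
    DECOY_SET = decoy_set
  )
  write_gmt(sets, paths$gmt)

  truth_json <- list(
    planted_triplets = sim$truth$planted_triplets,
    de_genes = sim$truth$de_genes,
    hub_lnc = sim$truth$hub_lnc,
    ligands = sim$truth$ligands,
    beta_hazard = sim$truth$beta_hazard,
    coupled_celltype = sim$truth$coupled_celltype
  )
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(expr = sim$expr, truth = sim$truth, interactions = tabs,
                 clinical = clin, fractions = fracs, paths = paths,
                 config_hash = chash))
}
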