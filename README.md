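# cernascreen

Screening for long non-coding RNAs (lncRNAs) that act as microRNA sponges
co-regulating a pair of target mRNAs — competing endogenous RNA (ceRNA)
triplets — in bulk tumor/normal expression cohorts. The motivating use case
is a lncRNA that dually de-represses the immune-checkpoint ligands PD-L1
(*CD274*) and PD-L2 (*PDCD1LG2*) by sequestering a shared miRNA, and
thereby carries prognostic and immunological signal.

## What the package computes

Expression is normalized to `log2(CPM + 1)`. The screen then chains:

1. **Differential expression** of lncRNAs (moderated t with
   method-of-moments empirical-Bayes variance shrinkage), kept at
   `|log2FC| > 1` and BH-adjusted `p < 0.05`;
2. **Ligand correlation**: Spearman ρ > 0.4 at raw p < 0.001 against each
   ligand over tumor samples, then the intersection of the two sets;
3. **Prediction-source intersection**: binding-prediction tables (two
   sources per edge class) reduced to the edges all sources agree on;
4. **Triplet assembly**: a lncRNA–mRNA pair with ρ > 0.5 (p < 0.001) plus
   a shared predicted miRNA negatively correlated with both partners forms
   a co-expressed competing triplet; networks export as SIF/GraphML;
5. **Hub ranking** by mean ligand correlation;
6. **Survival**: median split, Kaplan–Meier, log-rank, and
   univariate-to-multivariate Cox screening (hazard ratios with Wald 95%
   CIs, Efron ties);
7. **Enrichment**: preranked GSEA (weighted Kolmogorov–Smirnov running
   sum, gene-label permutations, sign-matched NES) and geometric-mean
   signature scores;
8. **Immune association**: per-cell-type rank-sum comparisons and Spearman
   correlations against 22 deconvolved leukocyte fractions, BH within the
   comparison;
9. **qPCR quantification**: Livak 2^−ΔCt / 2^−ΔΔCt with replicate means
   and paired signed-rank comparisons.

A calibrated synthetic-data generator (`sim_config()`,
`simulate_bundle()`) plants sponge triplets, a differential-expression
shift, a survival hazard, and an M2-macrophage coupling with known truth,
so the whole pipeline can be tested for recovery.

## Worked example

Generate a synthetic cohort with 5 planted triplets and run the full
screen:

```r
library(cernascreen)

dir <- tempfile()
cfg <- sim_config(n_tumor = 100, n_normal = 30, n_lnc = 120, n_mi = 40,
                  n_mrna = 80, n_triplets = 5, fp_edges = 200, seed = 42)
bundle <- simulate_bundle(cfg, dir)

pc <- pipeline_config(
  expression = bundle$paths$expression, clinical = bundle$paths$clinical,
  lnc_mi = bundle$paths$lnc_mi, mi_mrna = bundle$paths$mi_mrna,
  fractions = bundle$paths$fractions, gmt = bundle$paths$gmt,
  ligands = bundle$truth$ligands, out_dir = file.path(dir, "results"),
  n_perm = 500, seed = 42)
res <- run_pipeline(pc)

res$hub_rank
#>   gene_id     rho_a     rho_b mean_rho rank
#> 1 LNC0001 0.7954635 0.7650885 0.780276    1

res$triplets[, c("lnc_id", "mi_id", "mrna_id", "rho_lnc_mrna",
                 "rho_lnc_mi", "rho_mi_mrna")]
#>    lnc_id   mi_id mrna_id rho_lnc_mrna rho_lnc_mi rho_mi_mrna
#> 1 LNC0001 MIR0001  MR0001    0.7954635 -0.7163156  -0.6956736
#> 2 LNC0001 MIR0001  MR0002    0.7650885 -0.7163156  -0.7517552
#> 3 LNC0002 MIR0002  MR0003    0.7943954 -0.7892709  -0.7529913
#> 4 LNC0003 MIR0003  MR0004    0.8265587 -0.8305431  -0.8033723
#> 5 LNC0004 MIR0004  MR0005    0.7848785 -0.7255566  -0.7507831
```

All five planted triplets are recovered — the hub lncRNA (which sponges
the shared miRNA of both "ligand" mRNAs) ranks first with mean ligand
correlation 0.78, and each triplet shows the required sign pattern
(positive lncRNA–mRNA, negative miRNA against both partners). Decoy
prediction edges (200 per table) are eliminated by source intersection and
the correlation rules.

Downstream, the hub behaves as planted — higher hazard in the high-
expression group and a coupled M2-macrophage fraction:

```r
res$logrank
#> logrank: statistic = 8.6023, p = 0.003357

subset(res$cox$multivariate$table, covariate == "expression_group")
#>          covariate level      beta       hr   ci_low  ci_high          p
#> 1 expression_group  high 0.5843404 1.793807 1.069387 3.008964 0.02681494

subset(res$fraction_cor, cell_type == "Macrophages M2")
#>         cell_type       rho            p        adj_p   n
#> 16 Macrophages M2 0.5652205 8.986128e-10 1.976948e-08 100
```

The hazard ratio for the high-expression group (1.79, CI 1.07–3.01)
recovers the planted log-hazard of `log(1.74)` per SD, and the M2 fraction
correlates with hub expression as configured. Every stage also writes a
TSV/SIF/GraphML file with a provenance header into `out_dir`; rerunning
with the same configuration and seed reproduces the files byte for byte.

For real cohorts, point `pipeline_config()` at your own expression TSV
(genes × samples with a condition row), clinical table, interaction-table
exports and GMT file, and set `ligands = c("CD274", "PDCD1LG2")`.

## Package layout

- `R/` — stats primitives (`spearman`, `wilcoxon_rank_sum`, `bh_adjust`,
  ...), normalization and DE, the ceRNA screen, survival, enrichment,
  associations/qPCR, the synthetic generator, and the pipeline driver.
- `tests/testthat/` — unit and property tests per module, independent
  oracles (brute-force enrichment scores, grid-search partial likelihood,
  exact permutations), and end-to-end recovery tests.
- `vignettes/cernascreen-methods.Rmd` — the model, its assumptions,
  numerical conventions, and what the synthetic tests do and do not show.
- `inst/extdata/` — small synthetic stand-in fixtures (labelled
  `*_synthetic`).
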