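---
title: "Screening competing endogenous RNA triplets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening competing endogenous RNA triplets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Long non-coding RNAs (lncRNAs) can de-repress protein-coding transcripts by
sequestering shared microRNAs — the competing endogenous RNA (ceRNA)
mechanism. When the de-repressed targets are the immune-checkpoint ligands
PD-L1 (*CD274*) and PD-L2 (*PDCD1LG2*), a single lncRNA sponge can shape an
immunosuppressive tumor microenvironment and carry prognostic information.
`cernascreen` implements the complete screening workflow for such a dually
regulating lncRNA in bulk tumor/normal RNA-seq cohorts: expression
normalization, a differential-expression screen, correlation filtering
against the two ligands, intersection of binding-site prediction sources,
assembly of co-expressed competing triplets, hub ranking, survival and
clinicopathological association analysis, preranked gene-set enrichment,
immune cell-fraction association, and relative qPCR quantification for
wet-lab validation cohorts.

The screen itself is rule-based, so the package's credibility rests on two
things: each statistical primitive matching an independent oracle, and the
whole pipeline recovering a *planted* ground truth from synthetic data that
has the statistical structure the method assumes. Both are part of the test
suite.

# The screening model

All screening runs on `log2(CPM + 1)` values, where CPM is counts per
million within each sample's library. The stages apply, in order:

1. **Differential expression (lncRNAs).** Per-gene moderated t on the
   normalized scale, tumor versus normal. The log2 fold change is the
   difference of group means. Gene-wise residual variances $s_g^2$ (on $d$
   degrees of freedom) are shrunk toward a common scale:
   $\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$
   estimated by method of moments under a scaled-F model for the variance
   distribution, and the statistic referred to a t distribution on
   $d_0 + d$ degrees of freedom. At $d_0 \to \infty$ this collapses to a
   pooled-scale statistic, at $d_0 = 0$ to the ordinary t — both limits are
   asserted by tests, and agreement with an established empirical-Bayes
   implementation is checked independently. Genes pass with
   $|\mathrm{log_2FC}| > 1$ and BH-adjusted $p < 0.05$, both strict.
2. **Ligand correlation.** Spearman correlation of each surviving lncRNA
   with each ligand over tumor samples; retained when $\rho > 0.4$ and raw
   $p < 0.001$. The two ligand-specific sets are intersected. P-values in
   correlation screens are deliberately *not* multiplicity-adjusted — the
   thresholds are defined on raw p-values, and adjustment is applied only
   where a stage is defined on adjusted ones.
3. **Prediction-source intersection.** Binding predictions are consumed as
   exported tables, two sources per edge class (lncRNA→miRNA and
   miRNA→mRNA); only edges present in every source survive. With decoy
   (false-positive) edges drawn independently per source, the expected
   number of surviving decoys follows the birthday-style rate
   $f^2/\text{universe}$, which the generator tests verify.
4. **Triplet assembly.** A lncRNA–mRNA pair is a target pair when
   $\rho > 0.5$ with $p < 0.001$; for each predicted shared miRNA, a
   *co-expressed competing triplet* is emitted when the miRNA is negatively
   correlated with both partners. The negative screen has no canonical
   threshold in the field; the default is $\rho < 0$ with nominal
   $p < 0.05$, exposed as `neg_p_max`, because biologically genuine sponge
   relationships routinely show only weak negative marginal correlations
   (the miRNA's variance is dominated by other regulation). Every emitted
   triplet is re-validated from the raw matrix by an independent check in
   the test suite.
5. **Hub ranking.** Candidates are ordered by the mean of their two ligand
   correlations, ties broken lexicographically — a deterministic, recorded
   rule.

Identifier handling: Ensembl version suffixes are stripped and symbols
upper-cased before any set operation, because annotation-dialect mismatch
between cohorts and prediction exports is the dominant practical failure of
this kind of screen.

# Survival and association stages

Patients are split at the **median** expression of the hub; values exactly
at the median go to the low group (a fixed, recorded tie rule). Kaplan–Meier
curves, the two-group log-rank test, and Cox proportional-hazards models use
the standard estimators (Efron tie handling; Wald 95% intervals
$\exp(\hat\beta \pm 1.96\,\mathrm{se})$; reference level = first factor
level). The screening convention is univariate-to-multivariate: covariates
whose univariate fit has any coefficient with $p$ below the entry threshold
join a joint model. The default entry threshold is 0.05; the looser 0.1
convention that also circulates in the clinical literature is available by
argument (`univ_p_enter`), since both conventions are defensible and the
choice materially changes which covariates enter.

The optimal-cutpoint utility maximizes the log-rank statistic over observed
marker values inside a quantile band (default 10%–90%) — a maximally
selected rank statistic. Its p-value is reported *uncorrected* with an
explicit caveat; selecting a cutpoint by scanning inflates the type-I error,
and the package does not pretend otherwise.

Clinicopathological associations dispatch on the factor's arity: Wilcoxon
rank-sum for two levels, Kruskal–Wallis otherwise. Immune cell-fraction
comparisons run one rank-sum test per cell type with BH adjustment *within
the 22 cell types of one comparison* — the smallest defensible family,
recorded in the output metadata.

# Enrichment and signature scoring

Preranked GSEA ranks all expressed genes by log2 fold change (no DE filter;
ties broken by gene id). The enrichment score is the classic weighted
Kolmogorov–Smirnov running sum: a set member at position $i$ adds
$|r_i|^w / \sum_{j \in S} |r_j|^w$, a non-member subtracts $1/(N - N_h)$,
and the ES is the running sum's maximal signed deviation. Numerical
conventions made explicit because the field's tools leave them implicit:

* a set whose members all have zero weighted score contributes zero hit
  increments (no 0/0);
* when the maximal positive and negative deviations tie exactly in
  magnitude the positive one is reported — the sign is genuinely
  ill-defined at such ties;
* the ES depends on $N$ through the miss decrement, so padding the ranked
  list changes scores — an expected property, not a bug.

Significance uses gene-label permutations of set membership (preranked
mode, matching how log2FC-ranked analyses are actually run), with
$\mathrm{NES} = \mathrm{ES} / \overline{|\mathrm{ES}^{null}_{same sign}|}$
and $p = (1 + \#\{\text{null at least as extreme, same sign}\}) /
(1 + \#\{\text{null of same sign}\})$; BH across the sets of one call.

The IL-10⁺ tumor-associated-macrophage signature is scored per sample as
the **geometric mean** of member counts with a pseudocount of 1 — the score
the downstream correlations are defined on. Kernel-based enrichment
variants (GSVA-style) are intentionally out of scope: the geometric mean is
what the downstream analysis consumes, it is transparent, and for counts
well above the pseudocount it is scale-equivariant.

qPCR quantification follows Livak: $2^{-\Delta Ct}$ against the reference
gene with replicate Ct values averaged *before* differencing, and
$2^{-\Delta\Delta Ct}$ against the control condition's mean ΔCt, which
anchors the control's geometric-mean fold at exactly 1.

# The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_expression()` and its
siblings generate data with exactly the structure the screen assumes, plus
a truth record for recovery testing.

* **Counts.** Negative binomial (dispersion 0.2, i.e. variance
  $\mu + 0.2\mu^2$, a typical bulk RNA-seq value) with log-normal gene
  abundances and log-uniform library sizes in $[5\times10^5, 2\times10^6]$
  — log-uniform so that CPM normalization is doing real work in the tests.
* **Sponge structure.** Each planted triplet group shares a latent Gaussian
  factor loading positively on the lncRNA and mRNA(s) and negatively on the
  miRNA. Loadings are $\sqrt{2\sin(\pi\rho_S/6)}$ so the *Spearman*
  correlation of each planted pair hits the configured `sponge_strength`
  (default 0.8) after the Gaussian→NB quantile transform, which preserves
  rank correlation. Calibration to ±0.1 is asserted by simulation.
* **Hub and ligands.** The first two triplets share one lncRNA and one
  miRNA; their two mRNAs act as the planted ligand pair, making that lncRNA
  the unique hub correlated with both ligands.
* **Differential expression.** Planted lncRNAs and mRNAs carry a +2 log2
  fold change in tumors. Because CPM is a relative scale, boosting a set of
  genes steals library share from the rest; the count-space multiplier is
  therefore solved from the composition identity
  $m = f(S - W)/(S - fW)$ (with $f = 2^{\mathrm{lfc}}$, $S$ the total
  abundance, $W$ the planted mass) so the *CPM-scale* fold change equals
  the planted value, and planted genes are kept a small share of the
  library so null genes are not visibly displaced.
* **Survival.** Exponential event times with log-hazard
  $\beta \cdot z$(hub), $\beta = \log 1.74$ by default — the magnitude of a
  typical independent prognostic lncRNA. Censoring is independent
  exponential with its rate solved numerically (uniroot) to hit the target
  censoring fraction, keeping hazards proportional. Ordinal stage couples
  to the hub through a latent Gaussian; no published effect size exists for
  that association, so the coupling (0.5) was chosen once to be clearly
  detectable at cohort scale without being deterministic, and is exposed in
  the configuration.
* **Immune fractions.** 22 leukocyte subsets per sample. The coupled M2
  fraction is drawn from a Beta(3, 17) marginal through a Gaussian copula
  against the rank-transformed hub (target Spearman 0.47, the scale of a
  strong fraction–expression association); the other 21 subsets are
  Dirichlet and rescaled so each sample sums to exactly 1.
* **Prediction tables.** Two sources per edge class; every planted edge in
  both, decoys uniform and independent per source.

What the generator does **not** emulate: batch effects, GC/length biases,
isoform structure, zero-inflation beyond the NB, correlated decoy edges
between prediction sources, informative censoring, or molecular subtypes
beyond Bernoulli flags. Passing the recovery tests therefore shows the
pipeline is correct *under its own assumptions*; it does not certify
performance on real cohorts where those nuisances are present.

# Problem sizes and numerical choices

The reference synthetic study uses 200 tumor / 50 normal samples, 1000
genes (500 lncRNA / 100 miRNA / 400 mRNA), 10 planted triplets and 500
decoy edges per table; recovery there is essentially deterministic (≥ 9/10
triplets, ≤ 1 false positive, hub ranked first). Cox recovery uses 400
tumors and 200 replicates (mean $\hat\beta$ within ±0.05 of $\log 1.74$,
CI coverage 0.92–0.97); null calibrations use 1000–2000 replicates per
test. These sizes give Monte-Carlo error comfortably below the asserted
tolerances while keeping a full run of suite plus acceptance script in the
low minutes.

Other numerical decisions:

* Rank tests use average ranks with tie-corrected variances; exact
  enumeration for small samples (≤ 12 observations rank-sum / signed-rank)
  where base R's exact paths decline ties.
* Spearman p-values use the t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$; an exact permutation mode exists for
  $n \le 8$. At cohort sizes the two are indistinguishable. At $n = 5$ the
  permutation distribution's atoms exceed 0.05, so no continuous
  approximation can track it to that tolerance — small-sample agreement is
  asserted for $n \ge 6$.
* Two-sided p-values throughout.
* Cox fits use the Newton–Raphson of the standard survival machinery with
  Efron ties; an independently coded partial-likelihood grid oracle checks
  the estimates to $10^{-4}$ in tests. Suspected monotone likelihood
  (separation) is flagged on the result rather than silently reported.
* All generators are seeded; one seed reproduces every file byte for byte.
  Output files carry a provenance header (package version, configuration
  hash, seed) and no timestamps, precisely so replays are byte-identical.

# Known limitations

* The moderated-t is a self-contained method-of-moments variant, not a
  drop-in reimplementation of any specific tool; with voom-style precision
  weights or trended priors results will differ at the margins.
* The triplet screen is marginal-correlation-based; it does not attempt
  partial-correlation or conditional-independence analysis, and it cannot
  distinguish sponging from co-regulation by a shared transcription
  factor. That distinction requires perturbation experiments, which are the
  domain of the qPCR utilities.
* The optimal-cutpoint p-value is uncorrected by design and must not be
  quoted as a confirmatory result.
* No batch correction, covariate-adjusted DE, time-varying covariates,
  stratified Cox, or multi-level permutation refinement.
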