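---
title: "Methods: xWAS, conditional signal decomposition and colocalization"
author: "coloxwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: xWAS, conditional signal decomposition and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`coloxwas` implements a summary-statistics inference chain that nominates
putatively causal genes and proteins for complex traits — the design is the
one used in large kidney-function screens, where GWAS meta-analyses of
filtration markers (eGFRcr, eGFRcys, BUN) and a damage marker (ACR) are
integrated with tissue eQTL and plasma pQTL prediction models:

1. **cis prediction models** — elastic-net weights predicting a molecular
   feature (a transcript in a tissue, or a plasma protein aptamer) from
   nearby SNP dosages;
2. **TWAS/PWAS (xWAS)** — association of the genetically predicted feature
   with a trait, computed from GWAS summary statistics and an LD reference;
3. **COJO** — stepwise approximate conditional & joint analysis decomposing
   each associated region into conditionally independent signals;
4. **colocalization** — Wakefield approximate Bayes factors per signal and
   five-hypothesis posteriors for every (QTL signal, trait signal) pair;
5. **genomic regions** — recursive merging of significant features into
   regions and assembly of per-trait colocalization support;
6. **conditional prioritization** — cis-regulated genetic correlations
   between features, and pairwise conditional xWAS z-scores that decide
   whether two features in a region carry the same or independent signals.

Because the consortium GWAS and QTL panels that motivated this design are
not redistributable, the package ships a synthetic-data module that
generates LD panels, cis-heritable features and mediated GWAS summary
statistics with known ground truth, so every stage is verifiable at desk
scale.

# Models and statistics

## Elastic-net cis models

For a feature with gene span $[s, e]$, SNPs within `cis_window_bp`
(default 500 kb, the same constant used for region merging) are
standardized and the feature regressed on them with the elastic net
(`l1_ratio` default 0.5, 5-fold cross-validation, 20 log-spaced penalties).
The penalty with the best cross-validated prediction *correlation* is
selected — this criterion, rather than CV mean squared error, is what the
downstream accuracy field `training_r2` reports, so the CV loop is written
here instead of delegating to `cv.glmnet`. A feature is flagged
*untrainable* when the best CV correlation is not distinguishable from
zero. Because the best correlation is a maximum over the penalty grid, it
is positive by chance for most pure-noise features; the gate therefore uses
a one-sided Fisher-z test at the 0.01 level rather than a comparison with
zero, which flags about 95% of pure-noise features while leaving genuinely
cis-heritable features (CV correlation an order of magnitude above the
gate) untouched.

Features are z-standardized only; no rank normalization is applied before
training. Dosage standardization uses panel-estimated frequencies, not the
stated ones, for internal consistency between training and imputation.

## The xWAS statistic

With weight vector $w$, GWAS z-scores $z$ and reference LD correlation $R$
over the model SNPs surviving harmonization,

$$ z_{\mathrm{xWAS}} = \frac{w' z}{\sqrt{w' R w}} . $$

$R$ is ridge-stabilized as $\mathrm{cov2cor}(R + 0.01 I)$: adding to the
diagonal and renormalizing keeps unit diagonal and exact zero off-diagonal
entries, so single-SNP and orthogonal cases are unaffected while
near-singular reference panels stay invertible. The same stabilization
constant is used everywhere a reference correlation matrix is inverted or
factorized. Results are flagged *degraded* when fewer than half the model
weights survive harmonization (flag, not drop).

Multiple testing uses a Bonferroni threshold over *unique* features: a
gene modelled in several tissues counts once, an aptamer once. With 12,893
unique genes at $\alpha = 0.05$ this gives $3.9\times10^{-6}$, and with
1342 unique aptamers $3.7\times10^{-5}$ — the two analytic thresholds the
acceptance script reproduces.

## Approximate conditional & joint analysis

The joint model of a selected SNP set is reconstructed from marginal
statistics: diagonal cross-products $D_k = 2 f_k (1-f_k) N_k$,
off-diagonals $r_{jk}\sqrt{2f_j(1-f_j)\,2f_k(1-f_k)}\,\min(N_j,N_k)$
(conservative pairwise sample-size reconciliation), right-hand side
$D_k b_k$. The per-SNP phenotypic variance is estimated as
$2 f_k (1-f_k)(N_k\,se_k^2 + b_k^2)$ — the simple-regression identity up to
$O(1/N)$ — with the region median taken as $\mathrm{var}(y)$, and the
residual degrees of freedom are $\min(N) - |\mathrm{set}|$. A one-SNP
"joint" fit returns the marginal statistics themselves: the joint model of
a single SNP *is* the marginal model, and this convention makes the
reduction exact rather than exact-up-to-$N/(N-1)$.

Stepwise selection (`cojo_slct`) seeds with the smallest marginal p-value
below `p_entry` (default $5\times10^{-8}$), then repeatedly adds the SNP
with the smallest conditional p-value below the threshold whose reference
$r^2$ with every selected SNP is at most `collinearity` (default 0.1 — far
stricter than generic defaults, exposed as a flag). After each addition a
backward check drops selected SNPs whose joint p-value rises above the
entry threshold; the backward step can be disabled. A SNP dropped by the
backward check is excluded from re-entry, which guarantees termination.
Ties in minimal p-value break by smaller genomic position, for
determinism. Conditional statistics mask (report as missing, never zero)
any target SNP with $r^2$ above the collinearity cutoff to a conditioning
SNP. The conditional standard error uses the residual variance of the
conditioning-set joint model divided by the target's $D_k$, which reduces
to the marginal standard error under orthogonality; the whole procedure is
asserted against exact least squares on individual-level data when the
panel *is* the GWAS sample.

## Fine-mapping and colocalization

Per-SNP evidence is the Wakefield log approximate Bayes factor with
$V = se^2$, prior variance $W$ (default $0.15^2$ for quantitative traits):

$$ \mathrm{labf} = \tfrac12\left[\ln\frac{V}{V+W} +
   z^2\,\frac{W}{V+W}\right], $$

and posterior inclusion probabilities are the softmax of the labfs
(log-sum-exp, stable for spreads far beyond 700).

For a pair of signals with labf vectors over a common SNP set, the five
hypothesis masses are $L_0 = 1$, $L_1 = p_1 S_1$, $L_2 = p_2 S_2$,
$L_3 = p_1 p_2 (S_1 S_2 - C)$, $L_4 = p_{12} C$ with
$S_i = \sum_k e^{\mathrm{labf}_{ik}}$ and
$C = \sum_k e^{\mathrm{labf}_{1k} + \mathrm{labf}_{2k}}$, all accumulated
in log space; $L_3$ uses a `log1p` difference and clamps tiny negative
rounding to zero. Default priors are the conventional
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, all overridable. A pair is
reported colocalized when $PP(H_4) \ge 0.8$. The masses are verified
against explicit enumeration of every causal configuration for up to 12
SNPs.

`conditional_coloc` works on the gene span plus a 250-kb flank: both the
QTL and the trait statistics are decomposed with `cojo_slct`; a dataset
with two or more leads contributes one conditional statistics table per
lead (each conditioned on all other leads — never mixing marginal and
conditional within a signal), a dataset with one or no lead contributes
its marginals. Every (QTL signal, trait signal) combination is evaluated;
pairs sharing fewer than 10 SNPs are flagged low-coverage rather than
silently dropped.

## Regions and multi-trait support

Significant features merge into a region whenever their gene spans padded
by 500 kb overlap, closed under transitivity; overlap is closed-interval,
so touching endpoints merge. The region span is reported as the hull of
the padded member spans (clamped at 1 bp) — the merging sweep guarantees
these hulls are pairwise disjoint, making the operation idempotent. The
MHC (chromosome 6, 25.5–34 Mb) is one fixed region: any feature whose
padded span touches it is absorbed, even a single gene, and the reported
span stays 25.5–34 Mb. Region ids follow genomic order.

A region-trait pair is *supported* when at least one member feature is
xWAS-significant for the trait and at least one of its colocalization
pairs reaches the $PP(H_4)$ threshold. Supported regions whose traits'
minimal regional GWAS p-values all exceed $5\times10^{-8}$ are flagged as
detected through TWAS/PWAS only. Overlap counts are produced for every
nonempty trait subset.

## Cis-regulated genetic correlation and conditional xWAS

Two features' weight models are imputed into a common reference panel and
their Pearson correlation is the cis-regulated genetic correlation $\rho$.
The conditional association of feature $a$ given feature $b$ is

$$ z_{a|b} = \frac{z_a - \rho\, z_b}{\sqrt{1 - \rho^2}} , $$

the z-score analogue of summary-statistics conditioning. When
$|\rho| \ge 0.9$ the two associations are statistically inseparable and a
collinearity (shared-signal) verdict is returned instead of a number; the
bound is configurable — in practice correlations around $\pm0.9$ are
treated as one underlying association. Verdicts over ordered candidate
pairs: *independent* when both directions retain significance at the
modality's Bonferroni threshold, *explained* when one direction drops
while the other stands, *shared_attenuated* when both drop or the
collinearity bound is hit. Multi-way conditioning is approximated by
iterated pairwise application.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested:

* **LD panel** — haplotypes are thresholded latent Gaussian AR(1)
  processes (adjacent correlation `ld_decay`, default 0.7) at per-SNP MAF
  quantiles (MAF uniform on 0.05–0.5); two independent haplotypes sum to a
  dosage. This gives controllable, blockwise-extendable decay; adjacent
  dosage correlations match a bivariate-normal orthant calculation.
  Allele pairs are deterministic per SNP index and never strand-ambiguous.
* **features** — weighted sums of 1–3 standardized causal dosages plus
  noise, rescaled so the empirical genetic variance fraction equals
  `h2_cis` (default 0.2, a typical cis heritability for expression).
* **trait GWAS** — z-scores are drawn directly from their asymptotic
  sampling distribution, $z \sim N(\sqrt{n}\,R b,\ R)$, rather than by
  simulating millions of phenotypes; `beta`, `se`, `freq`, `n` are
  back-filled consistently on the standardized-trait scale. Default
  effective sizes are $10^5$ for the trait GWAS and $10^3$ for the QTL
  study — large enough that planted signals sit at the significance
  levels seen in modern GWAS meta-analyses ($|z| \approx 15{-}25$)
  without leaving desk scale. The
  mediation coefficient `alpha_mediation` (default 0.15 SD of trait per SD
  of feature) sizes trait effects; direct (unmediated) trait effects use
  the matched magnitude $\alpha\sqrt{h^2}$.
* **scenarios** — `null` (cis-heritable feature, zero trait effects: the
  feature layer stays trainable so the null exercises the downstream
  xWAS, and the *trait* causal sets in the truth record are empty);
  `single_shared` (one causal SNP shared by two features and the trait);
  `distinct_in_ld` (feature and trait causal SNPs distinct, $r^2$
  targeted at 0.3 by scanning panel pairs); `two_signals` (two features
  on two causal SNPs with $r^2 < 0.05$, both mediating the trait);
  `coregulated_pair` (second feature constructed with genetic value
  $\rho\,g_A + \sqrt{1-\rho^2}\,g_C$ to hit a target cis genetic
  correlation, default $-0.9$, mediating two traits).

Everything is reproducible from `(name, seed)`; the reference panel's
correlation matrix is treated as the population LD both for generation and
analysis, mirroring an in-sample LD reference.

What the generator does **not** emulate: coalescent or demographic
realism, allele-frequency spectra, imputation error, sample overlap
between GWAS, polygenic background outside the simulated region, strand
mismatches, or multi-allelic sites. Passing tests therefore demonstrate
the *inferential machinery* — allele bookkeeping, conditional
decomposition, posterior computation, calibration — not robustness to
real-data pathologies such as mis-specified LD references or population
stratification.

# Numerical and design choices

* Coordinates are 1-based inclusive throughout; all window arithmetic is
  documented as such.
* Strand-ambiguous SNPs (A/T, C/G) are dropped by default during
  harmonization (overridable); matching is by SNP id plus the literal
  allele pair — no positional matching and no strand-complement rescue,
  since identifiers are authoritative in every supported input.
* Degenerate inputs are rejected, not coerced: readers enforce the type
  invariants (unique ids, frequencies in (0,1), `z = beta/se` within
  $10^{-6}$), constant dosage columns are an error, and the simulator
  nudges a single haplotype when a small panel draws a monomorphic column.
* The `fusion_sumstats` dialect (SNP, A1, A2, Z, N) leaves `beta`/`se`
  unset; conditional analysis requires the `full` dialect. A study-level
  N must be supplied when the file carries none.
* p-values are written in scientific notation with 13 significant digits,
  which round-trips to $10^{-12}$ relative.
* Test problem sizes: oracle-equivalence checks run at $n = 5000$
  individuals and 30–50 SNPs; scenario recovery at 100 seeds per scenario
  with 40-SNP regions and a 500-individual reference panel; calibration
  checks at 2000 replicates. These sizes make every Monte Carlo bound in
  the suite sharp while keeping the default test run around a minute.

# Known limitations

* Colocalization assumes at most one causal variant per signal after
  conditioning (the standard five-hypothesis model); multi-causal
  colocalization in one pass is out of scope.
* The conditional xWAS z-score ignores sampling error in the estimated
  cis genetic correlation; with reference panels of 500+ individuals this
  error is second-order.
* COJO's cross-product reconstruction assumes Hardy–Weinberg scaling of
  genotype variances and a shared phenotypic variance across the region;
  both are exact in the simulator and near-exact in practice, but regions
  of extreme LD can still produce spurious extra signals — the strict 0.1
  collinearity cutoff is the guard.
* The pipeline orchestrates a single genomic region per run of the
  simulator; multi-region inputs are handled by the file-level interfaces
  rather than the scenario bundle.
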