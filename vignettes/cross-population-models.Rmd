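---
title: "Cross-population transcriptome prediction with multivariate adaptive shrinkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population transcriptome prediction with multivariate adaptive shrinkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popmash)
```

# The problem

Transcriptome-wide association studies (TWAS) test whether the genetically
regulated component of a gene's expression (GReX) associates with a trait.
The prediction models behind GReX are overwhelmingly trained in European
cohorts, and prediction accuracy decays with genetic distance between the
training and test populations.  popmash builds per-population prediction
models that borrow strength *across* populations: marginal cis-eQTL effects
are estimated separately within each population, shrunken jointly with an
empirical-Bayes multivariate normal mixture in which the populations are the
conditions, and assembled into compact per-population models by selecting,
for each population, the SNP with the lowest local false sign rate (lfsr)
per gene.

# The shrinkage model

For gene-SNP pair $j$, let $\hat\beta_j \in \mathbb{R}^R$ collect the
marginal effect estimates across the $R$ populations and $\hat s_j$ their
standard errors.  The model is

$$\hat\beta_j \mid \beta_j \sim N_R(\beta_j,\; S_j V S_j), \qquad
  \beta_j \sim \sum_{k,l} \pi_{k,l}\, N_R(0,\; \omega_l U_k),$$

with $S_j = \mathrm{diag}(\hat s_j)$ and $V$ the across-population error
correlation (identity by default).  The covariance library $\{U_k\}$
contains canonical patterns — the null (zero) matrix, the identity
(independent effects), one singleton per population (population-specific
effects), the all-ones matrix (fully shared effects), heterogeneity
matrices with off-diagonal 0.25/0.5/0.75 — plus data-driven components:
rank-1 outer products of the top three singular vectors of the strong rows'
z-score matrix and its full empirical covariance, each normalized to unit
maximum diagonal and clipped to positive semidefinite.  The scale grid
$\{\omega_l\}$ is geometric with ratio 2 spanning
$[\min(\hat s)^2/10,\; 2\max(\hat\beta^2)]$.

The mixture weights $\pi$ are fit by EM on the marginal likelihood.  Since
the per-row, per-component densities never change across iterations, they
are computed once; each density uses an eigendecomposition of
$S_j^{-1/2} U_k S_j^{-1/2}$ so that all grid scales come at vector cost.
Posteriors are conjugate per component.  For possibly singular $U$
(the null, the singletons, the rank-1 data-driven components) the inverse-free
form is used:

$$\mu_{jp} = \omega U (\omega U + S_j V S_j)^{-1} \hat\beta_j, \qquad
  \Sigma_{jp} = \omega U (\omega U + S_j V S_j)^{-1} S_j V S_j,$$

mixed over components with the posterior responsibilities.  The local false
sign rate per condition is
$\mathrm{lfsr} = \min\{P(\beta \ge 0 \mid \text{data}),\,
P(\beta \le 0 \mid \text{data})\}$, with the point mass at zero counted in
both tails — so a row carried entirely by the null component has lfsr 1.

Two fitting granularities exist because the combined-across-genes row set
and the gene-at-a-time alternative are both defensible readings of how such
a pipeline can be run; `runMash(..., perGene = FALSE)` (the default) fits
one mixture on the combined gene-SNP rows, `perGene = TRUE` fits within each
gene.  Posteriors are always computed for all rows; the weights are fit on a
random row subset (default cap 5000) as is conventional for this model
family.

## Missing conditions

A SNP can survive QC in one population and not another.  By default such
cells enter the mixture as $\hat\beta = 0$, $\hat s = 10^6$ — the standard
large-variance imputation under which the posterior for the unobserved
condition borrows entirely from the observed ones.  `missingPolicy =
"intersect"` instead drops incomplete rows; both are exposed because
neither choice is canonical.

# Model assembly

For each population the gene's SNP with the lowest lfsr is selected (ties
broken deterministically: lowest genomic position, then lexicographic
variant id); the deduplicated union across populations forms the gene's SNP
set, identical in every population's model, so a model never contains more
SNPs per gene than there are populations.  Each population's model carries
its own posterior-mean weights; the effect allele is the alt allele of the
dosage coding.  The marginal-effect baseline (`assembleMatrixEqtlModels()`)
applies the same union construction to per-population p-value argmins with
unadjusted effect sizes, and the elastic-net baseline
(`assembleElasticNetModel()`) fits glmnet with mixing parameter
$\alpha = 0.5$ per gene; genes whose cross-validated model keeps no SNP are
omitted from it.  The penalty is chosen by internal 10-fold
cross-validation (lambda.min) — the established practice for this model
family; a fixed `lambda` can be supplied instead.

Models are written in the PredictDB layout (tables `weights` and `extra`;
SQLite when the RSQLite driver is available, a flat TSV bundle with the
same columns otherwise), with per-gene SNP covariance files
(`GENE RSID1 RSID2 VALUE`, upper triangle) computed in the model's own
population panel with denominator $n-1$.

# Upstream screening

**Genotype QC** removes indels, multiallelic records and ambiguous-strand
SNPs (A/T, T/A, C/G, G/C), then variants with MAF < 0.01 or exact
Hardy-Weinberg p < 1e-6.  The HWE test is the exact conditional test
(two-sided by summing probabilities of heterozygote counts no more probable
than observed), computed in log space.  On chromosome X, HWE applies only
inside the pseudoautosomal regions (GRCh38 intervals by default,
configurable via `metadata(panel)$par`), males must be coded 0/2 outside
them and contribute single alleles to the frequency.  LD pruning is greedy
within sliding windows (500 variants, step 50, r² > 0.2), removing the
lower-MAF variant of an offending pair (ties: later position) and repeating
passes until no intra-window pair exceeds the threshold — the postcondition
is the contract; the tie-break is a documented choice since reference
implementations differ across versions.

**Expression processing** follows a fixed order: log2(TPM + 1) per exam;
per-exam residualization on age and sex; averaging the available exams per
sample; rank-based inverse normal transformation (Blom offset 3/8, average
ranks for ties); residualization on the first 10 genotype and 10 expression
principal components.  The log offset of 1 avoids minus infinity at zero
TPM; expression PCs are computed on the transformed matrix (the stage at
which they are computed is not canonical, so it is pinned and stated);
genotype PCs come from plain PCA on LD-pruned standardized dosages —
kinship-aware PCA is deliberately out of scope, as it changes no testable
contract here.  PCA signs are fixed by making each component's
largest-magnitude loading positive, so results are machine-reproducible.

**Heritability screening** estimates per-gene cis-h² per population by
unconstrained REML on the GCTA-style GRM built from cis SNPs (window = 1 Mb
upstream of the TSS to 1 Mb downstream of the TES, inclusive, floored at
position 1; per-gene MAF ≥ 0.01 after pruning the HWE-filtered panel).
The solver is average-information REML in the eigenbasis of the GRM with
EM-fallback and step halving, converging at relative log-likelihood change
< 1e-8 or 100 iterations; negative variance components are allowed, matching
unconstrained estimation.  The standard error of h² comes from the inverse
average-information matrix by the delta method; the p-value is a
likelihood-ratio test of zero genetic variance against the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (LRT clamped at 0).  A gene is called
heritable when some population has h² − 2·SE > 0.01 and p < 0.05.  Because
the eigendecomposition is reused across phenotypes, screening many genes
against one cis panel is cheap.

# TWAS

`predictGrex()` computes GReX as the weighted effect-allele dosage sum
(missing SNPs contribute zero and are tallied); prediction performance is
Spearman's rank correlation against adjusted observed expression.
`spredixcanGene()` implements the summary-statistics gene test: with weights
$w$, GWAS z-scores $z_l$, reference dosage variances $\sigma_l^2$ and
$\sigma_g^2 = w^\top \Gamma w$ ($\Gamma$ restricted to the harmonized,
GWAS-present SNPs),

$$z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} z_l .$$

Allele harmonization keeps exact matches, flips the sign for swapped
alleles, and drops ambiguous-strand or mismatched records.  Significance is
strict p < 5e-8 (the Bonferroni-corrected GWAS threshold); an association
replicates across two studies when it is significant in both with the same
method/population/tissue model tag and the same direction of effect.

# The synthetic-data generator

The generator emulates a four-population PBMC-like design and is the study
condition for every end-to-end test:

* **Populations.** Four populations with unequal sample sizes
  n = (334, 104, 528, 321) and Fst = (0.10, 0.12, 0.0, 0.05) relative to the
  ancestral pool, mirroring the unequal-n regime in which borrowing strength
  matters most for the smallest population.
* **Genotypes.** Per variant an ancestral frequency p0 ~ Uniform(0.05,
  0.95); population frequencies from the Balding-Nichols Beta distribution;
  haplotypes by thresholding latent AR(1) Gaussians (default correlation
  0.6 within blocks of 10 consecutive variants), dosage = two haplotypes.
  Genes are spaced 2.5 Mb apart (800 genes per synthetic chromosome keeps
  coordinates in 32-bit range) so cis windows never overlap and truth
  bookkeeping is unambiguous.  All variants are non-ambiguous biallelic
  SNPs unless artifact records are requested to exercise QC.
* **Expression.** Per gene: shared architecture (identical effect vector in
  all populations) with probability 0.7, population-specific with 0.2, null
  otherwise; 2 causal SNPs per non-null gene of 20 simulated cis SNPs;
  cis-h² uniform on (0.05, 0.6).  The environmental variance is set from the
  realized genetic variance so the recorded h² equals the simulated variance
  ratio exactly; half the environmental variance is stable between exams and
  half is exam-specific, so two time points are exchangeable and averaging
  them raises effective h² as in repeated-measure designs.  Age and sex act
  linearly on the latent scale; TPM output is exp of the latent value.
  These sharing/architecture defaults are tuning knobs describing a
  plausible regime, not estimates of any real cohort.
* **GWAS.** A quantitative trait sums gene-level effects of causal genes'
  genetic values plus noise at a target trait h² (default 0.3); marginal
  per-variant regression yields beta, SE and z = beta/SE with alleles and
  cohort frequencies.

What the generator does **not** emulate: realistic recombination maps
(LD is blockwise AR(1) and, apart from frequency differences, identically
structured across populations), admixture tracts, imputation dosage
uncertainty, trans-eQTLs, or polygenic trait architectures beyond the
simulated cis effects.  Tests passing on these data therefore demonstrate
the correctness and the qualitative mechanism of the method — not its
quantitative performance on real cohorts, where LD differences between
populations are richer and effect sharing is unknown.

# Verification choices and problem sizes

The test suite checks each numerical core against an independent oracle:
the exact HWE test against direct-arithmetic enumeration (all count triples
with total ≤ 50) and, for tiny samples, against full enumeration over
allele pairings; the mixture density against dense multivariate-normal
evaluation; posterior mean/SD/lfsr against 400×400 grid quadrature on
two-condition rows (the oracle's sign-boundary term gets a Euler-Maclaurin
end correction so its own discretization error stays below the comparison
tolerance); REML against profile-likelihood grids and model-simulated
recovery (n = 1000, M = 500; 20 recovery seeds, 100 coverage replicates);
S-PrediXcan against individual-level GReX regression on one simulated
cohort (n = 5000, 100 genes, exact collapse for single-SNP genes).  The
cross-population mechanism test uses the default four-population design with 200
genes and held-out cohorts of 500 samples per population; per-gene Spearman
rho is averaged over all model-population ≠ test-population scenarios before
the paired Wilcoxon comparison, since the per-scenario rho of two models
that select identical SNPs is identical (rank correlation is invariant to
monotone reweighting of a single SNP) and the scenario average isolates the
systematic between-method difference.  Null TWAS calibration uses 2000
single-top-SNP gene models against a null GWAS cohort of 2000.  These sizes
were chosen so each property is measured well inside its Monte-Carlo error
while the whole suite stays desk-scale.

# Limitations

* The data-driven covariance components use plain SVD of the strong-row
  z-matrix; no extreme-deconvolution refinement is applied.
* The error-correlation matrix V is identity by default; the optional
  estimate (correlation of z among rows with max |z| < 2) is attenuated by
  the truncation and is not iterated.
* Elastic-net models require a penalty choice; cross-validated lambda.min
  is used and recorded, acknowledging that a fixed-path variant without
  cross-validation is equally defensible.
* The heritable-gene fallback in `runPipeline()` (modeling all screened
  genes when none passes the lower-bound call) exists for small demo panels
  and should not be relied on at realistic sample sizes.
* Replication logic requires caller-supplied phenotype pairings between the
  two summary-statistics studies; no automatic phenotype matching is
  attempted.
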