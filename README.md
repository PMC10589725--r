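# popmash

Cross-population transcriptome prediction models via multivariate adaptive
shrinkage, in R.

Transcriptome-wide association studies (TWAS) test whether the genetically
regulated component of gene expression (GReX) associates with a trait. The
prediction models that produce GReX are usually trained in a single —
typically European — population, and their accuracy decays with genetic
distance to the test population. popmash builds per-population models that
borrow strength across populations:

1. **Per-population marginal cis-eQTL effects.** For each gene and cis SNP
   (±1 Mb of TSS/TES), simple OLS of residualized expression on dosage,
   separately within each population, giving effect/SE matrices with
   populations as conditions.
2. **Multivariate adaptive shrinkage.** The effects are modeled as a
   mixture of zero-mean multivariate normals,
   `Bhat_j ~ N(b_j, S_j V S_j)`, `b_j ~ Σ π_{k,l} N(0, ω_l U_k)`, with a
   covariance library of canonical (null, identity, per-population
   singleton, equal-effects, heterogeneity) and data-driven (SVD of strong
   rows) components. Mixture weights are fit by EM; posteriors are
   conjugate per component, mixed by responsibility; the local false sign
   rate (lfsr) — the posterior probability that an effect's reported sign
   is wrong or the effect is zero — scores every gene-SNP-population cell.
3. **Top-SNP model assembly.** Per population, each gene's lowest-lfsr SNP
   is selected; the deduplicated union across populations forms a shared
   per-gene SNP set (never more SNPs than populations), weighted by each
   population's posterior means. PredictDB-style output (weights + extra
   tables, per-gene SNP covariance files) makes the models usable for
   individual-level prediction and summary-statistics TWAS.

Around the core: variant QC (indel/multiallelic/ambiguous-strand removal,
MAF ≥ 0.01, exact Hardy-Weinberg p ≥ 1e-6 with chromosome-X rules, greedy
windowed LD pruning), the expression pipeline (log2, age/sex
residualization, exam averaging, inverse-normal transform, genotype and
expression PC adjustment), unconstrained average-information GREML
cis-heritability screening (heritable iff h² − 2·SE > 0.01 and p < 0.05 in
some population), marginal-effect and elastic-net (glmnet, α = 0.5)
baseline models, GReX prediction with Spearman evaluation, S-PrediXcan-style
summary TWAS (`z_g = Σ w_l (σ_l/σ_g) z_l`) with Bonferroni significance
(p < 5e-8) and same-direction cross-study replication, plus a
multi-population simulator (Balding-Nichols allele-frequency divergence,
AR(1)-block LD, shared/population-specific heritable expression, GWAS
summary statistics) that makes the whole pipeline testable without any
external data.

## Worked example

Four simulated populations with unequal sample sizes (334/104/528/321), 40
genes; QC, adjustment, shrinkage, model assembly, and a summary-statistics
TWAS on a simulated GWAS cohort:

```r
library(popmash)

cfg <- simConfig(nPopulations = 4L, nSamplesPerPop = c(334L, 104L, 528L, 321L),
                 nGenes = 40L, seed = 42L)
panels <- simulateGenotypes(cfg)
sim <- simulateExpression(panels, cfg)

adjusted <- list()
for (p in names(panels)) {
  qc <- filterVariants(panels[[p]])
  pruned <- ldPrune(qc, window = 50L, step = 10L)
  gpcs <- computePCs(t(dosageMatrix(qc[pruned, ])), k = 10L)$scores
  adjusted[[p]] <- adjustExpression(lapply(sim$expression[[p]], filterLowExpression),
                                    sim$covariates, genotypePCs = gpcs)
}

eff <- buildEffectMatrices(lapply(panels, filterVariants), adjusted)
eff
#> EffectMatrixSet: 780 gene-variant rows x 4 populations ( AFA, CHN, EUR, HIS )

m <- runMash(eff, seed = 42L)
models <- assembleMashrModels(m$posteriors, variantInfo(panels$AFA), tissue = "PBMC")
models$CHN
#> PredictionModel [mashr | CHN | PBMC]: 39 genes, 63 weights
table(modelExtra(models$CHN)$n_snps_in_model)
#>  1  2  3  4
#> 19 17  2  1
```

Most genes end up with one or two SNPs; the count can never exceed the
number of populations (here 4). The model weights are the CHN-specific
posterior-mean effect sizes at the union of the per-population top SNPs.

```r
cohort <- simulateCohortLike(panels$AFA, 5000L, seed = 43L)
gw <- simulateGwas(cohort, sim$truth, cfg, propCausal = 0.25)
covs <- computeModelCovariances(panels$AFA, models$AFA)
twas <- spredixcanAll(models$AFA, gw$stats, covs)
head(twas[order(twas$pvalue), c("gene", "zscore", "pvalue", "n_snps_used")], 5)
#>       gene     zscore        pvalue n_snps_used
#> 20 gene021 -35.093446 8.485747e-270           2
#> 11 gene012 -18.723792  3.167786e-78           1
#> 23 gene024  -6.716353  1.863285e-11           1
#> 35 gene036  -3.912510  9.134158e-05           1
#> 29 gene030  -2.713426  6.659145e-03           1
sum(twas$pvalue < 5e-8, na.rm = TRUE)
#> [1] 3
```

The three genome-wide-significant genes (`gene021`, `gene012`, `gene024`)
are all members of the simulated trait's causal gene set recorded in
`gw$truth@trait`, and the sub-threshold hits (`gene036`, `gene030`) are
causal too — the gene-level z statistics recover the planted architecture.

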