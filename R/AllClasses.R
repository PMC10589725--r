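#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowData assay<- colData<- rowRanges<-
NULL

## GRCh38 pseudoautosomal regions on chromosome X (1-based inclusive).
## Configurable per panel via metadata(panel)$par.
.GRCH38_PAR <- data.frame(
  start = c(10001, 155701383),
  end   = c(2781479, 156030895)
)

#' GenotypePanel: dosage matrix with variant and sample metadata
#'
#' A \linkS4class{RangedSummarizedExperiment} holding one population's
#' genotypes as an alt-allele dosage assay (variants x samples, values in
#' [0, 2]).  Row ranges carry variant position, ref/alt alleles and optional
#' population allele frequency; column data carry sample sex.  Males on
#' non-pseudoautosomal chromosome X must have dosage 0 or 2.
#'
#' @slot population single population label.
#' @export
setClass("GenotypePanel",
  contains = "RangedSummarizedExperiment",
  representation(population = "character")
)

setValidity("GenotypePanel", function(object) {
  msg <- NULL
  d <- SummarizedExperiment::assay(object, "dosage")
  if (length(d) && (min(d) < 0 || max(d) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("ref", "alt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'ref' and 'alt' alleles")
  if (!"sex" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain 'sex'")
  if (length(object@population) != 1L)
    msg <- c(msg, "population must be a single label")
  ## male hemizygous X coded 0/2
  xi <- which(.isChrX(as.character(GenomicRanges::seqnames(object))) &
              !.inPAR(GenomicRanges::start(object), metadata(object)$par))
  if (length(xi)) {
    male <- SummarizedExperiment::colData(object)$sex %in% c("M", "male", 1L)
    if (any(male)) {
      dx <- d[xi, male, drop = FALSE]
      if (length(dx) && any(dx != 0 & dx != 2))
        msg <- c(msg, "male non-PAR X dosages must be 0 or 2")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' ExpressionPanel: expression matrix with gene annotation
#'
#' A \linkS4class{RangedSummarizedExperiment} with one assay `expr`
#' (genes x samples).  Row ranges span TSS..TES (1-based inclusive) with
#' strand; the processing stage is tracked so operations can enforce their
#' preconditions: `tpm` (non-negative), `log_adjusted`, or `residualized`
#' (each gene mean ~ 0).
#'
#' @slot stage processing stage tag.
#' @export
setClass("ExpressionPanel",
  contains = "RangedSummarizedExperiment",
  representation(stage = "character")
)

setValidity("ExpressionPanel", function(object) {
  msg <- NULL
  if (!object@stage %in% c("tpm", "log_adjusted", "residualized"))
    msg <- c(msg, "stage must be one of tpm, log_adjusted, residualized")
  v <- SummarizedExperiment::assay(object, "expr")
  if (object@stage == "tpm" && length(v) && min(v) < 0)
    msg <- c(msg, "TPM values must be non-negative")
  if (object@stage == "residualized" && ncol(v) > 1) {
    if (max(abs(rowMeans(v))) >= 1e-8)
      msg <- c(msg, "residualized gene rows must have mean ~ 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulation configuration for multi-population study designs
#'
#' Defaults emulate a four-population PBMC design with unequal sample sizes
#' (334/104/528/321) and Balding-Nichols allele-frequency divergence.
#'
#' @slot nPopulations number of populations.
#' @slot populations population labels.
#' @slot nSamplesPerPop samples per population (>= 2 each).
#' @slot fstPerPop per-population Fst relative to the ancestral pool, in [0,1).
#' @slot nGenes number of genes.
#' @slot nCisSnpsPerGene cis SNPs simulated per gene.
#' @slot nCausalPerGene causal SNPs per non-null gene.
#' @slot ldBlockSize consecutive variants per LD block.
#' @slot ldRho AR(1) latent haplotype correlation within a block, in [0,1).
#' @slot h2Distribution (min, max) of the per-gene cis-h2 drawn uniformly.
#' @slot sharedEffectFraction probability a gene's causal effects are shared
#'   (identical) across populations.
#' @slot specificEffectFraction probability they are specific to one population.
#' @slot gwasN GWAS cohort size.
#' @slot seed integer seed; fixed seed implies byte-identical output.
#' @export
setClass("SimConfig", representation(
  nPopulations = "integer", populations = "character",
  nSamplesPerPop = "integer", fstPerPop = "numeric",
  nGenes = "integer", nCisSnpsPerGene = "integer", nCausalPerGene = "integer",
  ldBlockSize = "integer", ldRho = "numeric",
  h2Distribution = "numeric",
  sharedEffectFraction = "numeric", specificEffectFraction = "numeric",
  gwasN = "integer", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- NULL
  R <- object@nPopulations
  if (R < 1L) msg <- c(msg, "need at least one population")
  if (length(object@nSamplesPerPop) != R || any(object@nSamplesPerPop < 2L))
    msg <- c(msg, "nSamplesPerPop must have one entry >= 2 per population")
  if (length(object@fstPerPop) != R ||
      any(object@fstPerPop < 0) || any(object@fstPerPop >= 1))
    msg <- c(msg, "fstPerPop must lie in [0, 1) (Fst = 1 is degenerate)")
  if (length(object@populations) != R)
    msg <- c(msg, "populations must have one label per population")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must lie in [0, 1)")
  fr <- c(object@sharedEffectFraction, object@specificEffectFraction)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    msg <- c(msg, "effect fractions must lie in [0,1] and sum to <= 1")
  h2 <- object@h2Distribution
  if (length(h2) != 2 || any(h2 < 0) || any(h2 > 1) || h2[1] > h2[2])
    msg <- c(msg, "h2Distribution must be (min, max) within [0, 1]")
  if (object@nCausalPerGene > object@nCisSnpsPerGene)
    msg <- c(msg, "nCausalPerGene cannot exceed nCisSnpsPerGene")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SimConfig constructor with the four-population default design.
#' @param nPopulations,populations,nSamplesPerPop,fstPerPop,nGenes,nCisSnpsPerGene,nCausalPerGene,ldBlockSize,ldRho,h2Distribution,sharedEffectFraction,specificEffectFraction,gwasN,seed see slots.
#' @export
simConfig <- function(nPopulations = 4L,
                      populations = c("AFA", "CHN", "EUR", "HIS")[seq_len(nPopulations)],
                      nSamplesPerPop = c(334L, 104L, 528L, 321L)[seq_len(nPopulations)],
                      fstPerPop = c(0.10, 0.12, 0.0, 0.05)[seq_len(nPopulations)],
                      nGenes = 10L, nCisSnpsPerGene = 20L, nCausalPerGene = 2L,
                      ldBlockSize = 10L, ldRho = 0.6,
                      h2Distribution = c(0.05, 0.6),
                      sharedEffectFraction = 0.7, specificEffectFraction = 0.2,
                      gwasN = 5000L, seed = 1L) {
  if (is.null(populations)) populations <- paste0("POP", seq_len(nPopulations))
  new("SimConfig",
      nPopulations = as.integer(nPopulations), populations = populations,
      nSamplesPerPop = as.integer(nSamplesPerPop), fstPerPop = as.numeric(fstPerPop),
      nGenes = as.integer(nGenes), nCisSnpsPerGene = as.integer(nCisSnpsPerGene),
      nCausalPerGene = as.integer(nCausalPerGene),
      ldBlockSize = as.integer(ldBlockSize), ldRho = as.numeric(ldRho),
      h2Distribution = as.numeric(h2Distribution),
      sharedEffectFraction = as.numeric(sharedEffectFraction),
      specificEffectFraction = as.numeric(specificEffectFraction),
      gwasN = as.integer(gwasN), seed = as.integer(seed))
}

#' Ground truth emitted by the simulator
#'
#' @slot effects data.frame(gene, variant, population, beta): true causal
#'   effects per alt-allele dosage unit; zero rows are omitted.
#' @slot h2 data.frame(gene, population, h2): the variance ratio
#'   Var(Xb)/Var(y) targeted in simulation.
#' @slot architecture data.frame(gene, type): shared / specific / null.
#' @slot trait data.frame(gene, effect): trait-level causal genes (filled by
#'   [simulateGwas()]).
#' @export
setClass("TruthSet", representation(
  effects = "data.frame", h2 = "data.frame",
  architecture = "data.frame", trait = "data.frame"
))

#' Per-population marginal eQTL effects across conditions
#'
#' Long set of (gene, variant) rows with effect estimates and standard errors
#' across R population conditions; the input to the shrinkage core.  Cells
#' where a variant was absent or filtered in a population are unobserved
#' (mask FALSE); they are imputed as Bhat = 0, Shat = 1e6 when handed to the
#' mixture model so the posterior borrows entirely from observed conditions.
#'
#' @slot genes,variants row index of (gene, variant) pairs.
#' @slot bhat,shat,pval matrices rows x populations.
#' @slot df residual degrees of freedom per population.
#' @slot observed logical mask rows x populations.
#' @export
setClass("EffectMatrixSet", representation(
  genes = "character", variants = "character",
  bhat = "matrix", shat = "matrix", pval = "matrix",
  df = "numeric", observed = "matrix"
))

setValidity("EffectMatrixSet", function(object) {
  msg <- NULL
  dm <- dim(object@bhat)
  if (!identical(dim(object@shat), dm) || !identical(dim(object@observed), dm))
    msg <- c(msg, "bhat, shat, observed must share dimensions")
  if (length(object@genes) != dm[1] || length(object@variants) != dm[1])
    msg <- c(msg, "row index length mismatch")
  if (any(object@shat[object@observed] <= 0))
    msg <- c(msg, "Shat must be > 0 where observed")
  if (any(!is.finite(object@bhat[object@observed])))
    msg <- c(msg, "Bhat must be finite where observed")
  if (is.null(msg)) TRUE else msg
})

#' Covariance library for the multivariate shrinkage mixture
#'
#' @slot Ulist named list of R x R symmetric PSD matrices (includes labels
#'   such as null, identity, singleton_<pop>, equal_effects, het_<q>,
#'   pca_<m>, empirical).
#' @slot grid strictly increasing positive scale grid.
#' @slot populations condition labels.
#' @export
setClass("CovarianceLibrary", representation(
  Ulist = "list", grid = "numeric", populations = "character"
))

setValidity("CovarianceLibrary", function(object) {
  msg <- NULL
  if (!"null" %in% names(object@Ulist))
    msg <- c(msg, "library must include the null (zero) component")
  if (any(diff(object@grid) <= 0) || any(object@grid <= 0))
    msg <- c(msg, "grid must be strictly increasing and positive")
  for (nm in names(object@Ulist)) {
    U <- object@Ulist[[nm]]
    if (!isSymmetric(unname(U), tol = 1e-8))
      msg <- c(msg, paste0("component ", nm, " not symmetric"))
    ev <- min(eigen(U, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) msg <- c(msg, paste0("component ", nm, " not PSD"))
  }
  if (is.null(msg)) TRUE else msg
})

#' Fitted shrinkage mixture
#'
#' @slot library the covariance library.
#' @slot pi mixture weights over (component, scale) pairs plus the null;
#'   non-negative, summing to one.
#' @slot loglik log-likelihood trace over EM iterations (nondecreasing).
#' @slot niter EM iterations used.
#' @slot V across-population error correlation used in the fit.
#' @export
setClass("MashFit", representation(
  library = "CovarianceLibrary", pi = "numeric",
  loglik = "numeric", niter = "integer", V = "matrix"
))

setValidity("MashFit", function(object) {
  msg <- NULL
  if (any(object@pi < 0)) msg <- c(msg, "pi must be non-negative")
  if (abs(sum(object@pi) - 1) > 1e-12) msg <- c(msg, "pi must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' Posterior summaries per (gene, variant) row and population
#'
#' @slot genes,variants row index.
#' @slot populations condition labels.
#' @slot postMean,postSD,lfsr matrices rows x populations; lfsr is the local
#'   false sign rate: min of the posterior probabilities that the effect is
#'   >= 0 and <= 0 (the point mass at zero counts in both).
#' @export
setClass("PosteriorSet", representation(
  genes = "character", variants = "character", populations = "character",
  postMean = "matrix", postSD = "matrix", lfsr = "matrix"
))

setValidity("PosteriorSet", function(object) {
  msg <- NULL
  if (any(object@lfsr < -1e-12 | object@lfsr > 1 + 1e-12))
    msg <- c(msg, "lfsr must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Transcriptome prediction model (PredictDB-style)
#'
#' @slot method model method tag (mashr, matrixeqtl, en).
#' @slot population training population label.
#' @slot tissue tissue label.
#' @slot weights data.frame(gene, rsid, chrom, pos, ref_allele, eff_allele,
#'   weight): weight is on the residualized-expression SD scale per
#'   effect-allele dosage unit; eff_allele is the alt allele of the dosage
#'   coding.
#' @slot extra data.frame(gene, genename, n_snps_in_model, pred_perf_R2,
#'   pred_perf_pval).
#' @export
setClass("PredictionModel", representation(
  method = "character", population = "character", tissue = "character",
  weights = "data.frame", extra = "data.frame"
))

setValidity("PredictionModel", function(object) {
  msg <- NULL
  w <- object@weights
  need <- c("gene", "rsid", "ref_allele", "eff_allele", "weight")
  if (!all(need %in% colnames(w)))
    msg <- c(msg, "weights must have gene, rsid, ref_allele, eff_allele, weight")
  if (nrow(w) && anyDuplicated(paste(w$gene, w$rsid)))
    msg <- c(msg, "duplicate variant within a gene")
  if (is.null(msg)) TRUE else msg
})

#' Per-gene dosage covariance matrices for a model's SNPs
#'
#' @slot population panel in which covariances were computed.
#' @slot covariances named list (by gene) of symmetric matrices, sample
#'   covariance with denominator n - 1, dimension n_snps_in_model.
#' @export
setClass("CovarianceSet", representation(
  population = "character", covariances = "list"
))
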