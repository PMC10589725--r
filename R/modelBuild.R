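## Assembly of per-population transcriptome prediction models.  For the
## shrinkage (MASHR-style) models: per population, the gene's SNP with the
## lowest lfsr is selected; the union across populations (deduplicated, so
## at most R SNPs per gene) forms the shared SNP set, and each population's
## model carries its own posterior-mean weights.  Matrix-eQTL-style models
## use the same selection on p-values with unadjusted effect sizes.
## Elastic-net models are the baseline (alpha = 0.5, lambda by internal
## 10-fold cross-validation).

## deterministic argmin with tie-break: lowest genomic position, then
## lexicographic variant id
.argminTieBreak <- function(score, pos, ids) {
  ok <- which(is.finite(score))
  if (!length(ok)) return(NA_integer_)
  m <- min(score[ok])
  cand <- ok[score[ok] <= m]
  if (length(cand) > 1) {
    cand <- cand[order(pos[cand], ids[cand])]
  }
  cand[1]
}

#' Top-SNP selection by local false sign rate
#'
#' For each population, picks the gene's SNP with the lowest lfsr
#' (ties broken by lowest genomic position, then lexicographic variant id)
#' and returns the deduplicated union: between 1 and R variants.
#'
#' @param posteriors a \linkS4class{PosteriorSet}.
#' @param gene gene id.
#' @param variantPos named positions for tie-breaking (optional; defaults to
#'   lexicographic order only).
#' @return character vector of selected variant ids.
#' @export
selectTopSnpsMashr <- function(posteriors, gene, variantPos = NULL) {
  idx <- which(posteriors@genes == gene)
  if (!length(idx)) stop("gene absent from posteriors: ", gene)
  ids <- posteriors@variants[idx]
  pos <- if (is.null(variantPos)) rep(0, length(ids)) else
    variantPos[ids]
  sel <- character(0)
  for (r in seq_along(posteriors@populations)) {
    a <- .argminTieBreak(posteriors@lfsr[idx, r], pos, ids)
    if (!is.na(a)) sel <- union(sel, ids[a])
  }
  sel
}

.topSnpsByColumn <- function(score, ids, pos) {
  sel <- character(0)
  for (r in seq_len(ncol(score))) {
    a <- .argminTieBreak(score[, r], pos, ids)
    if (!is.na(a)) sel <- union(sel, ids[a])
  }
  sel
}

.modelRows <- function(gene, sel, weights, vinfo) {
  vi <- vinfo[match(sel, vinfo$id), ]
  data.frame(gene = gene, rsid = sel, chrom = vi$chrom, pos = vi$pos,
             ref_allele = vi$ref, eff_allele = vi$alt,
             weight = unname(weights[sel]), stringsAsFactors = FALSE)
}

#' Assemble shrinkage-based prediction models
#'
#' Every population's model contains the same selected SNP set per gene
#' (the cross-population union of lowest-lfsr top SNPs), weighted by that
#' population's posterior-mean effect sizes; the effect allele is the alt
#' allele of the dosage coding.  All-zero weights are retained (the gene
#' predicts 0 in that population).
#'
#' @param posteriors a \linkS4class{PosteriorSet}.
#' @param variantTable data.frame(id, chrom, pos, ref, alt) covering the
#'   posterior variants (e.g. [variantInfo()] of a union panel).
#' @param genes genes to include; defaults to all in the posterior set.
#' @param tissue tissue tag.
#' @return named list of \linkS4class{PredictionModel}, one per population.
#' @export
assembleMashrModels <- function(posteriors, variantTable, genes = NULL,
                                tissue = "tissue") {
  if (is.null(genes)) genes <- unique(posteriors@genes)
  pops <- posteriors@populations
  pos <- stats::setNames(variantTable$pos, variantTable$id)
  sets <- list()
  for (g in genes) {
    if (!any(posteriors@genes == g)) next       # skipped, logged
    sets[[g]] <- selectTopSnpsMashr(posteriors, g, variantPos = pos)
  }
  out <- list()
  for (r in seq_along(pops)) {
    rows <- list()
    for (g in names(sets)) {
      idx <- which(posteriors@genes == g)
      w <- stats::setNames(posteriors@postMean[idx, r],
                           posteriors@variants[idx])
      rows[[g]] <- .modelRows(g, sets[[g]], w, variantTable)
    }
    weights <- do.call(rbind, rows)
    extra <- data.frame(gene = names(sets), genename = names(sets),
                        n_snps_in_model = lengths(sets),
                        pred_perf_R2 = NA_real_, pred_perf_pval = NA_real_,
                        stringsAsFactors = FALSE)
    rownames(extra) <- NULL
    out[[pops[r]]] <- new("PredictionModel", method = "mashr",
                          population = pops[r], tissue = tissue,
                          weights = weights, extra = extra)
  }
  out
}

#' Assemble marginal-effect (Matrix-eQTL-style) prediction models
#'
#' Same selection scheme as the shrinkage models -- per population the SNP
#' with the lowest marginal p-value, union across populations -- but the
#' weights are the unadjusted per-population effect sizes.
#'
#' @param effects an \linkS4class{EffectMatrixSet}.
#' @param variantTable data.frame(id, chrom, pos, ref, alt).
#' @param genes genes to include.
#' @param tissue tissue tag.
#' @return named list of \linkS4class{PredictionModel} per population.
#' @export
assembleMatrixEqtlModels <- function(effects, variantTable, genes = NULL,
                                     tissue = "tissue") {
  if (is.null(genes)) genes <- unique(effects@genes)
  pops <- colnames(effects@bhat)
  pos <- stats::setNames(variantTable$pos, variantTable$id)
  sets <- list()
  for (g in genes) {
    idx <- which(effects@genes == g)
    if (!length(idx)) next
    ids <- effects@variants[idx]
    pv <- effects@pval[idx, , drop = FALSE]
    pv[!effects@observed[idx, , drop = FALSE]] <- NA
    sets[[g]] <- .topSnpsByColumn(pv, ids, pos[ids])
  }
  out <- list()
  for (r in seq_along(pops)) {
    rows <- list()
    for (g in names(sets)) {
      idx <- which(effects@genes == g)
      b <- effects@bhat[idx, r]
      b[!effects@observed[idx, r]] <- 0     # unobserved: no contribution
      w <- stats::setNames(b, effects@variants[idx])
      rows[[g]] <- .modelRows(g, sets[[g]], w, variantTable)
    }
    extra <- data.frame(gene = names(sets), genename = names(sets),
                        n_snps_in_model = lengths(sets),
                        pred_perf_R2 = NA_real_, pred_perf_pval = NA_real_,
                        stringsAsFactors = FALSE)
    rownames(extra) <- NULL
    out[[pops[r]]] <- new("PredictionModel", method = "matrixeqtl",
                          population = pops[r], tissue = tissue,
                          weights = do.call(rbind, rows), extra = extra)
  }
  out
}

#' Elastic-net gene model
#'
#' glmnet with mixing parameter alpha = 0.5 on standardized predictors;
#' lambda chosen by internal 10-fold cross-validation (lambda.min).  Genes
#' whose chosen model has no nonzero weight are omitted (returns NULL) --
#' their effect sizes did not converge to a usable model during training.
#'
#' @param cisDosages variants x samples dosage matrix (rownames = ids).
#' @param expression residualized expression vector for the gene.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param nfolds CV folds (default 10).
#' @param seed fold-assignment seed.
#' @param lambda fixed penalty; NULL (default) selects lambda.min by CV.
#' @return named weight vector, or NULL when no SNP is retained.
#' @export
fitElasticNetModel <- function(cisDosages, expression, alpha = 0.5,
                               nfolds = 10L, seed = 1L, lambda = NULL) {
  X <- t(as.matrix(cisDosages))
  stopifnot(nrow(X) >= 10)
  keep <- apply(X, 2, stats::var) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2) {
    ## glmnet needs >= 2 columns; pad with a constant column (its weight is
    ## always zero and it is dropped below)
    if (ncol(X) == 0) return(NULL)
    X <- cbind(X, .pad. = 0)
  }
  set.seed(as.integer(seed))
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(X, expression, alpha = alpha, nfolds = nfolds,
                            standardize = TRUE)
    b <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  } else {
    fit <- glmnet::glmnet(X, expression, alpha = alpha, standardize = TRUE)
    b <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE,
                               x = X, y = expression, alpha = alpha,
                               standardize = TRUE))[-1, 1]
  }
  b <- b[b != 0]
  if (!length(b)) return(NULL)
  b
}

#' Assemble elastic-net prediction models for one population
#'
#' @param panel post-QC \linkS4class{GenotypePanel}.
#' @param expression residualized \linkS4class{ExpressionPanel}.
#' @param genes genes to fit.
#' @param tissue tissue tag.
#' @param alpha,seed passed to [fitElasticNetModel()].
#' @param flank cis window flank.
#' @return a \linkS4class{PredictionModel} (genes with empty models absent).
#' @export
assembleElasticNetModel <- function(panel, expression, genes = NULL,
                                    tissue = "tissue", alpha = 0.5,
                                    seed = 1L, flank = 1000000L) {
  ann <- geneAnnotation(expression)
  if (is.null(genes)) genes <- ann$gene_id
  ex <- exprMatrix(expression)
  shared <- intersect(colnames(panel), colnames(ex))
  vinfo <- variantInfo(panel)
  rows <- list(); extras <- list()
  for (gi in which(ann$gene_id %in% genes)) {
    g <- ann$gene_id[gi]
    win <- cisWindow(ann$tss[gi], ann$tes[gi], chrom = ann$chrom[gi],
                     flank = flank)
    sub <- extractCisSnps(panel[, shared], win)
    if (nrow(sub) == 0) next
    w <- fitElasticNetModel(dosageMatrix(sub), ex[g, shared],
                            alpha = alpha, seed = seed)
    w <- w[names(w) %in% vinfo$id]
    if (is.null(w) || !length(w)) next
    rows[[g]] <- .modelRows(g, names(w), w, vinfo)
    extras[[g]] <- data.frame(gene = g, genename = g,
                              n_snps_in_model = length(w),
                              pred_perf_R2 = NA_real_,
                              pred_perf_pval = NA_real_,
                              stringsAsFactors = FALSE)
  }
  new("PredictionModel", method = "en", population = populationLabel(panel),
      tissue = tissue,
      weights = if (length(rows)) do.call(rbind, rows) else
        data.frame(gene = character(), rsid = character(),
                   chrom = character(), pos = integer(),
                   ref_allele = character(), eff_allele = character(),
                   weight = numeric()),
      extra = if (length(extras)) do.call(rbind, extras) else
        data.frame(gene = character(), genename = character(),
                   n_snps_in_model = integer(), pred_perf_R2 = numeric(),
                   pred_perf_pval = numeric()))
}

#' Pairwise dosage covariances for each gene's model SNPs
#'
#' Sample covariance (denominator n - 1) of the dosage columns of the
#' model's SNPs, computed in the model's own population panel.
#'
#' @param panel the population's \linkS4class{GenotypePanel}.
#' @param model a \linkS4class{PredictionModel}.
#' @return a \linkS4class{CovarianceSet}.
#' @export
computeModelCovariances <- function(panel, model) {
  dos <- dosageMatrix(panel)
  covs <- list()
  w <- modelWeights(model)
  for (g in unique(w$gene)) {
    ids <- w$rsid[w$gene == g]
    present <- ids[ids %in% rownames(dos)]
    if (!length(present)) next
    covs[[g]] <- stats::cov(t(dos[present, , drop = FALSE]))
  }
  new("CovarianceSet", population = populationLabel(panel),
      covariances = covs)
}
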