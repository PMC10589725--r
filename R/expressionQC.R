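## Expression processing: TPM filtering, the log -> covariate-residualize ->
## exam-average -> inverse-normal -> PC-residualize pipeline, PCA, and the
## cross-population gene intersection.

#' Drop genes with low average expression
#'
#' Keeps genes whose mean TPM across samples is at least `minMeanTpm`
#' (the removal rule is strict "<").
#'
#' @param panel an \linkS4class{ExpressionPanel} at stage "tpm".
#' @param minMeanTpm threshold on the gene's mean TPM (default 0.1).
#' @return the filtered panel.
#' @export
filterLowExpression <- function(panel, minMeanTpm = 0.1) {
  stopifnot(expressionStage(panel) == "tpm")
  keep <- rowMeans(exprMatrix(panel)) >= minMeanTpm
  panel[keep, ]
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))}
#' with offset `c` (Blom constant 3/8 by default); ties receive average
#' ranks.  The output is a monotone transform of the input, so any monotone
#' re-scaling of the input yields the identical result.
#'
#' @param values numeric vector, length >= 2, finite.
#' @param c rank offset constant (default 3/8).
#' @return transformed vector.
#' @export
inverseNormalTransform <- function(values, c = 3 / 8) {
  if (length(values) < 2) stop("need at least two values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(values)) == 1L)
    stop("all values identical: rank transform is degenerate")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - c) / (n - 2 * c + 1))
}

#' Principal component scores
#'
#' Top-k right-singular-vector scores of the column-centered matrix
#' (samples x features).  The sign of each component is fixed by making its
#' largest-magnitude loading positive, so results are deterministic.
#'
#' @param mat numeric matrix, samples x features.
#' @param k number of components (capped at min(dim)).
#' @return list with `scores` (samples x k), `loadings` (features x k) and
#'   `varianceExplained` (fraction per component).
#' @export
computePCs <- function(mat, k = 10L) {
  mat <- as.matrix(mat)
  cc <- sweep(mat, 2, colMeans(mat))
  k <- min(k, nrow(mat) - 1L, ncol(mat))
  sv <- svd(cc, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                  diag(sv$d[seq_len(k)], k, k), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  rownames(scores) <- rownames(mat)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       varianceExplained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

## residualize each column of y (samples x features) on design X (no
## intercept column needed: one is added)
.residualize <- function(y, X) {
  X <- cbind(1, X)
  qr.resid(qr(X), y)
}

#' Residualized expression: the full adjustment pipeline
#'
#' Pipeline order: (1) log2(TPM + 1) per exam; (2) per exam, residualize
#' each gene on age and sex; (3) average the available exams per sample (a
#' single exam passes through); (4) rank-based inverse normal transform per
#' gene; (5) residualize on the first `nGenotypePCs` genotype and
#' `nExpressionPCs` expression principal components.  Expression PCs are
#' computed on the step-4 matrix; genotype PCs should come from
#' [computePCs()] on LD-pruned standardized dosages.
#'
#' @param examPanels list of \linkS4class{ExpressionPanel} (stage "tpm"), one
#'   per exam; sample sets may differ (exam averaging uses what is present).
#' @param covariates data.frame with sample_id, age, sex.
#' @param genotypePCs matrix of genotype PC scores (samples x PCs) with
#'   rownames, or NULL to skip.
#' @param nGenotypePCs,nExpressionPCs number of PCs to adjust for.
#' @param logOffset offset inside the log2 transform (default 1).
#' @return an \linkS4class{ExpressionPanel} at stage "residualized".
#' @export
adjustExpression <- function(examPanels, covariates, genotypePCs = NULL,
                             nGenotypePCs = 10L, nExpressionPCs = 10L,
                             logOffset = 1) {
  if (inherits(examPanels, "ExpressionPanel")) examPanels <- list(examPanels)
  stopifnot(length(examPanels) >= 1)
  allSamples <- unique(unlist(lapply(examPanels, colnames)))
  missing <- setdiff(allSamples, covariates$sample_id)
  if (length(missing))
    stop("covariates missing for sample(s): ", paste(missing, collapse = ", "))
  genes <- rownames(examPanels[[1]])
  resids <- lapply(examPanels, function(p) {
    stopifnot(expressionStage(p) == "tpm",
              identical(rownames(p), genes))
    lg <- log2(exprMatrix(p) + logOffset)           # genes x samples
    cv <- covariates[match(colnames(lg), covariates$sample_id), ]
    X <- cbind(age = cv$age, sex = as.integer(cv$sex %in% c("M", "male", 1L)))
    t(.residualize(t(lg), X))                       # per-gene residuals
  })
  ## average exams per sample over the exams where the sample appears
  summed <- matrix(0, length(genes), length(allSamples),
                   dimnames = list(genes, allSamples))
  count <- matrix(0, length(genes), length(allSamples),
                  dimnames = list(genes, allSamples))
  for (rm_ in resids) {
    summed[, colnames(rm_)] <- summed[, colnames(rm_)] + rm_
    count[, colnames(rm_)] <- count[, colnames(rm_)] + 1
  }
  avg <- summed / count
  ## inverse normal per gene
  int <- t(apply(avg, 1, inverseNormalTransform))
  dimnames(int) <- dimnames(avg)
  ## PC adjustment
  epcs <- computePCs(t(int), k = nExpressionPCs)$scores
  design <- epcs
  if (!is.null(genotypePCs)) {
    g <- genotypePCs[match(colnames(int), rownames(genotypePCs)),
                     seq_len(min(nGenotypePCs, ncol(genotypePCs))),
                     drop = FALSE]
    if (anyNA(g)) stop("genotype PCs missing for some expression samples")
    design <- cbind(g, epcs)
  }
  out <- t(.residualize(t(int), design))
  dimnames(out) <- dimnames(int)
  ann <- geneAnnotation(examPanels[[1]])
  ann$gene_id <- genes
  newPanel <- expressionPanel(out, data.frame(
    gene_id = genes, chrom = ann$chrom, tss = ann$tss, tes = ann$tes,
    strand = ann$strand, stringsAsFactors = FALSE), stage = "residualized")
  newPanel
}

#' Genes present in every population panel
#'
#' @param panels list of \linkS4class{ExpressionPanel}.
#' @return gene ids present in all panels, in the first panel's order.
#' @export
intersectGenes <- function(panels) {
  common <- Reduce(intersect, lapply(panels, rownames))
  rownames(panels[[1]])[rownames(panels[[1]]) %in% common]
}
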