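## Per-population marginal cis-eQTL regression (the Matrix-eQTL linear
## model: simple OLS per SNP, no covariates -- expression is already
## residualized upstream), assembled into Bhat/Shat matrices with
## populations as conditions.

#' Marginal regression of expression on dosage
#'
#' Simple linear regression with intercept: beta = cov(x, y)/var(x), the
#' standard error from the residual variance with n - 2 degrees of freedom,
#' p two-sided from the t distribution.  A floor of 1e-12 is applied to the
#' standard error so degenerate (perfect-fit) SNPs do not divide by zero.
#'
#' @param dosage,expression numeric vectors of equal length >= 3.
#' @return list(beta, se, t, p, df).
#' @export
marginalRegression <- function(dosage, expression) {
  n <- length(dosage)
  stopifnot(n >= 3, n == length(expression))
  if (stats::var(dosage) == 0)
    stop("constant dosage: marginal effect undefined")
  xc <- dosage - mean(dosage)
  yc <- expression - mean(expression)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  rss <- max(sum(yc^2) - beta^2 * sxx, 0)
  se <- max(sqrt(rss / (n - 2) / sxx), 1e-12)
  tt <- beta / se
  list(beta = beta, se = se, t = tt,
       p = 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE),
       df = n - 2)
}

## vectorized marginal regression of one gene's expression on a dosage block
.marginalBlock <- function(dos, y) {
  n <- length(y)
  yc <- y - mean(y)
  xc <- dos - rowMeans(dos)
  sxx <- rowSums(xc^2)
  ok <- sxx > 0
  beta <- se <- p <- rep(NA_real_, nrow(dos))
  beta[ok] <- drop(xc[ok, , drop = FALSE] %*% yc) / sxx[ok]
  rss <- pmax(sum(yc^2) - beta[ok]^2 * sxx[ok], 0)
  se[ok] <- pmax(sqrt(rss / (n - 2) / sxx[ok]), 1e-12)
  tt <- beta[ok] / se[ok]
  p[ok] <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(beta = beta, se = se, p = p, observed = ok)
}

#' Build cross-population effect matrices
#'
#' For every gene and cis SNP in the whitelist, runs the marginal regression
#' in each population; cells where a variant is absent or filtered in a
#' population (or has constant dosage) are masked as unobserved rather than
#' zero-filled.
#'
#' @param panels named list of post-QC \linkS4class{GenotypePanel}, one per
#'   population; rowData must carry the owning gene (`gene` column) or gene
#'   windows are taken from `annotation`.
#' @param expressions named list of residualized
#'   \linkS4class{ExpressionPanel} matching `panels`.
#' @param genes gene ids to process (e.g. the heritable set); defaults to
#'   all genes shared across expression panels.
#' @param snpWhitelist variant ids to consider (e.g. SNPs present in the
#'   GWAS study to be used downstream), or NULL for all.
#' @param annotation optional data.frame(gene_id, chrom, tss, tes) when the
#'   panels lack a `gene` rowData column.
#' @param flank cis window flank (default 1e6).
#' @return an \linkS4class{EffectMatrixSet}.
#' @export
buildEffectMatrices <- function(panels, expressions, genes = NULL,
                                snpWhitelist = NULL, annotation = NULL,
                                flank = 1000000L) {
  pops <- names(panels)
  stopifnot(length(pops) >= 1, identical(sort(pops), sort(names(expressions))))
  if (is.null(genes)) genes <- intersectGenes(expressions)
  ## gene -> candidate cis variants, from the union of panels
  geneVars <- .cisVariantMap(panels, genes, annotation, flank)
  if (!is.null(snpWhitelist))
    geneVars <- lapply(geneVars, intersect, snpWhitelist)
  rowsGene <- rep(names(geneVars), lengths(geneVars))
  rowsVar <- unlist(geneVars, use.names = FALSE)
  R <- length(pops)
  nr <- length(rowsVar)
  bhat <- shat <- pval <- matrix(NA_real_, nr, R,
                                 dimnames = list(NULL, pops))
  observed <- matrix(FALSE, nr, R, dimnames = list(NULL, pops))
  df <- stats::setNames(numeric(R), pops)
  for (pp in pops) {
    pan <- panels[[pp]]
    ex <- exprMatrix(expressions[[pp]])
    shared <- intersect(colnames(pan), colnames(ex))
    dos <- dosageMatrix(pan)[, shared, drop = FALSE]
    df[pp] <- length(shared) - 2
    for (g in intersect(unique(rowsGene), rownames(ex))) {
      ridx <- which(rowsGene == g)
      vidx <- match(rowsVar[ridx], rownames(dos))
      present <- !is.na(vidx)
      if (!any(present)) next
      mb <- .marginalBlock(dos[vidx[present], , drop = FALSE],
                           ex[g, shared])
      rows <- ridx[present]
      bhat[rows, pp] <- mb$beta
      shat[rows, pp] <- mb$se
      pval[rows, pp] <- mb$p
      observed[rows, pp] <- mb$observed
    }
  }
  keep <- rowSums(observed) > 0
  new("EffectMatrixSet",
      genes = rowsGene[keep], variants = rowsVar[keep],
      bhat = bhat[keep, , drop = FALSE], shat = shat[keep, , drop = FALSE],
      pval = pval[keep, , drop = FALSE], df = df,
      observed = observed[keep, , drop = FALSE])
}

.cisVariantMap <- function(panels, genes, annotation, flank) {
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (pan in panels) {
    v <- variantInfo(pan)
    if ("gene" %in% colnames(v) && is.null(annotation)) {
      for (g in genes)
        out[[g]] <- union(out[[g]], v$id[v$gene == g])
    } else {
      stopifnot(!is.null(annotation))
      for (gi in which(annotation$gene_id %in% genes)) {
        g <- annotation$gene_id[gi]
        win <- cisWindow(annotation$tss[gi], annotation$tes[gi],
                         chrom = annotation$chrom[gi], flank = flank)
        hit <- v$chrom == win$chrom & v$pos >= win$start & v$pos <= win$end
        out[[g]] <- union(out[[g]], v$id[hit])
      }
    }
  }
  out[lengths(out) > 0]
}

#' Impute unobserved cells for the shrinkage core
#'
#' Returns Bhat/Shat with masked cells replaced by Bhat = 0 and a very large
#' standard error (1e6), the standard large-variance imputation under which
#' an unobserved condition's posterior borrows entirely from the observed
#' ones; or drops incomplete rows when `policy = "intersect"`.
#'
#' @param effects an \linkS4class{EffectMatrixSet}.
#' @param policy "impute" (default) or "intersect".
#' @return list(bhat, shat, genes, variants, observed).
#' @export
imputeEffects <- function(effects, policy = c("impute", "intersect")) {
  policy <- match.arg(policy)
  b <- effects@bhat; s <- effects@shat; m <- effects@observed
  if (policy == "intersect") {
    keep <- rowSums(m) == ncol(m)
    return(list(bhat = b[keep, , drop = FALSE], shat = s[keep, , drop = FALSE],
                genes = effects@genes[keep], variants = effects@variants[keep],
                observed = m[keep, , drop = FALSE]))
  }
  b[!m] <- 0
  s[!m] <- 1e6
  list(bhat = b, shat = s, genes = effects@genes,
       variants = effects@variants, observed = m)
}
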