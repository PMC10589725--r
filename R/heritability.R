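## GREML cis-heritability: cis-window extraction, GCTA-style genetic
## relationship matrix, unconstrained average-information REML (negative
## variance components allowed), and the heritable-gene call
## (h2 - 2*SE > 0.01 and p < 0.05 in at least one population).

#' Cis window around a gene
#'
#' 1 Mb upstream of the TSS to 1 Mb downstream of the TES, 1-based inclusive,
#' floored at position 1.
#'
#' @param tss,tes transcription start/end sites (1-based).
#' @param chrom chromosome label.
#' @param flank flank size in bp (default 1e6).
#' @return list(chrom, start, end).
#' @export
cisWindow <- function(tss, tes, chrom = "1", flank = 1000000L) {
  lo <- min(tss, tes); hi <- max(tss, tes)
  list(chrom = chrom, start = max(1L, lo - flank), end = hi + flank)
}

#' Extract cis SNPs for a gene
#'
#' Variants on the window's chromosome with position in [start, end]
#' (inclusive) and MAF >= `mafMin`.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param window a [cisWindow()] list.
#' @param mafMin per-gene MAF threshold (default 0.01).
#' @return the subset panel.
#' @export
extractCisSnps <- function(panel, window, mafMin = 0.01) {
  v <- variantInfo(panel)
  inWin <- v$chrom == window$chrom & v$pos >= window$start &
    v$pos <= window$end
  dos <- dosageMatrix(panel)
  maf <- rep(0, nrow(v))
  maf[inWin] <- vapply(which(inWin),
                       function(i) .mafFromDosage(dos[i, ]), numeric(1))
  panel[inWin & maf >= mafMin, ]
}

#' GCTA-style genetic relationship matrix
#'
#' A_jk = (1/M) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)) over
#' the M polymorphic SNPs (monomorphic SNPs are excluded from M).
#'
#' @param dosages variants x samples dosage matrix.
#' @return symmetric samples x samples matrix with attribute "M".
#' @export
computeGRM <- function(dosages) {
  dosages <- as.matrix(dosages)
  stopifnot(ncol(dosages) >= 2)
  p <- rowMeans(dosages) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic")
  Z <- (dosages[poly, , drop = FALSE] - 2 * p[poly]) /
    sqrt(2 * p[poly] * (1 - p[poly]))
  M <- sum(poly)
  A <- crossprod(Z) / M
  attr(A, "M") <- M
  A
}

## REML log-likelihood and derivatives in the eigenbasis of the GRM.
## w_i = sg * d_i + se must stay positive; X is the rotated fixed design.
.remlPieces <- function(theta, d, xr, yr) {
  w <- theta[1] * d + theta[2]
  if (min(w) <= 0) return(NULL)
  xtvx <- sum(xr^2 / w)
  xtvy <- sum(xr * yr / w)
  bhat <- xtvy / xtvx
  r <- (yr - xr * bhat) / w              # P y in the eigenbasis
  yPy <- sum(yr * r)
  ll <- -0.5 * (sum(log(w)) + log(xtvx) + yPy)
  list(w = w, xtvx = xtvx, r = r, yPy = yPy, ll = ll)
}

.remlTrPV <- function(pc, d, xr) {
  ## tr(P diag(v)) for v = d (genetic) and v = 1 (residual)
  c(sum(d / pc$w) - sum(xr^2 * d / pc$w^2) / pc$xtvx,
    sum(1 / pc$w) - sum(xr^2 / pc$w^2) / pc$xtvx)
}

.remlProject <- function(v, pc, xr) {
  ## apply P (in the eigenbasis) to a vector v
  v / pc$w - xr / pc$w * sum(xr * v / pc$w) / pc$xtvx
}

#' Unconstrained REML estimation of cis heritability
#'
#' Fits y ~ N(mu 1, sg A + se I) by restricted maximum likelihood with the
#' variance components unconstrained (negative values allowed, as with
#' GCTA's --reml-no-constrain), using average-information updates with
#' EM-step fallback and step halving when a step leaves the feasible region
#' or decreases the likelihood.  h2 = sg / (sg + se); its standard error
#' comes from the inverse average-information matrix by the delta method;
#' the p-value is a likelihood-ratio test of sg = 0 against the boundary
#' mixture (p = 0.5 P(chi2_1 > LRT), LRT clamped at >= 0).
#'
#' @param grm symmetric relationship matrix (or the list returned by
#'   [eigenGRM()] to reuse an eigendecomposition across phenotypes).
#' @param y phenotype vector; an intercept is the only fixed effect.
#' @param maxit maximum iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return data.frame(h2, se, p, sg, se2, loglik, converged, n).
#' @export
remlUnconstrained <- function(grm, y, maxit = 100L, tol = 1e-8) {
  eg <- if (is.list(grm) && !is.null(grm$vectors)) grm else eigenGRM(grm)
  n <- length(y)
  stopifnot(n == length(eg$values))
  yr <- drop(crossprod(eg$vectors, y))
  xr <- eg$xr
  d <- eg$values
  vy <- stats::var(y)
  theta <- c(vy / 2, vy / 2)
  pc <- .remlPieces(theta, d, xr, yr)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    tr <- .remlTrPV(pc, d, xr)
    Pr <- pc$r                    # P y in the eigenbasis
    APy <- d * Pr
    PAPy <- .remlProject(APy, pc, xr)
    PPy <- .remlProject(Pr, pc, xr)
    ## score: -0.5 (tr(P Vi) - y' P Vi P y)
    sc <- -0.5 * c(tr[1] - sum(Pr * APy), tr[2] - sum(Pr * Pr))
    ## average information: 0.5 y' P Vi P Vj P y
    AI <- matrix(0, 2, 2)
    AI[1, 1] <- 0.5 * sum(APy * PAPy)
    AI[1, 2] <- AI[2, 1] <- 0.5 * sum(APy * PPy)
    AI[2, 2] <- 0.5 * sum(Pr * PPy)
    step <- tryCatch(solve(AI, sc), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      ## EM fallback
      step <- c(theta[1]^2 * (sum(Pr * APy) - tr[1]) / n,
                theta[2]^2 * (sum(Pr * Pr) - tr[2]) / n)
    }
    ok <- FALSE
    for (half in 0:10) {
      cand <- theta + step / 2^half
      pcNew <- .remlPieces(cand, d, xr, yr)
      if (!is.null(pcNew) && pcNew$ll >= pc$ll - 1e-10) {
        ok <- TRUE; break
      }
    }
    if (!ok) { converged <- TRUE; break }   # no uphill step left: at optimum
    relchange <- abs(pcNew$ll - pc$ll) / (abs(pc$ll) + 1)
    theta <- cand; pc <- pcNew
    if (relchange < tol) { converged <- TRUE; break }
  }
  ## AI matrix at the optimum for standard errors
  Pr <- pc$r
  APy <- d * Pr
  PAPy <- .remlProject(APy, pc, xr)
  PPy <- .remlProject(Pr, pc, xr)
  AI <- matrix(0, 2, 2)
  AI[1, 1] <- 0.5 * sum(APy * PAPy)
  AI[1, 2] <- AI[2, 1] <- 0.5 * sum(APy * PPy)
  AI[2, 2] <- 0.5 * sum(Pr * PPy)
  Vtheta <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  tot <- theta[1] + theta[2]
  h2 <- theta[1] / tot
  grad <- c(theta[2], -theta[1]) / tot^2
  seh2 <- sqrt(max(drop(t(grad) %*% Vtheta %*% grad), 0))
  ## null model: V = se I
  ll0 <- .remlNullLoglik(yr, xr)
  lrt <- max(2 * (pc$ll - ll0), 0)
  p <- max(0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE),
           .Machine$double.xmin)
  if (lrt == 0) p <- 1
  data.frame(h2 = h2, se = seh2, p = p, sg = theta[1], se2 = theta[2],
             loglik = pc$ll, converged = converged, n = n)
}

.remlNullLoglik <- function(yr, xr) {
  n <- length(yr)
  xtx <- sum(xr^2)
  bhat <- sum(xr * yr) / xtx
  rss <- sum((yr - xr * bhat)^2)
  s2 <- rss / (n - 1)
  -0.5 * (n * log(s2) + log(xtx / s2) + rss / s2)
}

#' Eigendecomposition bundle for REML
#'
#' Decomposes the GRM once so repeated [remlUnconstrained()] calls on
#' different phenotypes reuse it (the per-fit cost becomes O(n) per
#' iteration).
#' @param grm symmetric relationship matrix.
#' @return list(values, vectors, xr) with xr the rotated intercept.
#' @export
eigenGRM <- function(grm) {
  eg <- eigen(grm, symmetric = TRUE)
  list(values = eg$values, vectors = eg$vectors,
       xr = drop(crossprod(eg$vectors, rep(1, nrow(grm)))))
}

#' Heritability estimates for a set of genes in one population
#'
#' LD pruning is expected to have been applied to the panel before calling
#' (the pruning -> cis extraction -> MAF order matches the screening
#' pipeline).
#'
#' @param panel pruned \linkS4class{GenotypePanel}.
#' @param expression residualized \linkS4class{ExpressionPanel}.
#' @param mafMin per-gene MAF threshold.
#' @param flank cis window flank.
#' @return data.frame(gene, population, n, M, h2, se, p, converged).
#' @export
estimateHeritability <- function(panel, expression, mafMin = 0.01,
                                 flank = 1000000L) {
  ann <- geneAnnotation(expression)
  ex <- exprMatrix(expression)
  shared <- intersect(colnames(ex), colnames(panel))
  out <- list()
  for (gi in seq_len(nrow(ann))) {
    g <- ann$gene_id[gi]
    win <- cisWindow(ann$tss[gi], ann$tes[gi], chrom = ann$chrom[gi],
                     flank = flank)
    sub <- extractCisSnps(panel[, shared], win, mafMin = mafMin)
    if (nrow(sub) < 1) next
    grm <- tryCatch(computeGRM(dosageMatrix(sub)), error = function(e) NULL)
    if (is.null(grm)) next
    fit <- remlUnconstrained(grm, ex[g, shared])
    out[[g]] <- data.frame(gene = g, population = populationLabel(panel),
                           n = length(shared), M = attr(grm, "M"),
                           h2 = fit$h2, se = fit$se, p = fit$p,
                           converged = fit$converged,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Heritable-gene call across populations
#'
#' TRUE for a gene iff any population satisfies h2 - 2 se > `lb` and
#' p < `alpha`; non-converged estimates are excluded.
#'
#' @param estimates data.frame as from [estimateHeritability()], possibly
#'   concatenated across populations.
#' @param lb lower-bound threshold on h2 - 2 se (default 0.01).
#' @param alpha significance level (default 0.05).
#' @return named logical vector per gene.
#' @export
callHeritable <- function(estimates, lb = 0.01, alpha = 0.05) {
  est <- estimates[estimates$converged, , drop = FALSE]
  ok <- est$h2 - 2 * est$se > lb & est$p < alpha
  tapply(ok, est$gene, any)[unique(estimates$gene)]
}
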