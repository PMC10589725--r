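## Empirical-Bayes multivariate adaptive shrinkage across populations.
## Effects b_j for row j (a gene-SNP pair) across R conditions are modeled
## as a mixture of zero-mean multivariate normals  b_j ~ sum_p pi_p
## N(0, omega_l U_k), observed as Bhat_j ~ N(b_j, S_j V S_j).  The mixture
## weights are fit by EM on the marginal likelihood (the per-row,
## per-component densities do not change across iterations, so they are
## computed once); posteriors are conjugate per component and mixed with
## the posterior responsibilities.  The local false sign rate per condition
## is min{P(b >= 0 | data), P(b <= 0 | data)}, both including the point
## mass at zero.

.LOG2PI <- log(2 * pi)

## symmetric square root / inverse square root of S V S for one row
.rowTsq <- function(s, V = NULL) {
  if (is.null(V)) {
    list(sq = s, isq = 1 / s, logdet = 2 * sum(log(s)), diagonal = TRUE)
  } else {
    T <- outer(s, s) * V
    eg <- eigen(T, symmetric = TRUE)
    ev <- pmax(eg$values, 1e-12)
    list(sq = eg$vectors %*% (sqrt(ev) * t(eg$vectors)),
         isq = eg$vectors %*% (1 / sqrt(ev) * t(eg$vectors)),
         logdet = sum(log(ev)), diagonal = FALSE)
  }
}

## per-row workhorse: log-density per mixture component, and (optionally,
## when pi is supplied) posterior mean / SD / sign probabilities
.mashRow <- function(b, s, Ulist, grid, V = NULL, pi = NULL) {
  R <- length(b)
  Ts <- .rowTsq(s, V)
  zt <- if (Ts$diagonal) b * Ts$isq else drop(Ts$isq %*% b)
  Ks <- names(Ulist)
  nonNull <- setdiff(Ks, "null")
  L <- length(grid)
  P <- 1L + length(nonNull) * L
  ll <- numeric(P)
  ll[1] <- -0.5 * (R * .LOG2PI + Ts$logdet + sum(zt^2))   # null component
  post <- NULL
  if (!is.null(pi)) {
    mu <- matrix(0, P, R)       # per-component posterior means
    vr <- matrix(0, P, R)       # per-component posterior variances
  }
  p <- 1L
  for (k in nonNull) {
    U <- Ulist[[k]]
    M <- if (Ts$diagonal) Ts$isq * t(Ts$isq * t(U)) else
      Ts$isq %*% U %*% Ts$isq
    eg <- eigen(M, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    u <- drop(crossprod(eg$vectors, zt))
    B <- if (Ts$diagonal) Ts$sq * eg$vectors else Ts$sq %*% eg$vectors
    for (l in seq_len(L)) {
      p <- p + 1L
      wl <- grid[l] * lam
      ll[p] <- -0.5 * (R * .LOG2PI + Ts$logdet + sum(log1p(wl)) +
                         sum(u^2 / (1 + wl)))
      if (!is.null(pi)) {
        shrink <- wl / (1 + wl)
        mu[p, ] <- drop(B %*% (shrink * u))
        vr[p, ] <- drop((B^2) %*% shrink)
      }
    }
  }
  if (is.null(pi)) return(list(ll = ll))
  lw <- ll + log(pmax(pi, 1e-300))
  m <- max(lw)
  gamma <- exp(lw - m); gamma <- gamma / sum(gamma)
  pm <- drop(crossprod(gamma, mu))
  m2 <- drop(crossprod(gamma, mu^2 + vr))
  psd <- sqrt(pmax(m2 - pm^2, 0))
  ## sign probabilities, point mass at zero counted in both tails
  sd <- sqrt(vr)
  degenerate <- sd < 1e-12
  negP <- posP <- zeroP <- numeric(R)
  for (r in seq_len(R)) {
    dg <- degenerate[, r]
    muz <- abs(mu[, r]) < 1e-12
    zeroP[r] <- sum(gamma[dg & muz])
    negP[r] <- sum(gamma[dg & !muz & mu[, r] < 0]) +
      sum(gamma[!dg] * stats::pnorm(0, mu[!dg, r], sd[!dg, r]))
    posP[r] <- sum(gamma[dg & !muz & mu[, r] > 0]) +
      sum(gamma[!dg] * stats::pnorm(0, mu[!dg, r], sd[!dg, r],
                                    lower.tail = FALSE))
  }
  lfsr <- pmin(negP + zeroP, posP + zeroP)
  list(ll = ll, postMean = pm, postSD = psd, lfsr = pmin(pmax(lfsr, 0), 1))
}

#' Log-density of one row under the mixture
#'
#' log sum_p pi_p N(Bhat; 0, omega_l U_k + S V S), evaluated with a stable
#' log-sum-exp.
#'
#' @param bhatRow,shatRow effect estimates and standard errors across
#'   conditions for one row.
#' @param library a \linkS4class{CovarianceLibrary}.
#' @param pi mixture weights (null first, then component-by-scale in library
#'   order).
#' @param V across-condition error correlation (NULL = identity).
#' @return scalar log-density.
#' @export
mixtureLoglik <- function(bhatRow, shatRow, library, pi, V = NULL) {
  ll <- .mashRow(bhatRow, shatRow, library@Ulist, library@grid, V)$ll
  lw <- ll + log(pmax(pi, 1e-300))
  m <- max(lw)
  m + log(sum(exp(lw - m)))
}

#' Build the covariance library
#'
#' Canonical components: null (zero), identity, one singleton e_r e_r' per
#' condition, equal effects (all-ones), and heterogeneity matrices with unit
#' diagonal and off-diagonal q in `hetGrid`.  Data-driven components come
#' from the strong rows' z-scores: rank-1 outer products of the top `nPCs`
#' right singular vectors plus the full empirical covariance, each
#' normalized to unit maximum diagonal and clipped to PSD.  The scale grid
#' is geometric with ratio 2 spanning [min(Shat)^2 / 10, 2 max(Bhat^2)].
#'
#' @param bhat,shat effect and standard-error matrices (rows x conditions);
#'   used for the grid bounds.
#' @param strongIdx indices of strong rows for the data-driven components;
#'   NULL selects rows with max |z| > 4 (capped at the top 1000 by max |z|,
#'   falling back to the top 1000 overall when fewer than R qualify).
#' @param hetGrid off-diagonal values for heterogeneity components.
#' @param nPCs number of singular vectors for rank-1 data-driven components.
#' @return a \linkS4class{CovarianceLibrary}.  When fewer strong rows than
#'   conditions are available the library is canonical-only, with a warning.
#' @export
buildCovarianceLibrary <- function(bhat, shat, strongIdx = NULL,
                                   hetGrid = c(0.25, 0.5, 0.75), nPCs = 3L) {
  R <- ncol(bhat)
  pops <- colnames(bhat)
  if (is.null(pops)) pops <- paste0("cond", seq_len(R))
  U <- list(null = matrix(0, R, R), identity = diag(R))
  for (r in seq_len(R)) {
    e <- matrix(0, R, R); e[r, r] <- 1
    U[[paste0("singleton_", pops[r])]] <- e
  }
  U$equal_effects <- matrix(1, R, R)
  for (q in hetGrid) {
    m <- matrix(q, R, R); diag(m) <- 1
    U[[paste0("het_", q)]] <- m
  }
  if (is.null(strongIdx)) strongIdx <- .strongRows(bhat, shat)
  if (length(strongIdx) < R) {
    warning("fewer strong rows than conditions: canonical-only library")
  } else {
    z <- bhat[strongIdx, , drop = FALSE] / shat[strongIdx, , drop = FALSE]
    sv <- svd(z)
    for (m_ in seq_len(min(nPCs, ncol(z), nrow(z)))) {
      u1 <- tcrossprod(sv$v[, m_])
      U[[paste0("pca_", m_)]] <- .normalizeU(u1)
    }
    U$empirical <- .normalizeU(crossprod(z) / nrow(z))
  }
  lo <- min(shat[is.finite(shat)])^2 / 10
  hi <- 2 * max(bhat[is.finite(bhat)]^2)
  if (!is.finite(lo) || lo <= 0) lo <- 1e-6
  if (!is.finite(hi) || hi <= lo) hi <- lo * 2
  grid <- lo * 2^(0:ceiling(log2(hi / lo)))
  new("CovarianceLibrary", Ulist = U, grid = grid, populations = pops)
}

.normalizeU <- function(U) {
  eg <- eigen(U, symmetric = TRUE)
  U <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
  U <- (U + t(U)) / 2
  mx <- max(diag(U))
  if (mx > 0) U <- U / mx
  U
}

.strongRows <- function(bhat, shat, zThresh = 4, cap = 1000L) {
  z <- abs(bhat / shat)
  mz <- apply(z, 1, max, na.rm = TRUE)
  idx <- which(mz > zThresh)
  if (length(idx) > cap) idx <- idx[order(mz[idx], decreasing = TRUE)][1:cap]
  if (length(idx) < ncol(bhat))
    idx <- order(mz, decreasing = TRUE)[seq_len(min(cap, length(mz)))]
  idx
}

#' Estimate the across-condition error correlation
#'
#' Correlation of z-scores among rows with max |z| < 2 (approximately null
#' rows), eigenvalue-clipped to be positive definite.
#'
#' @param bhat,shat matrices rows x conditions.
#' @return correlation matrix.
#' @export
estimateErrorCorrelation <- function(bhat, shat) {
  z <- bhat / shat
  mz <- apply(abs(z), 1, max, na.rm = TRUE)
  idx <- which(mz < 2)
  if (length(idx) < 10) return(diag(ncol(bhat)))
  V <- stats::cor(z[idx, , drop = FALSE])
  eg <- eigen(V, symmetric = TRUE)
  V <- eg$vectors %*% (pmax(eg$values, 1e-6) * t(eg$vectors))
  d <- sqrt(diag(V))
  V / outer(d, d)
}

## per-row x per-component log-likelihood matrix (fixed across EM)
.mashLikMatrix <- function(bhat, shat, library, V = NULL) {
  J <- nrow(bhat)
  P <- 1L + (length(library@Ulist) - 1L) * length(library@grid)
  out <- matrix(0, J, P)
  for (j in seq_len(J))
    out[j, ] <- .mashRow(bhat[j, ], shat[j, ], library@Ulist,
                         library@grid, V)$ll
  colnames(out) <- .componentNames(library)
  out
}

.componentNames <- function(library) {
  nonNull <- setdiff(names(library@Ulist), "null")
  c("null", as.vector(t(outer(nonNull, seq_along(library@grid),
                              function(k, l) paste0(k, ";", l)))))
}

#' Fit the mixture weights by EM
#'
#' Maximizes sum_j log sum_p pi_p L_jp over the probability simplex by
#' expectation-maximization (pi_p <- mean over rows of the posterior
#' responsibilities).  The likelihood trace is nondecreasing; convergence is
#' declared when the relative change drops below `tol`.
#'
#' @param bhat,shat matrices rows x conditions (>= 10 rows).
#' @param library a \linkS4class{CovarianceLibrary}.
#' @param V error correlation (NULL = identity).
#' @param maxit,tol EM controls.
#' @return a \linkS4class{MashFit}.
#' @export
fitMixtureWeights <- function(bhat, shat, library, V = NULL,
                              maxit = 1000L, tol = 1e-8) {
  if (length(library@Ulist) == 0) stop("empty covariance library")
  stopifnot(nrow(bhat) >= 10)
  Lm <- .mashLikMatrix(bhat, shat, library, V)
  rowMax <- apply(Lm, 1, max)
  W <- exp(Lm - rowMax)                  # scaled densities, J x P
  P <- ncol(W)
  pi <- rep(1 / P, P)
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    mix <- drop(W %*% pi)
    ll <- sum(log(mix) + rowMax)
    trace <- c(trace, ll)
    gamma <- W * rep(pi, each = nrow(W)) / mix
    piNew <- colMeans(gamma)
    piNew <- piNew / sum(piNew)
    if (it > 1 && abs(trace[it] - trace[it - 1]) /
          (abs(trace[it - 1]) + 1) < tol) {
      pi <- piNew
      break
    }
    pi <- piNew
  }
  names(pi) <- colnames(Lm)
  Vout <- if (is.null(V)) diag(ncol(bhat)) else V
  new("MashFit", library = library, pi = pi, loglik = trace,
      niter = length(trace), V = Vout)
}

#' Posterior means, SDs and local false sign rates
#'
#' Per row and condition, the conjugate per-component posterior
#' N(mu_jp, Sigma_jp) with Sigma_jp = omega U (omega U + SVS)^{-1} SVS and
#' mu_jp = omega U (omega U + SVS)^{-1} Bhat (no inverse of U required, so
#' singular components are handled exactly), mixed over components with the
#' posterior responsibilities.
#'
#' @param bhat,shat matrices rows x conditions.
#' @param fit a \linkS4class{MashFit}.
#' @param genes,variants optional row index labels.
#' @return a \linkS4class{PosteriorSet}.
#' @export
posteriorSummaries <- function(bhat, shat, fit, genes = NULL,
                               variants = NULL) {
  J <- nrow(bhat); R <- ncol(bhat)
  V <- if (isTRUE(all.equal(fit@V, diag(R), tolerance = 1e-12))) NULL else
    fit@V
  pm <- sd <- lf <- matrix(0, J, R,
                           dimnames = list(NULL, fit@library@populations))
  for (j in seq_len(J)) {
    res <- .mashRow(bhat[j, ], shat[j, ], fit@library@Ulist,
                    fit@library@grid, V, pi = fit@pi)
    pm[j, ] <- res$postMean
    sd[j, ] <- res$postSD
    lf[j, ] <- res$lfsr
  }
  if (is.null(genes)) genes <- as.character(seq_len(J))
  if (is.null(variants)) variants <- as.character(seq_len(J))
  new("PosteriorSet", genes = genes, variants = variants,
      populations = fit@library@populations,
      postMean = pm, postSD = sd, lfsr = lf)
}

#' One-call shrinkage of an effect-matrix set
#'
#' Convenience pipeline: impute or intersect missing cells, build the
#' covariance library from the strong rows, fit the mixture weights on a
#' random row subset, and compute posterior summaries for all rows.  With
#' `perGene = TRUE` the mixture is fit separately within each gene's rows
#' instead of on the combined gene-SNP row set.
#'
#' @param effects an \linkS4class{EffectMatrixSet}.
#' @param missingPolicy "impute" (Bhat = 0, Shat = 1e6) or "intersect".
#' @param estimateV estimate the error correlation from near-null rows.
#' @param perGene fit the mixture per gene rather than combined.
#' @param nRandom size of the random subset used to fit the weights.
#' @param seed seed for the random subset.
#' @return list(fit = \linkS4class{MashFit} (or per-gene list),
#'   posteriors = \linkS4class{PosteriorSet}).
#' @export
runMash <- function(effects, missingPolicy = c("impute", "intersect"),
                    estimateV = FALSE, perGene = FALSE,
                    nRandom = 5000L, seed = 1L) {
  dat <- imputeEffects(effects, match.arg(missingPolicy))
  V <- if (estimateV) estimateErrorCorrelation(dat$bhat, dat$shat) else NULL
  if (!perGene) {
    lib <- buildCovarianceLibrary(dat$bhat, dat$shat)
    set.seed(as.integer(seed))
    J <- nrow(dat$bhat)
    sub <- if (J > nRandom) sort(sample.int(J, nRandom)) else seq_len(J)
    fit <- fitMixtureWeights(dat$bhat[sub, , drop = FALSE],
                             dat$shat[sub, , drop = FALSE], lib, V)
    post <- posteriorSummaries(dat$bhat, dat$shat, fit,
                               genes = dat$genes, variants = dat$variants)
    return(list(fit = fit, posteriors = post))
  }
  fits <- list()
  pmList <- list()
  for (g in unique(dat$genes)) {
    idx <- which(dat$genes == g)
    if (length(idx) < 10) next
    lib <- buildCovarianceLibrary(dat$bhat[idx, , drop = FALSE],
                                  dat$shat[idx, , drop = FALSE])
    fit <- fitMixtureWeights(dat$bhat[idx, , drop = FALSE],
                             dat$shat[idx, , drop = FALSE], lib, V)
    fits[[g]] <- fit
    pmList[[g]] <- posteriorSummaries(dat$bhat[idx, , drop = FALSE],
                                      dat$shat[idx, , drop = FALSE], fit,
                                      genes = dat$genes[idx],
                                      variants = dat$variants[idx])
  }
  post <- new("PosteriorSet",
              genes = unlist(lapply(pmList, function(x) x@genes),
                             use.names = FALSE),
              variants = unlist(lapply(pmList, function(x) x@variants),
                                use.names = FALSE),
              populations = pmList[[1]]@populations,
              postMean = do.call(rbind, lapply(pmList, postMean)),
              postSD = do.call(rbind, lapply(pmList, postSD)),
              lfsr = do.call(rbind, lapply(pmList, lfsr)))
  list(fit = fits, posteriors = post)
}
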