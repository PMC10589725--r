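## Shared fixture builders and independent oracles.

## small genotype panel from explicit dosages
makePanel <- function(dos, chrom = "1", pos = NULL, ref = NULL, alt = NULL,
                      population = "POP1", sex = NULL, ids = NULL,
                      multiallelic = NULL) {
  m <- nrow(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- paste0("v", seq_len(m))
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  v <- data.frame(chrom = chrom, pos = pos, id = ids, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  if (!is.null(multiallelic)) v$multiallelic <- multiallelic
  rownames(dos) <- ids
  genotypePanel(dos, v, population = population, sex = sex)
}

## random HWE-ish dosage matrix (variants x samples)
randomDosages <- function(m, n, pmin = 0.1, pmax = 0.9) {
  p <- runif(m, pmin, pmax)
  matrix(rbinom(m * n, 2, rep(p, n)), m, n)
}

## --- HWE oracles -----------------------------------------------------------

## direct-arithmetic enumeration of the conditional het-count distribution
## (plain factorial formula, no log-space, no normalization tricks)
hweEnumOracle <- function(a, h, b) {
  n <- a + h + b
  nA <- 2 * a + h; nB <- 2 * b + h
  if (nA == 0 || nB == 0) return(1.0)
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  w <- sapply(hs, function(k) {
    factorial(n) / (factorial((nA - k) / 2) * factorial(k) *
                      factorial((nB - k) / 2)) * 2^k
  })
  p <- w / sum(w)
  pObs <- p[match(h, hs)]
  sum(p[p <= pObs * (1 + 1e-9)])
}

## full enumeration over allele pairings for tiny n: distributes nA alt
## alleles over 2n slots uniformly, pairs consecutive slots into genotypes
hwePairingOracle <- function(n, nA) {
  slots <- 2 * n
  combs <- utils::combn(slots, nA)
  hets <- apply(combs, 2, function(idx) {
    alle <- rep(0L, slots); alle[idx] <- 1L
    g <- alle[seq(1, slots, 2)] + alle[seq(2, slots, 2)]
    sum(g == 1L)
  })
  table(factor(hets, levels = 0:min(nA, 2 * n - nA))) / ncol(combs)
}

## --- mash oracles ----------------------------------------------------------

logMvnDensity <- function(x, Sigma) {
  R <- length(x)
  ch <- chol(Sigma)
  -0.5 * (R * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, x, transpose = TRUE)^2))
}

## dense mixture log-density oracle (independent of the package's eigen path)
mixtureLoglikOracle <- function(b, s, Ulist, grid, pi, V = NULL) {
  R <- length(b)
  if (is.null(V)) V <- diag(R)
  T <- outer(s, s) * V
  comps <- list(T)  # null
  for (k in setdiff(names(Ulist), "null"))
    for (w in grid) comps[[length(comps) + 1]] <- w * Ulist[[k]] + T
  ll <- vapply(comps, function(S) logMvnDensity(b, S), numeric(1))
  m <- max(ll + log(pi))
  m + log(sum(exp(ll + log(pi) - m)))
}

## 2-condition quadrature oracle for posterior mean/sd/lfsr: continuous
## mixture prior (PD components only), grid integration over b
posteriorQuadOracle <- function(b, s, Ulist, grid, piWeights, ngrid = 400) {
  stopifnot(length(b) == 2)
  T <- diag(s^2)
  comps <- list(); wts <- numeric(0)
  p <- 1
  nonNull <- setdiff(names(Ulist), "null")
  for (k in nonNull) for (w in grid) {
    p <- p + 1
    comps[[length(comps) + 1]] <- w * Ulist[[k]]
    wts <- c(wts, piWeights[p])
  }
  piNull <- piWeights[1]
  L <- max(abs(b)) + 6 * max(s) + 6 * sqrt(max(grid) *
                                             max(sapply(comps, function(U) max(diag(U)))))
  g1 <- seq(-L, L, length.out = ngrid)
  step <- g1[2] - g1[1]
  bb <- as.matrix(expand.grid(b1 = g1, b2 = g1))
  prior <- rep(0, nrow(bb))
  for (i in seq_along(comps)) {
    U <- comps[[i]]
    iU <- solve(U)
    q <- rowSums((bb %*% iU) * bb)
    prior <- prior + wts[i] * exp(-0.5 * q) /
      (2 * pi * sqrt(det(U)))
  }
  lik <- exp(-0.5 * ((b[1] - bb[, 1])^2 / s[1]^2 +
                       (b[2] - bb[, 2])^2 / s[2]^2)) /
    (2 * pi * s[1] * s[2])
  joint <- prior * lik * step^2
  nullLik <- piNull * exp(-0.5 * sum(b^2 / s^2)) / (2 * pi * s[1] * s[2])
  Zc <- sum(joint) + nullLik
  postNull <- nullLik / Zc
  w <- joint / Zc
  pm <- c(sum(w * bb[, 1]), sum(w * bb[, 2]))
  m2 <- c(sum(w * bb[, 1]^2), sum(w * bb[, 2]^2))
  psd <- sqrt(pmax(m2 - pm^2, 0))
  neg <- c(sum(w[bb[, 1] < 0]), sum(w[bb[, 2] < 0]))
  pos <- c(sum(w[bb[, 1] > 0]), sum(w[bb[, 2] > 0]))
  ## Euler-Maclaurin end correction at the sign boundary (midpoint rule):
  ## int_{-inf}^0 f = h*sum(f at centers < 0) + h^2/24 f'(0), with f'(0)
  ## estimated from the two cell columns adjacent to zero
  for (r in 1:2) {
    colNeg <- sum(w[abs(bb[, r] + step / 2) < step / 4])
    colPos <- sum(w[abs(bb[, r] - step / 2) < step / 4])
    corr <- (colPos - colNeg) / 24
    neg[r] <- neg[r] + corr
    pos[r] <- pos[r] - corr
  }
  lfsr <- pmin(neg + postNull, pos + postNull)
  list(postMean = pm, postSD = psd, lfsr = lfsr)
}

## --- Wilcoxon signed-rank exact oracle -------------------------------------

wilcoxonExactOracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ## enumerate all sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  mean(abs(Ws - n * (n + 1) / 4) >= abs(W - n * (n + 1) / 4) - 1e-9)
}
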