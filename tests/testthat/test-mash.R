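tinyLibrary <- function(R, Ulist, grid) {
  new("CovarianceLibrary", Ulist = c(list(null = matrix(0, R, R)), Ulist),
      grid = grid, populations = paste0("P", seq_len(R)))
}

test_that("mixture log-density matches closed forms and the dense oracle", {
  ## point mass on the null: log N(Bhat; 0, S^2)
  lib1 <- tinyLibrary(2, list(identity = diag(2)), grid = 1)
  b <- c(0.5, -1.2); s <- c(0.3, 0.8)
  pi0 <- c(1, 0)
  expect_equal(mixtureLoglik(b, s, lib1, pi0),
               sum(dnorm(b, 0, s, log = TRUE)), tolerance = 1e-12)
  ## R = 1, single component omega = 1, U = 1: scalar convolution
  libS <- tinyLibrary(1, list(identity = matrix(1, 1, 1)), grid = 1)
  expect_equal(mixtureLoglik(0.7, 0.4, libS, c(0, 1)),
               dnorm(0.7, 0, sqrt(1 + 0.16), log = TRUE), tolerance = 1e-12)
  ## random 3-condition row, multi-component library vs dense evaluation
  set.seed(1)
  U3 <- list(identity = diag(3), equal = matrix(1, 3, 3),
             het = {m <- matrix(0.5, 3, 3); diag(m) <- 1; m})
  lib3 <- tinyLibrary(3, U3, grid = c(0.5, 2))
  pi3 <- runif(7); pi3 <- pi3 / sum(pi3)
  for (i in 1:5) {
    b3 <- rnorm(3); s3 <- runif(3, 0.2, 1)
    expect_equal(mixtureLoglik(b3, s3, lib3, pi3),
                 mixtureLoglikOracle(b3, s3, lib3@Ulist, lib3@grid, pi3),
                 tolerance = 1e-10)
  }
  ## non-identity error correlation
  V <- matrix(c(1, 0.4, 0.4, 1), 2)
  lib2 <- tinyLibrary(2, list(identity = diag(2)), grid = c(1))
  pi2 <- c(0.3, 0.7)
  b2 <- c(1, -0.5); s2 <- c(0.5, 0.7)
  expect_equal(mixtureLoglik(b2, s2, lib2, pi2, V = V),
               mixtureLoglikOracle(b2, s2, lib2@Ulist, lib2@grid, pi2, V),
               tolerance = 1e-10)
})

test_that("covariance library has the documented canonical and data-driven parts", {
  set.seed(2)
  bhat <- matrix(rnorm(400, sd = 2), 100, 4,
                 dimnames = list(NULL, c("AFA", "CHN", "EUR", "HIS")))
  shat <- matrix(runif(400, 0.1, 0.5), 100, 4,
                 dimnames = list(NULL, c("AFA", "CHN", "EUR", "HIS")))
  lib <- buildCovarianceLibrary(bhat, shat)
  nm <- names(lib@Ulist)
  expect_true(all(c("null", "identity", "singleton_AFA", "singleton_CHN",
                    "equal_effects", "het_0.25", "het_0.5", "het_0.75",
                    "pca_1", "empirical") %in% nm))
  ## grid bounds recomputed by brute force
  expect_equal(min(lib@grid), min(shat)^2 / 10, tolerance = 1e-12)
  expect_gte(max(lib@grid), 2 * max(bhat^2))
  expect_lt(max(lib@grid) / 2, 2 * max(bhat^2))
  expect_true(all(abs(diff(log2(lib@grid)) - 1) < 1e-9))
  ## PSD with unit max diagonal for data-driven parts
  for (k in c("pca_1", "pca_2", "pca_3", "empirical")) {
    ev <- eigen(lib@Ulist[[k]], symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(max(diag(lib@Ulist[[k]])), 1, tolerance = 1e-9)
  }
  ## perfectly shared strong rows: top PC is the equal-effects pattern
  sh <- matrix(rep(rnorm(200, sd = 3), 4), 200, 4)
  libSh <- buildCovarianceLibrary(sh, matrix(1, 200, 4),
                                  strongIdx = seq_len(200))
  expect_lt(max(abs(libSh@Ulist$pca_1 - 1)), 1e-6)
  ## fewer strong rows than conditions: canonical-only with a warning
  expect_warning(
    libC <- buildCovarianceLibrary(bhat[1:2, ], shat[1:2, ],
                                   strongIdx = integer(0)),
    "canonical-only")
  expect_false("empirical" %in% names(libC@Ulist))
})

test_that("EM weight fitting: hand-checked step, ascent, simplex validity", {
  set.seed(3)
  lib <- tinyLibrary(2, list(identity = diag(2),
                             equal = matrix(1, 2, 2)), grid = 1)
  bhat <- matrix(rnorm(6), 3, 2)
  shat <- matrix(1, 3, 2)
  fit <- fitMixtureWeights(rbind(bhat, bhat, bhat, bhat), # >= 10 rows
                           rbind(shat, shat, shat, shat), lib, maxit = 1L)
  ## one EM step from uniform pi equals the responsibility average
  Lm <- popmash:::.mashLikMatrix(rbind(bhat, bhat, bhat, bhat),
                                 rbind(shat, shat, shat, shat), lib)
  W <- exp(Lm)
  gamma <- W / rowSums(W)               # uniform pi cancels
  expect_equal(unname(fit@pi), unname(colMeans(gamma)), tolerance = 1e-12)
  ## longer run: nondecreasing trace, simplex to 1e-12, beats uniform
  set.seed(4)
  b2 <- matrix(rnorm(100, sd = 1.5), 50, 2)
  fit2 <- fitMixtureWeights(b2, matrix(1, 50, 2), lib)
  expect_true(all(diff(fit2@loglik) >= -1e-8))
  expect_equal(sum(fit2@pi), 1, tolerance = 1e-12)
  expect_true(all(fit2@pi >= 0))
  unifLL <- sum(apply(b2, 1, function(x)
    mixtureLoglik(x, c(1, 1), lib, rep(1 / 3, 3))))
  expect_gte(tail(fit2@loglik, 1), unifLL)
  expect_error(fitMixtureWeights(b2[1:5, ], matrix(1, 5, 2), lib),
               "nrow")
})

test_that("EM recovers a dominant generating component", {
  set.seed(7)
  R <- 3
  Ue <- matrix(1, R, R)
  lib <- tinyLibrary(R, list(identity = diag(R), equal_effects = Ue,
                             singleton_1 = diag(c(1, 0, 0))), grid = 1)
  n <- 2000
  bTrue <- matrix(rnorm(n), n, R)       # fully shared effects
  bhat <- bTrue + matrix(rnorm(n * R, sd = 0.3), n, R)
  shat <- matrix(0.3, n, R)
  fit <- fitMixtureWeights(bhat, shat, lib)
  expect_gte(fit@pi[["equal_effects;1"]], 0.9)
})

test_that("posterior summaries: closed forms, shrinkage, antisymmetry", {
  ## null-only fit: posterior mean 0, lfsr 1
  libN <- tinyLibrary(2, list(identity = diag(2)), grid = 1)
  fitN <- new("MashFit", library = libN, pi = c(1, 0), loglik = 0,
              niter = 1L, V = diag(2))
  pN <- posteriorSummaries(matrix(c(1, -2), 1), matrix(c(0.5, 0.5), 1), fitN)
  expect_equal(unname(postMean(pN)[1, ]), c(0, 0))
  expect_equal(unname(lfsr(pN)[1, ]), c(1, 1))
  ## R = 1 single normal component: classical shrinkage bhat * w/(w + s^2)
  libS <- tinyLibrary(1, list(identity = matrix(1, 1, 1)), grid = 2.5)
  fitS <- new("MashFit", library = libS, pi = c(0, 1), loglik = 0,
              niter = 1L, V = diag(1))
  b <- 1.3; s <- 0.6
  pS <- posteriorSummaries(matrix(b, 1), matrix(s, 1), fitS)
  expect_equal(unname(postMean(pS)[1, 1]), b * 2.5 / (2.5 + s^2), tolerance = 1e-12)
  expect_equal(unname(postSD(pS)[1, 1]), sqrt(2.5 * s^2 / (2.5 + s^2)),
               tolerance = 1e-12)
  ## scaled-identity-only library: posterior norm never exceeds the estimate
  libI <- tinyLibrary(3, list(identity = diag(3)), grid = c(0.1, 1, 10))
  set.seed(5)
  bh <- matrix(rnorm(60, sd = 2), 20, 3)
  sh <- matrix(runif(60, 0.3, 1), 20, 3)
  fitI <- fitMixtureWeights(bh, sh, libI)
  pI <- posteriorSummaries(bh, sh, fitI)
  for (j in 1:20)
    expect_lte(sqrt(sum(postMean(pI)[j, ]^2)), sqrt(sum(bh[j, ]^2)) + 1e-12)
  ## negating Bhat negates the posterior mean, lfsr unchanged
  pNeg <- posteriorSummaries(-bh, sh, fitI)
  expect_equal(postMean(pNeg), -postMean(pI), tolerance = 1e-10)
  expect_equal(lfsr(pNeg), lfsr(pI), tolerance = 1e-10)
  ## sanity bound on the posterior mean magnitude
  expect_true(all(abs(postMean(pI)) <=
                    apply(abs(bh), 1, max) + 3 * apply(sh, 1, max)))
})

test_that("posterior mean/SD/lfsr match grid quadrature on 2-condition rows", {
  set.seed(6)
  Ulist <- list(het25 = {m <- matrix(0.25, 2, 2); diag(m) <- 1; m},
                het75 = {m <- matrix(0.75, 2, 2); diag(m) <- 1; m},
                identity = diag(2))
  lib <- tinyLibrary(2, Ulist, grid = c(0.5, 1.5))
  P <- 1 + 3 * 2
  pi <- c(0.2, rep(0.8 / (P - 1), P - 1))
  fit <- new("MashFit", library = lib, pi = pi, loglik = 0, niter = 1L,
             V = diag(2))
  for (i in 1:4) {
    b <- rnorm(2, sd = 1.2); s <- runif(2, 0.4, 0.9)
    post <- posteriorSummaries(matrix(b, 1), matrix(s, 1), fit)
    oracle <- posteriorQuadOracle(b, s, lib@Ulist, lib@grid, pi)
    expect_equal(unname(postMean(post)[1, ]), oracle$postMean,
                 tolerance = 1e-4)
    expect_equal(unname(postSD(post)[1, ]), oracle$postSD, tolerance = 1e-4)
    expect_equal(unname(lfsr(post)[1, ]), oracle$lfsr, tolerance = 1e-4)
  }
})

test_that("error-correlation estimation uses near-null rows and stays PD", {
  set.seed(8)
  n <- 3000
  V <- matrix(c(1, 0.6, 0.6, 1), 2)
  ch <- chol(V)
  z <- matrix(rnorm(n * 2), n, 2) %*% ch
  Vhat <- estimateErrorCorrelation(z, matrix(1, n, 2))
  ## selection on max |z| < 2 attenuates the correlation; compare against
  ## the same selection applied by hand
  keep <- apply(abs(z), 1, max) < 2
  expect_equal(Vhat[1, 2], cor(z[keep, ])[1, 2], tolerance = 1e-6)
  expect_gt(Vhat[1, 2], 0.3)
  expect_lt(Vhat[1, 2], 0.7)
  expect_true(all(eigen(Vhat, only.values = TRUE)$values > 0))
})

test_that("runMash per-gene mode produces posteriors for every eligible row", {
  set.seed(9)
  genes <- rep(c("g1", "g2"), each = 15)
  b <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("A", "B")))
  s <- matrix(runif(60, 0.3, 0.6), 30, 2, dimnames = list(NULL, c("A", "B")))
  eff <- new("EffectMatrixSet", genes = genes,
             variants = paste0("v", 1:30), bhat = b, shat = s, pval = b,
             df = c(A = 50, B = 50),
             observed = matrix(TRUE, 30, 2, dimnames = list(NULL, c("A", "B"))))
  combined <- runMash(eff, seed = 2L)
  expect_identical(length(combined$posteriors@genes), 30L)
  perGene <- suppressWarnings(runMash(eff, perGene = TRUE, seed = 2L))
  expect_identical(sort(perGene$posteriors@variants), sort(paste0("v", 1:30)))
  expect_s4_class(perGene$fit$g1, "MashFit")
})
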