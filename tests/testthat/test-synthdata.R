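smallCfg <- function(...) {
  simConfig(nPopulations = 2L, populations = c("A", "B"),
            nSamplesPerPop = c(100L, 100L), fstPerPop = c(0.1, 0),
            nGenes = 2L, nCisSnpsPerGene = 10L, seed = 1L, ...)
}

test_that("fixed seed gives byte-identical panels", {
  cfg <- smallCfg()
  p1 <- simulateGenotypes(cfg)
  p2 <- simulateGenotypes(cfg)
  expect_identical(dosageMatrix(p1$A), dosageMatrix(p2$A))
  expect_identical(dosageMatrix(p1$B), dosageMatrix(p2$B))
  expect_identical(variantInfo(p1$A), variantInfo(p2$A))
})

test_that("config invariants are enforced", {
  expect_error(simConfig(nPopulations = 2L, populations = c("A", "B"),
                         nSamplesPerPop = c(100L, 100L), fstPerPop = c(1, 0)),
               "degenerate")
  expect_error(simConfig(nPopulations = 1L, populations = "A",
                         nSamplesPerPop = 1L, fstPerPop = 0), ">= 2")
  expect_error(simConfig(sharedEffectFraction = 0.8,
                         specificEffectFraction = 0.5), "sum to <= 1")
})

test_that("Fst = 0 keeps population frequencies at the ancestral value", {
  cfg <- simConfig(nPopulations = 3L, populations = c("A", "B", "C"),
                   nSamplesPerPop = rep(400L, 3), fstPerPop = rep(0, 3),
                   nGenes = 2L, nCisSnpsPerGene = 15L, ldRho = 0, seed = 5L)
  panels <- simulateGenotypes(cfg)
  # realized generator frequencies are exactly the ancestral ones
  for (p in panels)
    expect_identical(variantInfo(p)$freq, variantInfo(p)$ancestralFreq)
  # observed between-population differences are pure sampling noise
  fA <- rowMeans(dosageMatrix(panels$A)) / 2
  fB <- rowMeans(dosageMatrix(panels$B)) / 2
  expect_lt(mean(abs(fA - fB)), 3 * mean(sqrt(0.25 / 400)))
})

test_that("allele-frequency divergence grows with Fst", {
  wahlund <- sapply(c(0.01, 0.05, 0.15, 0.3), function(f) {
    cfg <- simConfig(nPopulations = 4L, populations = paste0("P", 1:4),
                     nSamplesPerPop = rep(50L, 4), fstPerPop = rep(f, 4),
                     nGenes = 2L, nCisSnpsPerGene = 25L, seed = 31L)
    panels <- simulateGenotypes(cfg)
    freqs <- sapply(panels, function(p) variantInfo(p)$freq)
    mean(apply(freqs, 1, var))
  })
  expect_true(all(diff(wahlund) > 0))
})

test_that("no-LD panels match the analytic null for adjacent-variant r2", {
  ## E[r2] for independent variants ~ 1/(n-1) on n samples; average over seeds
  r2s <- sapply(1:30, function(s) {
    cfg <- simConfig(nPopulations = 1L, populations = "A",
                     nSamplesPerPop = 60L, fstPerPop = 0, nGenes = 1L,
                     nCisSnpsPerGene = 20L, ldRho = 0, seed = 100L + s)
    dos <- dosageMatrix(simulateGenotypes(cfg)$A)
    mean(sapply(1:(nrow(dos) - 1), function(i)
      suppressWarnings(cor(dos[i, ], dos[i + 1, ]))^2), na.rm = TRUE)
  })
  expect_equal(mean(r2s), 1 / 59, tolerance = 0.35)
  ## and positive LD when rho is high
  cfgLD <- simConfig(nPopulations = 1L, populations = "A",
                     nSamplesPerPop = 300L, fstPerPop = 0, nGenes = 1L,
                     nCisSnpsPerGene = 20L, ldRho = 0.9, ldBlockSize = 20L,
                     seed = 9L)
  dosLD <- dosageMatrix(simulateGenotypes(cfgLD)$A)
  r2LD <- mean(sapply(1:(nrow(dosLD) - 1), function(i)
    cor(dosLD[i, ], dosLD[i + 1, ])^2))
  expect_gt(r2LD, 0.2)
})

test_that("cis windows contain every causal SNP and truth h2 equals the simulated ratio", {
  cfg <- simConfig(nPopulations = 2L, populations = c("A", "B"),
                   nSamplesPerPop = c(300L, 300L), fstPerPop = c(0.05, 0),
                   nGenes = 6L, nCisSnpsPerGene = 12L, seed = 21L)
  panels <- simulateGenotypes(cfg)
  sim <- simulateExpression(panels, cfg)
  v <- variantInfo(panels$A)
  ann <- attr(panels, "layout")
  for (i in seq_len(nrow(sim$truth@effects))) {
    e <- sim$truth@effects[i, ]
    gi <- match(e$gene, ann$gene_id)
    win <- cisWindow(ann$tss[gi], ann$tes[gi])
    pos <- v$pos[match(e$variant, v$id)]
    expect_true(pos >= win$start && pos <= win$end)
    expect_identical(v$gene[match(e$variant, v$id)], e$gene)
  }
  ## recompute the variance ratio from emitted truth + data
  sim1 <- simulateExpression(panels, cfg, exams = 1L, ageEffect = 0,
                             sexEffect = 0)
  tr <- sim1$truth
  lat <- log(exprMatrix(sim1$expression$A$exam1))
  for (g in unique(tr@effects$gene[tr@effects$population == "A"])) {
    e <- tr@effects[tr@effects$gene == g & tr@effects$population == "A", ]
    gv <- drop(crossprod(dosageMatrix(panels$A)[e$variant, , drop = FALSE],
                         e$beta))
    h2rec <- tr@h2$h2[tr@h2$gene == g & tr@h2$population == "A"]
    ratio <- var(gv) / var(lat[g, ])
    expect_equal(ratio, h2rec, tolerance = 0.25)
  }
})

test_that("single-SNP gene at h2 = 0.5 recovers the variance ratio at n = 2000", {
  cfg <- simConfig(nPopulations = 1L, populations = "A",
                   nSamplesPerPop = 2000L, fstPerPop = 0, nGenes = 1L,
                   nCisSnpsPerGene = 1L, nCausalPerGene = 1L,
                   h2Distribution = c(0.5, 0.5), sharedEffectFraction = 1,
                   specificEffectFraction = 0, seed = 17L)
  panels <- simulateGenotypes(cfg)
  sim <- simulateExpression(panels, cfg, exams = 1L, ageEffect = 0,
                            sexEffect = 0)
  tr <- sim$truth
  expect_identical(tr@h2$h2, 0.5)
  e <- tr@effects
  gv <- drop(crossprod(dosageMatrix(panels$A)[e$variant, , drop = FALSE],
                       e$beta))
  y <- log(exprMatrix(sim$expression$A$exam1))[1, ]
  ratio <- var(gv) / var(y)
  expect_gte(ratio, 0.45)
  expect_lte(ratio, 0.55)
})

test_that("effect architecture follows the configured sharing fractions", {
  cfg <- simConfig(nPopulations = 3L, populations = c("A", "B", "C"),
                   nSamplesPerPop = rep(50L, 3), fstPerPop = rep(0.05, 3),
                   nGenes = 12L, nCisSnpsPerGene = 6L,
                   sharedEffectFraction = 1, specificEffectFraction = 0,
                   seed = 3L)
  panels <- simulateGenotypes(cfg)
  sim <- simulateExpression(panels, cfg)
  eff <- sim$truth@effects
  for (g in unique(eff$gene)) {
    byPop <- split(eff[eff$gene == g, c("variant", "beta")],
                   eff$population[eff$gene == g])
    expect_length(byPop, 3)
    for (p in byPop[-1]) expect_equal(p, byPop[[1]],
                                          ignore_attr = TRUE)
  }
  ## all-null configuration: expression independent of genotype
  cfg0 <- simConfig(nPopulations = 1L, populations = "A",
                    nSamplesPerPop = 500L, fstPerPop = 0, nGenes = 4L,
                    nCisSnpsPerGene = 5L, sharedEffectFraction = 0,
                    specificEffectFraction = 0, seed = 8L)
  p0 <- simulateGenotypes(cfg0)
  s0 <- simulateExpression(p0, cfg0, exams = 1L, ageEffect = 0, sexEffect = 0)
  expect_identical(nrow(s0$truth@effects), 0L)
  y <- log(exprMatrix(s0$expression$A$exam1))
  cors <- abs(cor(t(y), t(dosageMatrix(p0$A))))
  expect_lt(max(cors), 4.5 / sqrt(500))   # all within null fluctuation range
})

test_that("GWAS statistics are internally consistent and calibrated under the null", {
  cfg <- smallCfg()
  panels <- simulateGenotypes(cfg)
  sim <- simulateExpression(panels, cfg)
  cohort <- simulateCohortLike(panels$A, 1500L, seed = 4L)
  ## null trait: no causal genes
  nullRes <- simulateGwas(cohort, sim$truth, cfg, causalGenes = character(0))
  expect_equal(nullRes$stats$zscore,
               nullRes$stats$beta / nullRes$stats$se, tolerance = 1e-12)
  expect_identical(nrow(nullRes$truth@trait), 0L)
  ## causal trait records its genes
  res <- simulateGwas(cohort, sim$truth, cfg)
  expect_gt(nrow(res$truth@trait), 0)
  expect_true(all(res$truth@trait$gene %in% sim$truth@effects$gene))
})

test_that("null GWAS z-scores are standard normal over replicates", {
  cfg <- simConfig(nPopulations = 1L, populations = "A",
                   nSamplesPerPop = 50L, fstPerPop = 0, nGenes = 3L,
                   nCisSnpsPerGene = 20L, ldRho = 0, seed = 2L)
  panels <- simulateGenotypes(cfg)
  sim <- simulateExpression(panels, cfg)
  zs <- unlist(lapply(1:10, function(s) {
    cohort <- simulateCohortLike(panels$A, 400L, seed = 50L + s, ldRho = 0)
    simulateGwas(cohort, sim$truth, cfg, causalGenes = character(0),
                 seed = 60L + s)$stats$zscore
  }))
  frac <- mean(abs(zs) > 1.96)
  expect_equal(frac, 0.05, tolerance = 0.5)   # 600 z-scores, MC error
})

test_that("a single causal SNP attains the top |z| in its block at large n", {
  cfg <- simConfig(nPopulations = 1L, populations = "A",
                   nSamplesPerPop = 50L, fstPerPop = 0, nGenes = 1L,
                   nCisSnpsPerGene = 10L, nCausalPerGene = 1L,
                   ldBlockSize = 10L, ldRho = 0.5,
                   h2Distribution = c(0.4, 0.4), sharedEffectFraction = 1,
                   specificEffectFraction = 0, seed = 19L)
  panels <- simulateGenotypes(cfg)
  sim <- simulateExpression(panels, cfg)
  causal <- sim$truth@effects$variant[1]
  hits <- sapply(1:20, function(s) {
    cohort <- simulateCohortLike(panels$A, 3000L, seed = 200L + s,
                                 ldRho = 0.5)
    st <- simulateGwas(cohort, sim$truth, cfg,
                       causalGenes = sim$truth@effects$gene[1],
                       traitH2 = 0.5, seed = 300L + s)$stats
    st$variant_id[which.max(abs(st$zscore))] == causal
  })
  expect_gte(mean(hits), 0.95)
})
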