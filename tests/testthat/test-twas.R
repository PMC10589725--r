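simpleModel <- function(weights, method = "mashr", population = "POP1") {
  genes <- unique(weights$gene)
  new("PredictionModel", method = method, population = population,
      tissue = "t", weights = weights,
      extra = data.frame(gene = genes, genename = genes,
                         n_snps_in_model = as.integer(table(weights$gene)[genes]),
                         pred_perf_R2 = NA_real_, pred_perf_pval = NA_real_))
}

wrow <- function(gene, rsid, weight, ref = "A", alt = "G", pos = 1L) {
  data.frame(gene = gene, rsid = rsid, chrom = "1", pos = pos,
             ref_allele = ref, eff_allele = alt, weight = weight,
             stringsAsFactors = FALSE)
}

test_that("GReX is the weighted dosage sum, linear, with missing SNPs tallied", {
  set.seed(1)
  dos <- randomDosages(4, 30)
  rownames(dos) <- paste0("v", 1:4)
  panel <- makePanel(dos)
  ## single SNP, unit weight: the dosage column
  m1 <- simpleModel(wrow("g1", "v2", 1))
  gx <- predictGrex(panel, m1)
  expect_equal(unname(gx[, "g1"]), unname(dos[2, ]), tolerance = 1e-12)
  ## all-zero weights: all-zero GReX
  m0 <- simpleModel(rbind(wrow("g1", "v1", 0), wrow("g1", "v2", 0)))
  expect_true(all(predictGrex(panel, m0) == 0))
  ## dense matrix-product oracle
  w <- rbind(wrow("g1", "v1", 0.5), wrow("g1", "v3", -1.2),
             wrow("g2", "v2", 2), wrow("g2", "v4", 0.1))
  gx2 <- predictGrex(panel, simpleModel(w))
  oracle <- t(dos) %*% rbind(c(0.5, 0), c(0, 2), c(-1.2, 0), c(0, 0.1))
  expect_equal(unname(gx2[, c("g1", "g2")]), unname(oracle),
               tolerance = 1e-12)
  ## linearity in the weights
  wA <- rbind(wrow("g1", "v1", 0.3), wrow("g1", "v2", -0.4))
  wB <- rbind(wrow("g1", "v1", 1.1), wrow("g1", "v2", 0.2))
  wS <- rbind(wrow("g1", "v1", 1.4), wrow("g1", "v2", -0.2))
  expect_equal(predictGrex(panel, simpleModel(wS))[, 1],
               predictGrex(panel, simpleModel(wA))[, 1] +
                 predictGrex(panel, simpleModel(wB))[, 1], tolerance = 1e-12)
  ## SNP absent from the panel contributes zero and is tallied
  mMiss <- simpleModel(rbind(wrow("g1", "v1", 1), wrow("g1", "vX", 5)))
  gxM <- predictGrex(panel, mMiss)
  expect_equal(unname(gxM[, 1]), unname(dos[1, ]), tolerance = 1e-12)
  expect_identical(attr(gxM, "missingSnps"), 1L)
})

test_that("Spearman evaluation is rank-invariant and matches the rank-Pearson oracle", {
  set.seed(2)
  obs <- matrix(rnorm(30), 3, 10,
                dimnames = list(paste0("g", 1:3), sprintf("S%02d", 1:10)))
  obs <- obs - rowMeans(obs)
  panel <- expressionPanel(obs, data.frame(
    gene_id = paste0("g", 1:3), chrom = "1", tss = 1:3 * 1e6,
    tes = 1:3 * 1e6 + 100, strand = "+"), stage = "residualized")
  ## identical prediction: rho = 1; monotone transform: rho = 1
  gx <- t(obs)
  ev <- evaluatePrediction(gx, panel)
  expect_equal(ev$rho, rep(1, 3), tolerance = 1e-12)
  evMono <- evaluatePrediction(exp(2 * gx) + 5, panel)
  expect_equal(evMono$rho, rep(1, 3), tolerance = 1e-12)
  ## random pairs match rank-then-Pearson
  gxR <- matrix(rnorm(30), 10, 3,
                dimnames = list(sprintf("S%02d", 1:10), paste0("g", 1:3)))
  evR <- evaluatePrediction(gxR, panel)
  for (g in paste0("g", 1:3))
    expect_equal(evR$rho[evR$gene == g],
                 cor(rank(gxR[, g]), rank(obs[g, ])), tolerance = 1e-12)
  ## constant prediction: rho undefined, reported missing
  gxC <- gxR; gxC[, 1] <- 3
  expect_true(is.na(evaluatePrediction(gxC, panel)$rho[1]))
})

test_that("allele harmonization keeps, flips and drops as constructed", {
  model <- simpleModel(rbind(
    wrow("g1", "v1", 1, ref = "A", alt = "G"),
    wrow("g1", "v2", 1, ref = "C", alt = "T"),
    wrow("g1", "v3", 1, ref = "A", alt = "C"),
    wrow("g1", "v4", 1, ref = "T", alt = "G")))
  gwas <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4", "v9"),
    effect_allele = c("G", "C", "A", "C"[1], "G"),
    non_effect_allele = c("A", "T", "T", "A", "T"),
    beta = c(0.5, 0.3, 0.2, 0.1, 9), se = c(0.2, 0.12, 0.1, 0.05, 1),
    stringsAsFactors = FALSE)
  gwas$zscore <- gwas$beta / gwas$se
  h <- harmonizeAlleles(gwas, model)
  expect_identical(h$tally,
                   c(matched = 1L, flipped = 1L, dropped = 2L))
  ## exact match unchanged
  expect_equal(h$stats$zscore[h$stats$variant_id == "v1"], 2.5)
  ## swapped alleles: sign flipped
  expect_equal(h$stats$zscore[h$stats$variant_id == "v2"], -2.5)
  expect_equal(h$stats$beta[h$stats$variant_id == "v2"], -0.3)
  ## mismatched pair (v3: A/T vs model A/C) and off-model variant dropped
  expect_false("v3" %in% h$stats$variant_id)
  expect_false("v9" %in% h$stats$variant_id)
})

test_that("single-SNP genes collapse to the GWAS z-score with the weight sign", {
  set.seed(3)
  dos <- randomDosages(2, 200)
  rownames(dos) <- c("v1", "v2")
  panel <- makePanel(dos)
  gwas <- data.frame(variant_id = c("v1", "v2"),
                     effect_allele = "G", non_effect_allele = "A",
                     beta = c(0.4, -0.2), se = c(0.1, 0.1),
                     stringsAsFactors = FALSE)
  gwas$zscore <- gwas$beta / gwas$se
  mPos <- simpleModel(wrow("g1", "v1", 0.7))
  covs <- computeModelCovariances(panel, mPos)
  r <- spredixcanGene(mPos, "g1", harmonizeAlleles(gwas, mPos)$stats, covs)
  expect_equal(r$zscore, 4, tolerance = 1e-12)
  mNeg <- simpleModel(wrow("g1", "v1", -0.7))
  covsN <- computeModelCovariances(panel, mNeg)
  rN <- spredixcanGene(mNeg, "g1", harmonizeAlleles(gwas, mNeg)$stats, covsN)
  expect_equal(rN$zscore, -4, tolerance = 1e-12)
})

test_that("gene z-score is invariant to positive weight rescaling", {
  set.seed(4)
  dos <- randomDosages(3, 300)
  rownames(dos) <- paste0("v", 1:3)
  panel <- makePanel(dos)
  gwas <- data.frame(variant_id = paste0("v", 1:3),
                     effect_allele = "G", non_effect_allele = "A",
                     beta = c(0.4, -0.1, 0.05), se = c(0.1, 0.09, 0.11),
                     stringsAsFactors = FALSE)
  gwas$zscore <- gwas$beta / gwas$se
  w1 <- rbind(wrow("g1", "v1", 0.5), wrow("g1", "v2", -0.3),
              wrow("g1", "v3", 0.8))
  w2 <- w1; w2$weight <- w1$weight * 3.7
  m1 <- simpleModel(w1); m2 <- simpleModel(w2)
  c1 <- computeModelCovariances(panel, m1)
  r1 <- spredixcanGene(m1, "g1", harmonizeAlleles(gwas, m1)$stats, c1)
  r2 <- spredixcanGene(m2, "g1", harmonizeAlleles(gwas, m2)$stats, c1)
  expect_equal(r1$zscore, r2$zscore, tolerance = 1e-12)
})

test_that("covariance restriction to GWAS-present SNPs and skip tallies work", {
  set.seed(5)
  dos <- randomDosages(3, 100)
  rownames(dos) <- paste0("v", 1:3)
  panel <- makePanel(dos)
  w <- rbind(wrow("g1", "v1", 0.5), wrow("g1", "v2", 1),
             wrow("g2", "v3", 1))
  model <- simpleModel(w)
  covs <- computeModelCovariances(panel, model)
  ## v2 missing from GWAS: sigma_g uses the 1x1 restriction
  gwas <- data.frame(variant_id = "v1", effect_allele = "G",
                     non_effect_allele = "A", beta = 0.3, se = 0.1,
                     stringsAsFactors = FALSE)
  gwas$zscore <- 3
  res <- spredixcanAll(model, gwas, covs)
  expect_identical(nrow(res), 1L)
  expect_identical(res$n_snps_used, 1L)
  expect_identical(res$n_snps_in_model, 2L)
  expect_equal(res$zscore, 3, tolerance = 1e-12)  # single used SNP collapses
  expect_identical(attr(res, "skipped"), 1L)      # g2 has no overlap
})

test_that("significance is strict at 5e-8 and replication needs matching sign", {
  base <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                     method = "mashr", population = "AFA", tissue = "t",
                     zscore = c(5.9, 6.1, -6.0, 5.8),
                     pvalue = c(4.9e-8, 5e-8, 1e-9, 1e-9),
                     stringsAsFactors = FALSE)
  partner <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                        method = "mashr", population = "AFA", tissue = "t",
                        zscore = c(6.2, 7.0, 6.1, 5.5),
                        pvalue = c(1e-10, 1e-10, 1e-10, 0.5),
                        stringsAsFactors = FALSE)
  out <- callSignificantAndReplicate(base, partner)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, TRUE))
  ## g1 replicates; g2 not significant; g3 sign mismatch; g4 partner weak
  expect_identical(out$replicated, c(TRUE, FALSE, FALSE, FALSE))
  ## replication requires the same model tag
  partner2 <- partner
  partner2$population <- c("EUR", "AFA", "AFA", "AFA")
  out2 <- callSignificantAndReplicate(base, partner2)
  expect_false(out2$replicated[1])
  ## random tables equal the direct predicate
  set.seed(6)
  mk <- function() data.frame(gene = paste0("g", 1:50), method = "m",
                              population = "p", tissue = "t",
                              zscore = rnorm(50, sd = 4),
                              pvalue = runif(50)^8,
                              stringsAsFactors = FALSE)
  a <- mk(); b <- mk()
  out3 <- callSignificantAndReplicate(a, b, alpha = 1e-3)
  oracle <- a$pvalue < 1e-3 & b$pvalue < 1e-3 &
    sign(a$zscore) == sign(b$zscore)
  expect_identical(out3$replicated, oracle)
})

test_that("null GWAS yields calibrated gene-level p-values", {
  set.seed(7)
  nGenes <- 400
  n <- 400
  dos <- randomDosages(nGenes, n)
  rownames(dos) <- paste0("v", 1:nGenes)
  panel <- makePanel(dos)
  y <- rnorm(n)
  xc <- dos - rowMeans(dos)
  yc <- y - mean(y)
  sxx <- rowSums(xc^2)
  beta <- drop(xc %*% yc) / sxx
  se <- sqrt(pmax(sum(yc^2) - beta^2 * sxx, 0) / (n - 2) / sxx)
  gwas <- data.frame(variant_id = rownames(dos), effect_allele = "G",
                     non_effect_allele = "A", beta = beta, se = se,
                     zscore = beta / se, stringsAsFactors = FALSE)
  w <- do.call(rbind, lapply(seq_len(nGenes), function(i)
    wrow(paste0("g", i), rownames(dos)[i], 1)))
  model <- simpleModel(w)
  covs <- computeModelCovariances(panel, model)
  res <- spredixcanAll(model, gwas, covs)
  frac <- mean(res$pvalue < 0.05)
  expect_lt(abs(frac - 0.05), 0.035)
})
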