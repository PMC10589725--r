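## Multi-population synthetic data: Balding-Nichols allele-frequency
## divergence, AR(1)-thresholded haplotype LD, heritable expression with
## shared / population-specific cis effects, and GWAS-scale marginal
## summary statistics.  Everything downstream is testable against the
## emitted TruthSet.

.GENE_LENGTH <- 10000L
.GENE_SPACING <- 2500000L  # > 2 Mb + gene length: cis windows never overlap
.CIS_FLANK <- 1000000L

## sample latent-Gaussian haplotypes with AR(1) correlation rho within a
## block whose variants have thresholds qnorm(p); returns H x B 0/1 matrix
.sampleHaplotypeBlock <- function(H, p, rho) {
  B <- length(p)
  Z <- matrix(stats::rnorm(H * B), H, B)
  if (rho > 0 && B > 1) {
    for (j in 2:B) Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  }
  ## allele present when latent value falls below the p-quantile
  sweep(Z, 2, stats::qnorm(p), "<") + 0
}

.bnFrequencies <- function(p0, fst) {
  if (fst == 0) return(p0)
  a <- p0 * (1 - fst) / fst
  b <- (1 - p0) * (1 - fst) / fst
  p <- stats::rbeta(length(p0), a, b)
  pmin(pmax(p, 1e-4), 1 - 1e-4)
}

.GENES_PER_CHROM <- 800L   # keeps positions within 32-bit range

.variantLayout <- function(config, withArtifacts = FALSE) {
  G <- config@nGenes; m <- config@nCisSnpsPerGene
  slot <- (seq_len(G) - 1L) %% .GENES_PER_CHROM
  chromOf <- as.character(1L + (seq_len(G) - 1L) %/% .GENES_PER_CHROM)
  tss <- 1500000L + slot * .GENE_SPACING
  tes <- tss + .GENE_LENGTH - 1L
  posL <- vector("list", G); gene <- character(0)
  for (g in seq_len(G)) {
    lo <- tss[g] - 200000L; hi <- tes[g] + 200000L
    posL[[g]] <- sort(sample(lo:hi, m))
    gene <- c(gene, rep(sprintf("gene%03d", g), m))
  }
  pos <- unlist(posL)
  M <- length(pos)
  pairs <- matrix(c("A","C", "A","G", "T","C", "T","G",
                    "C","A", "G","A", "C","T", "G","T"), ncol = 2, byrow = TRUE)
  sel <- pairs[sample.int(nrow(pairs), M, replace = TRUE), , drop = FALSE]
  v <- data.frame(
    chrom = rep(chromOf, each = m), pos = pos,
    id = sprintf("snp%06d", seq_len(M)),
    ref = sel[, 1], alt = sel[, 2], gene = gene,
    multiallelic = FALSE,
    block = as.integer((ave(seq_along(pos), gene, FUN = seq_along) - 1L) %/%
                       config@ldBlockSize),
    stringsAsFactors = FALSE
  )
  ## per-gene block ids made globally unique
  v$block <- as.integer(factor(paste(v$gene, v$block)))
  if (withArtifacts) {
    ## convert a few variants into records each QC rule must drop
    idx <- seq_len(min(3L, M))
    v$ref[idx[1]] <- "A"; v$alt[idx[1]] <- "T"          # ambiguous strand
    if (length(idx) > 1) { v$ref[idx[2]] <- "AT" }       # indel
    if (length(idx) > 2) { v$multiallelic[idx[3]] <- TRUE }
  }
  list(variants = v, tss = tss, tes = tes, chrom = chromOf)
}

#' Simulate multi-population genotype panels
#'
#' Draws an ancestral frequency p0 ~ Uniform(0.05, 0.95) per variant, then a
#' per-population frequency from the Balding-Nichols Beta distribution
#' parameterized by that population's Fst (Fst = 0 reproduces p0 exactly).
#' Haplotypes within LD blocks of consecutive variants are generated by
#' thresholding latent AR(1) Gaussians at the frequency quantile; dosage is
#' the sum of two haplotypes.  Genes are laid out on synthetic chromosomes
#' with non-overlapping cis windows, and each variant record carries the gene
#' whose cis set it belongs to.
#'
#' @param config a [simConfig()] object (Fst = 1 is rejected as degenerate).
#' @param withArtifacts also inject one ambiguous-strand, one indel and one
#'   multiallelic record to exercise the QC filters.
#' @return named list of \linkS4class{GenotypePanel}, one per population;
#'   rowData carries the realized population frequency (`freq`), the
#'   ancestral frequency and the LD block id; the gene layout is attached as
#'   `attr(x, "layout")`.
#' @export
simulateGenotypes <- function(config, withArtifacts = FALSE) {
  validObject(config)
  set.seed(config@seed)
  lay <- .variantLayout(config, withArtifacts)
  v <- lay$variants
  M <- nrow(v)
  p0 <- stats::runif(M, 0.05, 0.95)
  panels <- vector("list", config@nPopulations)
  names(panels) <- config@populations
  for (r in seq_len(config@nPopulations)) {
    pr <- .bnFrequencies(p0, config@fstPerPop[r])
    n <- config@nSamplesPerPop[r]
    dos <- .simulateDosages(pr, v$block, n, config@ldRho)
    vr <- v
    vr$freq <- pr
    vr$ancestralFreq <- p0
    sex <- sample(c("F", "M"), n, replace = TRUE)
    panels[[r]] <- genotypePanel(dos, vr, population = config@populations[r],
                                 sex = sex)
    colnames(panels[[r]]) <- sprintf("%s_S%04d", config@populations[r],
                                     seq_len(n))
  }
  attr(panels, "layout") <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(config@nGenes)),
    chrom = lay$chrom, tss = lay$tss, tes = lay$tes, strand = "+",
    gene_type = "protein_coding", stringsAsFactors = FALSE
  )
  panels
}

.simulateDosages <- function(freq, block, n, rho) {
  M <- length(freq)
  dos <- matrix(0, M, n)
  for (b in unique(block)) {
    idx <- which(block == b)
    h1 <- .sampleHaplotypeBlock(n, freq[idx], rho)
    h2 <- .sampleHaplotypeBlock(n, freq[idx], rho)
    dos[idx, ] <- t(h1 + h2)
  }
  dos
}

#' Simulate a new cohort from an existing panel's population
#'
#' Draws fresh samples using the realized per-variant frequencies and the LD
#' block structure stored in a simulated panel; used for held-out test sets
#' and GWAS cohorts that share the training panel's LD.
#'
#' @param panel a \linkS4class{GenotypePanel} produced by
#'   [simulateGenotypes()].
#' @param n number of samples.
#' @param seed integer seed.
#' @param ldRho AR(1) latent correlation (defaults to the generating value if
#'   recorded, else 0.6).
#' @param population label for the new panel.
#' @return a \linkS4class{GenotypePanel}.
#' @export
simulateCohortLike <- function(panel, n, seed, ldRho = 0.6,
                               population = populationLabel(panel)) {
  set.seed(as.integer(seed))
  v <- variantInfo(panel)
  stopifnot(all(c("freq", "block") %in% colnames(v)))
  dos <- .simulateDosages(v$freq, v$block, n, ldRho)
  out <- genotypePanel(dos, v, population = population,
                       sex = sample(c("F", "M"), n, replace = TRUE))
  colnames(out) <- sprintf("%s_T%05d", population, seq_len(n))
  out
}

#' Simulate heritable expression across populations and exams
#'
#' Per gene the causal architecture is shared (identical effect vector in
#' every population) with probability `sharedEffectFraction`, specific to one
#' population with probability `specificEffectFraction`, and null otherwise.
#' The per-gene cis-h2 is drawn uniformly from `h2Distribution`; the
#' environmental variance in each population is set so that
#' Var(Xb)/Var(latent) equals the drawn h2 exactly (using the realized sample
#' variance of the genetic value).  Age and sex effects plus independent
#' exam-level noise are added per exam, and the emitted TPM-scale value is
#' exp of the latent value (strictly positive).
#'
#' @param panels named list of \linkS4class{GenotypePanel} from
#'   [simulateGenotypes()].
#' @param config the [simConfig()] used to build the panels.
#' @param exams number of expression time points.
#' @param ageEffect,sexEffect linear covariate effects on the latent scale.
#' @param truth optional \linkS4class{TruthSet} to reuse (the new panels then
#'   share the causal effects already drawn).
#' @param effectsFrom when reusing a truth for a panel whose population label
#'   it does not contain, the population whose effect vectors to apply.
#' @param seed seed; defaults to `config@seed + 1`.
#' @return list with `expression` (per population: list of per-exam
#'   \linkS4class{ExpressionPanel}), `covariates` (sample_id, age, sex,
#'   population) and `truth` (\linkS4class{TruthSet}).
#' @export
simulateExpression <- function(panels, config, exams = 2L,
                               ageEffect = 0.01, sexEffect = 0.1,
                               truth = NULL, effectsFrom = NULL,
                               seed = config@seed + 1L) {
  set.seed(as.integer(seed))
  layout <- attr(panels, "layout")
  if (is.null(layout))
    stop("panels must carry the simulated gene layout")
  genes <- layout$gene_id
  pops <- names(panels)
  newTruth <- is.null(truth)
  if (newTruth) {
    truth <- .drawArchitecture(panels, config, genes)
  }
  eff <- truth@effects
  h2tab <- truth@h2
  expr <- vector("list", length(pops)); names(expr) <- pops
  covars <- NULL
  h2rows <- list()
  for (pp in pops) {
    pan <- panels[[pp]]
    effPop <- if (!is.null(effectsFrom)) effectsFrom else pp
    dos <- dosageMatrix(pan)
    v <- variantInfo(pan)
    n <- ncol(dos)
    age <- round(stats::runif(n, 45, 84))
    sex01 <- as.integer(sampleSex(pan) == "M")
    covars <- rbind(covars, data.frame(
      sample_id = colnames(dos), age = age,
      sex = sampleSex(pan), population = pp, stringsAsFactors = FALSE))
    G <- length(genes)
    lat <- matrix(0, G, n, dimnames = list(genes, colnames(dos)))
    veVec <- numeric(G)
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      e <- eff[eff$gene == g & eff$population == effPop, , drop = FALSE]
      target <- h2tab$h2[h2tab$gene == g & h2tab$population == effPop]
      target <- if (length(target)) target[1] else 0
      gv <- rep(0, n)
      if (nrow(e)) {
        idx <- match(e$variant, v$id)
        gv <- drop(crossprod(dos[idx, , drop = FALSE], e$beta))
      }
      vg <- stats::var(gv)
      if (vg > 0 && target > 0) {
        ve <- vg * (1 - target) / target
        realized <- target
      } else {
        ve <- 1
        realized <- 0
      }
      veVec[gi] <- ve
      ## stable (between-exam) noise carries half the environmental variance;
      ## each exam adds the other half, so the single-exam variance ratio
      ## Var(Xb)/Var(latent) equals the recorded h2 exactly
      lat[gi, ] <- gv + ageEffect * (age - mean(age)) + sexEffect * sex01 +
        stats::rnorm(n, 0, sqrt(ve / 2))
      h2rows[[length(h2rows) + 1L]] <-
        data.frame(gene = g, population = pp, h2 = realized,
                   stringsAsFactors = FALSE)
    }
    exl <- vector("list", exams)
    for (ex in seq_len(exams)) {
      lex <- lat +
        matrix(stats::rnorm(G * n), G, n) * sqrt(veVec / 2)
      exl[[ex]] <- expressionPanel(exp(lex), layout, stage = "tpm")
    }
    names(exl) <- paste0("exam", seq_len(exams))
    expr[[pp]] <- exl
  }
  h2df <- do.call(rbind, h2rows)
  if (newTruth || !is.null(effectsFrom)) {
    truth@h2 <- if (newTruth) h2df else rbind(truth@h2, h2df)
  }
  list(expression = expr, covariates = covars, truth = truth)
}

.drawArchitecture <- function(panels, config, genes) {
  pops <- names(panels)
  v1 <- variantInfo(panels[[1]])
  effRows <- list(); archRows <- list(); h2Rows <- list()
  for (g in genes) {
    u <- stats::runif(1)
    type <- if (u < config@sharedEffectFraction) "shared"
            else if (u < config@sharedEffectFraction +
                         config@specificEffectFraction) "specific"
            else "null"
    archRows[[g]] <- data.frame(gene = g, type = type,
                                stringsAsFactors = FALSE)
    h2g <- stats::runif(1, config@h2Distribution[1], config@h2Distribution[2])
    if (type == "null") h2g <- 0
    snps <- v1$id[v1$gene == g]
    if (type != "null" && length(snps)) {
      causal <- sample(snps, min(config@nCausalPerGene, length(snps)))
      b <- stats::rnorm(length(causal))
      tgt <- if (type == "specific") sample(pops, 1) else pops
      for (pp in tgt) {
        effRows[[paste(g, pp)]] <- data.frame(
          gene = g, variant = causal, population = pp, beta = b,
          stringsAsFactors = FALSE)
      }
      for (pp in pops) {
        h2Rows[[paste(g, pp)]] <- data.frame(
          gene = g, population = pp,
          h2 = if (pp %in% tgt) h2g else 0, stringsAsFactors = FALSE)
      }
    } else {
      for (pp in pops)
        h2Rows[[paste(g, pp)]] <- data.frame(gene = g, population = pp,
                                             h2 = 0, stringsAsFactors = FALSE)
    }
  }
  new("TruthSet",
      effects = if (length(effRows)) do.call(rbind, effRows) else
        data.frame(gene = character(), variant = character(),
                   population = character(), beta = numeric()),
      h2 = do.call(rbind, h2Rows),
      architecture = do.call(rbind, archRows),
      trait = data.frame(gene = character(), effect = numeric()))
}

#' Simulate a quantitative trait and GWAS marginal summary statistics
#'
#' The trait is the sum over causal genes of (cis genetic value x gene-level
#' effect) plus Gaussian noise scaled to a target trait heritability; each
#' variant is then tested by simple marginal regression, yielding beta, se
#' and z = beta/se, together with the effect (alt) and non-effect (ref)
#' alleles and the cohort allele frequency.
#'
#' @param panel GWAS cohort genotypes (e.g. [simulateCohortLike()]).
#' @param truth \linkS4class{TruthSet} with the expression effects.
#' @param config the [simConfig()] (supplies the seed default).
#' @param causalGenes character vector of causal genes, or NULL to sample
#'   `propCausal` of the genes with nonzero effects; use `character(0)` for a
#'   null trait.
#' @param propCausal fraction of eligible genes made causal when
#'   `causalGenes` is NULL.
#' @param effectsFrom population whose effect vectors define genetic values.
#' @param traitH2 target Var(genetic)/Var(trait).
#' @param seed seed; defaults to `config@seed + 2`.
#' @return list with `stats` (data.frame: variant_id, chromosome, position,
#'   effect_allele, non_effect_allele, frequency, beta, se, zscore, n),
#'   `trait` (the simulated phenotype vector, for individual-level
#'   cross-checks) and `truth` (the TruthSet with the trait slot filled).
#' @export
simulateGwas <- function(panel, truth, config, causalGenes = NULL,
                         propCausal = 0.2,
                         effectsFrom = populationLabel(panel),
                         traitH2 = 0.3, seed = config@seed + 2L) {
  set.seed(as.integer(seed))
  dos <- dosageMatrix(panel)
  v <- variantInfo(panel)
  n <- ncol(dos)
  eff <- truth@effects[truth@effects$population == effectsFrom, , drop = FALSE]
  eligible <- unique(eff$gene)
  if (is.null(causalGenes))
    causalGenes <- sample(eligible, max(1L, round(propCausal * length(eligible))))
  causalGenes <- intersect(causalGenes, eligible)
  gvalue <- rep(0, n)
  geneEff <- numeric(0)
  for (g in causalGenes) {
    e <- eff[eff$gene == g, , drop = FALSE]
    idx <- match(e$variant, v$id)
    w <- stats::rnorm(1)
    geneEff <- c(geneEff, stats::setNames(w, g))
    gvalue <- gvalue + w * drop(crossprod(dos[idx, , drop = FALSE], e$beta))
  }
  vg <- stats::var(gvalue)
  ve <- if (vg > 0) vg * (1 - traitH2) / traitH2 else 1
  y <- gvalue + stats::rnorm(n, 0, sqrt(ve))
  ## vectorized per-variant marginal regression
  yc <- y - mean(y)
  xc <- dos - rowMeans(dos)
  sxx <- rowSums(xc^2)
  sxy <- drop(xc %*% yc)
  syy <- sum(yc^2)
  ok <- sxx > 0
  beta <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - beta * sxy[ok], 0)
  se <- sqrt(rss / (n - 2) / sxx[ok])
  se <- pmax(se, 1e-12)
  stats <- data.frame(
    variant_id = v$id[ok], chromosome = v$chrom[ok], position = v$pos[ok],
    effect_allele = v$alt[ok], non_effect_allele = v$ref[ok],
    frequency = rowMeans(dos)[ok] / 2,
    beta = beta, se = se, zscore = beta / se, n = n,
    stringsAsFactors = FALSE
  )
  truth@trait <- data.frame(gene = names(geneEff), effect = unname(geneEff),
                            stringsAsFactors = FALSE)
  list(stats = stats, trait = stats::setNames(y, colnames(dos)),
       truth = truth)
}
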