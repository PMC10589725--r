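## Variant-level genotype QC: Wigginton-style exact Hardy-Weinberg test,
## the indel / multiallelic / ambiguous-strand / MAF / HWE filter cascade
## with chromosome-X rules, and greedy windowed LD pruning.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.isAmbiguousPair <- function(ref, alt) {
  ok <- ref %in% names(.COMPLEMENT) & alt %in% names(.COMPLEMENT)
  out <- rep(FALSE, length(ref))
  out[ok] <- .COMPLEMENT[ref[ok]] == alt[ok]
  out
}

.isIndel <- function(ref, alt) nchar(ref) != 1L | nchar(alt) != 1L

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on genotype counts: conditional on the observed
#' allele counts, the p-value is the sum of probabilities of all heterozygote
#' counts no more probable than the observed one (the PLINK/Wigginton
#' convention).  Probabilities are computed in log space so large samples do
#' not overflow.
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (non-negative, total >= 1).
#' @return exact two-sided p-value in (0, 1].
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  stopifnot(nHomRef >= 0, nHet >= 0, nHomAlt >= 0)
  n <- nHomRef + nHet + nHomAlt
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * nHomRef + nHet            # allele counts; which is minor is moot:
  nB <- 2 * nHomAlt + nHet            # the distribution is symmetric in A/B
  if (nA == 0 || nB == 0) return(1.0) # monomorphic: single configuration
  hets <- seq(nHet %% 2, min(nA, nB), by = 2)
  ## log P(het = h | n, nA) up to a shared constant:
  ##   n! 2^h / ( ((nA-h)/2)! h! ((nB-h)/2)! )
  lp <- hets * log(2) -
    lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) - lgamma((nB - hets) / 2 + 1)
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  pObs <- p[match(nHet, hets)]
  min(1, sum(p[p <= pObs * (1 + 1e-12)]))
}

.genotypeCounts <- function(dos) {
  g <- round(dos)
  c(sum(g == 0), sum(g == 1), sum(g == 2))
}

#' Per-variant MAF from dosages
#'
#' Frequency is mean dosage / 2 folded to <= 0.5.  On non-pseudoautosomal X,
#' male samples contribute a single allele (dosage / 2).
#' @keywords internal
.mafFromDosage <- function(dos, male = NULL, hemizygous = FALSE) {
  if (hemizygous && !is.null(male) && any(male)) {
    alleles <- sum(dos[!male]) + sum(dos[male]) / 2
    total <- 2 * sum(!male) + sum(male)
    f <- alleles / total
  } else {
    f <- mean(dos) / 2
  }
  min(f, 1 - f)
}

#' Filter variants by type, MAF and Hardy-Weinberg equilibrium
#'
#' Drops (in order) indels, multiallelic records, ambiguous-strand SNPs
#' (A/T, T/A, C/G, G/C), then variants with MAF below `mafMin` or exact HWE
#' p-value below `hweAlpha`.  On chromosome X the HWE test is applied only
#' inside the pseudoautosomal regions (GRCh38 intervals by default,
#' overridable via `metadata(panel)$par`), and males contribute one allele
#' to the non-PAR MAF.  Applying the filter twice equals applying it once.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param hweAlpha HWE p-value threshold (default 1e-6); 0 disables the test.
#' @return the filtered panel; `metadata(x)$qcTally` holds the per-rule
#'   removal counts (indel, multiallelic, ambiguous, maf, hwe, kept).
#' @export
filterVariants <- function(panel, mafMin = 0.01, hweAlpha = 1e-6) {
  v <- variantInfo(panel)
  dos <- dosageMatrix(panel)
  male <- sampleSex(panel) %in% c("M", "male", 1L)
  par <- S4Vectors::metadata(panel)$par
  n <- nrow(v)
  status <- rep("kept", n)
  indel <- .isIndel(v$ref, v$alt)
  multi <- if ("multiallelic" %in% colnames(v)) v$multiallelic else
    rep(FALSE, n)
  ambig <- .isAmbiguousPair(v$ref, v$alt)
  status[ambig] <- "ambiguous"
  status[multi] <- "multiallelic"
  status[indel] <- "indel"
  onX <- .isChrX(v$chrom)
  inPar <- .inPAR(v$pos, par)
  for (i in which(status == "kept")) {
    hemi <- onX[i] && !inPar[i]
    maf <- .mafFromDosage(dos[i, ], male, hemizygous = hemi)
    if (maf < mafMin) { status[i] <- "maf"; next }
    if (hweAlpha > 0 && (!onX[i] || inPar[i])) {
      cnt <- .genotypeCounts(dos[i, ])
      if (hweExactTest(cnt[1], cnt[2], cnt[3]) < hweAlpha) status[i] <- "hwe"
    }
  }
  tally <- c(indel = sum(status == "indel"),
             multiallelic = sum(status == "multiallelic"),
             ambiguous = sum(status == "ambiguous"),
             maf = sum(status == "maf"),
             hwe = sum(status == "hwe"),
             kept = sum(status == "kept"))
  out <- panel[status == "kept", ]
  S4Vectors::metadata(out)$qcTally <- tally
  out
}

#' Greedy windowed LD pruning
#'
#' Within each window of `window` consecutive kept variants, pairs with
#' dosage-correlation r-squared above `r2Max` are broken by removing one
#' variant of the pair: the one with the lower MAF, ties broken by the later
#' genomic position.  The window slides by `step` kept variants; passes
#' repeat until no intra-window pair exceeds the threshold.  Zero-variance
#' variants are treated as r-squared 0 with every other variant.
#'
#' @param panel a \linkS4class{GenotypePanel} with >= 1 variant.
#' @param window window size in kept-variant count (default 500).
#' @param step slide in kept-variant count (default 50).
#' @param r2Max maximum allowed pairwise r-squared (default 0.2).
#' @return character vector of kept variant ids in positional order.
#' @export
ldPrune <- function(panel, window = 500L, step = 50L, r2Max = 0.2) {
  v <- variantInfo(panel)
  if (nrow(v) < 1) stop("at least one variant required")
  dos <- dosageMatrix(panel)
  ord <- order(v$chrom, v$pos)
  ids <- v$id[ord]
  maf <- vapply(ord, function(i) .mafFromDosage(dos[i, ]), numeric(1))
  names(maf) <- ids
  pos <- stats::setNames(v$pos[ord], ids)
  X <- t(dos[ord, , drop = FALSE])   # samples x variants
  colnames(X) <- ids
  kept <- ids
  repeat {
    removedAny <- FALSE
    start <- 1L
    while (start <= length(kept)) {
      idx <- seq(start, min(start + window - 1L, length(kept)))
      if (length(idx) >= 2) {
        w <- kept[idx]
        r2 <- suppressWarnings(stats::cor(X[, w, drop = FALSE]))^2
        r2[!is.finite(r2)] <- 0       # zero-variance columns
        diag(r2) <- 0
        while (max(r2) > r2Max) {
          pair <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
          a <- rownames(r2)[pair[1]]; b <- colnames(r2)[pair[2]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else if (pos[a] >= pos[b]) a else b
          keep <- setdiff(rownames(r2), drop)
          r2 <- r2[keep, keep, drop = FALSE]
          kept <- setdiff(kept, drop)
          removedAny <- TRUE
          if (length(keep) < 2) break
        }
      }
      if (start + window - 1L >= length(kept)) break
      start <- start + step
    }
    if (!removedAny) break
  }
  kept
}
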