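## Individual-level prediction of genetically regulated expression (GReX)
## with Spearman evaluation, and summary-statistics TWAS: per-gene z from
## GWAS z-scores, model weights and reference dosage covariances, with
## Bonferroni significance (p < 5e-8) and same-direction cross-study
## replication.

#' Predict genetically regulated expression
#'
#' GReX_sg = sum over the gene's model SNPs of weight x effect-allele
#' dosage.  SNPs absent from the panel contribute 0 and are tallied in
#' `attr(x, "missingSnps")`.
#'
#' @param panel a \linkS4class{GenotypePanel} (allele-harmonized to the
#'   model; see [harmonizeAlleles()]).
#' @param model a \linkS4class{PredictionModel}.
#' @return samples x genes matrix.
#' @export
predictGrex <- function(panel, model) {
  dos <- dosageMatrix(panel)
  w <- modelWeights(model)
  genes <- unique(w$gene)
  out <- matrix(0, ncol(dos), length(genes),
                dimnames = list(colnames(dos), genes))
  missing <- 0L
  for (g in genes) {
    rows <- w[w$gene == g, , drop = FALSE]
    hit <- rows$rsid %in% rownames(dos)
    missing <- missing + sum(!hit)
    if (any(hit)) {
      out[, g] <- drop(crossprod(dos[rows$rsid[hit], , drop = FALSE],
                                 rows$weight[hit]))
    }
  }
  attr(out, "missingSnps") <- missing
  out
}

#' Spearman evaluation of predicted expression
#'
#' Rank correlation per gene between GReX and observed (adjusted) expression
#' over the shared samples.  Genes with constant GReX have undefined rho and
#' are reported as NA.
#'
#' @param grex samples x genes matrix from [predictGrex()].
#' @param observed an \linkS4class{ExpressionPanel} (genes x samples).
#' @return data.frame(gene, rho, p, n).
#' @export
evaluatePrediction <- function(grex, observed) {
  obs <- exprMatrix(observed)
  shared <- intersect(rownames(grex), colnames(obs))
  genes <- intersect(colnames(grex), rownames(obs))
  out <- data.frame(gene = genes, rho = NA_real_, p = NA_real_,
                    n = length(shared), stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    x <- grex[shared, g]
    y <- obs[g, shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p[i] <- ct$p.value
  }
  out
}

#' Harmonize GWAS alleles to a model
#'
#' Exact effect/non-effect allele match: keep; swapped alleles: flip the
#' sign of z (and beta); ambiguous-strand (A/T, C/G) or mismatched pairs:
#' drop.  Returns the aligned statistics plus a {matched, flipped, dropped}
#' tally.
#'
#' @param gwas data.frame with variant_id, effect_allele, non_effect_allele,
#'   beta, se, zscore.
#' @param model a \linkS4class{PredictionModel}.
#' @return list(stats = aligned data.frame, tally = named counts).
#' @export
harmonizeAlleles <- function(gwas, model) {
  w <- modelWeights(model)
  mv <- w[!duplicated(w$rsid), c("rsid", "ref_allele", "eff_allele")]
  m <- merge(gwas, mv, by.x = "variant_id", by.y = "rsid")
  if (!"zscore" %in% colnames(m) && all(c("beta", "se") %in% colnames(m)))
    m$zscore <- m$beta / m$se
  ambig <- .isAmbiguousPair(m$effect_allele, m$non_effect_allele)
  exact <- !ambig & m$effect_allele == m$eff_allele &
    m$non_effect_allele == m$ref_allele
  swap <- !ambig & m$effect_allele == m$ref_allele &
    m$non_effect_allele == m$eff_allele
  dropped <- !(exact | swap)
  out <- m[!dropped, , drop = FALSE]
  flip <- swap[!dropped]
  out$zscore[flip] <- -out$zscore[flip]
  if ("beta" %in% colnames(out)) out$beta[flip] <- -out$beta[flip]
  out$effect_allele[flip] <- out$eff_allele[flip]
  out$non_effect_allele[flip] <- out$ref_allele[flip]
  list(stats = out[, setdiff(colnames(out), c("ref_allele", "eff_allele"))],
       tally = c(matched = sum(exact), flipped = sum(swap),
                 dropped = sum(dropped)))
}

#' Summary-statistics TWAS for one gene
#'
#' With model weights w, per-SNP GWAS z-scores z_l, reference dosage
#' variances sigma_l^2 (the covariance diagonal) and predicted-expression
#' variance sigma_g^2 = w' Gamma w (Gamma restricted to the SNPs present in
#' the GWAS after harmonization):
#' z_g = sum_l w_l (sigma_l / sigma_g) z_l, p = 2 Phi(-|z_g|).  The effect
#' size is computed analogously from betas when available.
#'
#' @param model a \linkS4class{PredictionModel}.
#' @param gene gene id.
#' @param gwas harmonized GWAS statistics ([harmonizeAlleles()] output).
#' @param covs a \linkS4class{CovarianceSet} for the model.
#' @return one-row data.frame(gene, zscore, pvalue, effect_size, var_g,
#'   n_snps_used, n_snps_in_model, status), or NULL when no model SNP
#'   overlaps the GWAS.
#' @export
spredixcanGene <- function(model, gene, gwas, covs) {
  w <- modelWeights(model)
  rows <- w[w$gene == gene, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  G <- covs@covariances[[gene]]
  hit <- rows$rsid %in% gwas$variant_id & rows$rsid %in% rownames(G)
  if (!any(hit)) return(NULL)
  rows <- rows[hit, , drop = FALSE]
  G <- G[rows$rsid, rows$rsid, drop = FALSE]
  gz <- gwas[match(rows$rsid, gwas$variant_id), ]
  varg <- drop(t(rows$weight) %*% G %*% rows$weight)
  if (varg <= 0) {
    return(data.frame(gene = gene, zscore = NA_real_, pvalue = NA_real_,
                      effect_size = NA_real_, var_g = varg,
                      n_snps_used = nrow(rows),
                      n_snps_in_model = sum(w$gene == gene),
                      status = "nonpositive_var_g",
                      stringsAsFactors = FALSE))
  }
  sig <- sqrt(diag(G))
  zg <- sum(rows$weight * sig * gz$zscore) / sqrt(varg)
  eff <- if ("beta" %in% colnames(gz))
    sum(rows$weight * sig^2 * gz$beta) / varg else NA_real_
  data.frame(gene = gene, zscore = zg,
             pvalue = 2 * stats::pnorm(-abs(zg)),
             effect_size = eff, var_g = varg,
             n_snps_used = nrow(rows),
             n_snps_in_model = sum(w$gene == gene),
             status = "ok", stringsAsFactors = FALSE)
}

#' Summary-statistics TWAS across all genes of a model
#'
#' @param model a \linkS4class{PredictionModel}.
#' @param gwas raw GWAS statistics (harmonized internally).
#' @param covs a \linkS4class{CovarianceSet}.
#' @return data.frame of [spredixcanGene()] rows with the model tag columns;
#'   skipped genes are tallied in `attr(x, "skipped")`.
#' @export
spredixcanAll <- function(model, gwas, covs) {
  h <- harmonizeAlleles(gwas, model)
  genes <- unique(modelWeights(model)$gene)
  rows <- lapply(genes, function(g) spredixcanGene(model, g, h$stats, covs))
  skipped <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$method <- model@method
    out$population <- model@population
    out$tissue <- model@tissue
  }
  attr(out, "skipped") <- skipped
  attr(out, "harmonization") <- h$tally
  out
}

#' Significance and cross-study replication calls
#'
#' A gene-trait association is significant when its p-value is strictly
#' below `alpha` (default: the Bonferroni-corrected GWAS threshold 5e-8);
#' it replicates when significant in both studies with the same
#' method/population/tissue model tag and the same direction of effect.
#'
#' @param results1,results2 [spredixcanAll()] outputs for the two studies.
#' @param alpha significance threshold (default 5e-8).
#' @return `results1` with columns significant, partner_zscore,
#'   partner_pvalue, replicated.
#' @export
callSignificantAndReplicate <- function(results1, results2, alpha = 5e-8) {
  r1 <- results1
  r1$significant <- !is.na(r1$pvalue) & r1$pvalue < alpha
  key <- function(d) paste(d$gene, d$method, d$population, d$tissue)
  idx <- match(key(r1), key(results2))
  r1$partner_zscore <- results2$zscore[idx]
  r1$partner_pvalue <- results2$pvalue[idx]
  sig2 <- !is.na(r1$partner_pvalue) & r1$partner_pvalue < alpha
  r1$replicated <- r1$significant & sig2 &
    sign(r1$zscore) == sign(r1$partner_zscore)
  r1$replicated[is.na(r1$replicated)] <- FALSE
  r1
}
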