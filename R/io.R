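## Readers and writers for the pipeline's exchange formats: plain dosage
## TSV, VCF with a DS field, expression / annotation / covariate / GWAS
## TSVs, posterior and effect long tables, PredictDB-style model stores
## (SQLite when RSQLite is available, flat TSV bundle otherwise) and
## gzipped covariance files.

#' Write a dosage TSV
#'
#' Columns: variant_id, chrom, pos, ref, alt, then one column per sample.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path output path.
#' @export
writeDosageTsv <- function(panel, path) {
  v <- variantInfo(panel)
  dos <- dosageMatrix(panel)
  df <- cbind(data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos,
                         ref = v$ref, alt = v$alt,
                         stringsAsFactors = FALSE),
              as.data.frame(dos))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a dosage TSV written by [writeDosageTsv()]
#'
#' @param path input path.
#' @param population population label for the panel.
#' @param sex optional per-sample sex.
#' @return a \linkS4class{GenotypePanel}.
#' @export
readDosageTsv <- function(path, population = "POP1", sex = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  meta <- c("variant_id", "chrom", "pos", "ref", "alt")
  samples <- setdiff(colnames(df), meta)
  dos <- as.matrix(df[, samples, drop = FALSE])
  rownames(dos) <- df$variant_id
  genotypePanel(dos,
                data.frame(chrom = as.character(df$chrom), pos = df$pos,
                           id = df$variant_id, ref = df$ref, alt = df$alt,
                           stringsAsFactors = FALSE),
                population = population, sex = sex)
}

#' Write genotypes as VCF with a DS (dosage) FORMAT field
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param path output path (plain text).
#' @export
writeVcf <- function(panel, path) {
  v <- variantInfo(panel)
  dos <- dosageMatrix(panel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(dos)), collapse = "\t")),
             con)
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "DS",
                format(dos, trim = TRUE, digits = 6))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a VCF into a GenotypePanel
#'
#' Uses the DS FORMAT field when present, otherwise counts GT alt alleles.
#' Requires the vcfR package.
#'
#' @param path VCF path (plain or gzipped).
#' @param population population label.
#' @param sex optional per-sample sex.
#' @return a \linkS4class{GenotypePanel}.
#' @export
readVcf <- function(path, population = "POP1", sex = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(vc, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(vc, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(gsub("\\|", "/", col), "/"),
             function(a) sum(a != "0" & a != "."), numeric(1))
    })
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  rownames(ds) <- ids
  genotypePanel(ds,
                data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                           id = ids, ref = fix$REF, alt = fix$ALT,
                           stringsAsFactors = FALSE),
                population = population, sex = sex)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an expression panel as TSV (genes x samples)
#' @param panel an \linkS4class{ExpressionPanel}.
#' @param path output path.
#' @export
writeExpressionTsv <- function(panel, path) {
  df <- cbind(data.frame(gene_id = rownames(panel)),
              as.data.frame(exprMatrix(panel)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Write the gene annotation as BED-like TSV
#'
#' Columns chrom, start, end, gene_id, strand; start/end are the 1-based
#' inclusive TSS/TES (stated in the header comment).
#' @param panel an \linkS4class{ExpressionPanel}.
#' @param path output path.
#' @export
writeAnnotationTsv <- function(panel, path) {
  ann <- geneAnnotation(panel)
  con <- file(path, "w")
  writeLines("# start/end are 1-based inclusive TSS/TES", con)
  close(con)
  data.table::fwrite(
    data.frame(chrom = ann$chrom, start = ann$tss, end = ann$tes,
               gene_id = ann$gene_id, strand = ann$strand),
    path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read expression + annotation TSVs into an ExpressionPanel
#' @param exprPath,annPath paths written by the two writers above.
#' @param stage stage tag of the stored values.
#' @return an \linkS4class{ExpressionPanel}.
#' @export
readExpressionTsv <- function(exprPath, annPath, stage = "tpm") {
  df <- as.data.frame(data.table::fread(exprPath, sep = "\t"))
  ann <- as.data.frame(data.table::fread(annPath, sep = "\t", skip = 1))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  ann <- ann[match(df$gene_id, ann$gene_id), ]
  expressionPanel(m, data.frame(gene_id = ann$gene_id, chrom = ann$chrom,
                                tss = ann$start, tes = ann$end,
                                strand = ann$strand,
                                stringsAsFactors = FALSE), stage = stage)
}

#' Write GWAS summary statistics TSV
#' @param stats data.frame from [simulateGwas()] (variant_id, chromosome,
#'   position, effect_allele, non_effect_allele, frequency, beta, se,
#'   zscore, n).
#' @param path output path.
#' @export
writeGwasTsv <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}

#' Read GWAS summary statistics TSV
#'
#' z is filled in as beta/se when absent and checked for consistency
#' (|z - beta/se| < 1e-6) when both are present.
#' @param path input path.
#' @return data.frame.
#' @export
readGwasTsv <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"zscore" %in% colnames(df)) {
    df$zscore <- df$beta / df$se
  } else if (all(c("beta", "se") %in% colnames(df))) {
    bad <- abs(df$zscore - df$beta / df$se) > 1e-6
    if (any(bad, na.rm = TRUE))
      warning(sum(bad, na.rm = TRUE), " rows with z inconsistent with beta/se")
  }
  df
}

#' Write marginal effects as a long TSV
#' @param effects an \linkS4class{EffectMatrixSet}.
#' @param path output path.
#' @export
writeEffectsTsv <- function(effects, path) {
  pops <- colnames(effects@bhat)
  long <- do.call(rbind, lapply(seq_along(pops), function(r) {
    data.frame(gene = effects@genes, variant = effects@variants,
               population = pops[r], beta = effects@bhat[, r],
               se = effects@shat[, r], p = effects@pval[, r],
               observed = effects@observed[, r], stringsAsFactors = FALSE)
  }))
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' Read a long effects TSV back into an EffectMatrixSet
#' @param path input path.
#' @param df residual degrees of freedom per population (named), when known.
#' @return an \linkS4class{EffectMatrixSet}.
#' @export
readEffectsTsv <- function(path, df = NULL) {
  long <- as.data.frame(data.table::fread(path, sep = "\t"))
  key <- paste(long$gene, long$variant)
  rows <- !duplicated(key)
  pops <- unique(long$population)
  nr <- sum(rows)
  ridx <- match(key, key[rows])
  cidx <- match(long$population, pops)
  mk <- function(col, default = NA_real_) {
    m <- matrix(default, nr, length(pops), dimnames = list(NULL, pops))
    m[cbind(ridx, cidx)] <- long[[col]]
    m
  }
  obs <- matrix(FALSE, nr, length(pops), dimnames = list(NULL, pops))
  obs[cbind(ridx, cidx)] <- long$observed
  if (is.null(df)) df <- stats::setNames(rep(NA_real_, length(pops)), pops)
  new("EffectMatrixSet", genes = long$gene[rows],
      variants = long$variant[rows], bhat = mk("beta"), shat = mk("se"),
      pval = mk("p"), df = df, observed = obs)
}

#' Write posterior summaries as a long TSV
#' @param posteriors a \linkS4class{PosteriorSet}.
#' @param path output path.
#' @export
writePosteriorTsv <- function(posteriors, path) {
  pops <- posteriors@populations
  long <- do.call(rbind, lapply(seq_along(pops), function(r) {
    data.frame(gene = posteriors@genes, variant = posteriors@variants,
               population = pops[r], post_mean = posteriors@postMean[, r],
               post_sd = posteriors@postSD[, r],
               lfsr = posteriors@lfsr[, r], stringsAsFactors = FALSE)
  }))
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' Store a prediction model (PredictDB-style)
#'
#' Writes tables `weights` (rsid, gene, weight, ref_allele, eff_allele) and
#' `extra` (gene, genename, n_snps_in_model, pred_perf_R2, pred_perf_pval).
#' With `format = "sqlite"` a PredictDB-compatible SQLite database is
#' written (requires RSQLite); the default flat bundle writes
#' `<path>.weights.tsv` and `<path>.extra.tsv` with identical columns.
#'
#' @param model a \linkS4class{PredictionModel}.
#' @param path output path stem (or .db path for sqlite).
#' @param format "tsv" or "sqlite".
#' @export
writeModelStore <- function(model, path, format = c("tsv", "sqlite")) {
  format <- match.arg(format)
  w <- modelWeights(model)[, c("rsid", "gene", "weight", "ref_allele",
                               "eff_allele")]
  e <- modelExtra(model)[, c("gene", "genename", "n_snps_in_model",
                             "pred_perf_R2", "pred_perf_pval")]
  if (format == "sqlite") {
    if (!requireNamespace("RSQLite", quietly = TRUE) ||
        !requireNamespace("DBI", quietly = TRUE))
      stop("sqlite output requires the RSQLite and DBI packages")
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    DBI::dbWriteTable(con, "weights", w, overwrite = TRUE)
    DBI::dbWriteTable(con, "extra", e, overwrite = TRUE)
  } else {
    data.table::fwrite(w, paste0(path, ".weights.tsv"), sep = "\t")
    data.table::fwrite(e, paste0(path, ".extra.tsv"), sep = "\t")
  }
  invisible(path)
}

#' Load a prediction model store
#' @param path path stem (tsv bundle) or .db path (sqlite).
#' @param method,population,tissue tag for the loaded model.
#' @param format "tsv" or "sqlite".
#' @param variantTable optional data.frame(id, chrom, pos) to restore
#'   positions.
#' @return a \linkS4class{PredictionModel}.
#' @export
readModelStore <- function(path, method = "mashr", population = "POP1",
                           tissue = "tissue", format = c("tsv", "sqlite"),
                           variantTable = NULL) {
  format <- match.arg(format)
  if (format == "sqlite") {
    if (!requireNamespace("RSQLite", quietly = TRUE) ||
        !requireNamespace("DBI", quietly = TRUE))
      stop("sqlite input requires the RSQLite and DBI packages")
    con <- DBI::dbConnect(RSQLite::SQLite(), path)
    on.exit(DBI::dbDisconnect(con))
    w <- DBI::dbReadTable(con, "weights")
    e <- DBI::dbReadTable(con, "extra")
  } else {
    w <- as.data.frame(data.table::fread(paste0(path, ".weights.tsv")))
    e <- as.data.frame(data.table::fread(paste0(path, ".extra.tsv")))
  }
  w$chrom <- NA_character_; w$pos <- NA_integer_
  if (!is.null(variantTable)) {
    i <- match(w$rsid, variantTable$id)
    w$chrom <- variantTable$chrom[i]
    w$pos <- variantTable$pos[i]
  }
  new("PredictionModel", method = method, population = population,
      tissue = tissue,
      weights = w[, c("gene", "rsid", "chrom", "pos", "ref_allele",
                      "eff_allele", "weight")],
      extra = e)
}

#' Write model SNP covariances (gzip TSV)
#'
#' Header `GENE RSID1 RSID2 VALUE`; upper triangle including the diagonal.
#' @param covs a \linkS4class{CovarianceSet}.
#' @param path output path (".gz" appended if missing).
#' @export
writeCovariances <- function(covs, path) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  rows <- list()
  for (g in names(covs@covariances)) {
    G <- covs@covariances[[g]]
    ids <- rownames(G)
    for (i in seq_along(ids)) for (j in i:length(ids)) {
      rows[[length(rows) + 1L]] <-
        data.frame(GENE = g, RSID1 = ids[i], RSID2 = ids[j],
                   VALUE = G[i, j], stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  con <- gzfile(path, "w")
  utils::write.table(df, con, sep = " ", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a covariance file written by [writeCovariances()]
#' @param path input path.
#' @param population population tag.
#' @return a \linkS4class{CovarianceSet}.
#' @export
readCovariances <- function(path, population = "POP1") {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  covs <- list()
  for (g in unique(df$GENE)) {
    sub <- df[df$GENE == g, ]
    ids <- unique(c(sub$RSID1, sub$RSID2))
    G <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (k in seq_len(nrow(sub))) {
      G[sub$RSID1[k], sub$RSID2[k]] <- sub$VALUE[k]
      G[sub$RSID2[k], sub$RSID1[k]] <- sub$VALUE[k]
    }
    covs[[g]] <- G
  }
  new("CovarianceSet", population = population, covariances = covs)
}
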