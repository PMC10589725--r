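## Constructors, accessors and show methods for the two panel classes.

.isChrX <- function(chrom) chrom %in% c("X", "chrX", "23")

## 1-based inclusive PAR intervals; par is a data.frame(start, end) or NULL
.inPAR <- function(pos, par = NULL) {
  if (is.null(par)) par <- .GRCH38_PAR
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(par)))
    out <- out | (pos >= par$start[i] & pos <= par$end[i])
  out
}

#' Construct a GenotypePanel
#'
#' @param dosage numeric matrix, variants x samples, alt-allele dosages in
#'   [0, 2]; rownames are variant ids, colnames sample ids.
#' @param variants data.frame with columns chrom, pos, id, ref, alt and
#'   optional flags/frequencies; one row per dosage row.
#' @param population single population label.
#' @param sex per-sample sex ("F"/"M"); defaults to all "F" (no hemizygosity).
#' @param par optional data.frame(start, end) of pseudoautosomal intervals on
#'   X (1-based inclusive); defaults to GRCh38 PAR1/PAR2.
#' @return a \linkS4class{GenotypePanel}.
#' @export
genotypePanel <- function(dosage, variants, population = "POP1",
                          sex = NULL, par = NULL) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(variants) == nrow(dosage))
  if (is.null(sex)) sex <- rep("F", ncol(dosage))
  if (is.null(rownames(dosage))) rownames(dosage) <- variants$id
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("%s_S%04d", population, seq_len(ncol(dosage)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, width = 1L)
  )
  names(gr) <- variants$id
  keep <- setdiff(colnames(variants), c("chrom", "pos"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(variants[, keep, drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = gr,
    colData = S4Vectors::DataFrame(sex = sex, row.names = colnames(dosage))
  )
  obj <- new("GenotypePanel", se, population = population)
  if (!is.null(par)) S4Vectors::metadata(obj)$par <- par
  obj
}

#' Construct an ExpressionPanel
#'
#' @param values numeric matrix genes x samples; rownames gene ids.
#' @param genes data.frame with columns gene_id, chrom, tss, tes, strand and
#'   optional gene_type; one row per value row.  TSS/TES are 1-based inclusive.
#' @param stage processing stage: "tpm", "log_adjusted" or "residualized".
#' @return an \linkS4class{ExpressionPanel}.
#' @export
expressionPanel <- function(values, genes, stage = "tpm") {
  values <- as.matrix(values)
  stopifnot(nrow(genes) == nrow(values))
  if (is.null(rownames(values))) rownames(values) <- genes$gene_id
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%04d", seq_len(ncol(values)))
  lo <- pmin(genes$tss, genes$tes); hi <- pmax(genes$tss, genes$tes)
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(start = lo, end = hi),
    strand = if ("strand" %in% colnames(genes)) genes$strand else "*"
  )
  names(gr) <- genes$gene_id
  keep <- setdiff(colnames(genes), c("chrom", "strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(genes[, keep, drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), rowRanges = gr,
    colData = S4Vectors::DataFrame(row.names = colnames(values))
  )
  new("ExpressionPanel", se, stage = stage)
}

#' @rdname GenotypePanel-class
#' @export
setMethod("dosageMatrix", "GenotypePanel",
          function(x) SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypePanel-class
#' @export
setMethod("populationLabel", "GenotypePanel", function(x) x@population)

#' @rdname GenotypePanel-class
#' @export
setMethod("sampleSex", "GenotypePanel",
          function(x) SummarizedExperiment::colData(x)$sex)

#' @rdname GenotypePanel-class
#' @export
setMethod("variantInfo", "GenotypePanel", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  cbind(
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr)),
    as.data.frame(S4Vectors::mcols(gr))
  )
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object), "variants x", ncol(object), "samples,",
      "population", object@population, "\n")
})

#' @rdname ExpressionPanel-class
#' @export
setMethod("exprMatrix", "ExpressionPanel",
          function(x) SummarizedExperiment::assay(x, "expr"))

#' @rdname ExpressionPanel-class
#' @export
setMethod("expressionStage", "ExpressionPanel", function(x) x@stage)

#' @rdname ExpressionPanel-class
#' @export
setMethod("geneAnnotation", "ExpressionPanel", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  df <- as.data.frame(S4Vectors::mcols(gr))
  cbind(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr))), df)
})

setMethod("show", "ExpressionPanel", function(object) {
  cat("ExpressionPanel:", nrow(object), "genes x", ncol(object),
      "samples, stage", object@stage, "\n")
})

#' @rdname EffectMatrixSet-class
#' @export
setMethod("bhat", "EffectMatrixSet", function(x) x@bhat)

#' @rdname EffectMatrixSet-class
#' @export
setMethod("shat", "EffectMatrixSet", function(x) x@shat)

setMethod("show", "EffectMatrixSet", function(object) {
  cat("EffectMatrixSet:", length(object@genes), "gene-variant rows x",
      ncol(object@bhat), "populations (",
      paste(colnames(object@bhat), collapse = ", "), ")\n")
})

#' @rdname PosteriorSet-class
#' @export
setMethod("postMean", "PosteriorSet", function(x) x@postMean)

#' @rdname PosteriorSet-class
#' @export
setMethod("postSD", "PosteriorSet", function(x) x@postSD)

#' @rdname PosteriorSet-class
#' @export
setMethod("lfsr", "PosteriorSet", function(x) x@lfsr)

setMethod("show", "PosteriorSet", function(object) {
  cat("PosteriorSet:", length(object@genes), "rows x",
      length(object@populations), "populations\n")
})

setMethod("show", "MashFit", function(object) {
  cat("MashFit:", length(object@pi), "mixture components,",
      object@niter, "EM iterations, loglik",
      format(utils::tail(object@loglik, 1)), "\n")
  top <- sort(object@pi, decreasing = TRUE)
  top <- top[top > 0.01]
  if (length(top))
    cat("  weights > 1%:", paste(sprintf("%s=%.3f", names(top), top),
                                 collapse = ", "), "\n")
})

#' @rdname PredictionModel-class
#' @export
setMethod("modelWeights", "PredictionModel", function(x) x@weights)

#' @rdname PredictionModel-class
#' @export
setMethod("modelExtra", "PredictionModel", function(x) x@extra)

setMethod("show", "PredictionModel", function(object) {
  cat(sprintf("PredictionModel [%s | %s | %s]: %d genes, %d weights\n",
              object@method, object@population, object@tissue,
              nrow(object@extra), nrow(object@weights)))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nPopulations, "populations (",
      paste(sprintf("%s n=%d Fst=%.2f", object@populations,
                    object@nSamplesPerPop, object@fstPerPop), collapse = "; "),
      ")\n ", object@nGenes, "genes x", object@nCisSnpsPerGene,
      "cis SNPs, seed", object@seed, "\n")
})
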