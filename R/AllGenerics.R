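#' @rdname GenotypePanel-class
#' @param object,x a popmash object.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("populationLabel", function(x) standardGeneric("populationLabel"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("sampleSex", function(x) standardGeneric("sampleSex"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname ExpressionPanel-class
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname ExpressionPanel-class
#' @export
setGeneric("expressionStage", function(x) standardGeneric("expressionStage"))

#' @rdname ExpressionPanel-class
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @rdname EffectMatrixSet-class
#' @export
setGeneric("bhat", function(x) standardGeneric("bhat"))

#' @rdname EffectMatrixSet-class
#' @export
setGeneric("shat", function(x) standardGeneric("shat"))

#' @rdname PosteriorSet-class
#' @export
setGeneric("postMean", function(x) standardGeneric("postMean"))

#' @rdname PosteriorSet-class
#' @export
setGeneric("postSD", function(x) standardGeneric("postSD"))

#' @rdname PosteriorSet-class
#' @export
setGeneric("lfsr", function(x) standardGeneric("lfsr"))

#' @rdname PredictionModel-class
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname PredictionModel-class
#' @export
setGeneric("modelExtra", function(x) standardGeneric("modelExtra"))
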