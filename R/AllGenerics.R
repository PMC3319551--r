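#' @include AllClasses.R
NULL

#' Number of rows/columns of a speller grid
#' @param x a SpellerGrid or SessionFeatures
#' @return integer J (6 for the standard matrix)
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' Feature dimensionality (bias included)
#' @param x a SessionFeatures, PseudoSymbolBlock or ClassifierParams
#' @return integer D
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' Number of characters in a session
#' @param x a SessionFeatures
#' @return integer K
#' @export
setGeneric("nCharacters", function(x) standardGeneric("nCharacters"))

#' Ground-truth characters of a session (evaluation only)
#' @param x a SessionFeatures
#' @return character vector, or NULL when the session is unlabeled
#' @export
setGeneric("sessionTruth", function(x) standardGeneric("sessionTruth"))

#' The speller grid of a session
#' @param x a SessionFeatures
#' @return a SpellerGrid
#' @export
setGeneric("sessionGrid", function(x) standardGeneric("sessionGrid"))

#' Per-block view of a session
#' @param x a SessionFeatures
#' @return list of PseudoSymbolBlock, in session order
#' @export
setGeneric("sessionBlocks", function(x) standardGeneric("sessionBlocks"))

#' Classifier weight vector
#' @param x a ClassifierParams
#' @return numeric vector w
#' @export
setGeneric("weights", function(x) standardGeneric("weights"))

#' Projection noise variance beta
#' @param x a ClassifierParams
#' @return numeric beta
#' @export
setGeneric("noiseVariance", function(x) standardGeneric("noiseVariance"))

#' Prior precision alpha of the weight vector
#' @param x a ClassifierParams
#' @return numeric alpha
#' @export
setGeneric("priorPrecision", function(x) standardGeneric("priorPrecision"))

#' Trace table of an EM fit
#' @param x a FitTrace
#' @return data.frame with one row per iteration
#' @export
setGeneric("traceTable", function(x) standardGeneric("traceTable"))
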