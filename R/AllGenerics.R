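#' Access the per-tissue TPM assays of a PairedExpression
#'
#' @param x a [PairedExpression].
#' @name diploidTPM
#' @rdname diploidTPM
#' @export
setGeneric("diploidTPM", function(x) standardGeneric("diploidTPM"))

#' @rdname diploidTPM
#' @export
setGeneric("hexaploidTPM", function(x) standardGeneric("hexaploidTPM"))

#' Flag expressed syntenic pairs
#'
#' @param x object holding paired expression values.
#' @param ... method arguments (see the [PairedExpression] method).
#' @name flagExpressed
#' @rdname flagExpressed
#' @export
setGeneric("flagExpressed", function(x, ...) standardGeneric("flagExpressed"))

#' Cross-ploidy TPM normalization factor
#'
#' @param x object holding paired expression values.
#' @param ... method arguments (see the [PairedExpression] method).
#' @name computeNormalizationFactor
#' @rdname computeNormalizationFactor
#' @export
setGeneric("computeNormalizationFactor",
           function(x, ...) standardGeneric("computeNormalizationFactor"))

#' Classify syntenic pairs into balanced and differential classes
#'
#' @param x object holding paired expression values.
#' @param ... method arguments (see the [PairedExpression] method).
#' @name classifyPairs
#' @rdname classifyPairs
#' @export
setGeneric("classifyPairs", function(x, ...) standardGeneric("classifyPairs"))

#' Retrieve pair classifications
#'
#' @param x a classified object.
#' @name pairClasses
#' @rdname pairClasses
#' @export
setGeneric("pairClasses", function(x) standardGeneric("pairClasses"))

#' @rdname pairClasses
#' @export
setGeneric("overallClass", function(x) standardGeneric("overallClass"))

#' Per-bin means of a metaprofile
#'
#' @param x a profile object.
#' @name binMeans
#' @rdname binMeans
#' @export
setGeneric("binMeans", function(x) standardGeneric("binMeans"))
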