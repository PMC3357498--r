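#' @rdname GenotypePanel-class
#' @param x,object a \code{GenotypePanel}
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GenotypePanel-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname NullDistribution-class
#' @param x a \code{NullDistribution}
#' @export
setGeneric("nullStats", function(x) standardGeneric("nullStats"))

#' @rdname PairwiseHFTable-class
#' @param x a \code{PairwiseHFTable}
#' @export
setGeneric("hfPairs", function(x) standardGeneric("hfPairs"))
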