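#' @rdname fixedSites
#' @export
setGeneric("fixedSites", function(x) standardGeneric("fixedSites"))

#' @rdname EnumeratedAlignment
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname EnumeratedAlignment
#' @export
setGeneric("kingdoms", function(x) standardGeneric("kingdoms"))

#' @rdname EnumeratedAlignment
#' @export
setGeneric("residueMatrix", function(x) standardGeneric("residueMatrix"))

#' @rdname EnumeratedAlignment
#' @export
setGeneric("loopSeqs", function(x) standardGeneric("loopSeqs"))

#' @rdname EnumeratedAlignment
#' @export
setGeneric("coordinateMap", function(x) standardGeneric("coordinateMap"))

#' @rdname NumericDataset
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname NumericDataset
#' @export
setGeneric("variableInfo", function(x) standardGeneric("variableInfo"))

#' @rdname NumericDataset
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname CVAModel-accessors
#' @export
setGeneric("canonicalCoefficients",
           function(object) standardGeneric("canonicalCoefficients"))

#' @rdname CVAModel-accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @rdname CVAModel-accessors
#' @export
setGeneric("varianceProportions",
           function(object) standardGeneric("varianceProportions"))

#' @rdname CVAModel-accessors
#' @export
setGeneric("groupCentroids", function(object) standardGeneric("groupCentroids"))

#' @rdname CVAModel-accessors
#' @export
setGeneric("modelVariables", function(object) standardGeneric("modelVariables"))

#' @rdname SWDAResult-accessors
#' @export
setGeneric("stepTable", function(object) standardGeneric("stepTable"))

#' @rdname SWDAResult-accessors
#' @export
setGeneric("stoppingReason", function(object) standardGeneric("stoppingReason"))
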