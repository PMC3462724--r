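#' @title Generics for restfc containers
#' @description Accessor generics shared by the cohort, feature-dataset and
#'   cross-validation classes.
#' @param x a restfc object
#' @param ... passed to methods
#' @name restfc-generics
NULL

#' @rdname restfc-generics
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname restfc-generics
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname restfc-generics
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname restfc-generics
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname restfc-generics
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname restfc-generics
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname restfc-generics
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname restfc-generics
#' @export
setGeneric("edgeMap", function(x) standardGeneric("edgeMap"))

#' @rdname restfc-generics
#' @export
setGeneric("consensusFeatures", function(x) standardGeneric("consensusFeatures"))

#' @rdname restfc-generics
#' @export
setGeneric("unionFeatures", function(x) standardGeneric("unionFeatures"))

#' @rdname restfc-generics
#' @export
setGeneric("featureWeights", function(x, ...) standardGeneric("featureWeights"))
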