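#' Accessor generics
#'
#' Small accessor layer so user code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("neuronLabels", function(x) standardGeneric("neuronLabels"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("metricOf", function(x) standardGeneric("metricOf"))

#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname accessors
#' @export
setGeneric("timeStep", function(x) standardGeneric("timeStep"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("membershipVector", function(x) standardGeneric("membershipVector"))

#' @rdname accessors
#' @export
setGeneric("fiberMap", function(x) standardGeneric("fiberMap"))

#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname accessors
#' @export
setGeneric("solutionStatus", function(x) standardGeneric("solutionStatus"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
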