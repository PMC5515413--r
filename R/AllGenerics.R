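#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the S4 classes in this package. Each has a
#' method on the class that carries the corresponding slot; see the class
#' documentation pages for details.
#'
#' @param x,object An object of the appropriate class.
#' @param ... Additional arguments passed to methods.
#' @return The slot value (see the method documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x, ...) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x, ...) standardGeneric("proteinIds"))

#' @rdname accessors
#' @export
setGeneric("isCommon", function(x, ...) standardGeneric("isCommon"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("truthTable", function(x, ...) standardGeneric("truthTable"))

#' @rdname accessors
#' @export
setGeneric("slope", function(object, ...) standardGeneric("slope"))

#' @rdname accessors
#' @export
setGeneric("intercept", function(object, ...) standardGeneric("intercept"))

#' @rdname accessors
#' @export
setGeneric("pearsonR", function(object, ...) standardGeneric("pearsonR"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("deviations", function(x, ...) standardGeneric("deviations"))

#' @rdname accessors
#' @export
setGeneric("bandWidth", function(x, ...) standardGeneric("bandWidth"))

#' @rdname accessors
#' @export
setGeneric("referenceFit", function(x, ...) standardGeneric("referenceFit"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x, ...) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("pchMask", function(x, ...) standardGeneric("pchMask"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(object, ...) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("trainIds", function(x, ...) standardGeneric("trainIds"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x, ...) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("peTable", function(x, ...) standardGeneric("peTable"))
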