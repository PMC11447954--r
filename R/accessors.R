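#' Accessors for the core result objects
#'
#' @param object a package object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' @rdname accessors
#' @export
setMethod("freeEnergy", "FreeEnergySurface", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("uncertainty", function(object) standardGeneric("uncertainty"))
#' @rdname accessors
#' @export
setMethod("uncertainty", "FreeEnergySurface", function(object) object@se)
#' @rdname accessors
#' @export
setMethod("uncertainty", "BasinResult", function(object) object@dGse)

#' @rdname accessors
#' @export
setGeneric("gridPoints", function(object) standardGeneric("gridPoints"))
#' @rdname accessors
#' @export
setMethod("gridPoints", "FreeEnergySurface", function(object) object@grid)

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setMethod("eigenvalues", "TicaModel", function(object) object@evals)
#' @rdname accessors
#' @export
setMethod("eigenvalues", "DeepTicaModel", function(object) object@evals)

#' @rdname accessors
#' @export
setGeneric("kernels", function(object) standardGeneric("kernels"))
#' @rdname accessors
#' @export
setMethod("kernels", "OpesState", function(object) object@kernels)

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setMethod("trainingLog", "DeepTicaModel", function(object) object@trainLog)

#' @rdname accessors
#' @export
setGeneric("deltaG", function(object) standardGeneric("deltaG"))
#' @rdname accessors
#' @export
setMethod("deltaG", "BasinResult", function(object) object@dG)
#' @rdname accessors
#' @export
setMethod("deltaG", "BindingFit", function(object) object@dG)

#' @rdname accessors
#' @export
setGeneric("barrierHeight", function(object) standardGeneric("barrierHeight"))
#' @rdname accessors
#' @export
setMethod("barrierHeight", "BasinResult", function(object) object@barrier)

#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(object) standardGeneric("descriptorValues"))
#' @rdname accessors
#' @export
setMethod("descriptorValues", "DescriptorSet", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("auxiliaries", function(object) standardGeneric("auxiliaries"))
#' @rdname accessors
#' @export
setMethod("auxiliaries", "DescriptorSet", function(object) object@aux)
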