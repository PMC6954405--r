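#' @rdname CGComplex-accessors
#' @export
setGeneric("caCoords", function(x, ...) standardGeneric("caCoords"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("cbCoords", function(x, ...) standardGeneric("cbCoords"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("scCoords", function(x, ...) standardGeneric("scCoords"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("cpCoords", function(x, ...) standardGeneric("cpCoords"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("peptide", function(x) standardGeneric("peptide"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("hasPeptide", function(x) standardGeneric("hasPeptide"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("peptideLength", function(x) standardGeneric("peptideLength"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("aaSequence", function(x, ...) standardGeneric("aaSequence"))

#' @rdname CGComplex-accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("getModel", function(x, i) standardGeneric("getModel"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("energyTable", function(x) standardGeneric("energyTable"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("restraintDistances",
           function(x, ...) standardGeneric("restraintDistances"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("restraintSet", function(x) standardGeneric("restraintSet"))

#' @rdname ClusterReport-accessors
#' @export
setGeneric("finalModels", function(x) standardGeneric("finalModels"))

#' @rdname ClusterReport-accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname EnergyBreakdown
#' @export
setGeneric("energyComponents",
           function(x) standardGeneric("energyComponents"))
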