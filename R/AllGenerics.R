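#' @rdname timepoints
#' @export
setGeneric("timepoints", function(x, ...) standardGeneric("timepoints"))

#' @rdname nTimepoints
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname nVoxels
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname signalMatrix
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname groundTruth
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname acquisitionScheduleOf
#' @export
setGeneric("acquisitionScheduleOf", function(x) standardGeneric("acquisitionScheduleOf"))

#' @rdname voxelGridOf
#' @export
setGeneric("voxelGridOf", function(x) standardGeneric("voxelGridOf"))

#' @rdname fitSSVB
#' @export
setGeneric("fitSSVB", function(dataset, ...) standardGeneric("fitSSVB"))

#' @rdname fitNLLS
#' @export
setGeneric("fitNLLS", function(dataset, ...) standardGeneric("fitNLLS"))

#' @rdname fitWD
#' @export
setGeneric("fitWD", function(dataset, ...) standardGeneric("fitWD"))

#' @rdname fitResult-accessors
#' @export
setGeneric("cbfMap", function(x) standardGeneric("cbfMap"))

#' @rdname fitResult-accessors
#' @export
setGeneric("attMap", function(x) standardGeneric("attMap"))

#' @rdname fitResult-accessors
#' @export
setGeneric("cbfSdMap", function(x) standardGeneric("cbfSdMap"))

#' @rdname fitResult-accessors
#' @export
setGeneric("attSdMap", function(x) standardGeneric("attSdMap"))

#' @rdname fitResult-accessors
#' @export
setGeneric("noiseVarMap", function(x) standardGeneric("noiseVarMap"))

#' @rdname fitResult-accessors
#' @export
setGeneric("costTrace", function(x) standardGeneric("costTrace"))

#' @rdname fitResult-accessors
#' @export
setGeneric("fitterName", function(x) standardGeneric("fitterName"))

#' @rdname computeBias
#' @export
setGeneric("computeBias", function(fit, truth, ...) standardGeneric("computeBias"))
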