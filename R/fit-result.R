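#' Accessors for fit results
#'
#' Extract the estimated parameter maps, uncertainty maps, noise variance
#' map, cost trace and fitter label from a \linkS4class{FitResult}.
#'
#' @param x a \linkS4class{FitResult}.
#' @return Numeric length-v vectors (maps), the numeric cost trace, or the
#'   fitter name.
#' @name fitResult-accessors
NULL

#' @rdname fitResult-accessors
#' @export
setMethod("cbfMap", "FitResult", function(x) x@cbfMap)

#' @rdname fitResult-accessors
#' @export
setMethod("attMap", "FitResult", function(x) x@attMap)

#' @rdname fitResult-accessors
#' @export
setMethod("cbfSdMap", "FitResult", function(x) x@cbfSdMap)

#' @rdname fitResult-accessors
#' @export
setMethod("attSdMap", "FitResult", function(x) x@attSdMap)

#' @rdname fitResult-accessors
#' @export
setMethod("noiseVarMap", "FitResult", function(x) x@noiseVarMap)

#' @rdname fitResult-accessors
#' @export
setMethod("costTrace", "FitResult", function(x) x@costTrace)

#' @rdname fitResult-accessors
#' @export
setMethod("fitterName", "FitResult", function(x) x@fitterName)

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "FitResult", function(x) length(x@cbfMap))

setMethod("show", "FitResult", function(object) {
    ok <- is.finite(object@cbfMap)
    cat(
        "FitResult [", object@fitterName, "]: ", length(object@cbfMap),
        " voxels (", sum(!ok), " failed)\n",
        sep = ""
    )
    cat(
        "  CBF: mean ", format(mean(object@cbfMap[ok]), digits = 4),
        "   ATT: mean ", format(mean(object@attMap[is.finite(object@attMap)]),
            digits = 4
        ), " s\n",
        sep = ""
    )
    if (object@epochsRun > 0L) {
        cat(
            "  ", object@epochsRun, " epochs, ", object@reversions,
            " reversions, best cost ",
            format(min(object@costTrace), digits = 6), "\n",
            sep = ""
        )
    }
})
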