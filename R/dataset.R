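#' Construct an ASL dataset
#'
#' Wraps a masked voxel-by-timepoint difference-signal matrix, its
#' acquisition schedule and voxel grid (plus optional ground truth for
#' synthetic data) into an \linkS4class{ASLDataset}
#' (a \linkS4class{SummarizedExperiment}: timepoints in rows, voxels in
#' columns).
#'
#' @param signal numeric \code{v x N} matrix, one row per masked voxel in
#'   raster order, one column per acquired volume in schedule order.
#' @param schedule an \linkS4class{AcquisitionSchedule} with
#'   \code{N = sum(repeats)} volumes.
#' @param grid a \linkS4class{VoxelGrid} with v masked voxels.
#' @param trueCBF,trueATT optional ground-truth parameters (scalar or
#'   length-v), stored for synthetic data.
#' @param noiseSd optional noise SD used in simulation.
#' @param affine optional 4x4 voxel-to-world matrix carried through to
#'   NIfTI output (identity with unit spacing by default).
#' @param seed optional integer seed recorded for provenance.
#' @return An \linkS4class{ASLDataset}.
#' @export
aslDataset <- function(signal, schedule, grid, trueCBF = NULL, trueATT = NULL,
                       noiseSd = NA_real_, affine = NULL, seed = NA_integer_) {
    signal <- as.matrix(signal)
    v <- nVoxels(grid)
    N <- nTimepoints(schedule)
    if (!identical(dim(signal), c(v, N))) {
        stop(
            "signal is ", nrow(signal), " x ", ncol(signal),
            " but grid/schedule imply ", v, " x ", N
        )
    }
    coords <- .voxelCoords(grid)
    cd <- S4Vectors::DataFrame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
    if (!is.null(trueCBF)) cd$trueCBF <- rep_len(trueCBF, v)
    if (!is.null(trueATT)) cd$trueATT <- rep_len(trueATT, v)
    rd <- S4Vectors::DataFrame(
        pld = rep(schedule@plds, schedule@repeats),
        repeatIndex = unlist(lapply(schedule@repeats, seq_len)),
        timepoint = timepoints(schedule)
    )
    if (is.null(affine)) affine <- diag(4)
    se <- SummarizedExperiment(
        assays = S4Vectors::SimpleList(signal = t(signal)),
        rowData = rd, colData = cd,
        metadata = list(
            schedule = schedule, grid = grid, noiseSd = noiseSd,
            affine = affine, seed = seed
        )
    )
    new("ASLDataset", se)
}

#' Signal matrix of a dataset
#' @param x an \linkS4class{ASLDataset}.
#' @return Numeric \code{v x N} matrix (voxels in rows).
#' @export
setMethod("signalMatrix", "ASLDataset", function(x) {
    t(assay(x, "signal"))
})

#' Ground truth of a synthetic dataset
#' @param x an \linkS4class{ASLDataset}.
#' @return \code{list(cbf =, att =)} of length-v vectors, or \code{NULL} for
#'   acquired data without ground truth.
#' @export
setMethod("groundTruth", "ASLDataset", function(x) {
    cd <- colData(x)
    if (!all(c("trueCBF", "trueATT") %in% names(cd))) {
        return(NULL)
    }
    list(cbf = cd$trueCBF, att = cd$trueATT)
})

#' Schedule of a dataset
#' @param x an \linkS4class{ASLDataset}.
#' @return The \linkS4class{AcquisitionSchedule}.
#' @export
setMethod("acquisitionScheduleOf", "ASLDataset", function(x) {
    metadata(x)$schedule
})

#' Voxel grid of a dataset
#' @param x an \linkS4class{ASLDataset}.
#' @return The \linkS4class{VoxelGrid}.
#' @export
setMethod("voxelGridOf", "ASLDataset", function(x) {
    metadata(x)$grid
})

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "ASLDataset", function(x) ncol(x))

#' @rdname nTimepoints
#' @export
setMethod("nTimepoints", "ASLDataset", function(x) nrow(x))

setMethod("show", "ASLDataset", function(object) {
    md <- metadata(object)
    cat(
        "ASLDataset: ", ncol(object), " voxels x ", nrow(object),
        " timepoints (schedule '", md$schedule@name, "')\n",
        sep = ""
    )
    gt <- groundTruth(object)
    if (!is.null(gt)) {
        cat(
            "  synthetic: true CBF ", format(mean(gt$cbf)), ", true ATT ",
            format(mean(gt$att)), " s, noise SD ",
            format(md$noiseSd), "\n",
            sep = ""
        )
    }
})
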