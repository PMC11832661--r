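#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata
NULL

#' Tissue and blood relaxation constants for the PCASL kinetic model
#'
#' Holds the physiological constants of the Buxton single-compartment model:
#' longitudinal relaxation times of tissue water (T1) and arterial blood
#' (T1b), the blood-brain partition coefficient of water (lambda), and the
#' equilibrium magnetisation of arterial blood (M0a, which sets the signal
#' scale and absorbs inversion efficiency).
#'
#' @slot t1Tissue T1 of tissue water, seconds.
#' @slot t1Blood T1 of arterial blood, seconds.
#' @slot partitionCoeff blood-brain partition coefficient (dimensionless).
#' @slot m0a equilibrium magnetisation of arterial blood (signal units).
#' @export
setClass("TissueConstants",
    representation(
        t1Tissue = "numeric",
        t1Blood = "numeric",
        partitionCoeff = "numeric",
        m0a = "numeric"
    )
)

setValidity("TissueConstants", function(object) {
    vals <- c(object@t1Tissue, object@t1Blood, object@partitionCoeff, object@m0a)
    if (length(vals) != 4L || any(!is.finite(vals))) {
        return("all constants must be finite scalars")
    }
    if (any(vals <= 0)) {
        return("all constants must be strictly positive")
    }
    TRUE
})

#' Multi-delay PCASL acquisition schedule
#'
#' Defines the timepoints of one pseudo-continuous ASL experiment: a single
#' label duration tau, an ordered set of post-label delays (PLDs), and the
#' number of repeated acquisitions at each PLD. The model timepoint of the
#' i-th PLD is \code{t_i = tau + pld_i}, time since the start of label
#' creation. The total number of volumes is \code{N = sum(repeats)}.
#'
#' @slot name schedule label (e.g. \code{"grey_paper"}).
#' @slot labelDuration label duration tau, seconds.
#' @slot plds post-label delays, seconds (may contain repeated values, which
#'   are kept verbatim as listed).
#' @slot repeats positive integer repeat count per PLD entry.
#' @export
setClass("AcquisitionSchedule",
    representation(
        name = "character",
        labelDuration = "numeric",
        plds = "numeric",
        repeats = "integer"
    )
)

setValidity("AcquisitionSchedule", function(object) {
    if (length(object@labelDuration) != 1L || !is.finite(object@labelDuration) ||
        object@labelDuration <= 0) {
        return("labelDuration must be a single positive number")
    }
    if (length(object@plds) == 0L || any(!is.finite(object@plds)) ||
        any(object@plds < 0)) {
        return("plds must be non-negative finite numbers")
    }
    if (length(object@repeats) != length(object@plds)) {
        return("repeats must have the same length as plds")
    }
    if (any(object@repeats < 1L)) {
        return("all repeat counts must be >= 1")
    }
    TRUE
})

#' Masked voxel grid
#'
#' A 3D grid of voxels with a boolean inclusion mask. Masked voxels are
#' enumerated in raster order (first array index fastest), giving a stable
#' bijection between masked voxels and \code{1..v}.
#'
#' @slot shape integer grid dimensions (length 3).
#' @slot mask logical array of dimension \code{shape}.
#' @export
setClass("VoxelGrid",
    representation(shape = "integer", mask = "array")
)

setValidity("VoxelGrid", function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L)) {
        return("shape must be 3 positive integers")
    }
    if (!is.logical(object@mask) || !identical(dim(object@mask), object@shape)) {
        return("mask must be a logical array matching shape")
    }
    if (!any(object@mask)) {
        return("mask must contain at least one voxel")
    }
    TRUE
})

#' Multi-delay ASL dataset
#'
#' Container for label-control difference (deltaM) data over a masked voxel
#' grid, built on \linkS4class{SummarizedExperiment}: rows are acquisition
#' timepoints (one per volume), columns are masked voxels. Row metadata
#' carries the PLD, repeat index and model timepoint of each volume; column
#' metadata carries voxel grid coordinates and, for synthetic data, the
#' ground-truth CBF and ATT. The acquisition schedule, voxel grid, affine
#' and simulation provenance live in \code{metadata()}.
#'
#' @export
setClass("ASLDataset", contains = "SummarizedExperiment")

setValidity("ASLDataset", function(object) {
    if (!"signal" %in% assayNames(object)) {
        return("ASLDataset requires a 'signal' assay")
    }
    md <- metadata(object)
    if (is.null(md$schedule) || !is(md$schedule, "AcquisitionSchedule")) {
        return("metadata must carry an AcquisitionSchedule")
    }
    if (is.null(md$grid) || !is(md$grid, "VoxelGrid")) {
        return("metadata must carry a VoxelGrid")
    }
    if (nrow(object) != sum(md$schedule@repeats)) {
        return("number of rows must equal the schedule's total volume count")
    }
    if (ncol(object) != sum(md$grid@mask)) {
        return("number of columns must equal the number of masked voxels")
    }
    TRUE
})

#' Per-voxel variational posterior state
#'
#' The factorised (diagonal Gaussian, no CBF-ATT covariance) approximate
#' posterior of the SSVB engine: per-voxel means and log standard deviations
#' for CBF and ATT, a per-voxel point-estimated log noise variance, and one
#' global log spatial precision per regularised map.
#'
#' @slot meanCBF,meanATT posterior means, length-v vectors.
#' @slot logSdCBF,logSdATT posterior log-SDs, length-v vectors.
#' @slot logNoiseVar per-voxel log noise variance (point estimate).
#' @slot logAlphaCBF,logAlphaATT log spatial precisions (scalars).
#' @export
setClass("VariationalState",
    representation(
        meanCBF = "numeric", meanATT = "numeric",
        logSdCBF = "numeric", logSdATT = "numeric",
        logNoiseVar = "numeric",
        logAlphaCBF = "numeric", logAlphaATT = "numeric"
    )
)

setValidity("VariationalState", function(object) {
    v <- length(object@meanCBF)
    lens <- c(
        length(object@meanATT), length(object@logSdCBF),
        length(object@logSdATT), length(object@logNoiseVar)
    )
    if (any(lens != v)) {
        return("all per-voxel fields must share one length v")
    }
    if (length(object@logAlphaCBF) != 1L || length(object@logAlphaATT) != 1L) {
        return("spatial precisions must be scalars")
    }
    allv <- c(
        object@meanCBF, object@meanATT, object@logSdCBF, object@logSdATT,
        object@logNoiseVar, object@logAlphaCBF, object@logAlphaATT
    )
    if (any(!is.finite(allv))) {
        return("all state values must be finite")
    }
    TRUE
})

#' SSVB optimiser configuration
#'
#' Settings for the stochastic free-energy optimisation: RMSProp learning
#' rate, the Monte-Carlo sample-growth reversion schedule (patience epochs
#' without a cost decrease trigger a revert-to-best and a sample size
#' increment), termination after a fixed number of reversions, and the seed
#' driving all stochasticity.
#'
#' @slot learningRate RMSProp learning rate (default 0.1).
#' @slot initialSampleSize starting Monte-Carlo sample size L (default 2).
#' @slot patience epochs without cost improvement before reverting (default 50).
#' @slot maxReversions reversions before termination (default 5).
#' @slot maxEpochs safety cap on total epochs (default 5000).
#' @slot rngSeed integer seed for all sampling.
#' @slot rmsDecay,rmsEpsilon RMSProp accumulator decay and stabiliser.
#' @slot initMethod posterior-mean initialisation: \code{"wd"} (default)
#'   initialises ATT per voxel from the weighted-delay calibration
#'   inversion of the data (falling back to \code{initATT} where the
#'   moment is undefined) and CBF from the linear amplitude solve at that
#'   ATT; \code{"flat"} initialises ATT at \code{initATT} everywhere.
#' @slot initATT,initLogSdCBF,initLogSdATT,initLogAlpha initial posterior
#'   values (CBF means are initialised from a linear fit to the data).
#' @slot noisePriorSd SD of the Gaussian prior on log noise variance.
#' @slot optimiseAlpha when \code{FALSE}, the spatial precisions are frozen
#'   at their initial values instead of being optimised.
#' @export
setClass("SSVBConfig",
    representation(
        learningRate = "numeric",
        initialSampleSize = "integer",
        patience = "integer",
        maxReversions = "integer",
        maxEpochs = "integer",
        rngSeed = "integer",
        rmsDecay = "numeric",
        rmsEpsilon = "numeric",
        initMethod = "character",
        initATT = "numeric",
        initLogSdCBF = "numeric",
        initLogSdATT = "numeric",
        initLogAlpha = "numeric",
        noisePriorSd = "numeric",
        optimiseAlpha = "logical"
    ),
    prototype(
        learningRate = 0.1,
        initialSampleSize = 2L,
        patience = 50L,
        maxReversions = 5L,
        maxEpochs = 5000L,
        rngSeed = 1L,
        rmsDecay = 0.9,
        rmsEpsilon = 1e-8,
        initMethod = "wd",
        initATT = 1.3,
        initLogSdCBF = log(10),
        initLogSdATT = log(0.5),
        initLogAlpha = log(1e-2),
        noisePriorSd = 4,
        optimiseAlpha = TRUE
    )
)

setValidity("SSVBConfig", function(object) {
    pos <- c(
        object@learningRate, object@initialSampleSize, object@patience,
        object@maxReversions, object@maxEpochs, object@rmsDecay,
        object@rmsEpsilon, object@noisePriorSd
    )
    if (any(!is.finite(pos)) || any(pos <= 0)) {
        return("learningRate, sample size, patience, reversions, epochs, RMSProp and noise-prior settings must all be positive")
    }
    if (!object@initMethod %in% c("wd", "flat")) {
        return("initMethod must be 'wd' or 'flat'")
    }
    TRUE
})

#' Result of one fit over a masked voxel grid
#'
#' Estimated CBF and ATT maps (posterior means for SSVB, point estimates for
#' the comparators), uncertainty maps where the fitter provides them, the
#' per-voxel noise variance, the optimisation cost trace, and fitter
#' metadata (epochs, reversions, warnings).
#'
#' @slot cbfMap,attMap estimated maps, length-v vectors.
#' @slot cbfSdMap,attSdMap per-voxel uncertainty (NA where unavailable).
#' @slot noiseVarMap per-voxel noise variance estimate (NA where unavailable).
#' @slot costTrace per-epoch cost (negative free energy) for SSVB; a single
#'   final SSD summary for the deterministic fitters.
#' @slot fitterName one of \code{"ssvb"}, \code{"nlls"}, \code{"wd"}.
#' @slot epochsRun,reversions optimisation counters (0 for non-iterative fits).
#' @slot metadata free-form list: config snapshot, seed, warning counts.
#' @export
setClass("FitResult",
    representation(
        cbfMap = "numeric", attMap = "numeric",
        cbfSdMap = "numeric", attSdMap = "numeric",
        noiseVarMap = "numeric",
        costTrace = "numeric",
        fitterName = "character",
        epochsRun = "integer",
        reversions = "integer",
        metadata = "list"
    )
)

setValidity("FitResult", function(object) {
    v <- length(object@cbfMap)
    lens <- c(
        length(object@attMap), length(object@cbfSdMap),
        length(object@attSdMap), length(object@noiseVarMap)
    )
    if (any(lens != v)) {
        return("all maps must share one length v")
    }
    if (length(object@costTrace) == 0L) {
        return("costTrace must be non-empty")
    }
    TRUE
})

#' Weighted-delay calibration curve
#'
#' The monotone mapping from arterial transit time to the first temporal
#' moment (weighted delay) of the noiseless PCASL signal for a given
#' schedule, tabulated over a grid of ATT values. ATT estimation inverts
#' this curve by monotone interpolation.
#'
#' @slot attGrid strictly increasing ATT grid, seconds.
#' @slot wdValues first-moment delay at each grid ATT, seconds.
#' @slot scheduleName name of the schedule the curve was built for.
#' @export
setClass("WDCalibration",
    representation(
        attGrid = "numeric",
        wdValues = "numeric",
        scheduleName = "character"
    )
)

setValidity("WDCalibration", function(object) {
    if (length(object@attGrid) != length(object@wdValues)) {
        return("attGrid and wdValues must have equal length")
    }
    if (length(object@attGrid) < 2L || any(diff(object@attGrid) <= 0)) {
        return("attGrid must be strictly increasing with >= 2 points")
    }
    if (any(diff(object@wdValues) <= 0)) {
        return("weighted delay must be strictly increasing in ATT over the grid (schedule unsuitable for WD)")
    }
    TRUE
})
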