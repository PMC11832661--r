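# Synthetic multi-delay PCASL data with known ground truth.
#
# Each dataset is a fully masked isotropic grid (default 5 x 5 x 5) on which
# every voxel shares the same true (CBF, ATT); zero-mean Gaussian noise of a
# chosen SD is added independently to every volume of every voxel. The
# default study design holds CBF at 60 units (the difference signal is
# linear in CBF, so varying it is equivalent to varying SNR) and crosses
# true ATT 0.5-3.0 s in 0.25 s steps with noise SD 10-40 in steps of 10:
# a 44-cell factorial, one homogeneous-truth dataset per cell.

#' Simulate one homogeneous-truth ASL dataset
#'
#' @param schedule an \linkS4class{AcquisitionSchedule} (or preset name).
#' @param constants a \linkS4class{TissueConstants}.
#' @param gridShape grid dimensions, fully masked (default \code{c(5,5,5)}).
#' @param trueCBF,trueATT shared ground truth of every voxel.
#' @param noiseSd SD of the added zero-mean Gaussian noise (0 for noiseless).
#' @param seed integer seed; the dataset is bit-reproducible given the seed.
#' @return An \linkS4class{ASLDataset} with ground truth stored.
#' @examples
#' d <- simulateDataset(schedulePreset("grey_paper"),
#'     trueATT = 1.5,
#'     noiseSd = 20, seed = 1
#' )
#' dim(signalMatrix(d)) # 125 x 36
#' @export
simulateDataset <- function(schedule, constants = tissueConstants(),
                            gridShape = c(5, 5, 5), trueCBF = 60,
                            trueATT = 1.5, noiseSd = 20, seed = 1L) {
    if (is.character(schedule)) schedule <- schedulePreset(schedule)
    stopifnot(noiseSd >= 0)
    grid <- voxelGrid(shape = gridShape)
    v <- nVoxels(grid)
    N <- nTimepoints(schedule)
    clean <- signalVector(schedule, cbf = trueCBF, att = trueATT, constants)
    signal <- matrix(clean, v, N, byrow = TRUE)
    if (noiseSd > 0) {
        set.seed(as.integer(seed))
        signal <- signal + matrix(stats::rnorm(v * N, sd = noiseSd), v, N)
    }
    aslDataset(signal, schedule, grid,
        trueCBF = trueCBF, trueATT = trueATT,
        noiseSd = noiseSd, seed = as.integer(seed)
    )
}

#' Simulate the full (ATT x noise) factorial suite
#'
#' One dataset per combination of \code{trueATTValues} and \code{noiseSds},
#' with per-dataset child seeds drawn deterministically from \code{seed}.
#'
#' @param schedule schedule or preset name.
#' @param constants a \linkS4class{TissueConstants}.
#' @param gridShape grid dimensions.
#' @param trueCBF shared true CBF (held constant across the suite).
#' @param trueATTValues true ATT levels, seconds.
#' @param noiseSds noise SD levels.
#' @param seed master seed for the suite.
#' @return A list of \linkS4class{ASLDataset} with names
#'   \code{"att<ATT>_sd<SD>"}, in ATT-major order.
#' @examples
#' suite <- simulateSuite("grey_paper",
#'     trueATTValues = c(1, 2),
#'     noiseSds = c(10, 20), seed = 1
#' )
#' length(suite) # 4
#' @export
simulateSuite <- function(schedule, constants = tissueConstants(),
                          gridShape = c(5, 5, 5), trueCBF = 60,
                          trueATTValues = seq(0.5, 3.0, by = 0.25),
                          noiseSds = c(10, 20, 30, 40), seed = 1L) {
    if (is.character(schedule)) schedule <- schedulePreset(schedule)
    cells <- expand.grid(
        noiseSd = noiseSds, trueATT = trueATTValues,
        KEEP.OUT.ATTRS = FALSE
    )
    cells <- cells[order(cells$trueATT, cells$noiseSd), , drop = FALSE]
    set.seed(as.integer(seed))
    childSeeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))
    out <- vector("list", nrow(cells))
    for (k in seq_len(nrow(cells))) {
        out[[k]] <- simulateDataset(
            schedule, constants, gridShape,
            trueCBF = trueCBF, trueATT = cells$trueATT[k],
            noiseSd = cells$noiseSd[k], seed = childSeeds[k]
        )
    }
    names(out) <- sprintf("att%.2f_sd%g", cells$trueATT, cells$noiseSd)
    out
}
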