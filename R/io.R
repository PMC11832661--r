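# NIfTI and manifest I/O. Maps are stored float32 (NIfTI convention) with
# NaN outside the mask; all computation is float64 internally. Voxel
# enumeration is raster order (first index fastest); the affine is carried
# through from input to output without any physical-space computation.

#' Read a 4D multi-delay ASL difference image and brain mask
#'
#' @param path 4D NIfTI of label-control difference volumes, in schedule
#'   order.
#' @param maskPath 3D NIfTI brain mask on the same grid (nonzero = in).
#' @param schedule an \linkS4class{AcquisitionSchedule}; the 4th dimension
#'   must equal the schedule's volume count.
#' @return An \linkS4class{ASLDataset}; the source NIfTI header is kept in
#'   \code{metadata()} for write-back.
#' @export
readASLNifti <- function(path, maskPath, schedule) {
    img <- RNifti::readNifti(path)
    msk <- RNifti::readNifti(maskPath)
    di <- dim(img)
    dm <- dim(msk)
    if (length(dm) < 3L) dm <- c(dm, rep(1L, 3L - length(dm))) # squeezed z
    if (length(di) != 4L) {
        stop("expected a 4D image, got dimensions ", paste(di, collapse = " x "))
    }
    if (!identical(as.integer(di[1:3]), as.integer(dm[1:3]))) {
        stop(
            "image grid ", paste(di[1:3], collapse = " x "),
            " does not match mask grid ", paste(dm, collapse = " x ")
        )
    }
    N <- nTimepoints(schedule)
    if (di[4] != N) {
        stop(
            "image has ", di[4], " volumes but the schedule defines ", N
        )
    }
    grid <- voxelGrid(mask = array(as.vector(msk) != 0, dim = dm[1:3]))
    flat <- matrix(as.numeric(img), prod(di[1:3]), di[4])
    signal <- flat[as.vector(grid@mask), , drop = FALSE]
    ds <- aslDataset(signal, schedule, grid, affine = unclass(RNifti::xform(img)))
    metadata(ds)$niftiReference <- RNifti::asNifti(array(0, dim = di[1:3]),
        reference = img
    )
    ds
}

# One 3D map -> NIfTI file, NaN outside the mask, float32 storage.
.writeMap <- function(map, grid, path, reference = NULL) {
    vol <- array(NaN, dim = grid@shape)
    vol[grid@mask] <- map
    img <- if (is.null(reference)) {
        RNifti::asNifti(vol)
    } else {
        RNifti::asNifti(vol, reference = reference)
    }
    RNifti::writeNifti(img, path, datatype = "float")
    invisible(path)
}

#' Write fitted parameter maps and a run manifest
#'
#' Writes one 3D NIfTI per map (\code{cbf}, \code{att}, \code{cbf_sd},
#' \code{att_sd}, \code{noise_var}; unmasked voxels \code{NaN}), the cost
#' trace as CSV, and a JSON manifest recording the fitter, seed and
#' optimisation counters.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param dataset the \linkS4class{ASLDataset} the fit was computed from
#'   (supplies grid, affine and NIfTI header).
#' @param outDir output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
writeParamMaps <- function(fit, dataset, outDir) {
    grid <- voxelGridOf(dataset)
    if (nVoxels(fit) != nVoxels(grid)) {
        stop(
            "fit has ", nVoxels(fit), " voxels but the grid has ",
            nVoxels(grid)
        )
    }
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    ref <- metadata(dataset)$niftiReference
    maps <- list(
        cbf = cbfMap(fit), att = attMap(fit),
        cbf_sd = cbfSdMap(fit), att_sd = attSdMap(fit),
        noise_var = noiseVarMap(fit)
    )
    paths <- character(0)
    for (nm in names(maps)) {
        p <- file.path(outDir, paste0(nm, ".nii.gz"))
        .writeMap(maps[[nm]], grid, p, reference = ref)
        paths[nm] <- p
    }
    tracePath <- file.path(outDir, "cost_trace.csv")
    utils::write.csv(
        data.frame(epoch = seq_along(costTrace(fit)), cost = costTrace(fit)),
        tracePath,
        row.names = FALSE
    )
    paths["cost_trace"] <- tracePath
    manifestPath <- file.path(outDir, "manifest.json")
    writeRunManifest(
        manifestPath,
        command = paste0("fit --method ", fitterName(fit)),
        config = fit@metadata,
        seed = fit@metadata$seed,
        schedule = acquisitionScheduleOf(dataset),
        extra = list(
            epochs = fit@epochsRun, reversions = fit@reversions,
            fitter = fitterName(fit)
        )
    )
    paths["manifest"] <- manifestPath
    invisible(paths)
}

#' Write a simulated dataset as 4D NIfTI with a ground-truth sidecar
#'
#' @param dataset a synthetic \linkS4class{ASLDataset}.
#' @param path output 4D NIfTI path (e.g. \code{data.nii.gz}); the mask and
#'   the JSON ground-truth sidecar are written alongside.
#' @return Invisibly, the named vector of written paths.
#' @export
writeDatasetNifti <- function(dataset, path) {
    grid <- voxelGridOf(dataset)
    Y <- signalMatrix(dataset)
    arr <- array(NaN, dim = c(grid@shape, ncol(Y)))
    flat <- matrix(arr, prod(grid@shape), ncol(Y))
    flat[as.vector(grid@mask), ] <- Y
    arr <- array(flat, dim = c(grid@shape, ncol(Y)))
    # acquisition data keeps full precision; parameter maps use float32
    RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "double")
    base <- sub("\\.nii(\\.gz)?$", "", path)
    maskPath <- paste0(base, "_mask.nii.gz")
    RNifti::writeNifti(
        RNifti::asNifti(array(as.numeric(grid@mask), dim = grid@shape)),
        maskPath,
        datatype = "float"
    )
    gt <- groundTruth(dataset)
    sidecar <- paste0(base, "_truth.json")
    md <- metadata(dataset)
    jsonlite::write_json(
        list(
            schedule = md$schedule@name,
            label_duration = md$schedule@labelDuration,
            plds = md$schedule@plds,
            repeats = md$schedule@repeats,
            true_cbf = if (is.null(gt)) NULL else mean(gt$cbf),
            true_att = if (is.null(gt)) NULL else mean(gt$att),
            noise_sd = md$noiseSd,
            seed = md$seed
        ),
        sidecar,
        auto_unbox = TRUE, digits = NA
    )
    invisible(c(data = path, mask = maskPath, truth = sidecar))
}

#' Write a JSON run manifest
#'
#' Records everything needed to re-run a stage bit-identically on one
#' thread: the command, a config snapshot, the seed, the schedule, the
#' package version and a timestamp.
#'
#' @param path output JSON path.
#' @param command command label.
#' @param config list snapshot of settings.
#' @param seed integer seed.
#' @param schedule optional \linkS4class{AcquisitionSchedule}.
#' @param extra optional further fields.
#' @return Invisibly, the path.
#' @export
writeRunManifest <- function(path, command, config = list(), seed = NA,
                             schedule = NULL, extra = list()) {
    manifest <- c(
        list(
            command = command,
            seed = seed,
            package_version = as.character(utils::packageVersion("ssvb")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            config = config
        ),
        if (!is.null(schedule)) {
            list(schedule = list(
                name = schedule@name,
                label_duration = schedule@labelDuration,
                plds = schedule@plds,
                repeats = schedule@repeats
            ))
        },
        extra
    )
    jsonlite::write_json(manifest, path,
        auto_unbox = TRUE, digits = NA,
        null = "null", force = TRUE
    )
    invisible(path)
}
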