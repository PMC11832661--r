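#' Construct an acquisition schedule
#'
#' @param labelDuration label duration tau, seconds.
#' @param plds post-label delays, seconds (kept verbatim, including any
#'   repeated values).
#' @param repeats integer repeat count per PLD entry; a single value is
#'   recycled across all PLDs.
#' @param name schedule label.
#'
#' @return An \linkS4class{AcquisitionSchedule}.
#' @examples
#' sched <- acquisitionSchedule(2.05, c(0.2, 1.0, 2.0), repeats = 4)
#' nTimepoints(sched)
#' @export
acquisitionSchedule <- function(labelDuration, plds, repeats = 1L,
                                name = "custom") {
    if (length(repeats) == 1L) repeats <- rep(repeats, length(plds))
    new("AcquisitionSchedule",
        name = as.character(name),
        labelDuration = as.numeric(labelDuration),
        plds = as.numeric(plds),
        repeats = as.integer(repeats)
    )
}

#' Construct tissue constants
#'
#' Defaults are consensus values for 3 T PCASL in grey matter: T1 = 1.3 s,
#' T1b = 1.65 s, lambda = 0.9, M0a = 1 (signal scale absorbed, inversion
#' efficiency not modelled separately).
#'
#' @param t1Tissue,t1Blood,partitionCoeff,m0a see
#'   \linkS4class{TissueConstants}.
#' @return A \linkS4class{TissueConstants}.
#' @export
tissueConstants <- function(t1Tissue = 1.3, t1Blood = 1.65,
                            partitionCoeff = 0.9, m0a = 1) {
    new("TissueConstants",
        t1Tissue = t1Tissue, t1Blood = t1Blood,
        partitionCoeff = partitionCoeff, m0a = m0a
    )
}

#' Named schedule presets
#'
#' Two shipped presets: \code{"grey_paper"}, the optimal grey-matter
#' sampling scheme (tau = 2.05 s, 9 PLDs with 4 repeats each, designed for
#' ATT in 0.5-2.5 s), and \code{"hcp_asl"}, the HCP Lifespan ASL scheme
#' (tau = 1.5 s, 5 PLDs with 6, 6, 6, 10, 15 repeats).
#'
#' @param name preset name.
#' @return An \linkS4class{AcquisitionSchedule}.
#' @examples
#' nTimepoints(schedulePreset("grey_paper")) # 36
#' nTimepoints(schedulePreset("hcp_asl")) # 43
#' @export
schedulePreset <- function(name = c("grey_paper", "hcp_asl")) {
    name <- match.arg(name)
    switch(name,
        grey_paper = acquisitionSchedule(
            labelDuration = 2.05,
            plds = c(0.200, 0.775, 0.775, 0.775, 1.800, 2.275, 2.475, 2.675, 2.800),
            repeats = 4L,
            name = "grey_paper"
        ),
        hcp_asl = acquisitionSchedule(
            labelDuration = 1.5,
            plds = c(0.2, 0.7, 1.2, 1.7, 2.2),
            repeats = c(6L, 6L, 6L, 10L, 15L),
            name = "hcp_asl"
        )
    )
}

#' Read a schedule (and optional constant overrides) from a YAML/JSON config
#'
#' Recognised keys: \code{label_duration} (s), \code{plds} (list of s),
#' \code{repeats} (list of int, or a single int), optional \code{name}, and
#' an optional \code{constants} block overriding \code{t1_tissue},
#' \code{t1_blood}, \code{partition_coeff}, \code{m0a}.
#'
#' @param path YAML (or JSON, parsed by yaml) file path.
#' @return A list with elements \code{schedule}
#'   (\linkS4class{AcquisitionSchedule}) and \code{constants}
#'   (\linkS4class{TissueConstants}).
#' @export
readScheduleConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    for (k in c("label_duration", "plds")) {
        if (is.null(cfg[[k]])) stop("schedule config missing key '", k, "'")
    }
    repeats <- cfg$repeats
    if (is.null(repeats)) repeats <- 1L
    sched <- acquisitionSchedule(
        labelDuration = cfg$label_duration,
        plds = unlist(cfg$plds),
        repeats = unlist(repeats),
        name = if (is.null(cfg$name)) "config" else cfg$name
    )
    cc <- cfg$constants
    constants <- tissueConstants(
        t1Tissue = if (is.null(cc$t1_tissue)) 1.3 else cc$t1_tissue,
        t1Blood = if (is.null(cc$t1_blood)) 1.65 else cc$t1_blood,
        partitionCoeff = if (is.null(cc$partition_coeff)) 0.9 else cc$partition_coeff,
        m0a = if (is.null(cc$m0a)) 1 else cc$m0a
    )
    list(schedule = sched, constants = constants)
}

#' Model timepoints of a schedule
#'
#' Per-volume times since the start of label creation, \code{t = tau + PLD},
#' expanded over repeats in PLD-major, repeat-minor order.
#'
#' @param x an \linkS4class{AcquisitionSchedule}.
#' @param expand if \code{FALSE}, return one timepoint per PLD entry without
#'   repeat expansion.
#' @param ... unused.
#' @return Numeric vector of times, seconds.
#' @export
setMethod("timepoints", "AcquisitionSchedule", function(x, expand = TRUE, ...) {
    t <- x@labelDuration + x@plds
    if (expand) rep(t, x@repeats) else t
})

#' Total number of acquired volumes
#' @param x an \linkS4class{AcquisitionSchedule} or \linkS4class{ASLDataset}.
#' @return Integer N = sum of repeats.
#' @export
setMethod("nTimepoints", "AcquisitionSchedule", function(x) {
    sum(x@repeats)
})

setMethod("show", "AcquisitionSchedule", function(object) {
    cat(
        "AcquisitionSchedule '", object@name, "': tau = ",
        object@labelDuration, " s, ", length(object@plds), " PLDs, N = ",
        sum(object@repeats), " volumes\n",
        sep = ""
    )
    cat("  PLDs (s):   ", paste(format(object@plds), collapse = " "), "\n")
    cat("  repeats:    ", paste(object@repeats, collapse = " "), "\n")
})

setMethod("show", "TissueConstants", function(object) {
    cat(
        "TissueConstants: T1 =", object@t1Tissue, "s, T1b =", object@t1Blood,
        "s, lambda =", object@partitionCoeff, ", M0a =", object@m0a, "\n"
    )
})
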