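#' Run the simulation bias benchmark for one schedule
#'
#' Simulates the homogeneous-truth factorial suite
#' (\code{\link{simulateSuite}}), fits every dataset with the requested
#' fitters, and tabulates percentage bias. Fit seeds for the stochastic
#' SSVB fitter are derived deterministically from \code{seed}.
#'
#' @param schedule schedule or preset name.
#' @param trueATTValues,noiseSds,trueCBF,gridShape suite design (see
#'   \code{\link{simulateSuite}}).
#' @param fitters subset of \code{c("ssvb", "nlls", "wd")}.
#' @param seed master seed for simulation and fitting.
#' @param constants a \linkS4class{TissueConstants}.
#' @param config base \linkS4class{SSVBConfig} for the SSVB fits (its
#'   \code{rngSeed} is replaced per dataset).
#' @return List with \code{table} (long bias table, see
#'   \code{\link{biasTable}}), \code{summary} (noise-averaged, see
#'   \code{\link{biasSummary}}) and \code{ssvbEpochs} (per-dataset epoch
#'   counts, when SSVB was run).
#' @examples
#' \donttest{
#' bench <- runBiasBenchmark("grey_paper",
#'     trueATTValues = c(1, 2),
#'     noiseSds = c(10, 20), seed = 1, fitters = "wd"
#' )
#' bench$summary
#' }
#' @export
runBiasBenchmark <- function(schedule, trueATTValues = seq(0.5, 3.0, by = 0.25),
                             noiseSds = c(10, 20, 30, 40), trueCBF = 60,
                             gridShape = c(5, 5, 5),
                             fitters = c("ssvb", "nlls", "wd"), seed = 1L,
                             constants = tissueConstants(),
                             config = ssvbConfig()) {
    fitters <- match.arg(fitters, several.ok = TRUE)
    suite <- simulateSuite(schedule,
        constants = constants, gridShape = gridShape,
        trueCBF = trueCBF, trueATTValues = trueATTValues,
        noiseSds = noiseSds, seed = seed
    )
    fits <- list()
    ssvbEpochs <- NULL
    if ("ssvb" %in% fitters) {
        fs <- vector("list", length(suite))
        for (k in seq_along(suite)) {
            cfg <- config
            cfg@rngSeed <- as.integer((seed + 7919L * k) %% .Machine$integer.max)
            fs[[k]] <- fitSSVB(suite[[k]], constants = constants, config = cfg)
        }
        fits$ssvb <- fs
        ssvbEpochs <- vapply(fs, function(f) f@epochsRun, integer(1))
        names(ssvbEpochs) <- names(suite)
    }
    if ("nlls" %in% fitters) {
        fits$nlls <- lapply(suite, fitNLLS, constants = constants)
    }
    if ("wd" %in% fitters) {
        fits$wd <- lapply(suite, fitWD, constants = constants)
    }
    tab <- biasTable(fits, suite)
    list(table = tab, summary = biasSummary(tab), ssvbEpochs = ssvbEpochs)
}
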