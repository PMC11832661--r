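# Scoring fitters against ground truth: percentage bias of the
# mean-across-voxels estimate, per parameter, per (true ATT, noise SD) cell,
# plus noise-averaged summaries with min-max envelopes across noise levels.

#' Percentage bias of a fit against ground truth
#'
#' The mean across masked, finite voxels of each estimated map is compared
#' with the (nonzero) ground truth value and expressed as a percentage:
#' \code{bias = 100 * (meanEstimate - truth) / truth}. \code{NaN} voxels
#' (possible for the NLLS and WD fitters) are excluded and counted.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param truth \code{list(cbf =, att =)} of scalar ground-truth values.
#' @param ... unused.
#' @return A two-row \code{data.frame} with columns \code{parameter},
#'   \code{truth}, \code{meanEstimate}, \code{biasPct}, \code{nExcluded}.
#' @examples
#' d <- simulateDataset("grey_paper",
#'     gridShape = c(2, 2, 1), trueATT = 1.5,
#'     noiseSd = 0, seed = 1
#' )
#' fit <- fitNLLS(d)
#' computeBias(fit, list(cbf = 60, att = 1.5))
#' @export
setMethod("computeBias", "FitResult", function(fit, truth, ...) {
    stopifnot(is.list(truth), truth$cbf != 0, truth$att != 0)
    one <- function(map, tr, parameter) {
        ok <- is.finite(map)
        if (!any(ok)) stop("all voxels are NaN for parameter ", parameter)
        m <- mean(map[ok])
        data.frame(
            parameter = parameter, truth = tr, meanEstimate = m,
            biasPct = 100 * (m - tr) / tr, nExcluded = sum(!ok)
        )
    }
    rbind(
        one(cbfMap(fit), truth$cbf, "cbf"),
        one(attMap(fit), truth$att, "att")
    )
})

#' Long-format bias table over a simulation suite
#'
#' @param fits named list: one element per fitter, each a list of
#'   \linkS4class{FitResult} parallel to \code{datasets}.
#' @param datasets list of synthetic \linkS4class{ASLDataset} with stored
#'   ground truth (e.g. from \code{\link{simulateSuite}}).
#' @return \code{data.frame} with one row per
#'   (fitter, dataset, parameter): columns \code{fitter}, \code{schedule},
#'   \code{trueATT}, \code{noiseSd}, \code{parameter}, \code{truth},
#'   \code{meanEstimate}, \code{biasPct}, \code{nExcluded}.
#' @export
biasTable <- function(fits, datasets) {
    stopifnot(length(fits) >= 1, length(datasets) >= 1)
    missing <- character(0)
    rows <- list()
    for (fname in names(fits)) {
        flist <- fits[[fname]]
        if (length(flist) != length(datasets)) {
            stop(
                "fitter '", fname, "' has ", length(flist),
                " fits for ", length(datasets), " datasets"
            )
        }
        for (k in seq_along(datasets)) {
            if (is.null(flist[[k]])) {
                missing <- c(missing, paste0(fname, "/", names(datasets)[k]))
                next
            }
            d <- datasets[[k]]
            gt <- groundTruth(d)
            if (is.null(gt)) stop("dataset ", k, " carries no ground truth")
            b <- computeBias(
                flist[[k]],
                list(cbf = mean(gt$cbf), att = mean(gt$att))
            )
            b$fitter <- fname
            b$schedule <- acquisitionScheduleOf(d)@name
            b$trueATT <- mean(gt$att)
            b$noiseSd <- metadata(d)$noiseSd
            rows[[length(rows) + 1L]] <- b
        }
    }
    if (length(missing)) {
        stop("missing fits for cells: ", paste(missing, collapse = ", "))
    }
    out <- do.call(rbind, rows)
    out[, c(
        "fitter", "schedule", "trueATT", "noiseSd", "parameter",
        "truth", "meanEstimate", "biasPct", "nExcluded"
    )]
}

#' Noise-averaged bias summary with min-max envelope
#'
#' For each (fitter, schedule, true ATT, parameter), the mean of the
#' percentage bias across noise SD levels together with its min-max
#' envelope (the "fan" across SNR levels).
#'
#' @param table output of \code{\link{biasTable}}.
#' @return \code{data.frame} with columns \code{fitter}, \code{schedule},
#'   \code{trueATT}, \code{parameter}, \code{meanBiasPct},
#'   \code{minBiasPct}, \code{maxBiasPct}, \code{nNoiseLevels}.
#' @export
biasSummary <- function(table) {
    stopifnot(nrow(table) > 0)
    key <- interaction(table$fitter, table$schedule, table$trueATT,
        table$parameter,
        drop = TRUE
    )
    parts <- split(table, key)
    out <- do.call(rbind, lapply(parts, function(p) {
        data.frame(
            fitter = p$fitter[1], schedule = p$schedule[1],
            trueATT = p$trueATT[1], parameter = p$parameter[1],
            meanBiasPct = mean(p$biasPct),
            minBiasPct = min(p$biasPct),
            maxBiasPct = max(p$biasPct),
            nNoiseLevels = nrow(p)
        )
    }))
    rownames(out) <- NULL
    out[order(out$fitter, out$schedule, out$parameter, out$trueATT), ]
}

#' Plot bias-versus-true-ATT curves
#'
#' One panel per (schedule, parameter): noise-averaged percentage bias as a
#' line per fitter with a min-max ribbon across noise levels.
#'
#' @param table output of \code{\link{biasTable}}.
#' @param outDir directory for the figure files (created if needed); when
#'   \code{NULL}, the ggplot objects are returned without writing.
#' @return Named list of ggplot objects (one per panel); written as PDF
#'   files when \code{outDir} is given.
#' @export
plotBiasCurves <- function(table, outDir = NULL) {
    if (is.null(table) || nrow(table) == 0) stop("bias table is empty")
    summ <- biasSummary(table)
    panels <- unique(summ[, c("schedule", "parameter")])
    if (!is.null(outDir) && !dir.exists(outDir)) {
        dir.create(outDir, recursive = TRUE)
    }
    plots <- list()
    for (r in seq_len(nrow(panels))) {
        sch <- panels$schedule[r]
        par <- panels$parameter[r]
        dat <- summ[summ$schedule == sch & summ$parameter == par, ]
        p <- ggplot2::ggplot(dat, ggplot2::aes(
            x = trueATT, y = meanBiasPct,
            colour = fitter, fill = fitter
        )) +
            ggplot2::geom_ribbon(
                ggplot2::aes(ymin = minBiasPct, ymax = maxBiasPct),
                alpha = 0.2, colour = NA
            ) +
            ggplot2::geom_line() +
            ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
            ggplot2::labs(
                x = "true ATT (s)", y = "bias (%)",
                title = paste0(toupper(par), " bias, schedule ", sch)
            ) +
            ggplot2::theme_minimal()
        nm <- paste0("bias_", sch, "_", par)
        plots[[nm]] <- p
        if (!is.null(outDir)) {
            ggplot2::ggsave(file.path(outDir, paste0(nm, ".pdf")), p,
                width = 6, height = 4
            )
        }
    }
    plots
}
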