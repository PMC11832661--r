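# Comparator fitters: unconstrained voxelwise non-linear least squares and
# signal-weighted-delay (first temporal moment) ATT estimation with a
# fixed-ATT linear CBF solve.

# Unit-amplitude signal template at a given ATT (T1app evaluated at the
# reference CBF), used for linear amplitude solves and NLLS starts.
.unitTemplate <- function(schedule, att, constants, refCBF = 60) {
    signalVector(schedule, cbf = refCBF, att = att, constants) / refCBF
}

#' Unconstrained voxelwise non-linear least squares fit
#'
#' Per voxel, minimises the sum of squared differences between the data and
#' the Buxton model over (CBF, ATT) by Levenberg-Marquardt with the analytic
#' Jacobian. No constraints are placed on either parameter and no data
#' smoothing is applied. Because the unconstrained SSD landscape is
#' multimodal at low SNR, each voxel is fitted from several ATT starting
#' points (CBF started from the linear amplitude solve at that ATT) and the
#' lowest-SSD solution is kept.
#'
#' @param dataset an \linkS4class{ASLDataset}.
#' @param constants a \linkS4class{TissueConstants}.
#' @param startATT ATT multi-start values, seconds.
#' @return A \linkS4class{FitResult}; point estimates with SD maps from the
#'   linearised covariance at the optimum. Voxels where no start converges
#'   are set to \code{NaN} and counted in \code{metadata$nFailed}.
#' @export
setMethod("fitNLLS", "ASLDataset", function(dataset,
                                            constants = tissueConstants(),
                                            startATT = c(0.7, 1.3, 2.0, 2.7)) {
    Y <- signalMatrix(dataset)
    schedule <- acquisitionScheduleOf(dataset)
    tpts <- timepoints(schedule)
    tau <- schedule@labelDuration
    v <- nrow(Y)
    N <- ncol(Y)
    templates <- vapply(
        startATT, function(a) .unitTemplate(schedule, a, constants),
        numeric(N)
    )
    tnorm <- colSums(templates^2)

    cbf <- att <- cbfSd <- attSd <- nvar <- rep(NaN, v)
    nFailed <- 0L
    nWarn <- 0L
    for (i in seq_len(v)) {
        y <- Y[i, ]
        bestSSD <- Inf
        bestPar <- NULL
        for (s in seq_along(startATT)) {
            start <- c(sum(y * templates[, s]) / tnorm[s], startATT[s])
            fit <- tryCatch(
                minpack.lm::nls.lm(
                    par = start,
                    fn = function(p) {
                        drop(.buxtonEval(p[1], p[2], tpts, tau, constants,
                            grad = FALSE
                        )$M) - y
                    },
                    jac = function(p) {
                        ev <- .buxtonEval(p[1], p[2], tpts, tau, constants)
                        cbind(drop(ev$dMdf), drop(ev$dMddt))
                    },
                    control = minpack.lm::nls.lm.control(maxiter = 200)
                ),
                error = function(e) NULL
            )
            if (is.null(fit)) next
            ssd <- sum(fit$fvec^2)
            if (is.finite(ssd) && ssd < bestSSD) {
                bestSSD <- ssd
                bestPar <- fit$par
                if (!fit$info %in% 1:3) nWarn <- nWarn + 1L
            }
        }
        if (is.null(bestPar)) {
            nFailed <- nFailed + 1L
            next
        }
        cbf[i] <- bestPar[1]
        att[i] <- bestPar[2]
        ev <- .buxtonEval(bestPar[1], bestPar[2], tpts, tau, constants)
        J <- cbind(drop(ev$dMdf), drop(ev$dMddt))
        s2 <- bestSSD / max(N - 2, 1)
        nvar[i] <- s2
        covm <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
        if (!is.null(covm) && all(diag(covm) >= 0)) {
            cbfSd[i] <- sqrt(covm[1, 1])
            attSd[i] <- sqrt(covm[2, 2])
        }
    }
    if (nFailed > 0L) {
        warning("NLLS failed to converge at ", nFailed, " voxel(s); set to NaN")
    }
    resid <- 0
    ok <- is.finite(cbf)
    if (any(ok)) {
        M <- .predictMatrix(cbf[ok], att[ok], schedule, constants)$M
        resid <- sum((M - Y[ok, , drop = FALSE])^2)
    }
    new("FitResult",
        cbfMap = cbf, attMap = att, cbfSdMap = cbfSd, attSdMap = attSd,
        noiseVarMap = nvar, costTrace = resid, fitterName = "nlls",
        epochsRun = 0L, reversions = 0L,
        metadata = list(
            nFailed = nFailed, nNonstandardConvergence = nWarn,
            startATT = startATT
        )
    )
})

# Distinct-PLD aggregation: averaging weights (N x U matrix) collapsing all
# volumes acquired at the same PLD value, and the corresponding timepoints.
.distinctPLD <- function(schedule) {
    tAll <- timepoints(schedule)
    pldAll <- rep(schedule@plds, schedule@repeats)
    u <- unique(schedule@plds)
    W <- vapply(u, function(p) {
        w <- as.numeric(pldAll == p)
        w / sum(w)
    }, numeric(length(tAll)))
    list(tbar = schedule@labelDuration + u, W = W)
}

# First temporal moment over distinct-PLD mean signals:
# sum(tbar * dM) / sum(dM).
.firstMoment <- function(meansByPLD, tbar) {
    den <- sum(meansByPLD)
    if (!is.finite(den) || den <= 0) {
        return(NaN)
    }
    sum(tbar * meansByPLD) / den
}

#' Build the weighted-delay calibration curve for a schedule
#'
#' Tabulates the first temporal moment of the noiseless model signal (over
#' the schedule's distinct PLDs, \code{tbar = tau + PLD}) as a function of
#' ATT. Trailing grid points where the model places no signal within the
#' sampled timepoints (total signal zero, the moment undefined) are dropped.
#' The mapping must be strictly increasing over the retained grid, otherwise
#' the schedule is unsuitable for WD and an error is raised.
#'
#' @param schedule an \linkS4class{AcquisitionSchedule} (or preset name).
#' @param constants a \linkS4class{TissueConstants}.
#' @param attGrid ATT grid, seconds (default 0.2-4.0 in 0.01 steps). The
#'   grid is additionally truncated to the maximal initial segment over
#'   which the mapping is strictly increasing: the weighted delay saturates
#'   once the inflow curve slips past the sampled timepoints, so longer ATT
#'   is not recoverable by this method under the given schedule.
#' @return A \linkS4class{WDCalibration}.
#' @export
buildWDCalibration <- function(schedule, constants = tissueConstants(),
                               attGrid = seq(0.2, 4.0, by = 0.01)) {
    if (is.character(schedule)) schedule <- schedulePreset(schedule)
    if (length(unique(schedule@plds)) < 2L) {
        stop("weighted delay requires at least two distinct PLDs")
    }
    dp <- .distinctPLD(schedule)
    wd <- vapply(attGrid, function(a) {
        m <- signalVector(schedule, cbf = 60, att = a, constants)
        .firstMoment(as.numeric(m %*% dp$W), dp$tbar)
    }, numeric(1))
    keep <- is.finite(wd)
    if (!all(keep)) {
        if (any(diff(keep) > 0)) {
            stop("signal support vanishes inside the ATT grid; choose a contiguous grid")
        }
        attGrid <- attGrid[keep]
        wd <- wd[keep]
    }
    # maximal strictly-increasing initial segment
    bad <- which(diff(wd) <= 0)
    if (length(bad)) {
        upto <- bad[1]
        if (upto < 2L) {
            stop("weighted delay is not increasing in ATT at the grid start; schedule unsuitable for WD")
        }
        attGrid <- attGrid[seq_len(upto)]
        wd <- wd[seq_len(upto)]
    }
    new("WDCalibration",
        attGrid = attGrid, wdValues = wd,
        scheduleName = schedule@name
    )
}

setMethod("show", "WDCalibration", function(object) {
    cat(
        "WDCalibration for '", object@scheduleName, "': ATT ",
        format(min(object@attGrid)), "-", format(max(object@attGrid)),
        " s over ", length(object@attGrid), " points, WD ",
        format(min(object@wdValues), digits = 4), "-",
        format(max(object@wdValues), digits = 4), " s\n",
        sep = ""
    )
})

#' Signal-weighted-delay fit
#'
#' Two-stage comparator. Stage 1 estimates ATT from the first temporal
#' moment of the per-voxel signal; stage 2, holding ATT fixed, solves for
#' CBF by linear least squares on the signal amplitude (iterated once to
#' refresh the small CBF dependence of T1app).
#'
#' Two ATT routes are provided. The default, \code{"moment"}, is the
#' classical signal-weighted delay: the moment is taken over all acquired
#' volumes on the PLD axis and used directly as the ATT estimate, clipped
#' to the schedule's PLD range. Because the true inflow curve is not the
#' idealised bolus this moment implies, the estimate carries a systematic
#' positive bias at short ATT that shrinks as ATT approaches the sampled
#' delays. The alternative, \code{"calibration"}, inverts the
#' schedule-specific noiseless-model calibration curve
#' (\code{\link{buildWDCalibration}}) by monotone interpolation, which
#' removes that approximation error (exact self-inversion on noiseless
#' data) at the cost of requiring the kinetic model.
#'
#' Voxels whose summed signal is non-positive get \code{NaN} ATT; moments
#' outside the usable range are clipped to the range ends and counted.
#'
#' @param dataset an \linkS4class{ASLDataset}.
#' @param constants a \linkS4class{TissueConstants}.
#' @param inversion ATT route, \code{"moment"} (default) or
#'   \code{"calibration"}.
#' @param calibration a \linkS4class{WDCalibration} for the dataset's
#'   schedule (built with defaults when missing; only used by the
#'   \code{"calibration"} route).
#' @return A \linkS4class{FitResult} (ATT SD unavailable for this method;
#'   CBF SD from the linear solve).
#' @export
setMethod("fitWD", "ASLDataset", function(dataset,
                                          constants = tissueConstants(),
                                          inversion = c("moment", "calibration"),
                                          calibration = NULL) {
    inversion <- match.arg(inversion)
    Y <- signalMatrix(dataset)
    schedule <- acquisitionScheduleOf(dataset)
    v <- nrow(Y)
    N <- ncol(Y)
    att <- rep(NaN, v)
    if (inversion == "moment") {
        pldAll <- rep(schedule@plds, schedule@repeats)
        den <- rowSums(Y)
        num <- as.numeric(Y %*% pldAll)
        okm <- is.finite(den) & den > 0
        moments <- num[okm] / den[okm]
        lo <- min(schedule@plds)
        hi <- max(schedule@plds)
        nClipped <- sum(moments < lo | moments > hi)
        att[okm] <- pmin(pmax(moments, lo), hi)
    } else {
        if (is.null(calibration)) {
            calibration <- buildWDCalibration(schedule, constants)
        }
        if (!identical(calibration@scheduleName, schedule@name)) {
            stop(
                "calibration was built for schedule '", calibration@scheduleName,
                "' but the dataset uses '", schedule@name, "'"
            )
        }
        dp <- .distinctPLD(schedule)
        means <- Y %*% dp$W # v x U distinct-PLD means
        moments <- apply(means, 1, .firstMoment, tbar = dp$tbar)
        okm <- is.finite(moments)
        nClipped <- sum(okm & (moments < min(calibration@wdValues) |
            moments > max(calibration@wdValues)))
        # monotone inversion of the calibration; rule = 2 clips to range ends
        att[okm] <- stats::approx(
            x = calibration@wdValues, y = calibration@attGrid,
            xout = moments[okm], rule = 2
        )$y
    }

    cbf <- cbfSd <- nvar <- rep(NaN, v)
    for (i in which(is.finite(att))) {
        y <- Y[i, ]
        s <- .unitTemplate(schedule, att[i], constants)
        c1 <- sum(y * s) / sum(s^2)
        # one refresh of T1app at the estimated amplitude
        if (is.finite(c1) && abs(c1) > 1e-8) {
            s <- signalVector(schedule, cbf = c1, att = att[i], constants) / c1
        }
        ss <- sum(s^2)
        cbf[i] <- sum(y * s) / ss
        res <- y - cbf[i] * s
        s2 <- sum(res^2) / max(N - 1, 1)
        nvar[i] <- s2
        cbfSd[i] <- sqrt(s2 / ss)
    }
    resid <- 0
    ok <- is.finite(cbf)
    if (any(ok)) {
        M <- .predictMatrix(cbf[ok], att[ok], schedule, constants)$M
        resid <- sum((M - Y[ok, , drop = FALSE])^2)
    }
    new("FitResult",
        cbfMap = cbf, attMap = att, cbfSdMap = cbfSd,
        attSdMap = rep(NaN, v), noiseVarMap = nvar,
        costTrace = resid, fitterName = "wd",
        epochsRun = 0L, reversions = 0L,
        metadata = list(
            inversion = inversion,
            nClipped = nClipped,
            nUndefinedMoment = v - sum(okm)
        )
    )
})
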