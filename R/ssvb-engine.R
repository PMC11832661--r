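# Stochastic variational Bayes (SSVB) engine.
#
# The approximate posterior is a per-voxel diagonal Gaussian over (CBF, ATT)
# with a per-voxel point-estimated log noise variance and one global log
# spatial precision per map. The variational free energy
#
#   F = E_q[ log p(y|theta) + log p(theta) - log q(theta) ]
#
# is estimated by Monte Carlo with L reparameterised samples
# theta* = mu + exp(logSd) * eps, eps ~ N(0,1), and maximised by RMSProp on
# all state fields jointly. Because each sample is a full map, the spatial
# prior couples voxels within a sample and is evaluated once per sample.
#
# Constant conventions: the 2*pi terms of the Gaussian log-likelihood and of
# the posterior entropy are omitted (they are constant offsets that cancel
# in optimisation); the noise prior uses the full Gaussian log-density. The
# cost reported per epoch is the negative free energy summed over the masked
# voxels (not averaged), so the patience rule acts on absolute cost.
#
# Under reparameterisation the entropy term is
#   -log q(theta*) = logSd + eps^2/2   (per voxel, per parameter)
# whose gradient is exactly +1 w.r.t. logSd and 0 w.r.t. mu: the pathwise
# derivative of log q through theta* cancels its direct mu-dependence.

#' Gaussian log-likelihood of an ASL signal vector
#'
#' \code{(N/2) log(phi) - (phi/2) * SSD} with \code{phi} the noise precision
#' and SSD the sum of squared differences between data and prediction; the
#' \code{2*pi} constant is omitted (see the package vignette).
#'
#' @param y data vector (length N).
#' @param prediction model prediction (length N).
#' @param noisePrecision noise precision phi (inverse variance), positive.
#' @return Scalar log-likelihood.
#' @export
logLikelihood <- function(y, prediction, noisePrecision) {
    if (length(y) != length(prediction)) {
        stop("y has length ", length(y), " but prediction has length ", length(prediction))
    }
    stopifnot(noisePrecision > 0)
    N <- length(y)
    ssd <- sum((y - prediction)^2)
    (N / 2) * log(noisePrecision) - (noisePrecision / 2) * ssd
}

#' Draw reparameterised samples from the variational posterior
#'
#' \code{theta* = mu + exp(logSd) * eps}, \code{eps ~ N(0,1)} i.i.d. across
#' samples and voxels, using the current R random number stream.
#'
#' @param state a \linkS4class{VariationalState}.
#' @param L number of samples.
#' @return \code{list(cbf =, att =)} of \code{L x v} matrices.
#' @export
samplePosterior <- function(state, L) {
    stopifnot(L >= 1)
    v <- length(state@meanCBF)
    epsC <- matrix(stats::rnorm(L * v), L, v)
    epsA <- matrix(stats::rnorm(L * v), L, v)
    list(
        cbf = sweep(epsC %*% diag(exp(state@logSdCBF), v), 2, state@meanCBF, "+"),
        att = sweep(epsA %*% diag(exp(state@logSdATT), v), 2, state@meanATT, "+")
    )
}

#' Monte-Carlo estimate of the variational free energy
#'
#' Averages, over \code{L} posterior samples, the summed voxelwise Gaussian
#' log-likelihood plus the log-prior of the sampled maps (spatial terms on
#' CBF and ATT, optional distributional priors) minus the log posterior
#' density of the sample, plus the (sample-independent) noise prior.
#'
#' @param state a \linkS4class{VariationalState}.
#' @param dataset an \linkS4class{ASLDataset} (or a bare \code{v x N} matrix
#'   together with \code{schedule}).
#' @param schedule,constants acquisition schedule and tissue constants
#'   (defaulted from the dataset where available).
#' @param D Laplacian for the spatial prior, or \code{NULL} to disable it.
#' @param L Monte-Carlo sample size.
#' @param model optional replacement forward model
#'   \code{function(cbf, att) -> v x N matrix}; defaults to the Buxton model
#'   under \code{schedule}.
#' @param cbfPrior,attPrior optional \code{list(mean =, var =)} Gaussian
#'   priors applied voxelwise to the sampled maps.
#' @param noisePrior optional \code{list(mean =, var =)} Gaussian prior on
#'   the per-voxel log noise variance.
#' @param eps optional pre-drawn standard-normal \code{list(cbf =, att =)}
#'   of \code{L x v} matrices (for reproducing a particular estimate);
#'   drawn internally when \code{NULL}.
#' @return Scalar free-energy estimate.
#' @export
freeEnergyEstimate <- function(state, dataset, schedule = NULL,
                               constants = tissueConstants(), D = NULL, L = 10,
                               model = NULL, cbfPrior = NULL, attPrior = NULL,
                               noisePrior = NULL, eps = NULL) {
    if (is(dataset, "ASLDataset")) {
        Y <- signalMatrix(dataset)
        if (is.null(schedule)) schedule <- acquisitionScheduleOf(dataset)
    } else {
        Y <- as.matrix(dataset)
    }
    v <- nrow(Y)
    N <- ncol(Y)
    if (is.null(model)) {
        force(schedule)
        model <- function(cbf, att) {
            .predictMatrix(cbf, att, schedule, constants, grad = FALSE)$M
        }
    }
    sdC <- exp(state@logSdCBF)
    sdA <- exp(state@logSdATT)
    if (is.null(eps)) {
        eps <- list(
            cbf = matrix(stats::rnorm(L * v), L, v),
            att = matrix(stats::rnorm(L * v), L, v)
        )
    }
    phi <- exp(-state@logNoiseVar)
    total <- 0
    for (l in seq_len(L)) {
        cbfS <- state@meanCBF + sdC * eps$cbf[l, ]
        attS <- state@meanATT + sdA * eps$att[l, ]
        M <- model(cbfS, attS)
        ssd <- rowSums((M - Y)^2)
        ll <- sum((N / 2) * (-state@logNoiseVar) - (phi / 2) * ssd)
        lp <- 0
        if (!is.null(D)) {
            lp <- lp + spatialLogPdf(cbfS, state@logAlphaCBF, D) +
                spatialLogPdf(attS, state@logAlphaATT, D)
        }
        if (!is.null(cbfPrior)) {
            lp <- lp + sum(normalLogPdf(cbfS, cbfPrior$mean, cbfPrior$var))
        }
        if (!is.null(attPrior)) {
            lp <- lp + sum(normalLogPdf(attS, attPrior$mean, attPrior$var))
        }
        # -log q, 2*pi omitted
        negLogQ <- sum(state@logSdCBF + eps$cbf[l, ]^2 / 2) +
            sum(state@logSdATT + eps$att[l, ]^2 / 2)
        total <- total + ll + lp + negLogQ
    }
    fe <- total / L
    if (!is.null(noisePrior)) {
        fe <- fe + sum(normalLogPdf(state@logNoiseVar, noisePrior$mean, noisePrior$var))
    }
    fe
}

# ---- internal optimisation machinery ------------------------------------

# Parameter vector layout: [muC | muA | lsdC | lsdA | lvar | laC | laA]
.packState <- function(state) {
    c(
        state@meanCBF, state@meanATT, state@logSdCBF, state@logSdATT,
        state@logNoiseVar, state@logAlphaCBF, state@logAlphaATT
    )
}

.unpackState <- function(par, v) {
    i <- function(k) ((k - 1) * v + 1):(k * v)
    new("VariationalState",
        meanCBF = par[i(1)], meanATT = par[i(2)],
        logSdCBF = par[i(3)], logSdATT = par[i(4)],
        logNoiseVar = par[i(5)],
        logAlphaCBF = par[5 * v + 1], logAlphaATT = par[5 * v + 2]
    )
}

# Value and gradient of the negative free energy (the cost) at `par`, using
# L fresh (or supplied) reparameterisation draws. Y is v x N, D the sparse
# Laplacian, noisePrior a list(mean, var) on log noise variance.
.costAndGrad <- function(par, Y, schedule, constants, D, L, noisePrior,
                         eps = NULL) {
    v <- nrow(Y)
    N <- ncol(Y)
    i <- function(k) ((k - 1) * v + 1):(k * v)
    muC <- par[i(1)]
    muA <- par[i(2)]
    lsdC <- par[i(3)]
    lsdA <- par[i(4)]
    lvar <- par[i(5)]
    laC <- par[5 * v + 1]
    laA <- par[5 * v + 2]
    sdC <- exp(lsdC)
    sdA <- exp(lsdA)
    phi <- exp(-lvar)
    alphaC <- exp(laC)
    alphaA <- exp(laA)
    if (is.null(eps)) {
        epsC <- matrix(stats::rnorm(L * v), L, v)
        epsA <- matrix(stats::rnorm(L * v), L, v)
    } else {
        epsC <- eps$cbf
        epsA <- eps$att
    }
    tpts <- timepoints(schedule)
    tau <- schedule@labelDuration

    fe <- 0
    gMuC <- gMuA <- gLsdC <- gLsdA <- gLvar <- numeric(v)
    gLaC <- gLaA <- 0
    for (l in seq_len(L)) {
        cbfS <- muC + sdC * epsC[l, ]
        attS <- muA + sdA * epsA[l, ]
        ev <- .buxtonEval(cbfS, attS, tpts, tau, constants, grad = TRUE)
        Rres <- ev$M - Y
        ssd <- rowSums(Rres * Rres)
        # likelihood value and gradients
        fe <- fe + sum((N / 2) * (-lvar) - (phi / 2) * ssd)
        glC <- -phi * rowSums(Rres * ev$dMdf)
        glA <- -phi * rowSums(Rres * ev$dMddt)
        gLvar <- gLvar + (-N / 2 + (phi / 2) * ssd)
        # spatial priors (quadratic form in -D penalises roughness)
        Dc <- as.numeric(D %*% cbfS)
        Da <- as.numeric(D %*% attS)
        roughC <- -sum(cbfS * Dc)
        roughA <- -sum(attS * Da)
        fe <- fe + (v / 2) * laC - (alphaC / 2) * roughC +
            (v / 2) * laA - (alphaA / 2) * roughA
        gspC <- alphaC * Dc # d/dtheta of -(alpha/2) theta'(-D)theta
        gspA <- alphaA * Da
        gLaC <- gLaC + (v / 2 - (alphaC / 2) * roughC)
        gLaA <- gLaA + (v / 2 - (alphaA / 2) * roughA)
        # entropy -log q (2*pi omitted): value; grad is +1 on logSd, 0 on mu
        fe <- fe + sum(lsdC + epsC[l, ]^2 / 2) + sum(lsdA + epsA[l, ]^2 / 2)
        # chain rule through theta* = mu + sd * eps
        gC <- glC + gspC
        gA <- glA + gspA
        gMuC <- gMuC + gC
        gMuA <- gMuA + gA
        gLsdC <- gLsdC + gC * sdC * epsC[l, ] + 1
        gLsdA <- gLsdA + gA * sdA * epsA[l, ] + 1
    }
    fe <- fe / L
    gMuC <- gMuC / L
    gMuA <- gMuA / L
    gLsdC <- gLsdC / L
    gLsdA <- gLsdA / L
    gLvar <- gLvar / L
    gLaC <- gLaC / L
    gLaA <- gLaA / L
    # noise prior (sample-independent)
    fe <- fe + sum(normalLogPdf(lvar, noisePrior$mean, noisePrior$var))
    gLvar <- gLvar - (lvar - noisePrior$mean) / noisePrior$var

    list(
        cost = -fe,
        grad = -c(gMuC, gMuA, gLsdC, gLsdA, gLvar, gLaC, gLaA)
    )
}

# Initial variational state. ATT means either flat at initATT or (default)
# at the weighted-delay calibration inversion of the image-average signal:
# pooling across voxels makes the first moment robust to noise, and the
# resulting global value places the optimiser near the typical transit time
# of the image across the whole plausible ATT range. CBF means from the
# per-voxel linear fit of the data onto the unit-amplitude signal template
# at the initial ATT; log noise variance at the per-voxel data variance
# (floored for degenerate voxels).
.initialState <- function(Y, schedule, constants, config) {
    v <- nrow(Y)
    att0 <- rep(config@initATT, v)
    if (config@initMethod == "wd") {
        cal <- tryCatch(buildWDCalibration(schedule, constants),
            error = function(e) NULL
        )
        if (!is.null(cal)) {
            dp <- .distinctPLD(schedule)
            pooled <- .firstMoment(as.numeric(colMeans(Y) %*% dp$W), dp$tbar)
            if (is.finite(pooled)) {
                att0 <- rep(stats::approx(
                    x = cal@wdValues, y = cal@attGrid,
                    xout = pooled, rule = 2
                )$y, v)
            }
        }
    }
    ev <- .buxtonEval(rep(60, v), att0, timepoints(schedule),
        schedule@labelDuration, constants,
        grad = FALSE
    )
    Tm <- ev$M / 60 # per-voxel unit-amplitude templates
    denom <- rowSums(Tm^2)
    cbf0 <- ifelse(denom > 0, rowSums(Y * Tm) / pmax(denom, 1e-12), 0)
    dataVar <- pmax(apply(Y, 1, stats::var), 1e-6)
    new("VariationalState",
        meanCBF = cbf0,
        meanATT = att0,
        logSdCBF = rep(config@initLogSdCBF, v),
        logSdATT = rep(config@initLogSdATT, v),
        logNoiseVar = log(dataVar),
        logAlphaCBF = config@initLogAlpha,
        logAlphaATT = config@initLogAlpha
    )
}

#' Fit CBF and ATT maps by stochastic variational Bayes
#'
#' Minimises the negative Monte-Carlo free energy over all variational
#' parameters (posterior means and log-SDs of CBF and ATT, per-voxel log
#' noise variance, and the two log spatial precisions) by RMSProp. After
#' \code{patience} consecutive epochs without improving the best cost, the
#' state reverts to the best snapshot and the Monte-Carlo sample size grows
#' by 1 (from \code{initialSampleSize}); the fit terminates after
#' \code{maxReversions} reversions (or the epoch cap) and returns the best
#' snapshot.
#'
#' @param dataset an \linkS4class{ASLDataset}.
#' @param constants a \linkS4class{TissueConstants}.
#' @param config an \linkS4class{SSVBConfig}; see \code{ssvbConfig()}.
#' @param ... passed to \code{ssvbConfig} when \code{config} is missing.
#' @return A \linkS4class{FitResult} with posterior mean maps, posterior SD
#'   maps, the noise variance map, the per-epoch cost trace and optimisation
#'   counters.
#' @examples
#' d <- simulateDataset("grey_paper",
#'     gridShape = c(3, 3, 1), trueATT = 1.5,
#'     noiseSd = 20, seed = 1
#' )
#' fit <- fitSSVB(d, config = ssvbConfig(rngSeed = 1, maxEpochs = 200))
#' mean(cbfMap(fit))
#' @export
setMethod("fitSSVB", "ASLDataset", function(dataset,
                                            constants = tissueConstants(),
                                            config = ssvbConfig(...), ...) {
    Y <- signalMatrix(dataset)
    schedule <- acquisitionScheduleOf(dataset)
    grid <- voxelGridOf(dataset)
    v <- nrow(Y)
    D <- buildLaplacian(grid)
    cfg <- config
    set.seed(cfg@rngSeed)

    state <- .initialState(Y, schedule, constants, cfg)
    noisePrior <- list(mean = state@logNoiseVar, var = cfg@noisePriorSd^2)
    par <- .packState(state)
    nPar <- length(par)

    L <- cfg@initialSampleSize
    acc <- numeric(nPar) # RMSProp accumulator
    bestCost <- Inf
    bestPar <- par
    stale <- 0L
    reversions <- 0L
    trace <- numeric(0)
    epoch <- 0L

    while (epoch < cfg@maxEpochs) {
        epoch <- epoch + 1L
        cg <- .costAndGrad(par, Y, schedule, constants, D, L, noisePrior)
        if (!is.finite(cg$cost)) {
            bad <- which(!is.finite(par))
            fields <- c("meanCBF", "meanATT", "logSdCBF", "logSdATT", "logNoiseVar")
            where <- if (length(bad)) {
                k <- bad[1]
                if (k <= 5 * v) {
                    paste0(fields[(k - 1) %/% v + 1], " voxel ", (k - 1) %% v + 1)
                } else {
                    c("logAlphaCBF", "logAlphaATT")[k - 5 * v]
                }
            } else {
                "cost (state finite)"
            }
            stop("non-finite cost at epoch ", epoch, ": ", where)
        }
        trace[epoch] <- cg$cost
        if (cg$cost < bestCost) {
            bestCost <- cg$cost
            bestPar <- par
            stale <- 0L
        } else {
            stale <- stale + 1L
        }
        if (stale >= cfg@patience) {
            # revert to best state, grow the MC sample size, restart RMSProp
            par <- bestPar
            L <- L + 1L
            reversions <- reversions + 1L
            stale <- 0L
            acc <- numeric(nPar)
            if (reversions >= cfg@maxReversions) break
            # re-evaluate the incumbent at the new sample size: comparing
            # fresh costs against a best recorded under a noisier estimator
            # would make the incumbent an extreme draw that fresh epochs
            # cannot fairly beat
            bestCost <- .costAndGrad(
                par, Y, schedule, constants, D, L,
                noisePrior
            )$cost
            next
        }
        g <- cg$grad
        if (!cfg@optimiseAlpha) g[(5 * v + 1):(5 * v + 2)] <- 0
        acc <- cfg@rmsDecay * acc + (1 - cfg@rmsDecay) * g^2
        par <- par - cfg@learningRate * g / (sqrt(acc) + cfg@rmsEpsilon)
    }

    best <- .unpackState(bestPar, v)
    new("FitResult",
        cbfMap = best@meanCBF,
        attMap = best@meanATT,
        cbfSdMap = exp(best@logSdCBF),
        attSdMap = exp(best@logSdATT),
        noiseVarMap = exp(best@logNoiseVar),
        costTrace = trace,
        fitterName = "ssvb",
        epochsRun = epoch,
        reversions = reversions,
        metadata = list(
            bestCost = bestCost,
            finalSampleSize = L,
            logAlphaCBF = best@logAlphaCBF,
            logAlphaATT = best@logAlphaATT,
            seed = cfg@rngSeed,
            learningRate = cfg@learningRate,
            patience = cfg@patience,
            rmsDecay = cfg@rmsDecay,
            rmsEpsilon = cfg@rmsEpsilon
        )
    )
})

#' SSVB configuration constructor
#'
#' @param learningRate RMSProp learning rate (default 0.1).
#' @param initialSampleSize starting Monte-Carlo sample size (default 2).
#' @param patience epochs without a best-cost decrease before reverting
#'   (default 50).
#' @param maxReversions reversions before termination (default 5).
#' @param maxEpochs safety cap (default 5000).
#' @param rngSeed integer seed.
#' @param ... overrides for the remaining \linkS4class{SSVBConfig} slots.
#' @return An \linkS4class{SSVBConfig}.
#' @export
ssvbConfig <- function(learningRate = 0.1, initialSampleSize = 2L,
                       patience = 50L, maxReversions = 5L, maxEpochs = 5000L,
                       rngSeed = 1L, ...) {
    new("SSVBConfig",
        learningRate = learningRate,
        initialSampleSize = as.integer(initialSampleSize),
        patience = as.integer(patience),
        maxReversions = as.integer(maxReversions),
        maxEpochs = as.integer(maxEpochs),
        rngSeed = as.integer(rngSeed),
        ...
    )
}
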