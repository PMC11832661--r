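# Buxton single-compartment PCASL kinetic model.
#
# The label-control difference signal of a voxel with perfusion f (CBF, in
# ml/100g/min-convention units) and arterial transit time dt (s) is the
# piecewise function
#
#   dM(t) = 0                                                    t <  dt
#   dM(t) = 2 M0a f T1app exp(-dt/T1b) (1 - exp(-(t-dt)/T1app))  dt <= t < dt+tau
#   dM(t) = 2 M0a f T1app exp(-dt/T1b) exp(-(t-dt-tau)/T1app)
#                                      (1 - exp(-tau/T1app))     t >= dt+tau
#
# with 1/T1app = 1/T1 + f_rate/lambda and f_rate = f/6000 (the standard
# ml/100g/min -> 1/s conversion). The label-decay factor exp(-dt/T1b) is
# carried in both post-arrival branches, which makes dM continuous at
# t = dt + tau. No clamping of f or dt is performed: negative inputs are
# evaluated piecewise as written so that gradient-based and unconstrained
# fitters see a smooth objective.

#' Apparent longitudinal relaxation time
#'
#' \code{1/T1app = 1/T1 + f/(6000 lambda)}: tissue relaxation accelerated by
#' venous outflow of labelled water. CBF enters in 1/s after the standard
#' ml/100g/min conversion (divide by 6000).
#'
#' @param cbf perfusion in the ml/100g/min unit convention.
#' @param constants a \linkS4class{TissueConstants}.
#' @return T1app in seconds.
#' @examples
#' t1Apparent(0) # equals T1
#' t1Apparent(60)
#' @export
t1Apparent <- function(cbf, constants = tissueConstants()) {
    rate <- 1 / constants@t1Tissue + (cbf / 6000) / constants@partitionCoeff
    if (any(rate <= 0)) {
        stop("non-positive apparent relaxation rate (pathological negative CBF)")
    }
    1 / rate
}

#' Buxton PCASL difference signal at arbitrary times
#'
#' Evaluates the three-branch kinetic model (see the package vignette) at
#' times \code{t} for one set of parameters.
#'
#' @param t times since the start of label creation, seconds (vectorised).
#' @param cbf perfusion (scalar).
#' @param att arterial transit time, seconds (scalar).
#' @param tau label duration, seconds.
#' @param constants a \linkS4class{TissueConstants}.
#' @return Signal values, same length as \code{t}.
#' @examples
#' buxtonSignal(seq(0, 6, 0.5), cbf = 60, att = 1.3, tau = 2.05)
#' @export
buxtonSignal <- function(t, cbf, att, tau, constants = tissueConstants()) {
    stopifnot(tau > 0, length(cbf) == 1L, length(att) == 1L)
    ev <- .buxtonEval(
        f = cbf, dt = att, t = t, tau = tau,
        constants = constants, grad = FALSE
    )
    drop(ev$M)
}

#' Noise-free model prediction for a full schedule
#'
#' Expands \code{\link{buxtonSignal}} over every volume of a schedule
#' (PLD-major, repeat-minor order); repeats at the same PLD share one
#' prediction.
#'
#' @param schedule an \linkS4class{AcquisitionSchedule}.
#' @param cbf,att kinetic parameters (scalars).
#' @param constants a \linkS4class{TissueConstants}.
#' @return Length-N signal vector.
#' @export
signalVector <- function(schedule, cbf, att, constants = tissueConstants()) {
    buxtonSignal(timepoints(schedule),
        cbf = cbf, att = att,
        tau = schedule@labelDuration, constants = constants
    )
}

# Vectorised model evaluation over voxels x timepoints, optionally with the
# analytic partial derivatives dM/df and dM/ddt needed by the SSVB gradient
# and the NLLS Jacobian.
#
# f, dt: length-v parameter vectors; t: length-N timepoints. Returns v x N
# matrices.
.buxtonEval <- function(f, dt, t, tau, constants, grad = TRUE) {
    v <- length(f)
    N <- length(t)
    X <- matrix(t, v, N, byrow = TRUE) - dt # t - dt
    a <- 1 / constants@t1Tissue
    b <- 1 / (6000 * constants@partitionCoeff)
    R <- a + b * f # 1/T1app, length v
    if (any(R <= 0)) {
        stop("non-positive apparent relaxation rate (pathological negative CBF)")
    }
    Tapp <- 1 / R
    A <- 2 * constants@m0a
    dec <- exp(-dt / constants@t1Blood) # label decay, length v
    E1 <- exp(-X * R) # exp(-(t-dt)/T1app), v x N (R recycles down columns)
    eTau <- exp(-tau * R) # length v
    Btau <- 1 - eTau

    mid <- X >= 0 & X < tau
    late <- X >= tau

    M <- matrix(0, v, N)
    # inflow branch
    Smid <- (A * f * Tapp * dec) * (1 - E1)
    # outflow branch: exp(-(t-dt-tau)/T1app) = E1 * exp(tau/T1app)
    E2 <- E1 / eTau
    Slate <- (A * f * Tapp * dec * Btau) * E2
    M[mid] <- Smid[mid]
    M[late] <- Slate[late]
    if (!grad) {
        return(list(M = M))
    }

    # d/ddt
    Gd <- matrix(0, v, N)
    gmid <- -Smid / constants@t1Blood - (A * f * dec) * E1
    glate <- Slate * (R - 1 / constants@t1Blood)
    Gd[mid] <- gmid[mid]
    Gd[late] <- glate[late]

    # d/df (T1app depends on f through R = a + b f)
    Gf <- matrix(0, v, N)
    fbT <- f * b * Tapp
    hmid <- (A * Tapp * dec) * ((1 - E1) * (1 - fbT) + (f * b) * X * E1)
    hlate <- (A * Tapp * dec) * E2 *
        (Btau * (1 - fbT - (f * b) * (X - tau)) + (f * b * tau) * eTau)
    Gf[mid] <- hmid[mid]
    Gf[late] <- hlate[late]

    list(M = M, dMdf = Gf, dMddt = Gd)
}

# Prediction matrix (v x N) for per-voxel parameters under a schedule.
.predictMatrix <- function(f, dt, schedule, constants, grad = FALSE) {
    .buxtonEval(f, dt,
        t = timepoints(schedule), tau = schedule@labelDuration,
        constants = constants, grad = grad
    )
}
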