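test_that("apparent T1 follows the outflow-corrected relaxation rate", {
    # zero flow: T1app equals tissue T1
    expect_equal(t1Apparent(0), 1.3)
    # closed form at the reference perfusion
    expect_equal(t1Apparent(60), 1 / (1 / 1.3 + (60 / 6000) / 0.9),
        tolerance = 1e-12
    )
    # huge partition coefficient removes the outflow term
    expect_equal(
        t1Apparent(60, tissueConstants(partitionCoeff = 1e12)), 1.3,
        tolerance = 1e-9
    )
    # pathological negative CBF that flips the rate sign is a domain error
    expect_error(t1Apparent(-1e5), "negative CBF")
})

test_that("signal matches an independent evaluation of the closed form", {
    cases <- expand.grid(
        cbf = c(10, 60, 120), att = c(0.5, 1.3, 2.6),
        tau = c(1.5, 2.05)
    )
    for (r in seq_len(nrow(cases))) {
        t <- seq(0, 7, by = 0.13)
        expect_equal(
            buxtonSignal(t, cases$cbf[r], cases$att[r], cases$tau[r]),
            oracleBuxton(t, cases$cbf[r], cases$att[r], cases$tau[r]),
            tolerance = 1e-12
        )
    }
    # spec reference point
    expect_equal(
        buxtonSignal(3.35, cbf = 60, att = 1.3, tau = 2.05),
        oracleBuxton(3.35, 60, 1.3, 2.05),
        tolerance = 1e-12
    )
})

test_that("signal is zero before arrival and proportional to perfusion", {
    expect_equal(buxtonSignal(0.9 * 1.3, cbf = 60, att = 1.3, tau = 2.05), 0)
    t <- seq(0, 6, by = 0.25)
    expect_equal(buxtonSignal(t, cbf = 0, att = 1.0, tau = 2.05), rep(0, length(t)))
    # exact amplitude doubling when the T1app coupling is frozen by
    # scaling lambda with CBF
    s1 <- buxtonSignal(t, cbf = 60, att = 1.0, tau = 2.05)
    s2 <- buxtonSignal(t,
        cbf = 120, att = 1.0, tau = 2.05,
        constants = tissueConstants(partitionCoeff = 1.8)
    )
    expect_equal(s2, 2 * s1, tolerance = 1e-12)
    # near-linearity with the coupling active: the f/6000 outflow term
    # perturbs the amplitude by ~1% and the late-time decay by a few
    # percent at f = 120
    s2c <- buxtonSignal(t, cbf = 120, att = 1.0, tau = 2.05)
    on <- s1 > 0
    expect_lt(max(abs(s2c[on] / (2 * s1[on]) - 1)), 0.05)
    expect_lt(abs(max(s2c) / (2 * max(s1)) - 1), 0.02)
})

test_that("signal is continuous at both breakpoints and decays after the bolus", {
    set.seed(41)
    for (i in 1:20) {
        cbf <- runif(1, 5, 120)
        att <- runif(1, 0.3, 3)
        tau <- runif(1, 1, 2.5)
        h <- 1e-9
        for (bp in c(att, att + tau)) {
            lo <- buxtonSignal(bp - h, cbf, att, tau)
            hi <- buxtonSignal(bp + h, cbf, att, tau)
            expect_lt(abs(hi - lo), 1e-6) # O(h) slope bound
        }
        # exact branch agreement at t = att + tau
        expect_equal(
            buxtonSignal(att + tau, cbf, att, tau),
            oracleBuxton(att + tau - .Machine$double.eps, cbf, att, tau),
            tolerance = 1e-9
        )
        # non-negative and strictly decreasing after the bolus
        t <- seq(att + tau + 0.01, att + tau + 3, length.out = 40)
        s <- buxtonSignal(t, cbf, att, tau)
        expect_true(all(s >= 0))
        expect_true(all(diff(s) < 0))
    }
})

test_that("analytic model gradients match numerical differentiation", {
    s <- schedulePreset("grey_paper")
    tp <- timepoints(s)
    const <- tissueConstants()
    for (par in list(c(60, 1.2), c(80, 2.6), c(-5, 0.9), c(40, -0.3))) {
        ev <- ssvb:::.buxtonEval(par[1], par[2], tp, 2.05, const)
        gf <- pracma::grad(function(x) {
            sum(ssvb:::.buxtonEval(x, par[2], tp, 2.05, const, grad = FALSE)$M)
        }, par[1])
        ga <- pracma::grad(function(x) {
            sum(ssvb:::.buxtonEval(par[1], x, tp, 2.05, const, grad = FALSE)$M)
        }, par[2])
        expect_equal(sum(ev$dMdf), gf, tolerance = 1e-6)
        expect_equal(sum(ev$dMddt), ga, tolerance = 1e-6)
    }
})

test_that("schedule presets and signal vectors have the documented shape", {
    grey <- schedulePreset("grey_paper")
    hcp <- schedulePreset("hcp_asl")
    expect_equal(nTimepoints(grey), 36L)
    expect_equal(nTimepoints(hcp), 43L)
    expect_equal(length(signalVector(grey, 60, 1.3)), 36L)
    # repeats at one PLD share the prediction
    one <- acquisitionSchedule(2.0, 1.5, repeats = 3L)
    sv <- signalVector(one, 60, 1.0)
    expect_equal(length(sv), 3L)
    expect_equal(length(unique(sv)), 1L)
    # timepoints are tau + PLD in PLD-major order
    expect_equal(
        timepoints(tinySchedule()),
        rep(2.0 + c(0.2, 1.0, 2.0), each = 2)
    )
})

test_that("schedule construction and config round-trip validate inputs", {
    expect_error(
        acquisitionSchedule(2.0, c(0.2, 0.5), repeats = c(1L, 2L, 3L)),
        "same length"
    )
    expect_error(acquisitionSchedule(2.0, c(-0.1, 0.5)), "non-negative")
    expect_error(acquisitionSchedule(0, 0.5), "positive")
    for (nm in c("grey_paper", "hcp_asl")) {
        path <- system.file("extdata", "schedules", paste0(nm, ".yaml"),
            package = "ssvb"
        )
        cfg <- readScheduleConfig(path)
        ref <- schedulePreset(nm)
        expect_equal(cfg$schedule@labelDuration, ref@labelDuration)
        expect_equal(cfg$schedule@plds, ref@plds)
        expect_equal(cfg$schedule@repeats, ref@repeats)
        expect_equal(cfg$constants@t1Tissue, 1.3)
    }
})
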