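mkFit <- function(cbf, att, name = "echo") {
    v <- length(cbf)
    new("FitResult",
        cbfMap = cbf, attMap = att, cbfSdMap = rep(1, v),
        attSdMap = rep(0.1, v), noiseVarMap = rep(1, v),
        costTrace = 0, fitterName = name, epochsRun = 0L, reversions = 0L,
        metadata = list()
    )
}

test_that("percentage bias follows the mean-then-bias definition", {
    f <- mkFit(rep(60, 4), rep(1.5, 4))
    b <- computeBias(f, list(cbf = 60, att = 1.5))
    expect_equal(b$biasPct, c(0, 0))
    # uniform 0.44 against truth 0.5 is -12%
    b2 <- computeBias(mkFit(rep(60, 3), rep(0.44, 3)), list(cbf = 60, att = 0.5))
    expect_equal(b2$biasPct[b2$parameter == "att"], -12)
    # mean first, then bias: (50, 70) vs 60 cancels
    b3 <- computeBias(mkFit(c(50, 70), c(1, 1)), list(cbf = 60, att = 1))
    expect_equal(b3$biasPct[b3$parameter == "cbf"], 0)
})

test_that("NaN voxels are excluded and counted; all-NaN maps error", {
    f <- mkFit(c(60, NaN, 60), c(1, 1, NaN))
    b <- computeBias(f, list(cbf = 60, att = 1))
    expect_equal(b$nExcluded, c(1, 1))
    expect_equal(b$biasPct, c(0, 0))
    expect_error(
        computeBias(
            mkFit(rep(NaN, 2), rep(1, 2)),
            list(cbf = 60, att = 1)
        ),
        "all voxels"
    )
})

test_that("the bias table enumerates the factorial and flags missing cells", {
    suite <- simulateSuite("grey_paper",
        gridShape = c(2, 2, 1),
        trueATTValues = c(1.0, 2.0), noiseSds = c(10, 20), seed = 2
    )
    echo <- lapply(suite, function(d) {
        gt <- groundTruth(d)
        mkFit(gt$cbf, gt$att)
    })
    wrong <- lapply(suite, function(d) mkFit(rep(66, 4), rep(1.1, 4), "off"))
    tab <- biasTable(list(echo = echo, off = wrong), suite)
    expect_equal(nrow(tab), 2 * 4 * 2) # 2 fitters x 4 datasets x 2 parameters
    expect_true(all(tab$biasPct[tab$fitter == "echo"] == 0))
    s <- biasSummary(tab)
    expect_true(all(s$meanBiasPct[s$fitter == "echo"] == 0))
    expect_equal(s$nNoiseLevels, rep(2L, nrow(s)))
    # summary means equal the mean of per-noise rows
    row <- s[s$fitter == "off" & s$trueATT == 1 & s$parameter == "cbf", ]
    cells <- tab[tab$fitter == "off" & tab$trueATT == 1 & tab$parameter == "cbf", ]
    expect_equal(row$meanBiasPct, mean(cells$biasPct))
    expect_equal(row$minBiasPct, min(cells$biasPct))
    # missing cells are an error
    broken <- wrong
    broken[2] <- list(NULL)
    expect_error(biasTable(list(off = broken), suite), "missing fits")
})

test_that("evaluation is a pure function of maps and truth", {
    suite <- simulateSuite("grey_paper",
        gridShape = c(2, 2, 1),
        trueATTValues = 1.5, noiseSds = c(10, 20), seed = 4
    )
    fits <- list(wd = lapply(suite, fitWD))
    t1 <- biasTable(fits, suite)
    t2 <- biasTable(fits, suite)
    expect_identical(t1, t2)
})

test_that("bias curve plotting produces one panel per schedule and parameter", {
    expect_error(plotBiasCurves(data.frame()), "empty")
    suite <- simulateSuite("grey_paper",
        gridShape = c(2, 2, 1),
        trueATTValues = c(1, 2), noiseSds = c(10, 20), seed = 5
    )
    echo <- lapply(suite, function(d) {
        gt <- groundTruth(d)
        mkFit(gt$cbf, gt$att)
    })
    tab <- biasTable(list(echo = echo), suite)
    out <- tempfile()
    plots <- plotBiasCurves(tab, outDir = out)
    expect_length(plots, 2L) # one schedule x two parameters
    expect_true(all(file.exists(file.path(
        out,
        c("bias_grey_paper_cbf.pdf", "bias_grey_paper_att.pdf")
    ))))
})
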