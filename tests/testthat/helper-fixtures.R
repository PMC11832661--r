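# Shared fixtures: tiny schedules and datasets built in code.

tinySchedule <- function() {
    acquisitionSchedule(2.0, plds = c(0.2, 1.0, 2.0), repeats = 2L, name = "tiny")
}

# Independent evaluation of the three-branch kinetic model, written directly
# from the closed form (no shared code with the package internals); used as
# the oracle for buxtonSignal.
oracleBuxton <- function(t, cbf, att, tau,
                         t1 = 1.3, t1b = 1.65, lambda = 0.9, m0a = 1) {
    t1app <- 1 / (1 / t1 + (cbf / 6000) / lambda)
    vapply(t, function(ti) {
        if (ti < att) {
            0
        } else if (ti < att + tau) {
            2 * m0a * cbf * t1app * exp(-att / t1b) *
                (1 - exp(-(ti - att) / t1app))
        } else {
            2 * m0a * cbf * t1app * exp(-att / t1b) *
                exp(-(ti - att - tau) / t1app) * (1 - exp(-tau / t1app))
        }
    }, numeric(1))
}

# Explicit 6-connectivity edge list of a mask, independent of buildLaplacian.
oracleEdges <- function(mask) {
    idx <- array(0L, dim = dim(mask))
    idx[mask] <- seq_len(sum(mask))
    edges <- NULL
    dims <- dim(mask)
    for (x in seq_len(dims[1])) {
        for (y in seq_len(dims[2])) {
            for (z in seq_len(dims[3])) {
                if (!mask[x, y, z]) next
                for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
                    nx <- x + d[1]
                    ny <- y + d[2]
                    nz <- z + d[3]
                    if (nx <= dims[1] && ny <= dims[2] && nz <= dims[3] &&
                        mask[nx, ny, nz]) {
                        edges <- rbind(edges, c(idx[x, y, z], idx[nx, ny, nz]))
                    }
                }
            }
        }
    }
    edges
}
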