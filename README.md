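# ssvb

Estimation of cerebral blood flow (CBF) and arterial transit time (ATT)
from multiple post-label-delay arterial spin labelling (ASL) MRI, using
stochastic variational Bayes, for researchers quantifying perfusion from
multi-delay PCASL difference data or benchmarking perfusion fitters on
simulated data.

## The method

Multi-delay ASL samples the label-control difference signal ΔM(t) at
several post-label delays. The signal follows the single-compartment PCASL
kinetic model: zero before the labelled blood arrives (t < Δt), an inflow
branch while the bolus of duration τ is arriving, and an exponential
outflow branch afterwards, with amplitude proportional to perfusion f and
all post-arrival branches damped by the label decay e^(−Δt/T1b). The
difficulty is the very low SNR of ASL combined with this non-linearity.

SSVB performs variational Bayesian inference by direct stochastic
maximisation of the free energy (ELBO)

    F = E_q[ log p(y|θ) + log p(θ) − log q(θ) ],

estimated with L reparameterised Monte-Carlo samples θ* = μ + σ·ε of the
per-voxel diagonal-Gaussian posterior over (CBF, ATT), and optimised by
RMSProp with analytic gradients. Adaptive spatial regularisation comes
from a first-order graph-Laplacian prior on each parameter map,

    log p(θ) = (v/2)·log α − (α/2)·Σ_{i~j} (θ_i − θ_j)²,

whose precision α is itself optimised, so the amount of smoothing is
determined by the data. Convergence uses a revert-and-grow schedule: after
50 epochs without a cost decrease the state reverts to the best snapshot
and the Monte-Carlo sample size grows by one, terminating after five such
reversions.

The package also provides the two classical comparators (unconstrained
voxelwise non-linear least squares via Levenberg-Marquardt, and
signal-weighted-delay ATT estimation with a fixed-ATT linear CBF solve), a
simulator for two shipped acquisition schedules with known ground truth,
and an evaluation harness reporting percentage bias against truth. See the
methods vignette (`vignettes/ssvb-methods.Rmd`) for the full model.

## Worked example

Simulate one 5x5x5 dataset on the grey-matter-optimised schedule (label
duration 2.05 s, 9 PLDs, 4 repeats), true CBF 60, true ATT 1.5 s, noise SD
20, then fit it:

```r
library(ssvb)
d <- simulateDataset("grey_paper", trueATT = 1.5, noiseSd = 20, seed = 7)
fit <- fitSSVB(d, config = ssvbConfig(rngSeed = 7))
fit
#> FitResult [ssvb]: 125 voxels (0 failed)
#>   CBF: mean 59.18   ATT: mean 1.488 s
#>   831 epochs, 5 reversions, best cost 16147
computeBias(fit, list(cbf = 60, att = 1.5))
#>   parameter truth meanEstimate biasPct nExcluded
#> 1       cbf  60.0        59.18  -1.365         0
#> 2       att   1.5         1.49  -0.803         0
```

At SNR ≈ 2 the posterior means recover both parameters to within ~1.5%.
The weighted-delay comparator on the same data is less accurate:

```r
computeBias(fitWD(d), list(cbf = 60, att = 1.5))
#>   parameter truth meanEstimate biasPct nExcluded
#> 1       cbf  60.0        57.05   -4.91         0
#> 2       att   1.5         1.42   -5.59         0
```

`runBiasBenchmark()` runs the full (true ATT x noise SD) factorial for any
fitter subset and returns the long bias table plus noise-averaged
summaries; `plotBiasCurves()` draws the bias-versus-ATT panels. Real
acquisitions enter through `readASLNifti(data, mask, schedule)` and results
leave through `writeParamMaps()`. A thin command-line wrapper over these
functions is included at `inst/cli/ssvb.R`
(`Rscript inst/cli/ssvb.R simulate|fit|evaluate|report ...`).

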