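# spikevar

Decomposing neural spike-count variability into within-trial spiking
irregularity and between-trial rate variability, in time.

## The problem

The Fano factor (FF) of trial-to-trial spike counts — variance over mean of
the count `N_T` in a window of width `T` — is the standard summary of
neural response variability, and its post-stimulus drop is one of the most
replicated observations in systems neuroscience. But FF mixes two very
different things: the irregularity with which spikes are placed *within* a
trial (a property of spike generation), and variation of the underlying
firing rate *between* trials (a property of the network state). For a
doubly stochastic renewal process the law of total variance separates them,
and FF becomes asymptotically linear in the window width:

    FF(T) = nΨ + T · nRV

* **nΨ** (normalized spiking irregularity, dimensionless): the expected
  conditional count variance over the mean count; equals the ISI CV² — `1/κ`
  for gamma-distributed ISIs of shape `κ` — for any renewal process, and is
  inflated beyond that by renewal violations such as bursting.
* **nRV** (normalized rate variability, 1/s): the variance of the
  conditional expected count over `T ×` mean count; equals
  `Var(λᵢ)/E[λᵢ]` for per-trial rates `λᵢ` in the renewal limit.

spikevar estimates both as a function of time from trial-indexed spike
trains, for whoever needs to know *which* component of variability their
stimulus, region or manipulation actually changed: the FF-asymptote line
fit (`ffaFit`), a more robust sub-bin conditional-variance estimator
(`vinciNpsi`), the CV2-based point-process variability `cvLocal2` (nPPV,
whose gap to nΨ diagnoses bursting), the comparator `varce` with its known
failure modes, and an empirical ground-truth oracle
(`empiricalDecomposition`) for simulated data. Around the estimators sit
doubly stochastic renewal simulators with time-varying rate and shape
schedules and perturbations (bursting, rate noise, rate switching), an
ISI-threshold burst detector calibrated on spontaneous activity,
population controls (response-polarity classification, mean matching), and
balanced excitatory/inhibitory leaky integrate-and-fire network
experiments that link presynaptic correlation structure to the
postsynaptic decomposition.

## Worked example

Simulate a doubly stochastic gamma unit — per-trial rates
`λᵢ ~ N(20, 5²)` Hz, ISI shape `κ = 2` — and decompose one 1-second window:

```r
library(spikevar)

ens <- sampleDoublyStochastic(
  makeSchedule("constant", list(rateMean = 20, rateSd = 5,
                                shape = 2, duration = 1)),
  nTrials = 800, seed = 11)

decompose(ens, c(0, 1), method = "vinci", seed = 12)
#> DecompositionEstimate (vinci, T = 1 s)
#>   FF = 1.728, nPsi = 0.549, nRV = 1.180 1/s, CVlocal2 = 0.494, rate = 20.26 Hz

theoreticalDecomposition(isiModel("gamma", 2), rateMean = 20, rateVar = 25)
#> $nPsi
#> [1] 0.5
#> $nRV
#> [1] 1.25
```

The window's FF of 1.73 would conventionally be read as "very variable";
the decomposition shows it is a mildly sub-Poisson point process
(nΨ ≈ 0.55 ≈ CVlocal2, so no bursting) whose apparent variability is
mostly the trial-to-trial rate spread (nRV ≈ 1.2/s, close to the
theoretical 25/20 = 1.25/s). `slidingDecomposition()` produces the same
quantities as a time course, `burstTimecourse()` adds bursts-per-spike,
and `runNetworkExperiment()` reproduces the network-mechanism experiments.
A thin command-line front end is installed at `inst/scripts/spikevar`
(subcommands `simulate`, `fixtures`, `decompose`, `bursts`).

The methods vignette (`vignettes/variability-decomposition.Rmd`) documents
the estimator constructions, the benchmark schedules, every default worth
arguing about, and the package's limitations.

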