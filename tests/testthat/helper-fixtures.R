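# Shared synthetic fixtures, built once per test run. Sizes are kept modest:
# the heavyweight checks in test-acceptance.R build their own ensembles.

fx <- new.env(parent = emptyenv())

# Lazily build-and-cache a fixture by name.
fixture <- function(name, builder) {
  if (is.null(fx[[name]])) fx[[name]] <- builder()
  fx[[name]]
}

gamma2_ens <- function() fixture("gamma2", function() {
  sampleDoublyStochastic(
    makeSchedule("constant", list(rateMean = 10, shape = 2, duration = 2)),
    nTrials = 1500, seed = 101)
})

poisson_ens <- function() fixture("poisson", function() {
  sampleDoublyStochastic(
    makeSchedule("constant", list(rateMean = 10, shape = 1, duration = 2)),
    nTrials = 1500, seed = 102)
})

ds_gamma_ens <- function() fixture("ds_gamma", function() {
  # doubly stochastic: lambda_i ~ N(50, 10^2), kappa = 2 -> nRV = 2 /s
  sampleDoublyStochastic(
    makeSchedule("constant",
                 list(rateMean = 50, rateSd = 10, shape = 2, duration = 2)),
    nTrials = 1000, seed = 103)
})

# ensemble from raw homogeneous sampler draws (any ISI family)
renewal_ensemble <- function(model, rate, duration, nTrials, seed) {
  trials <- lapply(seq_len(nTrials), function(i) {
    sampleRenewal(model, rate, duration, seed = seed + i)
  })
  trialEnsemble(trials, c(0, duration), unitId = model@family, seed = seed)
}
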