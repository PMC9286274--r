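test_that("correlated rate draws have the requested structure", {
  r1 <- sampleCorrelatedRates(40, 4, 1, 500, seed = 1)
  expect_equal(r1[, 1], r1[, 2])
  r0 <- sampleCorrelatedRates(40, 4, 0, 1000, seed = 2)
  expect_lt(abs(cor(r0)[1, 2]), 0.1)
  r6 <- sampleCorrelatedRates(40, 4, 0.6, 1000, seed = 3)
  expect_equal(cor(r6)[1, 2], 0.6, tolerance = 0.09)
  expect_true(all(r6 >= 0))
  expect_equal(colMeans(r6), c(lambda_e = 40, lambda_i = 40),
               tolerance = 0.02)
})

test_that("dichotomized-Gaussian trains match rate and pairwise correlation", {
  binned <- function(tr, dur, dt = 1e-3) {
    vapply(tr, function(s) tabulate(floor(s / dt) + 1L, nbins = dur / dt),
           integer(dur / dt))
  }
  # corr 0: independent, rate preserved within 2%
  tr0 <- generateCorrelatedPoisson(20, 40, 0, 30, seed = 4)
  rates <- vapply(tr0, length, 0L) / 30
  expect_equal(mean(rates), 40, tolerance = 0.02)
  c0 <- cor(binned(tr0, 30))
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.05)
  # corr 0.3 recovered in the counts (correlated trains: mean rate is
  # noisier, use a 3-sigma band for the rate)
  tr3 <- generateCorrelatedPoisson(10, 40, 0.3, 60, seed = 5)
  c3 <- cor(binned(tr3, 60))
  expect_equal(mean(c3[upper.tri(c3)]), 0.3, tolerance = 0.1)
  expect_equal(mean(vapply(tr3, length, 0L)) / 60, 40, tolerance = 0.04)
  # corr 1: identical trains
  tr1 <- generateCorrelatedPoisson(4, 40, 1, 2, seed = 6)
  expect_identical(tr1[[1]], tr1[[2]])
  expect_identical(tr1[[1]], tr1[[4]])
  expect_error(generateCorrelatedPoisson(4, 40, -0.2, 1), "feasible")
})

test_that("jitter preserves rate and delay shifts the mean", {
  tr <- generateCorrelatedPoisson(20, 40, 0, 5, seed = 7)
  ident <- applyJitterDelay(tr, 0, 0)
  expect_identical(ident, tr)
  delayed <- applyJitterDelay(tr, 0.002, 0.004, seed = 8)
  shift <- mean(unlist(delayed)) - mean(unlist(tr))
  expect_equal(shift, 0.004, tolerance = 0.2)
  nj <- vapply(applyJitterDelay(tr, 0.002, 0, seed = 9), length, 0L)
  expect_equal(sum(nj), sum(vapply(tr, length, 0L)), tolerance = 0.01)
  expect_true(all(vapply(delayed, function(s) all(diff(s) >= 0), TRUE)))
})

test_that("LIF neuron behaves sanely", {
  # no input, no output
  expect_length(lifSimulate(list(numeric(0)), list(numeric(0)),
                            lifParams(), 1), 0)
  # excitation-only drive: output rate positive and increasing in wE
  e <- replicate(50, sort(runif(40, 0, 1)), simplify = FALSE)
  none <- list(numeric(0))
  r1 <- length(lifSimulate(e, none, lifParams(wE = 6), 1))
  r2 <- length(lifSimulate(e, none, lifParams(wE = 12), 1))
  expect_gt(r1, 0)
  expect_gt(r2, r1)
  # instability guard
  expect_error(lifSimulate(e, none, lifParams(dt = 0.01), 1), "dt")
})

test_that("balanced network rate is roughly flat in rate correlation", {
  rates <- vapply(c(0, 1), function(rho) {
    ens <- simulateNetworkEnsemble(networkSpec(rateCorr = rho), lifParams(),
                                   80, seed = 10 + round(10 * rho))
    mean(vapply(trials(ens), length, 0L))
  }, 0)
  expect_gt(min(rates), 5)
  expect_lt(max(rates), 25)
  expect_lt(abs(diff(rates)) / mean(rates), 0.45)
})

test_that("rate correlation lowers output nRV; deterministic rates lower it further", {
  nrv <- vapply(c(0, 1), function(rho) {
    ens <- simulateNetworkEnsemble(networkSpec(rateCorr = rho), lifParams(),
                                   220, seed = 20 + round(10 * rho))
    suppressWarnings(decompose(ens, c(0.1, 1), nBoot = 40, seed = 21)@nRV)
  }, 0)
  expect_gt(nrv[1], nrv[2] + 3)
  det <- simulateNetworkEnsemble(networkSpec(deterministicRate = TRUE),
                                 lifParams(), 220, seed = 22)
  nrvDet <- suppressWarnings(decompose(det, c(0.1, 1), nBoot = 40,
                                       seed = 23)@nRV)
  expect_lt(nrvDet, nrv[1])
})

test_that("experiment runner validates input and returns the full table", {
  expect_error(runNetworkExperiment("rate_corr", numeric(0)), "non-empty")
  tab <- runNetworkExperiment("rate_corr", c(0, 1), nTrials = 60, seed = 30,
                              nBoot = 20)
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("grid_value", "rate_hz", "n_psi", "n_rv", "cv_local2",
                    "n_psi_sem") %in% names(tab)))
  expect_error(runNetworkExperiment("subpool_sweep", c(3), nTrials = 10,
                                    seed = 31), "divide")
})
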