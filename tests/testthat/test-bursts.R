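burst_pool <- function() fixture("burst_pool", function() {
  lapply(1:20, function(i) sampleDoublyStochastic(
    makeSchedule("constant", list(rateMean = 20, shape = 2, t0 = -0.5,
                                  duration = 1.5)),
    40, seed = 300 + i))
})

test_that("calibration pools spontaneous ISIs and sets a floored threshold", {
  cal <- calibrateBursts(burst_pool(), c(-0.5, 0))
  expect_gte(cal@isiThreshold, 0.004)
  expect_lt(cal@isiThreshold, 0.05)   # 5th centile of gamma(2) at 20 Hz
  expect_gte(cal@baselineBps, 0)
  expect_lt(cal@baselineBps, 0.05)    # chance runs are rare for renewal
  expect_error(calibrateBursts(list(trialEnsemble(list(c(0.1, 0.2)),
                                                  c(0, 1))), c(0, 1)),
               "100")
})

test_that("baseline bursts/spike is stable across calibration seeds", {
  bps <- vapply(c(1, 2, 3), function(s) {
    pool <- lapply(1:10, function(i) sampleDoublyStochastic(
      makeSchedule("constant", list(rateMean = 20, shape = 2, t0 = -0.5,
                                    duration = 0.5)),
      60, seed = 1000 * s + i))
    calibrateBursts(pool, c(-0.5, 0))@baselineBps
  }, 0)
  expect_lt(diff(range(bps)), 0.02)
})

test_that("detection follows the threshold-run rule deterministically", {
  cal <- new("BurstCalibration", isiThreshold = 0.005, minRun = 3L,
             baselineBps = 0)
  # 5 spikes at 3 ms: exactly one burst of 5
  b <- detectBursts(0.1 + 0.003 * (0:4), cal)
  expect_identical(nrow(b), 1L)
  expect_identical(b$n_spikes, 5L)
  expect_equal(b$start_s, 0.1)
  # periodic 50 ms train: never a burst
  cal50 <- calibrateBursts(burst_pool(), c(-0.5, 0))
  expect_identical(nrow(detectBursts(seq(0, 2, by = 0.05), cal50)), 0L)
  # two spikes below minRun are not a burst
  expect_identical(nrow(detectBursts(c(0.1, 0.103), cal)), 0L)
  # determinism
  s <- sort(runif(200, 0, 2))
  expect_identical(detectBursts(s, cal), detectBursts(s, cal))
})

test_that("detected bursts/spike rises monotonically with injected level", {
  cal <- calibrateBursts(burst_pool(), c(-0.5, 0))
  levels <- c(0, 0.02, 0.05, 0.1, 0.2)
  sch <- makeSchedule("constant", list(rateMean = 20, shape = 2, duration = 2))
  detected <- vapply(seq_along(levels), function(j) {
    pert <- if (levels[j] > 0)
      perturbationSpec(burst = list(pBurst = levels[j], nSpikes = 5L,
                                    intraIsi = 0.003)) else NULL
    ens <- sampleDoublyStochastic(sch, 60, perturbations = pert,
                                  seed = 400 + j)
    nb <- sum(vapply(trials(ens), function(s) {
      nrow(detectBursts(s, cal))
    }, 0L))
    nb / sum(vapply(trials(ens), length, 0L))
  }, 0)
  expect_true(all(diff(detected) > 0))
  expect_lt(detected[1], 0.02)
})

test_that("burst time course localizes an injection epoch and is flat without one", {
  cal <- calibrateBursts(burst_pool(), c(-0.5, 0))
  # bursts only in [0, 0.5): inject on the full train, then keep the
  # injected spikes only inside the epoch
  sch <- makeSchedule("constant", list(rateMean = 20, shape = 2, t0 = -0.5,
                                       duration = 1.5))
  base <- sampleDoublyStochastic(sch, 120, seed = 50)
  injected <- trialEnsemble(lapply(trials(base), function(s) {
    inside <- s[s >= 0 & s < 0.5]
    keep <- s[s < 0 | s >= 0.5]
    bb <- injectBursts(inside, 0.3, 4L, 0.003, window = c(0, 0.5))
    sort(c(keep, as.numeric(bb)))
  }), ensembleWindow(base))
  tc <- burstTimecourse(injected, cal, bin = 0.25, step = 0.25)
  inEpoch <- tc$center_s > 0 & tc$center_s < 0.5
  expect_gt(min(tc$bursts_per_spike[inEpoch]),
            max(tc$bursts_per_spike[!inEpoch]))
  # no injection: flat within 4 sigma of the grand mean
  tc0 <- burstTimecourse(base, cal, bin = 0.25, step = 0.25)
  dev <- abs(tc0$bursts_per_spike - mean(tc0$bursts_per_spike))
  expect_true(all(dev <= 4 * pmax(tc0$bursts_per_spike_sem, 1e-3)))
})

test_that("windows of elevated bursting coincide with nPsi exceeding nPPV", {
  cal <- calibrateBursts(burst_pool(), c(-0.5, 0))
  sch <- makeSchedule("constant", list(rateMean = 20, shape = 2, t0 = -0.5,
                                       duration = 1.5))
  base <- sampleDoublyStochastic(sch, 400, seed = 60)
  injected <- trialEnsemble(lapply(trials(base), function(s) {
    inside <- s[s >= 0 & s < 0.5]
    keep <- s[s < 0 | s >= 0.5]
    bb <- injectBursts(inside, 0.15, 5L, 0.003, window = c(0, 0.5))
    sort(c(keep, as.numeric(bb)))
  }), ensembleWindow(base))
  tc <- suppressWarnings(slidingDecomposition(injected, bin = 0.5,
    step = 0.25, nBoot = 30, seed = 61))
  tab <- as.data.frame(tc)
  bt <- burstTimecourse(injected, cal, bin = 0.5, step = 0.25)
  excess <- tab$n_psi - tab$cv_local2
  hot <- which.max(bt$bursts_per_spike)
  expect_identical(which.max(excess), hot)
  expect_gt(excess[hot], max(excess[-hot]) + 0.05)
})
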