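test_that("homogeneous renewal samplers reproduce the ISI family moments", {
  cases <- list(
    list(model = isiModel("exponential"), rate = 10, cv2 = 1),
    list(model = isiModel("gamma", 2), rate = 10, cv2 = 0.5),
    # inverse Gaussian: CV^2 = mean ISI / shape = (1/10) / 0.05 = 2
    list(model = isiModel("inverse_gaussian", 0.05), rate = 10, cv2 = 2))
  for (cs in cases) {
    isis <- unlist(lapply(1:40, function(i) {
      diff(sampleRenewal(cs$model, cs$rate, 50, seed = 500 + i))
    }))
    expect_gt(length(isis), 1e4)
    expect_equal(mean(isis), 1 / cs$rate, tolerance = 0.03)
    cv2 <- var(isis) / mean(isis)^2
    expect_equal(cv2, cs$cv2, tolerance = 0.08)
  }
})

test_that("exponential family is indistinguishable from gamma shape 1", {
  a <- unlist(lapply(1:20, function(i) {
    diff(sampleRenewal(isiModel("exponential"), 20, 20, seed = i))
  }))
  b <- unlist(lapply(1:20, function(i) {
    diff(sampleRenewal(isiModel("gamma", 1), 20, 20, seed = 1000 + i))
  }))
  expect_gt(suppressWarnings(stats::ks.test(a, b))$p.value, 0.01)
})

test_that("samplers reject non-positive rate and duration", {
  expect_error(sampleRenewal(isiModel("gamma", 2), -1, 1), "rate")
  expect_error(sampleRenewal(isiModel("gamma", 2), 10, 0), "duration")
  expect_error(sampleInhomogeneousRenewal(function(t) rep(NA_real_, length(t)),
                                          function(t) rep(1, length(t)),
                                          c(0, 1)), "undefined")
})

test_that("homogeneous counts are equilibrated: early and late windows match", {
  n <- 10000
  counts <- t(vapply(seq_len(n), function(i) {
    s <- sampleRenewal(isiModel("gamma", 2), 20, 1, seed = 20000 + i)
    c(early = sum(s < 0.3), late = sum(s >= 0.6 & s < 0.9))
  }, c(early = 0, late = 0)))
  expect_equal(mean(counts[, 1]), mean(counts[, 2]), tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(counts[, 1], counts[, 2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("constant schedules reduce the inhomogeneous sampler to the homogeneous one", {
  isis_i <- unlist(lapply(1:60, function(i) {
    diff(sampleInhomogeneousRenewal(function(t) rep(50, length(t)),
                                    function(t) rep(2, length(t)),
                                    c(0, 40), seed = i))
  }))
  expect_gt(length(isis_i), 1e5)
  mu <- mean(isis_i)
  cv2 <- var(isis_i) / mu^2
  # Monte-Carlo 3 sigma bands around the homogeneous gamma(2) truth
  se_mu <- sd(isis_i) / sqrt(length(isis_i))
  expect_lt(abs(mu - 1 / 50), 3 * se_mu + 2e-5)
  expect_equal(cv2, 0.5, tolerance = 0.03)
})

test_that("inhomogeneous sampling matches the integrated rate", {
  # ramp 10 -> 90 Hz over 1 s: expected count = 50
  n <- 400
  cnt <- vapply(seq_len(n), function(i) {
    length(sampleInhomogeneousRenewal(function(t) 10 + 80 * t,
                                      function(t) rep(2, length(t)),
                                      c(0, 1), seed = 3000 + i))
  }, 0L)
  expect_equal(mean(cnt), 50, tolerance = 3 * sd(cnt) / sqrt(n) / 50 + 0.02)
  # benchmark schedule with n_i = 0 is flat 50 Hz
  sch <- makeSchedule("benchmark")
  cnt2 <- vapply(seq_len(200), function(i) {
    length(sampleInhomogeneousRenewal(function(t) sch@rateFn(t, list(n_i = 0)),
                                      sch@shapeFn, c(-0.5, 1), seed = 4000 + i))
  }, 0L)
  expect_equal(mean(cnt2), 50 * 1.5, tolerance = 0.03)
})

test_that("burst injection replaces spikes as specified", {
  s <- sort(runif(40, 0, 0.9))
  expect_identical(as.numeric(injectBursts(s, 0, 5, 0.003, seed = 1)), s)
  full <- injectBursts(s, 1, 5, 0.003, window = c(0, 1), seed = 1)
  expect_length(full, 5 * length(s))
  expect_true(all(diff(full) > 0))
  # spikes pushed past the window end are dropped
  tail_spike <- injectBursts(0.999, 1, 5, 0.003, window = c(0, 1), seed = 1)
  expect_length(tail_spike, 1)
})

test_that("burst accounting: expected count m(1 + p(n-1)) within 3 sigma", {
  p <- 0.2; nsp <- 5L; m <- 200L
  reps <- vapply(1:300, function(i) {
    s <- seq(0.01, 2, length.out = m)
    length(injectBursts(s, p, nsp, 0.003, window = c(0, 2.1), seed = 7000 + i))
  }, 0L)
  expected <- m * (1 + p * (nsp - 1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 3 * se + 0.5)
})

test_that("benchmark schedule has the documented modulation and shape steps", {
  sch <- makeSchedule("benchmark")
  m <- function(t) sch@rateFn(t, list(n_i = 1)) - 50
  expect_equal(m(0), 2)           # 1 - 0 + exp(0)
  expect_equal(m(-0.3), 2)        # t_+ = 0 before alignment
  expect_equal(m(0.7), 0)         # clamped at zero mid-trial
  expect_equal(m(1.4), 2)         # mirrored late recovery
  expect_equal(sch@shapeFn(c(-0.2, 0.3, 0.8)), c(0.5, 4, 0.5))
  # rate clamped at 0 for strongly negative draws
  expect_true(all(sch@rateFn(seq(-0.5, 1, 0.01), list(n_i = -100)) >= 0))
  expect_error(makeSchedule("nope"), "arg")
})

test_that("every stochastic per-trial draw is recorded as ground truth", {
  sch <- makeSchedule("constant",
                      list(rateMean = 20, rateSd = 5, shape = 2, duration = 1))
  pert <- perturbationSpec(
    burst = list(pBurst = 0.1, nSpikes = 3L, intraIsi = 0.003),
    rateNoise = list(sd = 3, dt = 0.05))
  ens <- sampleDoublyStochastic(sch, 30, perturbations = pert, seed = 11)
  gt <- groundTruth(ens)
  expect_length(gt, 30)
  for (d in gt) {
    expect_true(is.numeric(d$lambda))
    expect_length(d$pert_noise_hz, 20)      # 1 s / 50 ms
    expect_true(is.numeric(d$burst_replaced) || is.integer(d$burst_replaced))
  }
  # switching draws are recorded too
  ens2 <- sampleDoublyStochastic(makeSchedule("rate_switching",
    list(rateMean = 10, duration = 1)), 5, seed = 12)
  expect_true(all(vapply(groundTruth(ens2),
                         function(d) is.logical(d$start_high), TRUE)))
})

test_that("identical seeds reproduce identical ensembles", {
  sch <- makeSchedule("constant", list(rateMean = 20, rateSd = 5, duration = 1))
  a <- sampleDoublyStochastic(sch, 20, seed = 5)
  b <- sampleDoublyStochastic(sch, 20, seed = 5)
  expect_identical(trials(a), trials(b))
  expect_identical(groundTruth(a), groundTruth(b))
})

test_that("TrialEnsemble validity catches malformed inputs", {
  expect_error(trialEnsemble(list(c(0.2, 0.1)), c(0, 1)), "increasing")
  expect_error(trialEnsemble(list(c(0.2, 1.5)), c(0, 1)), "window")
  expect_error(trialEnsemble(list(0.5), c(0, 1),
                             groundTruth = list(list(), list())), "per trial")
  ok <- trialEnsemble(list(numeric(0), 0.5), c(0, 1))
  expect_identical(nTrials(ok), 2L)
})
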