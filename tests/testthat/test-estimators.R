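test_that("spike counts use half-open windows and allow empty trials", {
  ens <- trialEnsemble(list(c(0.1, 0.2), numeric(0)), c(0, 1))
  cm <- spikeCounts(ens, rbind(c(0.1, 0.2), c(0.2, 0.3)))
  expect_identical(cm[1, ], c(1L, 1L))  # 0.1 in, 0.2 out of first window
  expect_identical(cm[2, ], c(0L, 0L))
  expect_error(spikeCounts(ens, rbind(c(0.5, 1.5))), "inside")
})

test_that("Poisson counts have matching mean and variance", {
  ens <- poisson_ens()
  cm <- spikeCounts(ens, rbind(c(0, 1)))
  expect_equal(mean(cm), 10, tolerance = 0.05)
  expect_equal(var(as.numeric(cm)) / mean(cm), 1, tolerance = 0.12)
})

test_that("Fano curve: Poisson at 1, gamma at 1/kappa, doubly stochastic linear", {
  Tg <- seq(0.25, 2, by = 0.25)
  fp <- fanoVsBinsize(poisson_ens(), 0, Tg, nBoot = 100, seed = 1)
  expect_true(all(abs(fp@ff - 1) < 5 * fp@ffSem + 0.05))
  fg <- fanoVsBinsize(gamma2_ens(), 0, Tg, nBoot = 100, seed = 1)
  big <- Tg >= 1
  expect_equal(mean(fg@ff[big]), 0.5, tolerance = 0.1)
  # doubly stochastic lambda_i ~ N(50, 10^2): asymptotic slope Var/E = 2 /s
  fd <- fanoVsBinsize(ds_gamma_ens(), 0, Tg, nBoot = 100, seed = 1)
  slope <- coef(lm(fd@ff[big] ~ Tg[big]))[2]
  expect_equal(unname(slope), 2, tolerance = 0.25)
  expect_true(all(diff(fd@meanCount) > 0))
})

test_that("FFA fit separates intercept and slope", {
  Tg <- seq(0.25, 2, by = 0.25)
  est <- suppressWarnings(
    ffaFit(fanoVsBinsize(gamma2_ens(), 0, Tg, nBoot = 100, seed = 2)))
  expect_equal(est@nPsi, 0.5, tolerance = 0.1)
  expect_lt(est@nRV, 0.15)
  estd <- ffaFit(fanoVsBinsize(ds_gamma_ens(), 0, Tg, nBoot = 100, seed = 3))
  expect_equal(estd@nRV, 2, tolerance = 0.25)
  # identical counts in every trial: zero variance, zero line
  flat <- trialEnsemble(rep(list(seq(0.05, 1.95, by = 0.1)), 30), c(0, 2))
  estf <- suppressWarnings(ffaFit(fanoVsBinsize(flat, 0, Tg, nBoot = 50,
                                                seed = 4)))
  expect_equal(estf@nPsi, 0)
  expect_equal(estf@nRV, 0)
  # too few usable points -> flagged unavailable
  low <- sampleDoublyStochastic(makeSchedule("constant",
    list(rateMean = 1, duration = 2)), 50, seed = 5)
  expect_warning(ffaFit(fanoVsBinsize(low, 0, Tg, nBoot = 20, seed = 6)),
                 "usable")
})

test_that("CV2 sequence follows its definition", {
  expect_equal(cv2Sequence(seq(0, 1, by = 0.05), c(0, 1.01)),
               rep(0, 19))                        # periodic -> all zero
  expect_equal(cv2Sequence(c(0.1, 0.11, 0.14), c(0, 1)), 1)  # 2*20/40
  expect_length(cv2Sequence(c(0.1, 0.2), c(0, 1)), 0)
  # only ISI pairs fully inside the window are used
  expect_length(cv2Sequence(c(0.1, 0.2, 0.3, 0.4), c(0.15, 0.35)), 0)
})

test_that("CVlocal2 recovers 1/kappa via the gamma calibration", {
  expect_equal(as.numeric(cvLocal2(poisson_ens())), 1, tolerance = 0.05)
  expect_equal(as.numeric(cvLocal2(gamma2_ens())), 0.5, tolerance = 0.05)
  # robust to a within-trial rate ramp at matched kappa
  ramp <- trialEnsemble(lapply(1:300, function(i) {
    sampleInhomogeneousRenewal(function(t) 20 + 60 * t,
                               function(t) rep(2, length(t)), c(0, 1),
                               seed = 9000 + i)
  }), c(0, 1))
  expect_equal(as.numeric(cvLocal2(ramp)), 0.5, tolerance = 0.07)
  expect_warning(cvLocal2(trialEnsemble(list(c(.1, .2, .3)), c(0, 1))),
                 "CV2 pairs")
})

test_that("sub-bin nPsi estimator is blind to rate variability, sensitive to bursts", {
  v <- vinciNpsi(ds_gamma_ens(), c(0, 1))
  expect_equal(v$nPsi, 0.5, tolerance = 0.1)
  expect_equal(v$evc, v$nPsi * v$meanCount)
  # bursting inflates nPsi beyond the CV2-based nPPV
  sch <- makeSchedule("constant", list(rateMean = 10, shape = 2, duration = 2))
  burst <- sampleDoublyStochastic(sch, 600,
    perturbations = perturbationSpec(burst = list(pBurst = 0.05,
      nSpikes = 5L, intraIsi = 0.003)), seed = 21)
  nb <- vinciNpsi(burst, c(0, 2))$nPsi
  expect_gt(nb, vinciNpsi(gamma2_ens(), c(0, 2))$nPsi)
  expect_gt(nb, as.numeric(cvLocal2(burst)))
  # insufficient counts flagged missing
  tiny <- sampleDoublyStochastic(makeSchedule("constant",
    list(rateMean = 1, duration = 2)), 50, seed = 22)
  expect_warning(res <- vinciNpsi(tiny, c(0, 1)), "missing")
  expect_true(is.na(res$nPsi))
})

test_that("nRV follows the decomposition identity and floors at zero", {
  expect_equal(nrvFromFano(1, 1, 0.3), 0)
  expect_equal(nrvFromFano(1.1, 0.5, 0.3), 2)
  expect_warning(out <- nrvFromFano(0.4, 0.7, 0.3), "floored")
  expect_equal(out, 0)
  est <- decompose(ds_gamma_ens(), c(0, 1), nBoot = 50, seed = 31)
  expect_equal(est@ff, est@nPsi + est@binWidth * est@nRV, tolerance = 1e-10)
  expect_equal(est@nRV, 2, tolerance = 0.25)
})

test_that("empirical oracle implements the law of total variance", {
  # no parameter variability -> VEC ~ 0
  fixed <- empiricalDecomposition(makeSchedule("constant",
    list(rateMean = 10, shape = 2, duration = 1)), R = 80, K = 40, T = 1,
    seed = 41)
  expect_lt(fixed$vec, 0.1 * fixed$evc)
  # Poisson with lambda_i ~ N(50, 10^2): nPsi ~ 1, nRV ~ 2 /s
  ds <- empiricalDecomposition(makeSchedule("constant",
    list(rateMean = 50, rateSd = 10, shape = 1, duration = 1)),
    R = 100, K = 150, T = 1, seed = 42)
  expect_equal(ds$n_psi, 1, tolerance = 0.1)
  expect_equal(ds$n_rv, 2, tolerance = 0.35)
  # law of total variance: EVC + VEC matches the pooled count variance
  sch <- makeSchedule("constant",
    list(rateMean = 20, rateSd = 5, shape = 2, duration = 1))
  pooled <- sampleDoublyStochastic(sch, 4000, seed = 44)
  totVar <- var(vapply(trials(pooled), length, 0L))
  emp <- empiricalDecomposition(sch, R = 60, K = 400, T = 1, seed = 45)
  expect_equal(emp$evc + emp$vec, totVar, tolerance = 0.15)
})

test_that("closed-form renewal limits", {
  expect_equal(theoreticalDecomposition(isiModel("gamma", 2), 50, 100),
               list(nPsi = 0.5, nRV = 2))
  expect_equal(theoreticalDecomposition(isiModel("gamma", 4), 10)$nRV, 0)
  expect_equal(theoreticalDecomposition(isiModel("exponential"), 10)$nPsi, 1)
  # IG CV^2 depends on the rate: mu / shape = (1/10)/0.05 = 2
  expect_equal(
    theoreticalDecomposition(isiModel("inverse_gaussian", 0.05), 10)$nPsi, 2)
})

test_that("renewal universality: nPsi equals the ISI CV^2 for all families", {
  cases <- list(list(m = isiModel("exponential"), cv2 = 1),
                list(m = isiModel("gamma", 2), cv2 = 0.5),
                list(m = isiModel("inverse_gaussian", 0.2), cv2 = 0.5))
  for (cs in cases) {
    est <- mean(vapply(1:4, function(r) {
      ens <- renewal_ensemble(cs$m, 10, 2, 2000, seed = 50 + 4000 * r)
      vinciNpsi(ens, c(0, 2))$nPsi
    }, 0))
    expect_equal(est, cs$cv2, tolerance = 0.05,
                 label = sprintf("nPsi (%s)", cs$m@family))
  }
})

test_that("nPsi is robust to within-bin rate modulation at matched kappa", {
  mods <- list(ramp = function(t) 20 + 60 * t,
               peak = function(t) 20 + 60 * exp(-((t - 0.5) / 0.15)^2),
               step = function(t) ifelse(t < 0.5, 20, 60))
  for (nm in names(mods)) {
    ens <- trialEnsemble(lapply(1:800, function(i) {
      sampleInhomogeneousRenewal(mods[[nm]], function(t) rep(2, length(t)),
                                 c(0, 1), seed = 60000 + i)
    }), c(0, 1))
    expect_equal(vinciNpsi(ens, c(0, 1))$nPsi, 0.5, tolerance = 0.1,
                 label = sprintf("nPsi (%s modulation)", nm))
  }
})

test_that("estimator bias shrinks with trials and counts along the grid", {
  grid <- expand.grid(nt = c(50, 200, 1000), rate = c(3, 10, 30))
  bias <- mapply(function(nt, rate) {
    errs <- vapply(1:4, function(r) {
      ens <- sampleDoublyStochastic(makeSchedule("constant",
        list(rateMean = rate, rateSd = rate / 5, shape = 2, duration = 1)),
        nt, seed = 70 + 10 * r)
      suppressWarnings(vinciNpsi(ens, c(0, 1), minCount = 2)$nPsi) - 0.5
    }, 0)
    mean(abs(errs))
  }, grid$nt, grid$rate)
  hardest <- bias[grid$nt == 50 & grid$rate == 3]
  easiest <- bias[grid$nt == 1000 & grid$rate == 30]
  expect_lt(easiest, hardest)
  expect_lt(easiest, 0.05)
})

test_that("VarCE uses the smallest Fano factor and hits zero", {
  ens <- ds_gamma_ens()
  w <- cbind(seq(0, 1.5, by = 0.5), seq(0.5, 2, by = 0.5))
  res <- varce(ens, w)
  expect_equal(min(res$varce), 0)
  expect_equal(res$phi, min(res$ff))
  expect_true(all(res$varce >= 0))
  # single window: phi = its own FF, VarCE = 0
  single <- varce(ens, rbind(c(0, 1)))
  expect_equal(single$varce, 0)
})

test_that("sliding decomposition is flat for stationary Poisson and flags sparse bins", {
  tc <- suppressWarnings(slidingDecomposition(poisson_ens(), bin = 0.5,
    step = 0.25, nBoot = 60, seed = 80))
  tab <- as.data.frame(tc)
  expect_equal(diff(tab$center_s), rep(0.25, nrow(tab) - 1))
  expect_false(any(tab$missing))
  expect_true(all(abs(tab$ff - 1) < 5 * tab$ff_sem + 0.05))
  expect_true(all(tab$n_rv < 0.6))
  expect_equal(mean(tab$mean_rate_hz), 10, tolerance = 0.05)
  # sparse ensemble: all centers flagged missing
  sparse <- sampleDoublyStochastic(makeSchedule("constant",
    list(rateMean = 2, duration = 2)), 40, seed = 81)
  tcs <- suppressWarnings(slidingDecomposition(sparse, bin = 0.5, step = 0.5,
    nBoot = 10, seed = 82))
  expect_true(all(as.data.frame(tcs)$missing))
})
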