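#' Construct an ISI model
#'
#' @param family \code{"exponential"}, \code{"gamma"} or
#'   \code{"inverse_gaussian"}.
#' @param shape positive shape parameter (gamma \eqn{\kappa}, or the inverse
#'   Gaussian shape); ignored for \code{"exponential"}.
#' @return an [ISIModel-class].
#' @examples
#' isiModel("gamma", shape = 2)
#' @export
isiModel <- function(family = c("gamma", "exponential", "inverse_gaussian"),
                     shape = 1) {
  family <- match.arg(family)
  new("ISIModel", family = family, shape = as.numeric(shape))
}

#' Construct a trial ensemble
#'
#' @param trials list of strictly increasing spike-time vectors (seconds).
#' @param window half-open observation window, numeric(2).
#' @param groundTruth optional list of per-trial draws.
#' @param unitId unit identifier.
#' @param seed seed the ensemble was generated with (for provenance).
#' @return a [TrialEnsemble-class].
#' @export
trialEnsemble <- function(trials, window, groundTruth = list(),
                          unitId = "unit", seed = NA_integer_) {
  new("TrialEnsemble", trials = lapply(trials, as.numeric),
      window = as.numeric(window), groundTruth = groundTruth,
      unitId = as.character(unitId),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# Inverse Gaussian sampler (Michael, Schucany & Haas 1976).
rinvgauss <- function(n, mu, lambda) {
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  ifelse(runif(n) <= mu / (mu + x), x, mu^2 / x)
}

# Draw n ISIs from a model at the given rate (mean ISI = 1/rate).
risi <- function(n, model, rate) {
  switch(model@family,
    exponential = rexp(n, rate),
    gamma = rgamma(n, shape = model@shape, scale = 1 / (model@shape * rate)),
    inverse_gaussian = rinvgauss(n, mu = 1 / rate, lambda = model@shape))
}

#' Sample a homogeneous renewal spike train
#'
#' Generates one realization of a stationary (equilibrium) renewal process
#' on \eqn{[0, duration)}. For exponential and gamma ISIs the first spike is
#' drawn from the exact stationary forward-recurrence distribution (a
#' uniform fraction of a length-biased ISI, which for gamma \eqn{\kappa} is
#' gamma \eqn{\kappa + 1}); for inverse Gaussian ISIs, where the residual
#' distribution has no convenient sampler, a burn-in of 10 mean ISIs before
#' the window is used instead. Both give counts whose distribution does not
#' depend on the window position.
#'
#' @param model an [ISIModel-class].
#' @param rate mean firing rate in Hz (> 0).
#' @param duration window length in seconds (> 0).
#' @param seed optional integer seed.
#' @return numeric vector of spike times in \eqn{[0, duration)}.
#' @examples
#' s <- sampleRenewal(isiModel("gamma", 2), rate = 10, duration = 2, seed = 1)
#' @export
sampleRenewal <- function(model, rate, duration, seed = NULL) {
  stopifnot(is(model, "ISIModel"))
  stopifnot_scalar_pos(rate, "rate")
  stopifnot_scalar_pos(duration, "duration")
  with_seed(seed, {
    if (model@family == "inverse_gaussian") {
      # burn-in: start 10 mean ISIs before the window
      first <- -10 / rate + risi(1, model, rate)
    } else {
      # stationary start: forward recurrence = U * length-biased ISI,
      # which for gamma(kappa) is gamma(kappa + 1)
      shape <- if (model@family == "exponential") 1 else model@shape
      lb <- rgamma(1, shape = shape + 1, scale = 1 / (shape * rate))
      first <- runif(1) * lb
    }
    times <- first
    chunk <- max(32L, ceiling(1.3 * rate * (duration - min(first, 0)) + 20))
    while (times[length(times)] < duration) {
      isis <- risi(chunk, model, rate)
      times <- c(times, times[length(times)] + cumsum(isis))
    }
    times[times >= 0 & times < duration]
  })
}

#' Sample an inhomogeneous renewal spike train by time rescaling
#'
#' Generates one realization of a renewal process with time-varying rate
#' \eqn{\lambda(t)} (clamped at 0) and gamma shape \eqn{\kappa(t) > 0} on a
#' half-open window. Unit-mean gamma ISIs are drawn in operational time
#' \eqn{\Lambda(t) = \int \lambda(\tau) d\tau} and mapped back through the
#' inverse of \eqn{\Lambda}; the shape used for each ISI is \eqn{\kappa} at
#' the time of the previous spike. With constant rate and shape this reduces
#' to [sampleRenewal()] with a gamma model. A burn-in of 5 mean ISIs before
#' the window start removes the transient of the non-equilibrium start.
#'
#' @param rateFn function of time returning the rate in Hz (vectorized).
#' @param shapeFn function of time returning \eqn{\kappa(t)} (vectorized).
#' @param window half-open window \eqn{[t_0, t_1)}, numeric(2).
#' @param seed optional integer seed.
#' @param dt rate-integration grid step in seconds (default 1 ms).
#' @return numeric vector of spike times in the window.
#' @examples
#' s <- sampleInhomogeneousRenewal(function(t) 50 * (1 + 0.5 * sin(2 * pi * t)),
#'                                 function(t) rep(2, length(t)),
#'                                 window = c(0, 1), seed = 1)
#' @export
sampleInhomogeneousRenewal <- function(rateFn, shapeFn, window, seed = NULL,
                                       dt = 1e-3) {
  stopifnot(is.function(rateFn), is.function(shapeFn))
  if (length(window) != 2L || diff(window) <= 0)
    stop("window must be numeric(2) with window[1] < window[2]")
  with_seed(seed, {
    probe <- rateFn(seq(window[1], window[2], length.out = 64L))
    if (any(!is.finite(probe)))
      stop("rate schedule is undefined inside the window")
    mean_rate <- mean(pmax(probe, 0))
    if (mean_rate <= 0) return(numeric(0))
    burn <- 5 / mean_rate
    tg <- seq(window[1] - burn, window[2], by = dt)
    lam <- pmax(rateFn(tg), 0)
    kap <- shapeFn(tg)
    if (any(!is.finite(lam)) || any(!is.finite(kap)) || any(kap <= 0))
      stop("rate/shape schedule is undefined or non-positive in the window")
    Lam <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2) * dt)
    Lam <- Lam + seq_along(Lam) * 1e-12  # strictly increasing for inversion
    total <- Lam[length(Lam)]
    op <- 0
    t_cur <- tg[1]
    out <- numeric(0)
    repeat {
      k <- kap[min(length(kap), max(1L, findInterval(t_cur, tg)))]
      op <- op + rgamma(1, shape = k, scale = 1 / k)
      if (op >= total) break
      t_cur <- approx(Lam, tg, xout = op, ties = "ordered")$y
      if (t_cur >= window[2]) break
      if (t_cur >= window[1]) out <- c(out, t_cur)
    }
    out
  })
}

#' Replace spikes by bursts
#'
#' Each input spike is independently replaced, with probability
#' \code{pBurst}, by \code{nSpikes} spikes at \code{intraIsi} spacing
#' starting at the original spike time. The output is re-sorted (overlapping
#' bursts merge); duplicate times are perturbed by a nanosecond to keep
#' trains strictly increasing; spikes pushed past the window end are
#' dropped.
#'
#' @param spikeTimes strictly increasing numeric vector.
#' @param pBurst per-spike replacement probability in \eqn{[0, 1]}.
#' @param nSpikes spikes per burst (integer \eqn{\ge} 2).
#' @param intraIsi intra-burst ISI in seconds (> 0).
#' @param window optional half-open window; added spikes at or past
#'   \code{window[2]} are dropped.
#' @param seed optional integer seed.
#' @return spike-time vector with attribute \code{"replaced"}: the indices
#'   of the input spikes that were turned into bursts.
#' @examples
#' injectBursts(c(0.1, 0.5), pBurst = 1, nSpikes = 3, intraIsi = 0.003)
#' @export
injectBursts <- function(spikeTimes, pBurst, nSpikes, intraIsi,
                         window = NULL, seed = NULL) {
  if (pBurst < 0 || pBurst > 1) stop("pBurst must be in [0, 1]")
  if (nSpikes < 2) stop("nSpikes must be >= 2")
  stopifnot_scalar_pos(intraIsi, "intraIsi")
  with_seed(seed, {
    m <- length(spikeTimes)
    if (m == 0L || pBurst == 0) {
      out <- spikeTimes
      attr(out, "replaced") <- integer(0)
      return(out)
    }
    hit <- which(runif(m) < pBurst)
    extra <- if (length(hit))
      rep(spikeTimes[hit], each = nSpikes - 1L) +
        rep(seq_len(nSpikes - 1L) * intraIsi, times = length(hit))
    else numeric(0)
    out <- sort(c(spikeTimes, extra))
    if (!is.null(window)) out <- out[out < window[2]]
    d <- which(diff(out) <= 0)
    while (length(d)) {  # merged coincident spikes: nudge to keep strict order
      out[d + 1L] <- out[d] + 1e-9
      out <- sort(out)
      d <- which(diff(out) <= 0)
    }
    if (!is.null(window)) out <- out[out < window[2]]
    attr(out, "replaced") <- hit
    out
  })
}

#' Build a rate/shape schedule
#'
#' Constructs the [TrialSchedule-class] objects used by
#' [sampleDoublyStochastic()] and [empiricalDecomposition()].
#'
#' Kinds:
#' \describe{
#'   \item{\code{constant}}{constant rate and shape; per-trial rate drawn
#'     from N(\code{rateMean}, \code{rateSd}^2) clamped at 0 (degenerate
#'     when \code{rateSd = 0}). Params: \code{rateMean}, \code{rateSd}
#'     (default 0), \code{shape} (default 1), \code{duration}, \code{t0}.}
#'   \item{\code{benchmark}}{the doubly stochastic gamma benchmark: rate
#'     \eqn{\lambda_i(t) = 50 + n_i m(t)} with
#'     \eqn{m(t) = (1 - 5 t_+ + e^{-2 t_+})_+}, \eqn{n_i \sim N(0, nSd^2)}
#'     (\code{nSd} default 30; set \code{nIsVariance = TRUE} for the
#'     variance-30 reading), plus a mirrored late-trial recovery of the
#'     rate variability at \code{tRec} (default 1.4 s; \code{NA} disables
#'     it), and \eqn{1/\kappa} stepping 2 \eqn{\to} 0.25 \eqn{\to} 2 at
#'     \code{tOn} (default 0.3 s, after the rate-variability collapse has
#'     completed -- the shape change lags the rate change) and \code{tOff}
#'     (default 0.8 s). \code{modClamp = "whole"} clamps the whole rate
#'     expression instead of the modulation term (both readings end clamped
#'     at 0). Params also: \code{baseRate} (50), \code{t0} (-0.5),
#'     \code{duration} (2), \code{kappaOut} (0.5), \code{kappaIn} (4).}
#'   \item{\code{rate_noise}}{constant base rate plus per-trial
#'     piecewise-constant white noise: independent normal Hz increments per
#'     \code{dt} (default 50 ms) with variance \code{variance} (default
#'     3 Hz^2; pass \code{sd} instead for an sd reading), clamped at 0.
#'     Params also: \code{rateMean}, \code{rateSd}, \code{shape},
#'     \code{duration}, \code{t0}.}
#'   \item{\code{rate_switching}}{alternates between \code{low} and
#'     \code{high} rates (defaults 0.25 and 1.75 times \code{rateMean})
#'     with exponential dwell times of mean \code{dwellMean} (default
#'     10 ms: switching rapid relative to any counting window, the regime
#'     in which single-realization estimators only slightly overestimate
#'     the spiking irregularity); the initial state is equiprobable.}
#'   \item{\code{custom}}{params must supply \code{rateFn(t, draw)},
#'     \code{shapeFn(t)}, \code{drawFn(n)}, \code{duration}, \code{t0}.}
#' }
#'
#' @param kind schedule kind, see Details.
#' @param params named list of parameters overriding the defaults above.
#' @return a [TrialSchedule-class].
#' @examples
#' sch <- makeSchedule("benchmark")
#' sch@rateFn(0, list(n_i = 0))  # 50 Hz at t = 0 when n_i = 0
#' @export
makeSchedule <- function(kind = c("constant", "benchmark", "rate_noise",
                                  "rate_switching", "custom"),
                         params = list()) {
  kind <- match.arg(kind)
  p <- params
  pick <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default

  if (kind == "constant") {
    rateMean <- pick("rateMean", 10)
    rateSd <- pick("rateSd", 0)
    shape <- pick("shape", 1)
    duration <- pick("duration", 2)
    t0 <- pick("t0", 0)
    return(new("TrialSchedule", duration = duration, t0 = t0,
      rateFn = function(t, draw) rep(max(draw$lambda, 0), length(t)),
      shapeFn = local({ sh <- shape; function(t) rep(sh, length(t)) }),
      drawFn = local({ m <- rateMean; s <- rateSd
        function(n) lapply(rnorm(n, m, s), function(l) list(lambda = max(l, 0)))
      }),
      kind = kind,
      params = list(rateMean = rateMean, rateSd = rateSd, shape = shape,
                    duration = duration, t0 = t0)))
  }

  if (kind == "benchmark") {
    baseRate <- pick("baseRate", 50)
    nSd <- pick("nSd", 30)
    if (isTRUE(pick("nIsVariance", FALSE))) nSd <- sqrt(nSd)
    modClamp <- pick("modClamp", "modulation")
    tOn <- pick("tOn", 0.3); tOff <- pick("tOff", 0.8)
    kappaOut <- pick("kappaOut", 0.5); kappaIn <- pick("kappaIn", 4)
    t0 <- pick("t0", -0.5); duration <- pick("duration", 2)
    tRec <- pick("tRec", 1.4)  # NA disables the late recovery
    mod <- function(u) {
      up <- pmax(u, 0)
      1 - 5 * up + exp(-2 * up)
    }
    # collapse after t = 0 plus a mirrored recovery towards the trial end;
    # the two branches have disjoint support so max() composes them
    mFull <- function(t) {
      out <- mod(t)
      if (!is.na(tRec)) out <- pmax(out, mod(tRec - t))
      if (modClamp == "modulation") out <- pmax(out, 0)
      out
    }
    rateFn <- function(t, draw) pmax(baseRate + draw$n_i * mFull(t), 0)
    return(new("TrialSchedule", duration = duration, t0 = t0,
      rateFn = rateFn,
      shapeFn = function(t) ifelse(t >= tOn & t < tOff, kappaIn, kappaOut),
      drawFn = function(n) lapply(rnorm(n, 0, nSd), function(x) list(n_i = x)),
      kind = kind,
      params = list(baseRate = baseRate, nSd = nSd, tOn = tOn, tOff = tOff,
                    kappaOut = kappaOut, kappaIn = kappaIn, t0 = t0,
                    duration = duration, tRec = tRec, modClamp = modClamp)))
  }

  if (kind == "rate_noise") {
    base <- makeSchedule("constant", p)
    # N(0, 3) read as variance 3 Hz^2 by default; pass sd explicitly for
    # the sd reading
    sd <- pick("sd", sqrt(pick("variance", 3)))
    ndt <- pick("dt", 0.05)
    duration <- base@duration; t0 <- base@t0
    nSteps <- ceiling(duration / ndt)
    baseDraw <- base@drawFn
    return(new("TrialSchedule", duration = duration, t0 = t0,
      rateFn = function(t, draw) {
        idx <- pmin(pmax(floor((t - t0) / ndt) + 1L, 1L), nSteps)
        pmax(max(draw$lambda, 0) + draw$noise_hz[idx], 0)
      },
      shapeFn = base@shapeFn,
      drawFn = function(n) {
        lapply(baseDraw(n), function(d) {
          d$noise_hz <- rnorm(nSteps, 0, sd)
          d
        })
      },
      kind = kind,
      params = c(base@params, list(sd = sd, dt = ndt))))
  }

  if (kind == "rate_switching") {
    rateMean <- pick("rateMean", 10)
    low <- pick("low", 0.25 * rateMean)
    high <- pick("high", 1.75 * rateMean)
    dwellMean <- pick("dwellMean", 0.01)
    shape <- pick("shape", 1)
    duration <- pick("duration", 2); t0 <- pick("t0", 0)
    return(new("TrialSchedule", duration = duration, t0 = t0,
      rateFn = function(t, draw) {
        # state index = number of switch times at or before t
        st <- findInterval(t, draw$switch_t)
        high_now <- (st %% 2 == 0) == draw$start_high
        ifelse(high_now, high, low)
      },
      shapeFn = local({ sh <- shape; function(t) rep(sh, length(t)) }),
      drawFn = function(n) {
        lapply(seq_len(n), function(i) {
          dw <- rexp(ceiling(4 * duration / dwellMean) + 8L, 1 / dwellMean)
          list(switch_t = t0 + cumsum(dw)[t0 + cumsum(dw) < t0 + duration],
               start_high = runif(1) < 0.5)
        })
      },
      kind = kind,
      params = list(rateMean = rateMean, low = low, high = high,
                    dwellMean = dwellMean, shape = shape,
                    duration = duration, t0 = t0)))
  }

  # custom
  need <- c("rateFn", "shapeFn", "drawFn", "duration", "t0")
  if (!all(need %in% names(p)))
    stop("custom schedules need params: ", paste(need, collapse = ", "))
  new("TrialSchedule", duration = p$duration, t0 = p$t0, rateFn = p$rateFn,
      shapeFn = p$shapeFn, drawFn = p$drawFn, kind = kind, params = p)
}

#' Perturbation specification
#'
#' Bundles the optional perturbations applied by
#' [sampleDoublyStochastic()]: within-trial rate noise and rate switching
#' modify the rate schedule before spike generation; bursting modifies the
#' emitted spike train.
#'
#' @param burst \code{list(pBurst, nSpikes, intraIsi)} or \code{NULL}.
#' @param rateNoise \code{list(sd, dt)} (Hz, seconds) or \code{NULL}.
#' @param rateSwitching \code{list(low, high, dwellMean)} or \code{NULL}.
#' @return a validated list of class \code{"PerturbationSpec"}.
#' @export
perturbationSpec <- function(burst = NULL, rateNoise = NULL,
                             rateSwitching = NULL) {
  if (!is.null(burst)) {
    stopifnot(all(c("pBurst", "nSpikes", "intraIsi") %in% names(burst)))
    if (burst$pBurst < 0 || burst$pBurst > 1) stop("pBurst must be in [0, 1]")
    if (burst$nSpikes < 2) stop("nSpikes must be >= 2")
    stopifnot_scalar_pos(burst$intraIsi, "intraIsi")
  }
  if (!is.null(rateNoise)) {
    stopifnot(all(c("sd", "dt") %in% names(rateNoise)))
    if (rateNoise$sd < 0) stop("rate-noise sd must be >= 0")
    stopifnot_scalar_pos(rateNoise$dt, "rate-noise dt")
  }
  if (!is.null(rateSwitching))
    stopifnot(all(c("low", "high", "dwellMean") %in% names(rateSwitching)))
  structure(list(burst = burst, rateNoise = rateNoise,
                 rateSwitching = rateSwitching),
            class = "PerturbationSpec")
}

# Fold rate perturbations into a schedule: the perturbation draws become
# part of the per-trial ground truth so realizations can be replayed.
apply_rate_perturbations <- function(schedule, perturbations) {
  if (is.null(perturbations)) return(schedule)
  sch <- schedule
  t0 <- sch@t0; duration <- sch@duration
  if (!is.null(perturbations$rateNoise)) {
    sd <- perturbations$rateNoise$sd; ndt <- perturbations$rateNoise$dt
    nSteps <- ceiling(duration / ndt)
    innerDraw <- sch@drawFn; innerRate <- sch@rateFn
    sch <- new("TrialSchedule", duration = duration, t0 = t0,
      rateFn = function(t, draw) {
        idx <- pmin(pmax(floor((t - t0) / ndt) + 1L, 1L), nSteps)
        pmax(innerRate(t, draw) + draw$pert_noise_hz[idx], 0)
      },
      shapeFn = sch@shapeFn,
      drawFn = function(n) lapply(innerDraw(n), function(d) {
        d$pert_noise_hz <- rnorm(nSteps, 0, sd); d
      }),
      kind = sch@kind, params = sch@params)
  }
  if (!is.null(perturbations$rateSwitching)) {
    low <- perturbations$rateSwitching$low
    high <- perturbations$rateSwitching$high
    dwellMean <- perturbations$rateSwitching$dwellMean
    innerDraw <- sch@drawFn
    sch <- new("TrialSchedule", duration = duration, t0 = t0,
      rateFn = function(t, draw) {
        st <- findInterval(t, draw$pert_switch_t)
        high_now <- (st %% 2 == 0) == draw$pert_start_high
        ifelse(high_now, high, low)
      },
      shapeFn = sch@shapeFn,
      drawFn = function(n) lapply(innerDraw(n), function(d) {
        dw <- rexp(ceiling(4 * duration / dwellMean) + 8L, 1 / dwellMean)
        ts <- t0 + cumsum(dw)
        d$pert_switch_t <- ts[ts < t0 + duration]
        d$pert_start_high <- runif(1) < 0.5
        d
      }),
      kind = sch@kind, params = sch@params)
  }
  sch
}

# One realization of a schedule conditioned on a per-trial draw.
sample_given_draw <- function(schedule, draw, dt = 1e-3) {
  win <- c(schedule@t0, schedule@t0 + schedule@duration)
  constant_sched <- schedule@kind == "constant" &&
    is.null(draw$pert_noise_hz) && is.null(draw$pert_switch_t)
  if (constant_sched) {
    lam <- max(draw$lambda, 0)
    if (lam <= 0) return(numeric(0))
    sh <- schedule@shapeFn(win[1])
    win[1] + sampleRenewal(isiModel("gamma", sh), lam, schedule@duration)
  } else {
    sampleInhomogeneousRenewal(function(t) schedule@rateFn(t, draw),
                               schedule@shapeFn, win, dt = dt)
  }
}

#' Sample a doubly stochastic renewal ensemble
#'
#' Draws independent per-trial parameters from the schedule, generates one
#' spike train per trial, and applies perturbations: rate noise and rate
#' switching modify the rate schedule before generation, bursts modify the
#' emitted spike train. Every stochastic per-trial quantity (schedule draws,
#' realized noise increments, switch times, burst-replaced spike indices) is
#' recorded in the ensemble's ground truth.
#'
#' @param schedule a [TrialSchedule-class].
#' @param nTrials number of trials (\eqn{\ge} 1).
#' @param perturbations a [perturbationSpec()] or \code{NULL}.
#' @param seed optional integer seed (recorded in the ensemble).
#' @param unitId unit identifier.
#' @param dt integration step passed to [sampleInhomogeneousRenewal()].
#' @return a [TrialEnsemble-class].
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 20, rateSd = 4, shape = 2)), nTrials = 50, seed = 1)
#' @export
sampleDoublyStochastic <- function(schedule, nTrials, perturbations = NULL,
                                   seed = NULL, unitId = "sim", dt = 1e-3) {
  stopifnot(is(schedule, "TrialSchedule"))
  if (nTrials < 1) stop("nTrials must be >= 1")
  sch <- apply_rate_perturbations(schedule, perturbations)
  win <- c(sch@t0, sch@t0 + sch@duration)
  burst <- perturbations$burst
  run <- function() {
    draws <- sch@drawFn(nTrials)
    trials <- vector("list", nTrials)
    for (i in seq_len(nTrials)) {
      s <- sample_given_draw(sch, draws[[i]], dt = dt)
      if (!is.null(burst) && length(s)) {
        s <- injectBursts(s, burst$pBurst, burst$nSpikes, burst$intraIsi,
                          window = win)
        draws[[i]]$burst_replaced <- attr(s, "replaced")
        attributes(s) <- NULL
      }
      trials[[i]] <- as.numeric(s)
    }
    trialEnsemble(trials, win, groundTruth = draws, unitId = unitId,
                  seed = if (is.null(seed)) NA_integer_ else seed)
  }
  with_seed(seed, run())
}
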