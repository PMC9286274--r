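#' @useDynLib spikevar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct LIF neuron parameters
#'
#' Defaults: membrane time constant 20 ms, threshold 20 and reset/rest 0 in
#' arbitrary units, refractory 2 ms, synaptic time constant 5 ms,
#' integration step 0.1 ms. The synaptic weights were calibrated once so
#' that the default balanced 50E/50I network at 40 Hz presynaptic rate
#' drives the neuron at 5-20 Hz (fluctuation-driven regime); only trend
#' directions, not absolute rates, are meaningful.
#'
#' @param tauM,vThresh,vReset,vRest,refractory,tauSyn,wE,wI,dt see
#'   [LIFParams-class].
#' @return a [LIFParams-class].
#' @export
lifParams <- function(tauM = 0.02, vThresh = 20, vReset = 0, vRest = 0,
                      refractory = 0.002, tauSyn = 0.005, wE = 14,
                      wI = 14, dt = 1e-4) {
  new("LIFParams", tauM = tauM, vThresh = vThresh, vReset = vReset,
      vRest = vRest, refractory = refractory, tauSyn = tauSyn, wE = wE,
      wI = wI, dt = dt)
}

#' Construct a presynaptic network specification
#'
#' @param nE,nI pool sizes (default 50 and 50).
#' @param rateMean,rateSd per-trial pool rate distribution in Hz (default
#'   N(40, 4^2), read as mean 40 and sd 4; pass the variance's square root
#'   explicitly for the variance-4 reading).
#' @param rateCorr trial-to-trial E/I rate correlation.
#' @param spikeCorr pairwise spike correlation within correlation groups.
#' @param corrMode \code{"none"}, \code{"between_pool"} (corresponding E/I
#'   sub-pools are jointly equicorrelated) or \code{"within_pool"} (each
#'   sub-pool is equicorrelated on its own).
#' @param nSubpools sub-pools per pool (default 2); must divide both sizes.
#' @param eiDelay mean added latency of inhibitory spikes, seconds.
#' @param jitterSd Laplace spike-time jitter sd, seconds (default 2 ms).
#' @param deterministicRate use \code{rateMean} on every trial.
#' @param duration trial duration, seconds.
#' @return a [NetworkSpec-class].
#' @export
networkSpec <- function(nE = 50L, nI = 50L, rateMean = 40, rateSd = 4,
                        rateCorr = 0, spikeCorr = 0,
                        corrMode = c("none", "between_pool", "within_pool"),
                        nSubpools = 2L, eiDelay = 0, jitterSd = 0.002,
                        deterministicRate = FALSE, duration = 1) {
  corrMode <- match.arg(corrMode)
  new("NetworkSpec", nE = as.integer(nE), nI = as.integer(nI),
      rateMean = rateMean, rateSd = rateSd, rateCorr = rateCorr,
      spikeCorr = spikeCorr, corrMode = corrMode,
      nSubpools = as.integer(nSubpools), eiDelay = eiDelay,
      jitterSd = jitterSd, deterministicRate = deterministicRate,
      duration = duration)
}

#' Sample correlated per-trial pool rates
#'
#' Bivariate normal with equal marginals N(\code{rateMean},
#' \code{rateSd}^2), correlation \code{rho}, clamped at 0.
#'
#' @param rateMean,rateSd marginal mean and sd, Hz.
#' @param rho correlation in \eqn{[-1, 1]}.
#' @param nTrials number of trials.
#' @param seed optional integer seed.
#' @return numeric matrix \code{nTrials x 2} with columns
#'   \code{lambda_e}, \code{lambda_i}.
#' @examples
#' r <- sampleCorrelatedRates(40, 4, 0.6, 1000, seed = 1); cor(r)[1, 2]
#' @export
sampleCorrelatedRates <- function(rateMean, rateSd, rho, nTrials,
                                  seed = NULL) {
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  with_seed(seed, {
    z1 <- rnorm(nTrials)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nTrials)
    out <- cbind(lambda_e = pmax(rateMean + rateSd * z1, 0),
                 lambda_i = pmax(rateMean + rateSd * z2, 0))
    out
  })
}

# Latent equicorrelation of a dichotomized Gaussian with marginal
# probability p achieving pairwise Bernoulli correlation target.
dg_latent_corr <- function(p, target) {
  if (target <= 1e-9) return(0)
  if (target >= 1 - 1e-9) return(1)
  th <- qnorm(1 - p)
  p11 <- function(rho) {
    # P(X > th, Y > th) for standard bivariate normal with correlation rho
    integrate(function(x) {
      dnorm(x) * pnorm((rho * x - th) / sqrt(1 - rho^2))
    }, th, Inf, rel.tol = 1e-9)$value
  }
  want <- target * p * (1 - p) + p^2
  uniroot(function(r) p11(r) - want, lower = 1e-6, upper = 1 - 1e-6,
          tol = 1e-9)$root
}

#' Generate correlated Poisson-like spike trains
#'
#' Dichotomized-Gaussian construction (Macke et al. 2009): per time bin of
#' width \code{dt}, an equicorrelated latent standard Gaussian vector is
#' thresholded so that the marginal spike probability is
#' \code{rate * dt} and the pairwise spike-count correlation matches
#' \code{pairwiseCorr}. With zero correlation the trains are independent
#' Bernoulli approximations of Poisson processes; with correlation 1 all
#' trains in the group are identical.
#'
#' @param nNeurons number of trains in the equicorrelated group.
#' @param rate marginal firing rate, Hz; a scalar, or a vector of length
#'   \code{nNeurons} for heterogeneous rates (the latent correlation is
#'   then solved at the mean rate and the realized pairwise correlations
#'   vary mildly across pairs).
#' @param pairwiseCorr target pairwise count correlation in \eqn{[0, 1]};
#'   values outside that range are infeasible for this construction and
#'   raise an error.
#' @param duration train length, seconds.
#' @param dt bin width, seconds (default 1 ms).
#' @param seed optional integer seed.
#' @return list of spike-time vectors (bin centers).
#' @examples
#' tr <- generateCorrelatedPoisson(5, 40, 0.3, 2, seed = 1)
#' @export
generateCorrelatedPoisson <- function(nNeurons, rate, pairwiseCorr,
                                      duration, dt = 1e-3, seed = NULL) {
  if (pairwiseCorr < 0 || pairwiseCorr > 1)
    stop("pairwiseCorr must be within the feasible range [0, 1] for the ",
         "dichotomized-Gaussian construction")
  p <- rep_len(rate * dt, nNeurons)
  if (any(p >= 1)) stop("rate * dt must be below 1; decrease dt")
  with_seed(seed, {
    nb <- floor(duration / dt + 1e-9)
    if (all(p <= 0)) return(rep(list(numeric(0)), nNeurons))
    rho <- dg_latent_corr(mean(p), pairwiseCorr)
    th <- qnorm(1 - p)
    shared <- if (rho > 0) sqrt(rho) * rnorm(nb) else numeric(nb)
    centers <- (seq_len(nb) - 0.5) * dt
    lapply(seq_len(nNeurons), function(i) {
      z <- shared + sqrt(1 - rho) * rnorm(nb)
      centers[z > th[i]]
    })
  })
}

#' Jitter and delay spike trains
#'
#' Adds an independent Laplace(\code{delayMean}, sd = \code{jitterSd}) draw
#' to every spike time and re-sorts each train. Used to soften the discrete
#' bin structure of the correlated generator and to impose a mean E-to-I
#' latency. Jittering spike times (rather than ISIs) preserves each train's
#' rate.
#'
#' @param trains list of spike-time vectors.
#' @param jitterSd Laplace standard deviation, seconds (\eqn{\ge} 0).
#' @param delayMean mean shift, seconds.
#' @param seed optional integer seed.
#' @param window optional half-open window; shifted spikes outside it are
#'   dropped.
#' @return list of jittered spike-time vectors.
#' @export
applyJitterDelay <- function(trains, jitterSd, delayMean = 0, seed = NULL,
                             window = NULL) {
  if (jitterSd < 0) stop("jitterSd must be >= 0")
  with_seed(seed, lapply(trains, function(s) {
    if (!length(s)) return(s)
    s <- s + if (jitterSd > 0) rlaplace(length(s), delayMean, jitterSd)
    else delayMean
    s <- sort(s)
    if (!is.null(window)) s <- s[s >= window[1] & s < window[2]]
    s
  }))
}

#' Simulate the postsynaptic LIF neuron
#'
#' Current-based leaky integrate-and-fire neuron driven by pooled
#' excitatory and inhibitory input trains through a shared
#' single-exponential synaptic kernel (weights of opposite sign), advanced
#' by the exact exponential update at step \code{dt} with threshold-reset
#' spiking and an absolute refractory period.
#'
#' @param eTrains,iTrains lists of input spike-time vectors, seconds.
#' @param params a [LIFParams-class].
#' @param duration simulated time, seconds.
#' @return output spike-time vector.
#' @examples
#' e <- replicate(50, sort(runif(40, 0, 1)), simplify = FALSE)
#' i <- replicate(50, sort(runif(40, 0, 1)), simplify = FALSE)
#' out <- lifSimulate(e, i, lifParams(), duration = 1)
#' @export
lifSimulate <- function(eTrains, iTrains, params = lifParams(),
                        duration = 1) {
  stopifnot(is(params, "LIFParams"))
  if (params@dt > min(params@tauM, params@tauSyn) / 5)
    stop("dt too large for stable integration; need dt <= min(tauM, tauSyn)/5")
  nb <- ceiling(duration / params@dt)
  bin_pool <- function(trains) {
    s <- unlist(trains, use.names = FALSE)
    s <- s[s >= 0 & s < duration]
    tabulate(floor(s / params@dt) + 1L, nbins = nb)
  }
  out <- lif_core(bin_pool(eTrains), bin_pool(iTrains), params@dt,
                  params@tauM, params@tauSyn, params@wE, params@wI,
                  params@vThresh, params@vReset, params@vRest,
                  params@refractory)
  out[out < duration]
}

# One postsynaptic trial given per-trial pool rates.
network_trial <- function(spec, params, lamE, lamI) {
  dur <- spec@duration
  dtg <- 1e-3
  jd <- function(trains, delay) {
    applyJitterDelay(trains, spec@jitterSd, delay, window = c(0, dur))
  }
  if (spec@corrMode == "none") {
    # independent Poisson neurons: pool directly
    nEsp <- rpois(1, spec@nE * lamE * dur)
    nIsp <- rpois(1, spec@nI * lamI * dur)
    eTr <- list(sort(runif(nEsp, 0, dur)))
    iTr <- list(sort(runif(nIsp, 0, dur)))
  } else if (spec@corrMode == "between_pool") {
    gE <- spec@nE / spec@nSubpools
    gI <- spec@nI / spec@nSubpools
    eTr <- list(); iTr <- list()
    for (k in seq_len(spec@nSubpools)) {
      # one equicorrelated group spanning the E and I sub-pool k, each
      # neuron keeping its own pool's trial rate
      grp <- generateCorrelatedPoisson(gE + gI, c(rep(lamE, gE),
                                                  rep(lamI, gI)),
                                       spec@spikeCorr, dur, dt = dtg)
      eTr <- c(eTr, grp[seq_len(gE)])
      iTr <- c(iTr, grp[gE + seq_len(gI)])
    }
  } else {  # within_pool
    gE <- spec@nE / spec@nSubpools
    gI <- spec@nI / spec@nSubpools
    eTr <- unlist(lapply(seq_len(spec@nSubpools), function(k) {
      generateCorrelatedPoisson(gE, lamE, spec@spikeCorr, dur, dt = dtg)
    }), recursive = FALSE)
    iTr <- unlist(lapply(seq_len(spec@nSubpools), function(k) {
      generateCorrelatedPoisson(gI, lamI, spec@spikeCorr, dur, dt = dtg)
    }), recursive = FALSE)
  }
  out <- lifSimulate(jd(eTr, 0), jd(iTr, spec@eiDelay), params, dur)
  as.numeric(out)
}

#' Simulate a postsynaptic trial ensemble from a network specification
#'
#' Draws per-trial E/I pool rates (correlated across trials by
#' \code{rateCorr}, or fixed when \code{deterministicRate}), generates the
#' presynaptic pools (independent Poisson, or correlated Poisson groups per
#' \code{corrMode}), applies jitter and the E-to-I delay, and integrates
#' the LIF neuron.
#'
#' @param spec a [NetworkSpec-class].
#' @param params a [LIFParams-class].
#' @param nTrials number of trials.
#' @param seed optional integer seed.
#' @return a [TrialEnsemble-class] of postsynaptic spike trains with the
#'   per-trial rates as ground truth.
#' @export
simulateNetworkEnsemble <- function(spec, params = lifParams(), nTrials,
                                    seed = NULL) {
  stopifnot(is(spec, "NetworkSpec"))
  with_seed(seed, {
    rates <- if (spec@deterministicRate) {
      matrix(spec@rateMean, nTrials, 2)
    } else {
      sampleCorrelatedRates(spec@rateMean, spec@rateSd, spec@rateCorr,
                            nTrials)
    }
    trials <- lapply(seq_len(nTrials), function(i) {
      network_trial(spec, params, rates[i, 1], rates[i, 2])
    })
    trialEnsemble(trials, c(0, spec@duration),
                  groundTruth = lapply(seq_len(nTrials), function(i) {
                    list(lambda_e = rates[i, 1], lambda_i = rates[i, 2])
                  }),
                  unitId = "lif", seed = seed)
  })
}

#' Run a presynaptic-manipulation experiment grid
#'
#' Reproduces the mechanistic experiments linking presynaptic correlation
#' structure to the postsynaptic variability components. For each grid
#' value the manipulated field of the base specification is set, an
#' ensemble of postsynaptic trials is simulated, and the single-window
#' decomposition (sub-bin nPsi estimator) is tabulated. The initial 100 ms
#' of each trial are excluded from the analysis window to avoid the
#' integrate-and-fire onset transient.
#'
#' Kinds and their grids:
#' \describe{
#'   \item{\code{rate_corr}}{grid of E/I rate correlations \eqn{\rho};
#'     expected: nRV decreases with \eqn{\rho}, nPsi flat.}
#'   \item{\code{spike_corr_between}}{grid of between-pool spike
#'     correlations at the spec's \code{eiDelay}; expected at positive
#'     delay: nPsi decreases, rate increases.}
#'   \item{\code{spike_corr_within}}{grid of within-pool spike
#'     correlations; expected: nPsi and rate increase.}
#'   \item{\code{ei_ratio}}{grid of excitatory fractions
#'     \eqn{n_E/(n_E+n_I)} at fixed total size; expected: rate increases
#'     and nPsi decreases above 0.5.}
#'   \item{\code{subpool_sweep}}{grid of sub-pool counts at fixed
#'     between-pool spike correlation; expected: the correlation effect on
#'     nPsi weakens as sub-pools shrink.}
#' }
#'
#' @param kind experiment kind, see Details.
#' @param grid numeric grid of the manipulated variable.
#' @param nTrials trials per grid point (default 1000).
#' @param spec base [NetworkSpec-class].
#' @param params a [LIFParams-class].
#' @param seed optional integer seed.
#' @param nBoot bootstrap resamples for the sems.
#' @param analysisStart start of the decomposition window, seconds.
#' @return data.frame with one row per grid point: \code{kind},
#'   \code{grid_value}, \code{rate_hz}, \code{n_psi}, \code{n_rv},
#'   \code{cv_local2}, \code{ff} and matching \code{*_sem} columns.
#' @export
runNetworkExperiment <- function(kind = c("rate_corr", "spike_corr_between",
                                          "spike_corr_within", "ei_ratio",
                                          "subpool_sweep"),
                                 grid, nTrials = 1000,
                                 spec = networkSpec(), params = lifParams(),
                                 seed = NULL, nBoot = 200,
                                 analysisStart = 0.1) {
  kind <- match.arg(kind)
  if (!length(grid)) stop("grid must be non-empty")
  rows <- lapply(seq_along(grid), function(g) {
    sp <- spec
    val <- grid[g]
    if (kind == "rate_corr") {
      sp@rateCorr <- val
      sp@corrMode <- "none"
    } else if (kind == "spike_corr_between") {
      sp@spikeCorr <- val
      sp@corrMode <- "between_pool"
    } else if (kind == "spike_corr_within") {
      sp@spikeCorr <- val
      sp@corrMode <- "within_pool"
    } else if (kind == "ei_ratio") {
      tot <- sp@nE + sp@nI
      sp@nE <- as.integer(round(val * tot))
      sp@nI <- tot - sp@nE
      sp@nSubpools <- 1L
    } else {  # subpool_sweep
      sp@nSubpools <- as.integer(val)
      sp@corrMode <- "between_pool"
    }
    validObject(sp)
    ens <- simulateNetworkEnsemble(sp, params, nTrials,
                                   seed = child_seed(seed, g))
    est <- suppressWarnings(
      decompose(ens, c(analysisStart, sp@duration), method = "vinci",
                nBoot = nBoot, seed = child_seed(seed, 1000L + g)))
    data.frame(kind = kind, grid_value = val, rate_hz = est@meanRate,
               n_psi = est@nPsi, n_rv = est@nRV, cv_local2 = est@cvLocal2,
               ff = est@ff, rate_hz_sem = est@sem[["meanRate"]],
               n_psi_sem = est@sem[["nPsi"]], n_rv_sem = est@sem[["nRV"]],
               cv_local2_sem = est@sem[["cvLocal2"]],
               ff_sem = est@sem[["ff"]])
  })
  do.call(rbind, rows)
}
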