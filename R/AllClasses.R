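#' @import methods
#' @importFrom stats approx approxfun integrate optimize pgamma qnorm quantile
#'   rbinom rexp rgamma rnorm rpois runif sd setNames t.test uniroot var
#'   weighted.mean cor pnorm dnorm complete.cases spline splinefun
NULL

#' Interspike-interval model
#'
#' Describes the renewal interspike-interval (ISI) family used by the spike
#' train samplers. Three families are supported: \code{"exponential"}
#' (Poisson process), \code{"gamma"} and \code{"inverse_gaussian"}. The
#' \code{shape} slot holds the gamma shape \eqn{\kappa} or the inverse
#' Gaussian shape parameter; it is ignored for the exponential family, which
#' is identical to a gamma model with \eqn{\kappa = 1}.
#'
#' The ISI coefficient of variation squared is \eqn{1/\kappa} for the gamma
#' family and \eqn{\mu/\lambda_{sh}} (mean ISI over shape) for the inverse
#' Gaussian family.
#'
#' @slot family character, one of \code{"exponential"}, \code{"gamma"},
#'   \code{"inverse_gaussian"}.
#' @slot shape positive numeric shape parameter.
#' @seealso [isiModel()], [sampleRenewal()]
#' @exportClass ISIModel
setClass("ISIModel",
  representation(family = "character", shape = "numeric"),
  prototype(family = "gamma", shape = 1))

setValidity("ISIModel", function(object) {
  ok <- c("exponential", "gamma", "inverse_gaussian")
  if (length(object@family) != 1L || !object@family %in% ok)
    return(sprintf("family must be one of: %s", paste(ok, collapse = ", ")))
  if (length(object@shape) != 1L || !is.finite(object@shape) ||
      object@shape <= 0)
    return("shape must be a single positive number")
  TRUE
})

#' Per-trial rate and shape schedule
#'
#' A \code{TrialSchedule} describes how the firing rate \eqn{\lambda_i(t)}
#' (Hz) and the gamma shape \eqn{\kappa(t)} evolve over a trial, together
#' with the distribution of the per-trial random quantities (for instance
#' the rate offset \eqn{n_i}) that make the process doubly stochastic.
#'
#' @slot duration trial duration in seconds.
#' @slot t0 alignment origin in seconds (may be negative); the trial window
#'   is \eqn{[t0, t0 + duration)}.
#' @slot rateFn function \code{(t, draw)} returning the rate in Hz at times
#'   \code{t} for a trial whose per-trial draw is \code{draw}; negative
#'   values are clamped to zero by the samplers.
#' @slot shapeFn function \code{(t)} returning the shape \eqn{\kappa(t) > 0}.
#' @slot drawFn function \code{(n)} returning a list of \code{n} per-trial
#'   draws (each a named list); recorded as ground truth by
#'   [sampleDoublyStochastic()].
#' @slot kind character label (\code{"benchmark"}, \code{"constant"}, ...).
#' @slot params list of the parameters the schedule was built from.
#' @seealso [makeSchedule()]
#' @exportClass TrialSchedule
setClass("TrialSchedule",
  representation(duration = "numeric", t0 = "numeric", rateFn = "function",
                 shapeFn = "function", drawFn = "function",
                 kind = "character", params = "list"))

setValidity("TrialSchedule", function(object) {
  if (length(object@duration) != 1L || object@duration <= 0)
    return("duration must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("t0 must be a single finite number")
  TRUE
})

#' Trial-indexed spike-time ensemble for one unit
#'
#' The central data container: spike times (seconds, relative to the
#' alignment event) for every trial of one unit, the common observation
#' window, and -- for simulated data -- the per-trial ground-truth draws
#' that generated each trial.
#'
#' @slot trials list of numeric vectors, one per trial, each strictly
#'   increasing and contained in \code{window}.
#' @slot window numeric of length 2, the half-open observation window
#'   \eqn{[t_{start}, t_{end})}.
#' @slot groundTruth list of per-trial named lists of realized random
#'   quantities (empty list when unknown, e.g. for recorded data).
#' @slot unitId character identifier.
#' @slot seed integer seed used to generate the ensemble (\code{NA} for
#'   recorded data).
#' @seealso [sampleDoublyStochastic()], [readEnsemble()], [writeEnsemble()]
#' @exportClass TrialEnsemble
setClass("TrialEnsemble",
  representation(trials = "list", window = "numeric", groundTruth = "list",
                 unitId = "character", seed = "integer"),
  prototype(groundTruth = list(), unitId = "unit", seed = NA_integer_))

setValidity("TrialEnsemble", function(object) {
  if (length(object@window) != 2L || diff(object@window) <= 0)
    return("window must be numeric(2) with window[1] < window[2]")
  for (i in seq_along(object@trials)) {
    s <- object@trials[[i]]
    if (!is.numeric(s))
      return(sprintf("trial %d is not numeric", i))
    if (length(s) && (any(s < object@window[1]) || any(s >= object@window[2])))
      return(sprintf("trial %d has spikes outside the half-open window", i))
    if (length(s) > 1L && any(diff(s) <= 0))
      return(sprintf("spike times in trial %d are not strictly increasing", i))
  }
  if (length(object@groundTruth) &&
      length(object@groundTruth) != length(object@trials))
    return("groundTruth must be empty or have one entry per trial")
  TRUE
})

#' Fano factor as a function of counting-window width
#'
#' Holds the across-trial Fano factor \eqn{FF(T) = Var(N_T)/E[N_T]} for a
#' grid of nested half-open windows \eqn{[anchor, anchor + T)}, with
#' bootstrap uncertainty and the mean count per window. Windows whose mean
#' count is zero are flagged \code{NA}.
#'
#' @slot Tgrid strictly increasing window widths, seconds.
#' @slot ff Fano factor per width.
#' @slot ffSem bootstrap standard error per width.
#' @slot meanCount mean spike count per width.
#' @slot anchorTime left edge of all windows, seconds.
#' @slot nTrials number of trials used.
#' @seealso [fanoVsBinsize()], [ffaFit()]
#' @exportClass FanoCurve
setClass("FanoCurve",
  representation(Tgrid = "numeric", ff = "numeric", ffSem = "numeric",
                 meanCount = "numeric", anchorTime = "numeric",
                 nTrials = "integer"))

setValidity("FanoCurve", function(object) {
  n <- length(object@Tgrid)
  if (any(diff(object@Tgrid) <= 0))
    return("Tgrid must be strictly increasing")
  if (length(object@ff) != n || length(object@ffSem) != n ||
      length(object@meanCount) != n)
    return("ff, ffSem and meanCount must match Tgrid in length")
  if (any(object@ff < 0, na.rm = TRUE))
    return("ff must be non-negative")
  TRUE
})

#' Single-window variability decomposition
#'
#' The decomposition of the Fano factor in one counting window of width
#' \eqn{T}: \eqn{FF = n\Psi + T \cdot nRV}, where \eqn{n\Psi} is the
#' normalized within-trial spiking irregularity (dimensionless) and
#' \eqn{nRV} the normalized between-trial rate variability (1/s).
#' \code{cvLocal2} is the CV2-based estimate of the point-process
#' variability (nPPV), on the same \eqn{1/\kappa} scale as \eqn{n\Psi}.
#'
#' @slot nPsi,nRV,ff,cvLocal2,meanRate point estimates (\code{meanRate} in
#'   Hz); \code{NA} when unavailable.
#' @slot sem named numeric of bootstrap standard errors.
#' @slot method \code{"ffa"}, \code{"vinci"} or \code{"empirical"}.
#' @slot binWidth counting-window width \eqn{T} in seconds.
#' @seealso [decompose()], [ffaFit()], [vinciNpsi()]
#' @exportClass DecompositionEstimate
setClass("DecompositionEstimate",
  representation(nPsi = "numeric", nRV = "numeric", ff = "numeric",
                 cvLocal2 = "numeric", meanRate = "numeric",
                 sem = "numeric", method = "character",
                 binWidth = "numeric"))

#' Sliding-window variability time course
#'
#' Per-center estimates of FF, nPsi, nRV, CVlocal2, mean rate and burst
#' statistics over a sliding counting window. Centers where the mean count
#' falls below the minimum are flagged missing (\code{NA}) rather than
#' interpolated.
#'
#' @slot table data.frame with one row per window center; columns
#'   \code{center_s}, \code{ff}, \code{n_psi}, \code{n_rv}, \code{cv_local2},
#'   \code{mean_rate_hz}, matching \code{*_sem} columns,
#'   \code{n_valid_trials} and \code{missing}.
#' @slot bin window width in seconds.
#' @slot step center spacing in seconds.
#' @slot method estimator used for nPsi.
#' @seealso [slidingDecomposition()]
#' @exportClass VariabilityTimecourse
setClass("VariabilityTimecourse",
  representation(table = "data.frame", bin = "numeric", step = "numeric",
                 method = "character"))

#' Burst-detection calibration
#'
#' Parameters of the ISI-threshold burst detector, fitted on a spontaneous
#' epoch of a pool of units: a burst is a maximal run of at least
#' \code{minRun} spikes whose consecutive ISIs are all at or below
#' \code{isiThreshold}. \code{baselineBps} is the burst rate per spike
#' detected in the calibration epoch (the chance level for renewal spiking).
#'
#' @slot isiThreshold seconds.
#' @slot minRun integer, minimum spikes per burst.
#' @slot baselineBps baseline bursts per spike.
#' @seealso [calibrateBursts()], [detectBursts()]
#' @exportClass BurstCalibration
setClass("BurstCalibration",
  representation(isiThreshold = "numeric", minRun = "integer",
                 baselineBps = "numeric"))

setValidity("BurstCalibration", function(object) {
  if (object@isiThreshold <= 0) return("isiThreshold must be positive")
  if (object@minRun < 2L) return("minRun must be at least 2")
  if (object@baselineBps < 0) return("baselineBps must be non-negative")
  TRUE
})

#' Leaky integrate-and-fire neuron parameters
#'
#' Current-based LIF neuron with a single-exponential synaptic kernel shared
#' by excitatory and inhibitory inputs (weights applied with opposite
#' signs). Potentials are in arbitrary consistent units with resting
#' potential 0.
#'
#' @slot tauM membrane time constant, seconds.
#' @slot vThresh,vReset,vRest threshold, reset and resting potentials.
#' @slot refractory absolute refractory period, seconds.
#' @slot tauSyn synaptic kernel time constant, seconds.
#' @slot wE,wI synaptic increments per excitatory / inhibitory input spike
#'   (both positive; the inhibitory current enters with a minus sign).
#' @slot dt integration step, seconds.
#' @seealso [lifParams()], [lifSimulate()]
#' @exportClass LIFParams
setClass("LIFParams",
  representation(tauM = "numeric", vThresh = "numeric", vReset = "numeric",
                 vRest = "numeric", refractory = "numeric",
                 tauSyn = "numeric", wE = "numeric", wI = "numeric",
                 dt = "numeric"))

setValidity("LIFParams", function(object) {
  if (object@vThresh <= object@vReset)
    return("vThresh must exceed vReset")
  if (any(c(object@tauM, object@tauSyn, object@dt) <= 0))
    return("time constants and dt must be positive")
  if (object@wE <= 0 || object@wI < 0)
    return("wE must be positive and wI non-negative")
  TRUE
})

#' Balanced E/I presynaptic network specification
#'
#' Describes the presynaptic drive of the network experiments: excitatory
#' and inhibitory Poisson pools with trial-to-trial rate variability and
#' optional rate correlation \eqn{\rho} between the pools, optional pairwise
#' spike correlation \eqn{c} within or between sub-pools, an E-to-I spike
#' delay, and Laplace spike-time jitter.
#'
#' @slot nE,nI pool sizes.
#' @slot rateMean,rateSd per-trial pool rate distribution, Hz (normal,
#'   clamped at 0).
#' @slot rateCorr trial-to-trial correlation of the E and I pool rates.
#' @slot spikeCorr pairwise spike-count correlation within the designated
#'   correlation groups.
#' @slot corrMode \code{"none"}, \code{"between_pool"} or
#'   \code{"within_pool"}.
#' @slot nSubpools number of sub-pools per pool (must divide both sizes).
#' @slot eiDelay mean added latency of inhibitory spikes, seconds.
#' @slot jitterSd Laplace jitter standard deviation, seconds.
#' @slot deterministicRate if \code{TRUE} all trials use \code{rateMean}.
#' @slot duration trial duration, seconds.
#' @seealso [networkSpec()], [runNetworkExperiment()]
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(nE = "integer", nI = "integer", rateMean = "numeric",
                 rateSd = "numeric", rateCorr = "numeric",
                 spikeCorr = "numeric", corrMode = "character",
                 nSubpools = "integer", eiDelay = "numeric",
                 jitterSd = "numeric", deterministicRate = "logical",
                 duration = "numeric"))

setValidity("NetworkSpec", function(object) {
  if (object@nE < 1L || object@nI < 1L) return("pool sizes must be >= 1")
  if (abs(object@rateCorr) > 1) return("rateCorr must be in [-1, 1]")
  if (object@spikeCorr < 0 || object@spikeCorr > 1)
    return("spikeCorr must be in [0, 1]")
  if (!object@corrMode %in% c("none", "between_pool", "within_pool"))
    return("corrMode must be none, between_pool or within_pool")
  if (object@nE %% object@nSubpools != 0L ||
      object@nI %% object@nSubpools != 0L)
    return("nSubpools must divide both pool sizes")
  if (object@duration <= 0) return("duration must be positive")
  TRUE
})
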