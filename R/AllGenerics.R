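#' Accessors for spikevar classes
#'
#' @param x a spikevar object.
#' @param ... unused.
#' @name accessors
NULL

#' @describeIn accessors list of per-trial spike-time vectors.
#' @export
setGeneric("trials", function(x, ...) standardGeneric("trials"))

#' @describeIn accessors number of trials.
#' @export
setGeneric("nTrials", function(x, ...) standardGeneric("nTrials"))

#' @describeIn accessors the half-open observation window, numeric(2).
#' @export
setGeneric("ensembleWindow", function(x, ...) standardGeneric("ensembleWindow"))

#' @describeIn accessors list of per-trial ground-truth draws.
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))

#' @describeIn accessors unit identifier.
#' @export
setGeneric("unitId", function(x, ...) standardGeneric("unitId"))

#' @rdname accessors
#' @export
setMethod("trials", "TrialEnsemble", function(x, ...) x@trials)

#' @rdname accessors
#' @export
setMethod("nTrials", "TrialEnsemble", function(x, ...) length(x@trials))

#' @rdname accessors
#' @export
setMethod("ensembleWindow", "TrialEnsemble", function(x, ...) x@window)

#' @rdname accessors
#' @export
setMethod("groundTruth", "TrialEnsemble", function(x, ...) x@groundTruth)

#' @rdname accessors
#' @export
setMethod("unitId", "TrialEnsemble", function(x, ...) x@unitId)

setMethod("show", "TrialEnsemble", function(object) {
  n <- length(object@trials)
  ns <- vapply(object@trials, length, 0L)
  cat(sprintf("TrialEnsemble '%s': %d trials, window [%g, %g) s\n",
              object@unitId, n, object@window[1], object@window[2]))
  cat(sprintf("  %d spikes total (mean %.1f/trial, mean rate %.2f Hz)\n",
              sum(ns), mean(ns), mean(ns) / diff(object@window)))
  if (length(object@groundTruth))
    cat(sprintf("  ground truth: %s\n",
                paste(names(object@groundTruth[[1]]), collapse = ", ")))
})

setMethod("show", "ISIModel", function(object) {
  cat(sprintf("ISIModel: %s (shape = %g)\n", object@family, object@shape))
})

setMethod("show", "TrialSchedule", function(object) {
  cat(sprintf("TrialSchedule '%s': window [%g, %g) s\n", object@kind,
              object@t0, object@t0 + object@duration))
})

setMethod("show", "FanoCurve", function(object) {
  cat(sprintf("FanoCurve: %d widths in [%g, %g] s, anchor %g s, %d trials\n",
              length(object@Tgrid), min(object@Tgrid), max(object@Tgrid),
              object@anchorTime, object@nTrials))
})

setMethod("show", "DecompositionEstimate", function(object) {
  cat(sprintf("DecompositionEstimate (%s, T = %g s)\n", object@method,
              object@binWidth))
  cat(sprintf("  FF = %.3f, nPsi = %.3f, nRV = %.3f 1/s, CVlocal2 = %.3f, rate = %.2f Hz\n",
              object@ff, object@nPsi, object@nRV, object@cvLocal2,
              object@meanRate))
})

setMethod("show", "VariabilityTimecourse", function(object) {
  cat(sprintf("VariabilityTimecourse (%s): %d centers, bin %g s, step %g s, %d missing\n",
              object@method, nrow(object@table), object@bin, object@step,
              sum(object@table$missing)))
})

setMethod("show", "BurstCalibration", function(object) {
  cat(sprintf("BurstCalibration: ISI threshold %.1f ms, min run %d, baseline %.4f bursts/spike\n",
              1e3 * object@isiThreshold, object@minRun, object@baselineBps))
})

setMethod("show", "NetworkSpec", function(object) {
  cat(sprintf("NetworkSpec: %dE/%dI, rate ~ N(%g, %g^2) Hz, rho = %g, c = %g (%s, %d sub-pools)\n",
              object@nE, object@nI, object@rateMean, object@rateSd,
              object@rateCorr, object@spikeCorr, object@corrMode,
              object@nSubpools))
  cat(sprintf("  E->I delay %g ms, jitter sd %g ms, duration %g s\n",
              1e3 * object@eiDelay, 1e3 * object@jitterSd, object@duration))
})

#' Coerce a FanoCurve to a data.frame
#'
#' @param x a [FanoCurve-class].
#' @param ... unused.
#' @return data.frame with columns \code{T_s}, \code{ff}, \code{ff_sem},
#'   \code{mean_count}.
#' @method as.data.frame FanoCurve
#' @export
as.data.frame.FanoCurve <- function(x, ...) {
  data.frame(T_s = x@Tgrid, ff = x@ff, ff_sem = x@ffSem,
             mean_count = x@meanCount)
}
setMethod("as.data.frame", "FanoCurve", as.data.frame.FanoCurve)

#' Coerce a VariabilityTimecourse to a data.frame
#'
#' @param x a [VariabilityTimecourse-class].
#' @param ... unused.
#' @return the per-center table (one row per window center).
#' @method as.data.frame VariabilityTimecourse
#' @export
as.data.frame.VariabilityTimecourse <- function(x, ...) x@table
setMethod("as.data.frame", "VariabilityTimecourse",
          as.data.frame.VariabilityTimecourse)
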