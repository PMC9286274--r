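#' Calibrate the ISI-threshold burst detector on a spontaneous epoch
#'
#' Pools ISIs from a spontaneous (pre-stimulus) window across a pool of
#' units and sets the burst ISI threshold at a low percentile of that
#' pooled distribution (default the 5th), floored at 4 ms. A burst is then
#' a maximal run of at least \code{minRun} spikes with all consecutive ISIs
#' at or below the threshold. The baseline bursts-per-spike level detected
#' in the same spontaneous window is recorded so stimulus-epoch burst rates
#' can be baseline-adjusted.
#'
#' @param ensembles list of [TrialEnsemble-class] objects (the unit pool).
#' @param spontaneousWindow half-open window of spontaneous activity.
#' @param percentile ISI percentile (0-1 scale) for the threshold,
#'   default 0.05.
#' @param minRun minimum spikes per burst, default 3.
#' @param minIsi lower floor for the threshold, seconds (default 4 ms).
#' @return a [BurstCalibration-class].
#' @examples
#' pool <- lapply(1:5, function(i) sampleDoublyStochastic(
#'   makeSchedule("constant", list(rateMean = 20, shape = 2, t0 = -0.5,
#'                                 duration = 1)), 30, seed = i))
#' calibrateBursts(pool, c(-0.5, 0))
#' @export
calibrateBursts <- function(ensembles, spontaneousWindow, percentile = 0.05,
                            minRun = 3L, minIsi = 0.004) {
  if (is(ensembles, "TrialEnsemble")) ensembles <- list(ensembles)
  isis <- unlist(lapply(ensembles, function(e) {
    unlist(lapply(e@trials, function(s) {
      diff(s[s >= spontaneousWindow[1] & s < spontaneousWindow[2]])
    }))
  }))
  if (length(isis) < 100L)
    stop(sprintf("only %d pooled spontaneous ISIs (< 100); cannot calibrate",
                 length(isis)))
  thr <- max(quantile(isis, percentile, names = FALSE), minIsi)
  cal <- new("BurstCalibration", isiThreshold = thr,
             minRun = as.integer(minRun), baselineBps = 0)
  bps <- vapply(ensembles, function(e) {
    bursts_per_spike(e, cal, spontaneousWindow)
  }, 0)
  cal@baselineBps <- mean(bps, na.rm = TRUE)
  cal
}

#' Detect bursts in one spike train
#'
#' A burst is a maximal run of at least \code{minRun} spikes whose
#' consecutive ISIs are all at or below the calibrated threshold. Detection
#' is deterministic given the input and the calibration.
#'
#' @param spikeTimes strictly increasing spike times, seconds.
#' @param calibration a [BurstCalibration-class].
#' @param window optional half-open window restricting detection.
#' @return data.frame of burst events with columns \code{start_s},
#'   \code{n_spikes} (zero rows when none).
#' @examples
#' cal <- new("BurstCalibration", isiThreshold = 0.005, minRun = 3L,
#'            baselineBps = 0)
#' detectBursts(c(0.1, 0.103, 0.106, 0.109, 0.5), cal)
#' @export
detectBursts <- function(spikeTimes, calibration, window = NULL) {
  stopifnot(is(calibration, "BurstCalibration"))
  s <- spikeTimes
  if (!is.null(window)) s <- s[s >= window[1] & s < window[2]]
  if (length(s) < calibration@minRun)
    return(data.frame(start_s = numeric(0), n_spikes = integer(0)))
  fast <- diff(s) <= calibration@isiThreshold
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= (calibration@minRun - 1L)
  data.frame(start_s = s[starts[keep]],
             n_spikes = r$lengths[keep] + 1L)
}

# bursts per spike in a window for one ensemble (pooled over trials)
bursts_per_spike <- function(ensemble, calibration, window) {
  nb <- 0L; ns <- 0L
  for (s in ensemble@trials) {
    sw <- s[s >= window[1] & s < window[2]]
    ns <- ns + length(sw)
    nb <- nb + nrow(detectBursts(sw, calibration))
  }
  if (ns == 0L) NA_real_ else nb / ns
}

#' Sliding-window burst rate
#'
#' Bursts per spike (burst events divided by total spikes, pooled over
#' trials) in a window of width \code{bin} sliding in steps of \code{step}.
#' Windows with fewer than \code{minCount} spikes per trial on average are
#' flagged missing. Standard errors are bootstrap over trials.
#'
#' @param ensemble a [TrialEnsemble-class].
#' @param calibration a [BurstCalibration-class].
#' @param bin,step window width and spacing, seconds.
#' @param minCount missing-data threshold in spikes per bin (default 3).
#' @param baselineAdjust subtract the calibration's baseline bursts/spike
#'   (default \code{FALSE}).
#' @param nBoot bootstrap resamples (default 200).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{center_s}, \code{bursts_per_spike},
#'   \code{bursts_per_spike_sem}, \code{n_spikes}, \code{missing}.
#' @export
burstTimecourse <- function(ensemble, calibration, bin, step, minCount = 3,
                            baselineAdjust = FALSE, nBoot = 200,
                            seed = NULL) {
  stopifnot(is(ensemble, "TrialEnsemble"), is(calibration, "BurstCalibration"))
  win <- ensemble@window
  centers <- seq(win[1] + bin / 2, win[2] - bin / 2 + 1e-9, by = step)
  base <- if (baselineAdjust) calibration@baselineBps else 0
  n <- nTrials(ensemble)
  rows <- lapply(seq_along(centers), function(j) {
    w <- centers[j] + c(-bin, bin) / 2
    nb <- vapply(ensemble@trials, function(s) {
      nrow(detectBursts(s, calibration, w))
    }, 0L)
    ns <- vapply(ensemble@trials, count_in, 0L, w[1], w[2])
    tot <- sum(ns)
    if (mean(ns) < minCount || tot == 0L) {
      return(data.frame(center_s = centers[j], bursts_per_spike = NA_real_,
                        bursts_per_spike_sem = NA_real_, n_spikes = tot,
                        missing = TRUE))
    }
    bps <- sum(nb) / tot - base
    sem <- with_seed(child_seed(seed, j), {
      reps <- vapply(seq_len(nBoot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(ns[idx]) == 0L) NA_real_ else sum(nb[idx]) / sum(ns[idx])
      }, 0)
      sd(reps, na.rm = TRUE)
    })
    data.frame(center_s = centers[j], bursts_per_spike = bps,
               bursts_per_spike_sem = sem, n_spikes = tot, missing = FALSE)
  })
  do.call(rbind, rows)
}
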