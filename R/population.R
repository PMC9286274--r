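#' Classify a unit's response polarity
#'
#' Paired t-test on per-trial spike counts in a pre-stimulus versus a
#' post-stimulus window (counts are rate-normalized by window length so
#' unequal windows compare fairly): \code{"excited"} when the rate
#' increases at \code{p < alpha}, \code{"inhibited"} when it decreases at
#' \code{p < alpha}, otherwise \code{"null"}. Degenerate inputs
#' (zero-variance differences) return \code{"null"} with a warning.
#'
#' @param ensemble a [TrialEnsemble-class] with at least 5 trials.
#' @param preWindow,postWindow half-open comparison windows.
#' @param alpha significance level (default 0.05).
#' @return one of \code{"excited"}, \code{"null"}, \code{"inhibited"},
#'   with attributes \code{p.value} and \code{meanDiff} (Hz).
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("custom", list(
#'   rateFn = function(t, d) ifelse(t < 0, 10, 30),
#'   shapeFn = function(t) rep(1, length(t)),
#'   drawFn = function(n) rep(list(list()), n),
#'   duration = 1, t0 = -0.5)), 30, seed = 1)
#' classifyResponse(ens, c(-0.5, 0), c(0, 0.5))
#' @export
classifyResponse <- function(ensemble, preWindow, postWindow, alpha = 0.05) {
  stopifnot(is(ensemble, "TrialEnsemble"))
  if (nTrials(ensemble) < 5L) stop("need at least 5 trials")
  pre <- vapply(ensemble@trials, count_in, 0L, preWindow[1], preWindow[2]) /
    diff(preWindow)
  post <- vapply(ensemble@trials, count_in, 0L, postWindow[1], postWindow[2]) /
    diff(postWindow)
  d <- post - pre
  if (sd(d) == 0) {
    sv_warn("zero-variance pre/post differences; classified as null")
    return(structure("null", p.value = NA_real_, meanDiff = mean(d)))
  }
  tt <- t.test(post, pre, paired = TRUE)
  label <- if (tt$p.value < alpha) {
    if (mean(d) > 0) "excited" else "inhibited"
  } else "null"
  structure(label, p.value = tt$p.value, meanDiff = mean(d))
}

#' Mean matching: per-time-bin unit selection with a common rate
#' distribution
#'
#' Greedy histogram matching in the spirit of the mean-matched Fano factor:
#' the target rate histogram is the pointwise minimum, across time bins, of
#' the per-bin firing-rate histograms; at every time bin units are randomly
#' discarded per histogram cell until the cell occupancy matches the
#' target. Repeating with different random discards (\code{nRepeats})
#' averages out the selection noise in downstream metrics.
#'
#' @param collection list of [TrialEnsemble-class] objects sharing a
#'   window (\eqn{\ge} 10 units).
#' @param binCenters time-bin centers, seconds.
#' @param bin time-bin width, seconds.
#' @param histBreaks rate-histogram cell width in Hz (default 2) or an
#'   explicit vector of break points.
#' @param nRepeats number of random selections (default 10).
#' @param seed optional integer seed.
#' @return list with \code{masks}: a list of \code{nRepeats} logical
#'   matrices (units x bins, \code{TRUE} = retained), \code{rates}: the
#'   units x bins mean-rate matrix, and \code{target}: the target
#'   histogram counts.
#' @export
meanMatch <- function(collection, binCenters, bin, histBreaks = 2,
                      nRepeats = 10, seed = NULL) {
  if (length(collection) < 10L) stop("need at least 10 units")
  rates <- vapply(collection, function(e) {
    vapply(binCenters, function(ct) {
      mean(vapply(e@trials, count_in, 0L, ct - bin / 2, ct + bin / 2)) / bin
    }, 0)
  }, numeric(length(binCenters)))
  rates <- t(rates)  # units x bins
  breaks <- if (length(histBreaks) == 1L) {
    seq(0, max(rates) + histBreaks, by = histBreaks)
  } else histBreaks
  cells <- matrix(findInterval(rates, breaks, rightmost.closed = TRUE),
                  nrow = nrow(rates))
  nCells <- length(breaks) - 1L
  histPerBin <- vapply(seq_len(ncol(cells)), function(j) {
    tabulate(cells[, j], nbins = nCells)
  }, integer(nCells))
  target <- apply(histPerBin, 1, min)
  if (sum(target) == 0L)
    stop("empty target distribution; use coarser rate-histogram cells")
  masks <- with_seed(seed, lapply(seq_len(nRepeats), function(r) {
    keep <- matrix(FALSE, nrow(rates), ncol(rates))
    for (j in seq_len(ncol(rates))) {
      for (cell in which(target > 0L)) {
        members <- which(cells[, j] == cell)
        pick <- members[sample.int(length(members), target[cell])]
        keep[pick, j] <- TRUE
      }
    }
    keep
  }))
  list(masks = masks, rates = rates, target = target)
}

#' Aggregate per-unit variability time courses
#'
#' Unweighted mean and standard error across units, per metric and per
#' window center, ignoring missing entries. Units whose overall mean count
#' per bin falls below \code{minCount} are excluded entirely (a message
#' reports how many).
#'
#' @param timecourses list of [VariabilityTimecourse-class] objects with
#'   identical centers (one per unit).
#' @param minCount exclusion threshold in mean spikes per bin (default 3).
#' @param mask optional logical matrix (units x centers) from
#'   [meanMatch()]; \code{FALSE} entries are dropped from the average.
#' @return data.frame with one row per center: per-metric population mean
#'   and sem (columns \code{ff}, \code{n_psi}, \code{n_rv},
#'   \code{cv_local2}, \code{mean_rate_hz} and \code{*_sem}), plus
#'   \code{n_units}.
#' @export
aggregateTimecourses <- function(timecourses, minCount = 3, mask = NULL) {
  stopifnot(length(timecourses) >= 1L)
  tabs <- lapply(timecourses, as.data.frame)
  centers <- tabs[[1]]$center_s
  for (tb in tabs) {
    if (length(tb$center_s) != length(centers) ||
        any(abs(tb$center_s - centers) > 1e-9))
      stop("time courses must share aligned centers")
  }
  bin <- timecourses[[1]]@bin
  unitMean <- vapply(tabs, function(tb) {
    mean(tb$mean_rate_hz, na.rm = TRUE) * bin
  }, 0)
  keepUnit <- unitMean >= minCount
  if (any(!keepUnit))
    message(sprintf("excluding %d unit(s) with < %g spikes/bin on average",
                    sum(!keepUnit), minCount))
  if (!any(keepUnit)) stop("no unit passes the exclusion threshold")
  tabs <- tabs[keepUnit]
  if (!is.null(mask)) mask <- mask[keepUnit, , drop = FALSE]
  metrics <- c("ff", "n_psi", "n_rv", "cv_local2", "mean_rate_hz")
  out <- data.frame(center_s = centers)
  for (mname in metrics) {
    m <- vapply(tabs, function(tb) tb[[mname]], numeric(length(centers)))
    m <- matrix(m, nrow = length(centers))
    if (!is.null(mask)) m[t(!mask)] <- NA_real_
    out[[mname]] <- rowMeans(m, na.rm = TRUE)
    out[[paste0(mname, "_sem")]] <- apply(m, 1, function(x) {
      x <- x[is.finite(x)]
      if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
    })
  }
  out$n_units <- length(tabs)
  out
}
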