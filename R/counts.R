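#' Spike counts per trial and window
#'
#' Counts spikes per trial in a set of half-open windows \eqn{[t, t + T)}.
#'
#' @param ensemble a [TrialEnsemble-class].
#' @param windows numeric matrix (or coercible) with two columns, the left
#'   and right edges of each counting window; all windows must lie inside
#'   the ensemble window.
#' @return integer matrix, trials in rows and windows in columns, with the
#'   window edges attached as attribute \code{"windows"}.
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 10)), nTrials = 5, seed = 1)
#' spikeCounts(ens, rbind(c(0, 0.5), c(0.5, 1)))
#' @export
spikeCounts <- function(ensemble, windows) {
  stopifnot(is(ensemble, "TrialEnsemble"))
  windows <- matrix(as.numeric(windows), ncol = 2)
  if (any(windows[, 2] <= windows[, 1]))
    stop("window widths must be positive")
  ew <- ensemble@window
  if (any(windows[, 1] < ew[1] - 1e-12) || any(windows[, 2] > ew[2] + 1e-12))
    stop("counting windows must lie inside the ensemble window")
  counts <- vapply(seq_len(nrow(windows)), function(j) {
    vapply(ensemble@trials, count_in, 0L, windows[j, 1], windows[j, 2])
  }, integer(length(ensemble@trials)))
  counts <- matrix(counts, nrow = length(ensemble@trials))
  attr(counts, "windows") <- windows
  counts
}

#' Fano factor versus counting-window width
#'
#' Computes the across-trial Fano factor \eqn{FF(T) = Var(N_T)/E[N_T]} for
#' nested half-open windows \eqn{[anchor, anchor + T)} over a grid of
#' widths, with a bootstrap-over-trials standard error. Widths at which the
#' mean count is zero are flagged \code{NA} rather than raising an error.
#'
#' @param ensemble a [TrialEnsemble-class] with at least 2 trials.
#' @param anchorTime left edge of all windows, seconds.
#' @param Tgrid strictly increasing vector of window widths, seconds;
#'   \code{anchorTime + max(Tgrid)} must lie inside the ensemble window.
#' @param nBoot bootstrap resamples for the standard error (default 500).
#' @param seed optional integer seed for the bootstrap.
#' @return a [FanoCurve-class].
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 10)), nTrials = 200, seed = 1)
#' fanoVsBinsize(ens, 0, seq(0.1, 1, by = 0.1))
#' @export
fanoVsBinsize <- function(ensemble, anchorTime, Tgrid, nBoot = 500,
                          seed = NULL) {
  stopifnot(is(ensemble, "TrialEnsemble"))
  if (nTrials(ensemble) < 2L) stop("need at least 2 trials")
  Tgrid <- sort(as.numeric(Tgrid))
  counts <- spikeCounts(ensemble, cbind(anchorTime, anchorTime + Tgrid))
  mc <- colMeans(counts)
  vc <- col_var(counts)
  ff <- ifelse(mc > 0, vc / mc, NA_real_)
  sem <- with_seed(seed, boot_stat(counts, function(m) {
    mm <- colMeans(m)
    ifelse(mm > 0, col_var(m) / mm, NA_real_)
  }, nBoot))
  new("FanoCurve", Tgrid = Tgrid, ff = ff, ffSem = sem, meanCount = mc,
      anchorTime = as.numeric(anchorTime), nTrials = nTrials(ensemble))
}

# Bootstrap over rows (trials): sd of a column-wise statistic.
boot_stat <- function(counts, stat, nBoot) {
  n <- nrow(counts)
  reps <- vapply(seq_len(nBoot), function(b) {
    stat(counts[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }, numeric(length(stat(counts))))
  if (is.null(dim(reps))) sd(reps, na.rm = TRUE)
  else apply(reps, 1, sd, na.rm = TRUE)
}
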