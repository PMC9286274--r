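#' Sub-bin (Vinci-style) estimator of EVC and nPsi
#'
#' Estimates the expected conditional count variance
#' \eqn{EVC = E[Var(N_T | \gamma_i)]} from a single realization per trial by
#' splitting the counting window into equal sub-bins and using the
#' within-trial variance of sub-bin counts, which is blind to between-trial
#' rate variability. Two refinements remove the dominant biases of the raw
#' sub-bin variance:
#' \itemize{
#'   \item sub-bin counts are column-centered (the across-trial mean of each
#'     sub-bin is subtracted) so that a shared within-window rate modulation
#'     does not inflate the estimate;
#'   \item the statistic is computed at \code{m} and \code{2m} sub-bins and
#'     extrapolated linearly in the reciprocal sub-bin width, cancelling the
#'     \eqn{O(1/(\lambda w))} short-window bias of renewal counting
#'     statistics.
#' }
#' \eqn{n\Psi} is the EVC normalized by the mean count.
#'
#' @param ensemble a [TrialEnsemble-class].
#' @param window half-open counting window (defaults to the full ensemble
#'   window).
#' @param mSubbins number of (coarse) sub-bins; default
#'   \code{max(2, min(10, floor(meanCount / 4)))}.
#' @param minCount minimum mean count per window (default 3); below it the
#'   estimate is flagged missing (\code{NA}).
#' @param floorAtZero floor negative estimates at 0 with a warning
#'   (default \code{TRUE}).
#' @return list with \code{evc}, \code{nPsi}, \code{mSubbins},
#'   \code{meanCount}.
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 10, rateSd = 2, shape = 2)), nTrials = 500, seed = 1)
#' vinciNpsi(ens, c(0, 1))$nPsi  # close to 0.5 despite rate variability
#' @export
vinciNpsi <- function(ensemble, window = NULL, mSubbins = NULL,
                      minCount = 3, floorAtZero = TRUE) {
  stopifnot(is(ensemble, "TrialEnsemble"))
  if (is.null(window)) window <- ensemble@window
  fine <- subbin_counts(ensemble, window, mSubbins)
  res <- vinci_core(fine)
  if (res$meanCount < minCount) {
    sv_warn(sprintf("mean count %.2f < %g; nPsi flagged missing",
                    res$meanCount, minCount))
    return(list(evc = NA_real_, nPsi = NA_real_, mSubbins = res$m,
                meanCount = res$meanCount))
  }
  nPsi <- res$nPsi
  if (floorAtZero && !is.na(nPsi) && nPsi < 0) {
    sv_warn(sprintf("nPsi estimate %.3f floored at 0", nPsi))
    nPsi <- 0
  }
  list(evc = nPsi * res$meanCount, nPsi = nPsi, mSubbins = res$m,
       meanCount = res$meanCount)
}

# Sub-bin count matrix at 2m sub-bins (fine scale), m chosen from the data
# unless supplied. Attribute "m" carries the coarse sub-bin count.
subbin_counts <- function(ensemble, window, mSubbins = NULL) {
  N <- vapply(ensemble@trials, count_in, 0L, window[1], window[2])
  m <- if (is.null(mSubbins)) max(2L, min(10L, floor(mean(N) / 4)))
  else as.integer(mSubbins)
  if (m < 2L) stop("mSubbins must be >= 2")
  edges <- seq(window[1], window[2], length.out = 2L * m + 1L)
  fine <- t(vapply(ensemble@trials, function(s) {
    s <- s[s >= window[1] & s < window[2]]
    tabulate(findInterval(s, edges), nbins = 2L * m)
  }, integer(2L * m)))
  attr(fine, "m") <- m
  fine
}

# Core statistic on a fine-scale (2m columns) sub-bin count matrix:
# column-centered per-trial variance at m and 2m sub-bins, extrapolated
# linearly in 1/width. Returns the raw (unfloored) nPsi.
vinci_core <- function(fine) {
  m <- attr(fine, "m")
  coarse <- fine[, seq(1, 2 * m, by = 2), drop = FALSE] +
    fine[, seq(2, 2 * m, by = 2), drop = FALSE]
  N <- rowSums(fine)
  meanN <- mean(N)
  if (meanN <= 0) return(list(nPsi = NA_real_, meanCount = 0, m = m))
  ffhat <- function(cm) {
    cc <- sweep(cm, 2, colMeans(cm))
    ncol(cm) * mean(row_var(cc)) / meanN
  }
  list(nPsi = 2 * ffhat(coarse) - ffhat(fine), meanCount = meanN, m = m)
}

#' Fano-factor-asymptote (FFA) fit
#'
#' Fits a weighted least-squares line to the linear zone of a
#' [FanoCurve-class]: the Fano factor of a doubly stochastic renewal process
#' is asymptotically linear in the window width \eqn{T}, with intercept
#' \eqn{n\Psi} and slope \eqn{nRV}. The linear zone is the largest
#' contiguous upper range of the width grid whose mean count is at least
#' \code{minCount} (default 5 spikes per window). Weights are
#' \eqn{1/sem^2}. Negative intercepts and slopes are floored at 0 with a
#' warning.
#'
#' @param curve a [FanoCurve-class].
#' @param minCount minimum mean count defining the linear zone.
#' @return a [DecompositionEstimate-class] with \code{method = "ffa"} and
#'   \code{binWidth} equal to the largest usable width; \code{cvLocal2} and
#'   \code{meanRate} are \code{NA} (they are filled by [decompose()]).
#'   Fewer than 3 usable grid points gives \code{NA} estimates with a
#'   warning.
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 10, shape = 2)), nTrials = 500, seed = 1)
#' ffaFit(fanoVsBinsize(ens, 0, seq(0.2, 2, by = 0.2), seed = 1))
#' @export
ffaFit <- function(curve, minCount = 5) {
  stopifnot(is(curve, "FanoCurve"))
  fit <- ffa_core(curve@Tgrid, curve@ff, curve@ffSem, curve@meanCount,
                  minCount)
  if (is.na(fit$nPsi)) {
    sv_warn("fewer than 3 usable grid points in the linear zone; FFA unavailable")
    return(new("DecompositionEstimate", nPsi = NA_real_, nRV = NA_real_,
               ff = NA_real_, cvLocal2 = NA_real_, meanRate = NA_real_,
               sem = c(nPsi = NA_real_, nRV = NA_real_), method = "ffa",
               binWidth = max(curve@Tgrid)))
  }
  nPsi <- fit$nPsi; nRV <- fit$nRV
  if (nPsi < 0) {
    sv_warn(sprintf("FFA intercept %.3f floored at 0", nPsi)); nPsi <- 0
  }
  if (nRV < 0) {
    sv_warn(sprintf("FFA slope %.3f floored at 0", nRV)); nRV <- 0
  }
  new("DecompositionEstimate", nPsi = nPsi, nRV = nRV,
      ff = fit$nPsi + fit$Tmax * fit$nRV, cvLocal2 = NA_real_,
      meanRate = NA_real_,
      sem = c(nPsi = fit$semPsi, nRV = fit$semRv), method = "ffa",
      binWidth = fit$Tmax)
}

# Weighted LS line over the largest contiguous upper range with
# meanCount >= minCount; returns unfloored intercept/slope.
ffa_core <- function(Tgrid, ff, sem, meanCount, minCount) {
  ok <- is.finite(ff) & meanCount >= minCount
  # largest contiguous upper range
  idx <- length(ok)
  while (idx >= 1L && ok[idx]) idx <- idx - 1L
  use <- if (idx < length(ok)) seq(idx + 1L, length(ok)) else integer(0)
  if (length(use) < 3L)
    return(list(nPsi = NA_real_, nRV = NA_real_, semPsi = NA_real_,
                semRv = NA_real_, Tmax = max(Tgrid)))
  x <- Tgrid[use]; y <- ff[use]
  w <- 1 / sem[use]^2
  w[!is.finite(w)] <- max(w[is.finite(w)], 1)
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  cf <- fit$coefficients
  # WLS covariance (sems treated as known up to scale)
  XtWX <- crossprod(cbind(1, x) * sqrt(w))
  s2 <- sum(w * fit$residuals^2) / max(1, length(use) - 2)
  vc <- s2 * solve(XtWX)
  list(nPsi = unname(cf[1]), nRV = unname(cf[2]), semPsi = sqrt(vc[1, 1]),
       semRv = sqrt(vc[2, 2]), Tmax = max(x))
}

#' Rate variability from the Fano decomposition identity
#'
#' Solves \eqn{FF = n\Psi + T \cdot nRV} for \eqn{nRV}: the between-trial
#' rate variability in 1/s is \eqn{(FF - n\Psi)/T}, floored at 0 with a
#' warning when negative (both components are variances of non-negative
#' origin).
#'
#' @param ff Fano factor of the counting window.
#' @param nPsi spiking-irregularity estimate for the same window.
#' @param T window width in seconds (> 0).
#' @param floorAtZero floor negative values at 0 (default \code{TRUE}).
#' @return nRV in 1/s.
#' @examples
#' nrvFromFano(1.1, 0.5, 0.3)  # 2
#' @export
nrvFromFano <- function(ff, nPsi, T, floorAtZero = TRUE) {
  stopifnot_scalar_pos(T, "T")
  out <- (ff - nPsi) / T
  if (floorAtZero && !is.na(out) && out < 0) {
    sv_warn(sprintf("nRV estimate %.3f 1/s floored at 0", out))
    out <- 0
  }
  out
}

#' Single-window decomposition of spike-count variability
#'
#' Computes, for one counting window: the Fano factor, the spiking
#' irregularity \eqn{n\Psi} (by the sub-bin \code{"vinci"} estimator or the
#' \code{"ffa"} line fit within the window), the rate variability
#' \eqn{nRV = (FF - n\Psi)/T}, the CV2-based nPPV estimate and the mean
#' rate, each with a bootstrap-over-trials standard error.
#'
#' @param ensemble a [TrialEnsemble-class].
#' @param window half-open counting window (defaults to the full ensemble
#'   window).
#' @param method \code{"vinci"} (default) or \code{"ffa"}.
#' @param minCount minimum mean count; below it the estimates are flagged
#'   missing.
#' @param nBoot bootstrap resamples for the standard errors (default 200).
#' @param seed optional integer seed for the bootstrap.
#' @param nFfaGrid number of nested widths used by the within-window FFA
#'   fit (default 12).
#' @param minCountFfa linear-zone threshold for the FFA fit (default 5).
#' @return a [DecompositionEstimate-class].
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 10, rateSd = 2, shape = 2)), nTrials = 500, seed = 1)
#' decompose(ens, c(0, 1), seed = 1)
#' @export
decompose <- function(ensemble, window = NULL,
                      method = c("vinci", "ffa"), minCount = 3,
                      nBoot = 200, seed = NULL, nFfaGrid = 12,
                      minCountFfa = 5) {
  method <- match.arg(method)
  stopifnot(is(ensemble, "TrialEnsemble"))
  if (is.null(window)) window <- ensemble@window
  T <- diff(window)
  prep <- decomp_prep(ensemble, window, method, nFfaGrid)
  est <- decomp_stat(prep, seq_len(prep$n), method, minCountFfa)
  if (est["meanN"] < minCount) {
    sv_warn(sprintf("mean count %.2f < %g; window flagged missing",
                    est["meanN"], minCount))
    return(new("DecompositionEstimate", nPsi = NA_real_, nRV = NA_real_,
               ff = NA_real_, cvLocal2 = NA_real_,
               meanRate = as.numeric(est["meanN"]) / T,
               sem = c(ff = NA_real_, nPsi = NA_real_, nRV = NA_real_,
                       cvLocal2 = NA_real_, meanRate = NA_real_),
               method = method, binWidth = T))
  }
  sems <- with_seed(seed, {
    reps <- vapply(seq_len(nBoot), function(b) {
      decomp_stat(prep, sample.int(prep$n, prep$n, replace = TRUE),
                  method, minCountFfa)
    }, est)
    apply(reps, 1, sd, na.rm = TRUE)
  })
  nPsi <- as.numeric(est["nPsi"]); nRV <- as.numeric(est["nRV"])
  if (!is.na(nPsi) && nPsi < 0) {
    sv_warn(sprintf("nPsi estimate %.3f floored at 0", nPsi)); nPsi <- 0
  }
  if (!is.na(nRV) && nRV < 0) {
    sv_warn(sprintf("nRV estimate %.3f 1/s floored at 0", nRV)); nRV <- 0
  }
  new("DecompositionEstimate", nPsi = nPsi, nRV = nRV,
      ff = as.numeric(est["ff"]), cvLocal2 = as.numeric(est["cvl2"]),
      meanRate = as.numeric(est["meanN"]) / T,
      sem = c(ff = sems[["ff"]], nPsi = sems[["nPsi"]], nRV = sems[["nRV"]],
              cvLocal2 = sems[["cvl2"]], meanRate = sems[["meanN"]] / T),
      method = method, binWidth = T)
}

# Precompute per-trial quantities for one window so the bootstrap is pure
# matrix work.
decomp_prep <- function(ensemble, window, method, nFfaGrid) {
  n <- nTrials(ensemble)
  fine <- subbin_counts(ensemble, window, NULL)
  cv2 <- lapply(ensemble@trials, cv2Sequence, window = window)
  prep <- list(n = n, T = diff(window), fine = fine,
               cv2sum = vapply(cv2, sum, 0), cv2n = vapply(cv2, length, 0L))
  if (method == "ffa") {
    Tgrid <- diff(window) * seq_len(nFfaGrid) / nFfaGrid
    prep$ffaCounts <- spikeCounts(ensemble, cbind(window[1], window[1] + Tgrid))
    prep$Tgrid <- Tgrid
    # fixed weights for the WLS fit, from a small internal bootstrap
    prep$ffaSem <- boot_stat(prep$ffaCounts, function(m) {
      mm <- colMeans(m); ifelse(mm > 0, col_var(m) / mm, NA_real_)
    }, 100L)
  }
  prep
}

decomp_stat <- function(prep, idx, method, minCountFfa) {
  fine <- prep$fine[idx, , drop = FALSE]
  attr(fine, "m") <- attr(prep$fine, "m")
  N <- rowSums(fine)
  meanN <- mean(N)
  ff <- if (meanN > 0) var(N) / meanN else NA_real_
  nPsi <- if (method == "vinci") {
    vinci_core(fine)$nPsi
  } else {
    cnt <- prep$ffaCounts[idx, , drop = FALSE]
    mm <- colMeans(cnt)
    ffg <- ifelse(mm > 0, col_var(cnt) / mm, NA_real_)
    ffa_core(prep$Tgrid, ffg, prep$ffaSem, mm, minCountFfa)$nPsi
  }
  nRV <- if (!is.na(ff) && !is.na(nPsi)) (ff - nPsi) / prep$T else NA_real_
  npairs <- sum(prep$cv2n[idx])
  cvl2 <- if (npairs >= 10) {
    1 / gamma_cv2_inverse(sum(prep$cv2sum[idx]) / npairs)$kappa
  } else NA_real_
  c(ff = ff, nPsi = nPsi, nRV = nRV, cvl2 = cvl2, meanN = meanN)
}

#' Sliding-window variability time course
#'
#' Applies [decompose()] in a window of width \code{bin} sliding in steps of
#' \code{step} across the ensemble window. Centers whose mean count falls
#' below \code{minCount} (default 3 spikes per bin) are reported missing
#' rather than interpolated. Negative nPsi/nRV values are floored at 0; one
#' aggregate warning reports how many windows were floored.
#'
#' @param ensemble a [TrialEnsemble-class].
#' @param bin window width, seconds.
#' @param step center spacing, seconds.
#' @param method \code{"vinci"} (default) or \code{"ffa"}.
#' @param minCount missing-data threshold in spikes per bin.
#' @param nBoot bootstrap resamples per center.
#' @param seed optional integer seed.
#' @return a [VariabilityTimecourse-class].
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 20, shape = 2)), nTrials = 100, seed = 1)
#' slidingDecomposition(ens, bin = 0.3, step = 0.1, nBoot = 50, seed = 1)
#' @export
slidingDecomposition <- function(ensemble, bin, step,
                                 method = c("vinci", "ffa"), minCount = 3,
                                 nBoot = 200, seed = NULL) {
  method <- match.arg(method)
  stopifnot(is(ensemble, "TrialEnsemble"))
  win <- ensemble@window
  if (bin > diff(win)) stop("bin must not exceed the ensemble window")
  stopifnot_scalar_pos(step, "step")
  centers <- seq(win[1] + bin / 2, win[2] - bin / 2 + 1e-9, by = step)
  floored <- 0L
  rows <- lapply(seq_along(centers), function(j) {
    w <- centers[j] + c(-bin, bin) / 2
    est <- withCallingHandlers(
      decompose(ensemble, w, method = method, minCount = minCount,
                nBoot = nBoot, seed = child_seed(seed, j)),
      spikevar_warning = function(cond) {
        if (grepl("floored", conditionMessage(cond)))
          floored <<- floored + 1L
        invokeRestart("muffleWarning")
      })
    nvalid <- sum(vapply(ensemble@trials, count_in, 0L, w[1], w[2]) > 0L)
    data.frame(center_s = centers[j], ff = est@ff, n_psi = est@nPsi,
               n_rv = est@nRV, cv_local2 = est@cvLocal2,
               mean_rate_hz = est@meanRate,
               ff_sem = est@sem[["ff"]], n_psi_sem = est@sem[["nPsi"]],
               n_rv_sem = est@sem[["nRV"]],
               cv_local2_sem = est@sem[["cvLocal2"]],
               mean_rate_hz_sem = est@sem[["meanRate"]],
               n_valid_trials = nvalid, missing = is.na(est@nPsi))
  })
  if (floored > 0L)
    sv_warn(sprintf("negative nPsi/nRV floored at 0 in %d window(s)", floored))
  new("VariabilityTimecourse", table = do.call(rbind, rows), bin = bin,
      step = step, method = method)
}

#' Empirical ground-truth decomposition for a simulated schedule
#'
#' The oracle against which the single-realization estimators are judged:
#' draws \code{K} per-trial parameter sets from the schedule, generates
#' \code{R} realizations of each, and computes the two terms of the law of
#' total variance directly -- \eqn{EVC} as the mean over parameter draws of
#' the count variance across realizations, and \eqn{VEC} as the variance
#' over draws of the mean count. \eqn{n\Psi = EVC/\langle N\rangle} and
#' \eqn{nRV = VEC/(T \langle N\rangle)}.
#'
#' @param schedule a [TrialSchedule-class].
#' @param R realizations per parameter draw (default 100).
#' @param K parameter draws (default 100).
#' @param T counting-window width, seconds.
#' @param anchors left window edges (default: the schedule start); several
#'   anchors give a time course on shared draws.
#' @param perturbations optional [perturbationSpec()]; rate perturbations
#'   become part of the per-draw parameters, bursts are applied per
#'   realization (they are point-process variability).
#' @param seed optional integer seed.
#' @param dt integration step for inhomogeneous sampling.
#' @return data.frame with one row per anchor: \code{anchor_s},
#'   \code{mean_count}, \code{evc}, \code{vec}, \code{n_psi}, \code{n_rv}.
#' @examples
#' emp <- empiricalDecomposition(makeSchedule("constant",
#'   list(rateMean = 10, rateSd = 2)), R = 50, K = 50, T = 1, seed = 1)
#' @export
empiricalDecomposition <- function(schedule, R = 100, K = 100, T,
                                   anchors = NULL, perturbations = NULL,
                                   seed = NULL, dt = 1e-3) {
  stopifnot(is(schedule, "TrialSchedule"))
  if (R < 2 || K < 2) stop("R and K must be at least 2")
  stopifnot_scalar_pos(T, "T")
  sch <- apply_rate_perturbations(schedule, perturbations)
  if (is.null(anchors)) anchors <- sch@t0
  if (any(anchors < sch@t0 - 1e-12) ||
      any(anchors + T > sch@t0 + sch@duration + 1e-12))
    stop("anchors + T must lie inside the schedule window")
  burst <- perturbations$burst
  win <- c(sch@t0, sch@t0 + sch@duration)
  with_seed(seed, {
    draws <- sch@drawFn(K)
    mu <- matrix(0, K, length(anchors))  # per-draw mean count
    v <- matrix(0, K, length(anchors))   # per-draw count variance
    for (i in seq_len(K)) {
      cnt <- matrix(0L, R, length(anchors))
      for (r in seq_len(R)) {
        s <- sample_given_draw(sch, draws[[i]], dt = dt)
        if (!is.null(burst) && length(s))
          s <- injectBursts(s, burst$pBurst, burst$nSpikes, burst$intraIsi,
                            window = win)
        cnt[r, ] <- vapply(anchors, function(a) count_in(s, a, a + T), 0L)
      }
      mu[i, ] <- colMeans(cnt)
      v[i, ] <- col_var(cnt)
    }
    evc <- colMeans(v)
    vec <- col_var(mu)
    meanN <- colMeans(mu)
    data.frame(anchor_s = anchors, mean_count = meanN, evc = evc, vec = vec,
               n_psi = ifelse(meanN > 0, evc / meanN, NA_real_),
               n_rv = ifelse(meanN > 0, vec / (T * meanN), NA_real_))
  })
}

#' Closed-form renewal-limit decomposition
#'
#' The large-window limits for a doubly stochastic renewal process whose
#' per-trial rate \eqn{\lambda_i} varies across trials at fixed ISI shape:
#' \eqn{n\Psi = E[\lambda_i^3 \sigma_i^2]/E[\lambda_i]} (the ISI CV squared
#' when the shape is fixed) and \eqn{nRV = Var(\lambda_i)/E[\lambda_i]}.
#'
#' @param model an [ISIModel-class].
#' @param rateMean mean of the per-trial rate, Hz.
#' @param rateVar variance of the per-trial rate, Hz^2 (default 0).
#' @return list with \code{nPsi} (dimensionless) and \code{nRV} (1/s).
#'   For the inverse Gaussian family the ISI CV squared depends on the rate
#'   and is evaluated at \code{rateMean}.
#' @examples
#' theoreticalDecomposition(isiModel("gamma", 2), 50, 100)  # 0.5, 2
#' @export
theoreticalDecomposition <- function(model, rateMean, rateVar = 0) {
  stopifnot(is(model, "ISIModel"))
  stopifnot_scalar_pos(rateMean, "rateMean")
  cv2 <- switch(model@family,
    exponential = 1,
    gamma = 1 / model@shape,
    inverse_gaussian = 1 / (rateMean * model@shape))
  list(nPsi = cv2, nRV = rateVar / rateMean)
}

#' VarCE: variance of the conditional expectation with constant phi
#'
#' The comparator method: \eqn{VarCE(w) = Var(N_w) - \phi E[N_w]} with a
#' single constant \eqn{\phi} chosen as the smallest Fano factor across
#' windows, i.e. the largest constant that keeps VarCE non-negative
#' everywhere (the minimum attains exactly 0). Windows with zero mean count
#' are excluded from the \eqn{\phi} minimum and flagged. VarCE assumes a
#' time-constant spiking irregularity; when the true \eqn{n\Psi} varies it
#' misattributes that variation to rate variability.
#'
#' @param ensemble a [TrialEnsemble-class].
#' @param windows two-column matrix of half-open windows (\eqn{\ge} 2 rows).
#' @return list with \code{phi}, \code{varce} (one value per window,
#'   count^2 units), \code{ff} per window, and \code{excluded} (logical per
#'   window).
#' @examples
#' ens <- sampleDoublyStochastic(makeSchedule("constant",
#'   list(rateMean = 10, rateSd = 3)), nTrials = 300, seed = 1)
#' w <- cbind(seq(0, 1.5, 0.5), seq(0.5, 2, 0.5))
#' varce(ens, w)$phi
#' @export
varce <- function(ensemble, windows) {
  windows <- matrix(as.numeric(windows), ncol = 2)
  if (nrow(windows) < 1L) stop("need at least one window")
  counts <- spikeCounts(ensemble, windows)
  mc <- colMeans(counts)
  vc <- col_var(counts)
  ff <- ifelse(mc > 0, vc / mc, NA_real_)
  excluded <- !is.finite(ff)
  if (any(excluded))
    sv_warn(sprintf("%d window(s) with zero mean count excluded from phi",
                    sum(excluded)))
  if (all(excluded)) stop("no window with positive mean count")
  # ties broken by the earliest window (which.min keeps the first minimum)
  phi <- ff[which.min(ifelse(excluded, Inf, ff))]
  list(phi = phi, varce = vc - phi * mc, ff = ff, excluded = excluded)
}
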