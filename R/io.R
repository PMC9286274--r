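#' Write a trial ensemble to CSV with a JSON sidecar
#'
#' Spike times go to a two-column CSV (\code{trial}, \code{spike_time_s};
#' trial indices 0-based, times in seconds at full precision); window,
#' unit id, seed and ground truth go to a JSON sidecar at the same path
#' with extension \code{.json}.
#'
#' @param ensemble a [TrialEnsemble-class].
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @seealso [readEnsemble()]
#' @export
writeEnsemble <- function(ensemble, path) {
  stopifnot(is(ensemble, "TrialEnsemble"))
  n <- vapply(ensemble@trials, length, 0L)
  df <- data.frame(trial = rep(seq_along(ensemble@trials) - 1L, n),
                   spike_time_s = unlist(ensemble@trials, use.names = FALSE))
  utils::write.csv(format(df, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(window = ensemble@window, unit_id = ensemble@unitId,
               seed = ensemble@seed, n_trials = length(ensemble@trials),
               ground_truth = ensemble@groundTruth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]*$", ".json", path)

#' Read a trial ensemble from CSV (+ JSON sidecar)
#'
#' Inverse of [writeEnsemble()]: \code{read} after \code{write} reproduces
#' the spike times bit-for-bit. Empty trials are preserved through the
#' sidecar's trial count. Unsorted times within a trial raise an error
#' naming the trial; a missing sidecar falls back to a window spanning the
#' data with a warning.
#'
#' @param path CSV file path.
#' @return a [TrialEnsemble-class].
#' @export
readEnsemble <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("trial", "spike_time_s") %in% names(df)))
    stop("spike CSV must have columns trial, spike_time_s")
  df <- suppressWarnings(
    data.frame(trial = as.integer(df$trial),
               spike_time_s = as.numeric(df$spike_time_s)))
  bad <- which(!complete.cases(df))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1] + 1L, path))
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
    nT <- meta$n_trials
    window <- as.numeric(unlist(meta$window))
    gt <- if (length(meta$ground_truth)) {
      lapply(meta$ground_truth, function(d) lapply(d, unlist))
    } else list()
    unit <- if (!is.null(meta$unit_id)) meta$unit_id else "unit"
    seed <- if (!is.null(meta$seed) && !is.na(meta$seed))
      as.integer(meta$seed) else NA_integer_
  } else {
    sv_warn("missing sidecar JSON; inferring window from the data")
    nT <- max(df$trial) + 1L
    window <- c(min(df$spike_time_s, 0), max(df$spike_time_s) + 1e-6)
    gt <- list(); unit <- "unit"; seed <- NA_integer_
  }
  trials <- rep(list(numeric(0)), nT)
  if (nrow(df)) {
    split_times <- split(df$spike_time_s, factor(df$trial, levels = 0:(nT - 1L)))
    for (i in seq_len(nT)) {
      s <- as.numeric(split_times[[i]])
      if (length(s) > 1L && any(diff(s) <= 0))
        stop(sprintf("spike times not strictly increasing in trial %d", i - 1L))
      trials[[i]] <- s
    }
  }
  trialEnsemble(trials, window, groundTruth = gt, unitId = unit, seed = seed)
}

#' Read a run configuration (YAML)
#'
#' Configurations round-trip losslessly through [writeRunConfig()]. Keys
#' mirror the estimator arguments: \code{bin_s}, \code{step_s},
#' \code{method}, \code{min_count}, \code{n_boot}, \code{seed}, plus
#' free-form simulation sections.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

#' @rdname readRunConfig
#' @param config named list to serialize.
#' @export
writeRunConfig <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

#' Generate the benchmark fixture suites
#'
#' Writes deterministic (given \code{seed}) synthetic ensembles with
#' ground-truth manifests, covering the validation scenarios used
#' throughout the package:
#' \describe{
#'   \item{\code{benchmark}}{the doubly stochastic gamma process with scheduled
#'     rate-variability collapse and 1/kappa steps.}
#'   \item{\code{validation}}{six ensembles: Poisson, gamma, doubly stochastic
#'     gamma, rate noise, rate switching, bursting.}
#'   \item{\code{accuracy_grid}}{gamma ensembles over trials x rate grid for
#'     consistency checks.}
#'   \item{\code{burst_levels}}{gamma ensembles with graded injected burst
#'     levels for detector recovery.}
#'   \item{\code{net_small}}{a small LIF network ensemble.}
#' }
#'
#' @param suite one of \code{"benchmark"}, \code{"validation"}, \code{"accuracy_grid"},
#'   \code{"burst_levels"}, \code{"net_small"}.
#' @param dir output directory (created if needed).
#' @param seed integer seed (default 1).
#' @param nTrials trials per ensemble (defaults chosen per suite).
#' @return invisible character vector of the CSV paths written; a
#'   \code{manifest.json} in \code{dir} describes each ensemble's ground
#'   truth.
#' @export
makeFixtures <- function(suite = c("benchmark", "validation", "accuracy_grid", "burst_levels",
                                   "net_small"),
                         dir, seed = 1, nTrials = NULL) {
  suite <- match.arg(suite)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  manifest <- list(suite = suite, seed = seed)
  emit <- function(ens, name, truth) {
    p <- file.path(dir, paste0(name, ".csv"))
    writeEnsemble(ens, p)
    paths <<- c(paths, p)
    manifest$ensembles[[name]] <<- truth
  }
  if (suite == "benchmark") {
    n <- if (is.null(nTrials)) 2000L else nTrials
    sch <- makeSchedule("benchmark")
    ens <- sampleDoublyStochastic(sch, n, seed = seed, unitId = "benchmark")
    emit(ens, "benchmark", c(sch@params,
                         list(true_npsi_out = 2, true_npsi_in = 0.25)))
  } else if (suite == "validation") {
    n <- if (is.null(nTrials)) 1000L else nTrials
    base <- list(rateMean = 10, shape = 2, duration = 2)
    cases <- list(
      poisson = list(sch = makeSchedule("constant",
        list(rateMean = 10, shape = 1, duration = 2)), pert = NULL,
        true_npsi = 1, true_nrv = 0),
      gamma = list(sch = makeSchedule("constant", base), pert = NULL,
        true_npsi = 0.5, true_nrv = 0),
      doubly_stochastic = list(sch = makeSchedule("constant",
        c(base, list(rateSd = 2))), pert = NULL,
        true_npsi = 0.5, true_nrv = 0.4),
      rate_noise = list(sch = makeSchedule("rate_noise",
        c(base, list(dt = 0.05))), pert = NULL,
        true_npsi = 0.5, true_nrv = NA),
      rate_switching = list(sch = makeSchedule("rate_switching",
        list(rateMean = 10, shape = 2, duration = 2)), pert = NULL,
        true_npsi = 0.5, true_nrv = NA),
      bursting = list(sch = makeSchedule("constant", base),
        pert = perturbationSpec(burst = list(pBurst = 0.05, nSpikes = 5L,
                                             intraIsi = 0.003)),
        true_npsi = NA, true_nrv = 0))
    for (nm in names(cases)) {
      cs <- cases[[nm]]
      ens <- sampleDoublyStochastic(cs$sch, n, perturbations = cs$pert,
                                    seed = child_seed(seed, match(nm, names(cases))),
                                    unitId = nm)
      emit(ens, nm, list(params = cs$sch@params, true_npsi = cs$true_npsi,
                         true_nrv = cs$true_nrv))
    }
  } else if (suite == "accuracy_grid") {
    trialsGrid <- c(50L, 200L, 1000L)
    rateGrid <- c(3, 10, 30)  # mean spikes in a 1 s bin
    k <- 0L
    for (nt in trialsGrid) for (r in rateGrid) {
      k <- k + 1L
      sch <- makeSchedule("constant",
        list(rateMean = r, rateSd = r / 5, shape = 2, duration = 1))
      ens <- sampleDoublyStochastic(sch, nt, seed = child_seed(seed, k),
                                    unitId = sprintf("g_t%d_r%g", nt, r))
      emit(ens, sprintf("grid_t%d_r%g", nt, r),
           list(n_trials = nt, rate = r, true_npsi = 0.5,
                true_nrv = (r / 5)^2 / r))
    }
  } else if (suite == "burst_levels") {
    n <- if (is.null(nTrials)) 200L else nTrials
    levels <- c(0, 0.02, 0.05, 0.1, 0.2)
    sch <- makeSchedule("constant",
      list(rateMean = 20, shape = 2, t0 = -0.5, duration = 1.5))
    for (j in seq_along(levels)) {
      pert <- if (levels[j] > 0)
        perturbationSpec(burst = list(pBurst = levels[j], nSpikes = 5L,
                                      intraIsi = 0.003)) else NULL
      ens <- sampleDoublyStochastic(sch, n, perturbations = pert,
                                    seed = child_seed(seed, j),
                                    unitId = sprintf("burst_p%g", levels[j]))
      emit(ens, sprintf("burst_p%03.0f", 1000 * levels[j]),
           list(p_burst = levels[j], n_spikes = 5, intra_isi_s = 0.003))
    }
  } else {  # net_small
    n <- if (is.null(nTrials)) 100L else nTrials
    sp <- networkSpec()
    ens <- simulateNetworkEnsemble(sp, lifParams(), n, seed = seed)
    emit(ens, "lif_balanced", list(n_e = sp@nE, n_i = sp@nI,
                                   rate_mean = sp@rateMean))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
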