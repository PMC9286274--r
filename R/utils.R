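# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state when `seed` is non-NULL, restoring
# the caller's RNG afterwards; with seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer or NULL")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed, stable across platforms and kept
# below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1103 * k) %% 2147483647)
}

# Package warnings carry a condition class so callers (and the CLI log) can
# collect them without pattern matching.
sv_warn <- function(msg, class = "spikevar_warning") {
  warning(warningCondition(msg, class = c(class, "spikevar_warning")))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("%s must be a single positive number", name))
}

# Laplace(mu, sd) sampler: difference of two exponentials with scale b where
# sd = b * sqrt(2).
rlaplace <- function(n, mu = 0, sd = 1) {
  b <- sd / sqrt(2)
  mu + rexp(n, rate = 1 / b) - rexp(n, rate = 1 / b)
}

# Half-open count of spikes in [t0, t1).
count_in <- function(spikes, t0, t1) sum(spikes >= t0 & spikes < t1)

# Column variance of a matrix (rows = resamples), without apply overhead.
col_var <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - colSums(m)^2 / n) / (n - 1)
}

# Per-row sample variance of a matrix.
row_var <- function(m) {
  k <- ncol(m)
  (rowSums(m^2) - rowSums(m)^2 / k) / (k - 1)
}
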