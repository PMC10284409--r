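#' Simulation configuration
#'
#' Bundles the design and Monte-Carlo parameters shared by every scenario:
#' the per-cell sample size, the baseline outcome mean, the common noise
#' variance, the significance threshold, the number of Monte-Carlo replicates
#' and the master RNG seed.
#'
#' Defaults reproduce the reference simulation setting: 5 animals per
#' sex-by-treatment cell, outcomes Normal(1, variance 0.5), significance at
#' p < 0.05, 1000 replicates. The variance is a *variance*, so outcomes are
#' drawn with sd = sqrt(noise_variance).
#'
#' @param n_per_cell Animals per sex-by-treatment cell (integer, >= 2 so the
#'   within-cell variance is estimable).
#' @param baseline_mean True mean of every cell before any signal is added
#'   (unitless).
#' @param noise_variance Common within-cell outcome variance (unitless, > 0;
#'   0 is tolerated as a degenerate noise-free limit used in tests).
#' @param alpha Two-sided significance threshold, strict inequality p < alpha.
#' @param n_sim Number of Monte-Carlo replicates per grid point (>= 1).
#' @param seed Master RNG seed; all per-replicate streams are derived from it
#'   via [derive_seed()].
#' @return An object of class `simulation_config` (a named list).
#' @examples
#' cfg <- simulation_config(n_sim = 100, seed = 7)
#' cfg$alpha
#' @export
simulation_config <- function(n_per_cell = 5L, baseline_mean = 1,
                              noise_variance = 0.5, alpha = 0.05,
                              n_sim = 1000L, seed = 1L) {
  n_per_cell <- as.integer(n_per_cell)
  n_sim <- as.integer(n_sim)
  seed <- as.integer(seed)
  if (is.na(n_per_cell) || n_per_cell < 2L)
    stop_sabv("sabv_error_config", "n_per_cell must be an integer >= 2")
  if (is.na(n_sim) || n_sim < 1L)
    stop_sabv("sabv_error_config", "n_sim must be an integer >= 1")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_sabv("sabv_error_config", "alpha must lie strictly between 0 and 1")
  if (!is.finite(noise_variance) || noise_variance < 0)
    stop_sabv("sabv_error_config", "noise_variance must be >= 0 (0 only as a degenerate limit)")
  if (!is.finite(baseline_mean))
    stop_sabv("sabv_error_config", "baseline_mean must be finite")
  if (is.na(seed)) stop_sabv("sabv_error_config", "seed must be a finite integer")
  structure(
    list(n_per_cell = n_per_cell, baseline_mean = baseline_mean,
         noise_variance = noise_variance, alpha = alpha,
         n_sim = n_sim, seed = seed),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  n per cell      : %d (total N = %d)\n", x$n_per_cell, 4L * x$n_per_cell))
  cat(sprintf("  baseline mean   : %g\n", x$baseline_mean))
  cat(sprintf("  noise variance  : %g (sd = %g)\n", x$noise_variance, sqrt(x$noise_variance)))
  cat(sprintf("  alpha           : %g\n", x$alpha))
  cat(sprintf("  replicates      : %d\n", x$n_sim))
  cat(sprintf("  master seed     : %d\n", x$seed))
  invisible(x)
}

#' Derive a child RNG seed from a master seed and integer keys
#'
#' Platform-stable spawning rule for per-replicate random streams: a
#' multiplicative-congruential hash of the master seed and an arbitrary tuple
#' of non-negative integer keys (scenario index, grid-point key, replicate
#' index, arm). All arithmetic stays below 2^53 so the result is exact in
#' double precision on every platform; the returned seed lies in
#' [1, 2^31 - 1] and is safe for [set.seed()].
#'
#' Streams derived with different key tuples are independent for practical
#' purposes, so any single replicate of any sweep is reconstructible from the
#' master seed alone.
#'
#' @param seed Master seed (integer).
#' @param ... Non-negative integer keys identifying the stream.
#' @return A single integer seed in [1, 2^31 - 1].
#' @examples
#' derive_seed(1, 3, 500, 0)
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.double(seed)) %% m
  keys <- as.double(c(...))
  if (any(!is.finite(keys)) || any(keys < 0))
    stop_sabv("sabv_error_config", "derive_seed keys must be finite non-negative integers")
  for (k in keys) {
    # 48271 * (m - 1) + k + 1 < 2^47: exact in doubles
    h <- (h * 48271 + k + 1) %% m
  }
  as.integer(h) + 1L
}

# classed error helper: all package errors carry a class usable with
# tryCatch()/expect_error(class = ...)
stop_sabv <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sabv_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
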