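#' Generate a synthetic observed PK series
#'
#' Stands in for digitised clinical concentration tables when exercising the
#' calibration workflow: the compound is simulated with its clearance scaled
#' by a known multiplier, sampled at the requested times, and multiplied by
#' mean-one lognormal noise of a given coefficient of variation. The series
#' regenerates exactly from the same parameters and seed.
#'
#' @param compound A `compound_params` (the "truth" the calibration should
#'   recover acts through `clearance_multiplier`).
#' @param regimen A [dose_regimen()].
#' @param phys A `physiology`.
#' @param clearance_multiplier Factor applied to `clapp` before simulating.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param sample_times Sampling times (h), non-empty, within the horizon.
#' @param seed Seed for the noise draw.
#' @param solver_opts Solver settings.
#' @return Tibble with `time_h`, `conc_ng_mL`; the generating parameters are
#'   attached as attribute `"generator"`.
#' @export
generate_observed_pk <- function(compound, regimen, phys =
                                   reference_physiology(),
                                 clearance_multiplier = 1, noise_cv = 0,
                                 sample_times, seed = NULL,
                                 solver_opts = solver_options(dt_out = 0.05)) {
  if (length(sample_times) == 0) abort("sample_times must be non-empty")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  shifted <- compound
  shifted$clapp <- compound$clapp * clearance_multiplier
  pk <- simulate_pk(shifted, regimen, phys, solver_opts)
  conc <- approx(pk$data$time_h, pk$data$plasma_ng_mL,
                 xout = sample_times)$y
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    factors <- withr::with_seed(seed %||% 1L, {
      rlnorm(length(sample_times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
    conc <- conc * factors
  }
  out <- tibble::tibble(time_h = sample_times, conc_ng_mL = conc)
  attr(out, "generator") <- list(
    compound = compound$name, clearance_multiplier = clearance_multiplier,
    noise_cv = noise_cv, seed = seed, dose_mg = regimen$dose_mg)
  out
}

#' Generate synthetic regression datasets with known ground truth
#'
#' Test-beds for the model-tree module with documented generating functions
#' so oracles are exact:
#' * `"linear"`: `y = 1 + 3 x1` on `p` uniform features in `[-1, 1]`;
#' * `"piecewise"`: slope change at `x1 = 0`
#'   (`y = 1 + 2 x1` below, `y = 1 - 3 x1` above), uniform on `[-2, 2]`;
#' * `"friedman"`: the standard five-term benchmark
#'   `10 sin(pi x1 x2) + 20 (x3 - 0.5)^2 + 10 x4 + 5 x5` on uniforms in
#'   `[0, 1]`.
#' Gaussian noise of standard deviation `noise_sd` is added to `y`.
#'
#' @param kind `"linear"`, `"piecewise"` or `"friedman"`.
#' @param n Number of rows (>= 10).
#' @param noise_sd Noise standard deviation.
#' @param seed Seed; identical seeds regenerate the dataset exactly.
#' @param p Number of features (linear/piecewise only; friedman uses 10).
#' @return Tibble of features `x1..xp` and target `y`; the generating
#'   parameters are attached as attribute `"generator"`.
#' @export
generate_regression_data <- function(kind = c("linear", "piecewise",
                                              "friedman"),
                                     n, noise_sd = 0, seed = NULL, p = 3) {
  kind <- match.arg(kind)
  if (n < 10) abort("n must be at least 10")
  withr::with_seed(seed %||% 1L, {
    if (kind == "friedman") p <- 10
    lo <- switch(kind, linear = -1, piecewise = -2, friedman = 0)
    hi <- switch(kind, linear = 1, piecewise = 2, friedman = 1)
    X <- matrix(runif(n * p, lo, hi), n, p)
    truth <- switch(kind,
      linear = 1 + 3 * X[, 1],
      piecewise = ifelse(X[, 1] < 0, 1 + 2 * X[, 1], 1 - 3 * X[, 1]),
      friedman = 10 * sin(pi * X[, 1] * X[, 2]) + 20 * (X[, 3] - 0.5)^2 +
        10 * X[, 4] + 5 * X[, 5])
    y <- truth + rnorm(n, sd = noise_sd)
    out <- tibble::as_tibble(as.data.frame(X, col.names = paste0("x", 1:p)))
    names(out) <- paste0("x", seq_len(p))
    out$y <- y
    attr(out, "generator") <- list(kind = kind, n = n, noise_sd = noise_sd,
                                   seed = seed, p = p)
    out
  })
}
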