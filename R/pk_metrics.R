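#' Trapezoidal area under a concentration-time curve
#'
#' @param time_h,conc Equal-length numeric vectors; `time_h` sorted.
#' @return AUC in concentration x hours.
#' @export
auc_trapezoid <- function(time_h, conc) {
  stopifnot(length(time_h) == length(conc), !is.unsorted(time_h))
  sum(diff(time_h) * (head(conc, -1) + tail(conc, -1)) / 2)
}

#' Terminal log-linear slope of a concentration series
#'
#' Least-squares regression of `log(conc)` on time over a window; the
#' elimination rate constant `lambda_z` is the negated slope and is reported
#' with the goodness of fit of the regression.
#'
#' @param time_h,conc Concentration series (conc must be positive within the
#'   window).
#' @param window Length-2 vector `c(t_lo, t_hi)`; defaults to the full span.
#' @return One-row tibble: `lambda_z` (1/h), `half_life_h`, `r_squared`,
#'   `n_points`, `window_lo`, `window_hi`.
#' @export
terminal_slope <- function(time_h, conc, window = range(time_h)) {
  stopifnot(length(time_h) == length(conc), length(window) == 2)
  keep <- time_h >= window[1] & time_h <= window[2] & !is.na(conc)
  if (any(conc[keep] <= 0)) {
    abort("non-positive concentrations in the terminal window")
  }
  if (sum(keep) < 3) abort("terminal regression needs at least 3 positive points")
  t <- time_h[keep]
  y <- log(conc[keep])
  fit <- lm.fit(cbind(1, t), y)
  lambda <- -fit$coefficients[2]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
  tibble::tibble(lambda_z = unname(lambda),
                 half_life_h = log(2) / unname(lambda),
                 r_squared = r2, n_points = sum(keep),
                 window_lo = window[1], window_hi = window[2])
}

# quadratic vertex through the three grid points around the discrete max;
# reported Tmax resolution in clinical tables is ~0.1 h so the refinement
# matters on a 0.01 h grid only for smoothness, but it is cheap
refine_peak <- function(time_h, conc) {
  i <- which.max(conc)
  if (i == 1 || i == length(conc)) {
    return(list(cmax = conc[i], tmax = time_h[i]))
  }
  t3 <- time_h[(i - 1):(i + 1)]
  c3 <- conc[(i - 1):(i + 1)]
  X <- cbind(1, t3, t3^2)
  beta <- tryCatch(solve(X, c3), error = function(e) NULL)
  if (is.null(beta) || beta[3] >= 0) {
    return(list(cmax = conc[i], tmax = time_h[i]))
  }
  tv <- -beta[2] / (2 * beta[3])
  if (tv < t3[1] || tv > t3[3]) return(list(cmax = conc[i], tmax = time_h[i]))
  list(cmax = drop(beta[1] + beta[2] * tv + beta[3] * tv^2), tmax = tv)
}

#' Non-compartmental summary metrics of a simulated profile
#'
#' Computes AUC0-t (trapezoid on the dense grid), the terminal rate constant
#' by log-linear regression (default window: the last 30% of the span),
#' AUC0-inf by extrapolation `AUC0-t + C(t_end)/lambda_z`, and Cmax/Tmax
#' with local quadratic refinement around the grid maximum.
#'
#' For an identically zero profile the AUC and Cmax are zero and the
#' division-based metrics are returned as `NA`.
#'
#' @param profile A `pk_profile`, or a data frame with `time_h` and a
#'   concentration column (`plasma_ng_mL` or `conc_ng_mL`).
#' @param t_end End of the observation window (h); defaults to the profile
#'   end.
#' @param terminal_window Optional explicit `c(t_lo, t_hi)` for the slope
#'   regression.
#' @return A one-row `pk_metrics` tibble.
#' @export
compute_pk_metrics <- function(profile, t_end = NULL, terminal_window = NULL) {
  df <- if (inherits(profile, "pk_profile")) profile$data else profile
  cname <- intersect(c("plasma_ng_mL", "conc_ng_mL"), names(df))[1]
  if (is.na(cname)) abort("no concentration column (plasma_ng_mL / conc_ng_mL)")
  t_end <- t_end %||% max(df$time_h)
  if (t_end > max(df$time_h)) abort("t_end extends beyond the profile")
  keep <- df$time_h <= t_end
  t <- df$time_h[keep]
  conc <- df[[cname]][keep]

  auc_t <- auc_trapezoid(t, conc)
  if (max(conc) <= 0) {
    return(tibble::tibble(auc_0_t = 0, auc_0_inf = NA_real_, cmax = 0,
                          tmax = NA_real_, terminal_half_life = NA_real_,
                          lambda_z = NA_real_, lambda_z_r2 = NA_real_))
  }
  peak <- refine_peak(t, conc)
  if (is.null(terminal_window)) {
    span <- t_end - t[1]
    terminal_window <- c(t_end - 0.3 * span, t_end)
  }
  ts <- terminal_slope(t, conc, terminal_window)
  c_end <- conc[length(conc)]
  tibble::tibble(
    auc_0_t = auc_t,
    auc_0_inf = auc_t + c_end / ts$lambda_z,
    cmax = peak$cmax, tmax = peak$tmax,
    terminal_half_life = ts$half_life_h,
    lambda_z = ts$lambda_z, lambda_z_r2 = ts$r_squared
  )
}

#' Geometric mean with a t-based confidence interval
#'
#' `gm = exp(mean(log x))`; the 2.5-97.5% limits are the exponential of the
#' t-interval on the log scale. With a single value the interval degenerates
#' to the point itself (single virtual subject), reported as such.
#'
#' @param values Positive numbers.
#' @param conf Confidence level (default 0.95, i.e. 2.5-97.5% limits).
#' @return One-row tibble: `gm`, `ci_lo`, `ci_hi`, `n`.
#' @export
geometric_mean_ci <- function(values, conf = 0.95) {
  if (any(values <= 0)) abort("geometric mean requires positive values")
  lx <- log(values)
  n <- length(lx)
  gm <- exp(mean(lx))
  if (n < 2 || sd(lx) == 0) {
    return(tibble::tibble(gm = gm, ci_lo = gm, ci_hi = gm, n = n))
  }
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * sd(lx) / sqrt(n)
  tibble::tibble(gm = gm, ci_lo = exp(mean(lx) - half),
                 ci_hi = exp(mean(lx) + half), n = n)
}

#' Two-fold significance rule for paired PK quantities
#'
#' Changes of at least two-fold in either direction are flagged significant.
#'
#' @param a,b Positive values to compare.
#' @param threshold Fold-change cut-off (default 2, boundary inclusive).
#' @return One-row tibble: `ratio` (`max(a/b, b/a)`) and `significant`.
#' @export
fold_change_flag <- function(a, b, threshold = 2) {
  if (a <= 0 || b <= 0) abort("fold_change_flag requires positive values")
  ratio <- max(a / b, b / a)
  tibble::tibble(ratio = ratio, significant = ratio >= threshold)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper used for predicted-vs-observed comparisons.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, nonzero variance).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("pearson_r needs at least 3 points")
  if (var(x) == 0 || var(y) == 0) abort("pearson_r undefined for zero variance")
  cor(x, y, method = "pearson")
}
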