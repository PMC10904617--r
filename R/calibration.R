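#' Multiplicative PK calibration factors
#'
#' The calibration workflow separates estimation (a terminal log-slope ratio
#' against observed data, [estimate_slope_ratio()]) from application of a
#' user-supplied factor triple. The named preset `"vonoprazan_2024"` is the
#' published triple for vonoprazan: fraction absorbed halved, apparent
#' clearance scaled 3.08-fold, absorption rate divided by 3.5.
#'
#' @param fa_multiplier,clapp_multiplier,ka_divisor Positive factors, or a
#'   preset name as the first argument.
#' @return A `calibration_factors` object.
#' @examples
#' calibration_factors("vonoprazan_2024")
#' calibration_factors(1, 2.5, 1)
#' @export
calibration_factors <- function(fa_multiplier = 1, clapp_multiplier = 1,
                                ka_divisor = 1) {
  preset <- NULL
  if (is.character(fa_multiplier)) {
    preset <- match.arg(fa_multiplier, "vonoprazan_2024")
    fa_multiplier <- 0.5
    clapp_multiplier <- 3.08
    ka_divisor <- 3.5
  }
  if (fa_multiplier <= 0 || clapp_multiplier <= 0 || ka_divisor <= 0) {
    abort("calibration factors must be positive")
  }
  structure(list(fa_multiplier = fa_multiplier,
                 clapp_multiplier = clapp_multiplier,
                 ka_divisor = ka_divisor, preset = preset),
            class = "calibration_factors")
}

#' @export
print.calibration_factors <- function(x, ...) {
  cat(sprintf("<calibration_factors%s>  Fa x%g,  CLapp x%g,  gi_ka /%g\n",
              if (is.null(x$preset)) "" else paste0(": ", x$preset),
              x$fa_multiplier, x$clapp_multiplier, x$ka_divisor))
  invisible(x)
}

#' Apply calibration factors to a compound parameter set
#'
#' Returns a copy with `fa * fa_multiplier` (clamped to 1 with a warning if
#' exceeded), `clapp * clapp_multiplier` and `gi_ka / ka_divisor`; all other
#' fields are unchanged and the factors are recorded in the result for
#' provenance. Application is deliberately not idempotent.
#'
#' @param compound A `compound_params` object.
#' @param factors A [calibration_factors()] object.
#' @return The adjusted `compound_params`.
#' @export
apply_calibration <- function(compound, factors) {
  stopifnot(inherits(compound, "compound_params"),
            inherits(factors, "calibration_factors"))
  out <- compound
  fa_new <- compound$fa * factors$fa_multiplier
  if (fa_new > 1) {
    warn(sprintf("calibrated fa %.3g exceeds 1; clamped", fa_new))
    fa_new <- 1
  }
  out$fa <- fa_new
  out$clapp <- compound$clapp * factors$clapp_multiplier
  out$gi_ka <- compound$gi_ka / factors$ka_divisor
  out$calibration <- factors
  out
}

#' Ratio of simulated to observed terminal log-slopes
#'
#' The estimation half of the calibration workflow: fits the terminal
#' elimination rate constant to both the simulated plasma curve and an
#' observed concentration table over a common window and returns
#' `lambda_sim / lambda_obs`. A ratio of, say, 3 means the simulation
#' eliminates three times faster than observed.
#'
#' @param simulated A `pk_profile` (or data frame with `time_h`,
#'   `plasma_ng_mL`).
#' @param observed Data frame with `time_h` and `conc_ng_mL`.
#' @param window `c(t_lo, t_hi)` for the regressions; defaults to the last
#'   30% of the observed span.
#' @return The unitless slope ratio.
#' @export
estimate_slope_ratio <- function(simulated, observed, window = NULL) {
  sim_df <- if (inherits(simulated, "pk_profile")) simulated$data else simulated
  if (is.null(window)) {
    span <- range(observed$time_h)
    window <- c(span[2] - 0.3 * diff(span), span[2])
  }
  lam_sim <- terminal_slope(sim_df$time_h, sim_df$plasma_ng_mL, window)$lambda_z
  lam_obs <- terminal_slope(observed$time_h, observed$conc_ng_mL,
                            window)$lambda_z
  lam_sim / lam_obs
}

#' The 17 inputs of the published local sensitivity analysis
#'
#' @return Character vector of parameter names accepted by
#'   [local_sensitivity()].
#' @export
sensitivity_parameters <- function() {
  c("fup", "bpr", "gi_ka", "clapp", "vss_per_kg",
    "kp_bone", "kp_brain", "kp_adipose", "kp_heart", "kp_kidney", "kp_gut",
    "kp_liver", "kp_lung", "kp_muscle", "kp_skin", "kp_spleen", "kp_scaler")
}

perturb_compound <- function(compound, parameter, factor) {
  out <- compound
  if (parameter %in% c("fup", "bpr", "gi_ka", "clapp", "kp_scaler")) {
    out[[parameter]] <- compound[[parameter]] * factor
  } else if (grepl("^kp_", parameter)) {
    tissue <- sub("^kp_", "", parameter)
    if (!tissue %in% names(compound$kp)) {
      abort(paste0("unknown tissue in parameter '", parameter, "'"))
    }
    out$kp[tissue] <- compound$kp[[tissue]] * factor
  } else {
    abort(paste0("unknown parameter '", parameter, "'; valid names: ",
                 paste(sensitivity_parameters(), collapse = ", ")))
  }
  out
}

#' Local sensitivity of AUC and Cmax to the model inputs
#'
#' Perturbs each named parameter by +/- `delta` (default 1%) and reports the
#' percent change of AUC0-t and Cmax per average 1% parameter change
#' (central differences by default; `mode` selects one-sided variants).
#' `vss_per_kg` acts through the Kp scaler: the scaler is rescaled by the
#' closed-form factor `(vss' * BW - Vp) / (vss * BW - Vp)` so that explicit
#' literature scalers are perturbed consistently.
#'
#' @param compound A `compound_params`.
#' @param regimen A [dose_regimen()]; AUC0-t is taken over its horizon.
#' @param phys A `physiology`.
#' @param parameters `"all"` (the 17 published names, see
#'   [sensitivity_parameters()]) or a subset.
#' @param delta Fractional perturbation (default 0.01).
#' @param mode `"central"`, `"plus"` or `"minus"` differences.
#' @param solver_opts Solver settings; the default output grid is coarsened
#'   to 0.05 h, ample for AUC/Cmax differences.
#' @return Tibble with `parameter`, `pct_change_auc`, `pct_change_cmax`.
#' @export
local_sensitivity <- function(compound, regimen = dose_regimen(), phys =
                                reference_physiology(), parameters = "all",
                              delta = 0.01,
                              mode = c("central", "plus", "minus"),
                              solver_opts = solver_options(dt_out = 0.05)) {
  mode <- match.arg(mode)
  if (identical(parameters, "all")) parameters <- sensitivity_parameters()
  unknown <- setdiff(parameters, sensitivity_parameters())
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", "),
                 "; valid names: ",
                 paste(sensitivity_parameters(), collapse = ", ")))
  }

  metrics_for <- function(cmp) {
    pk <- simulate_pk(cmp, regimen, phys, solver_opts)
    m <- compute_pk_metrics(pk)
    c(auc = m$auc_0_t, cmax = m$cmax)
  }
  base <- metrics_for(compound)

  vss_consistent <- function(cmp, factor) {
    # rescale the scaler with the elasticity of the closed-form solve
    bw <- phys$body_weight_kg
    vp <- phys$plasma_L
    ratio <- (cmp$vss_per_kg * factor * bw - vp) / (cmp$vss_per_kg * bw - vp)
    out <- cmp
    out$vss_per_kg <- cmp$vss_per_kg * factor
    out$kp_scaler <- cmp$kp_scaler * ratio
    out
  }

  rows <- purrr::map(parameters, function(p) {
    perturbed <- function(factor) {
      cmp <- if (p == "vss_per_kg") vss_consistent(compound, factor)
             else perturb_compound(compound, p, factor)
      metrics_for(cmp)
    }
    hi <- if (mode != "minus") perturbed(1 + delta) else base
    lo <- if (mode != "plus") perturbed(1 - delta) else base
    denom <- switch(mode, central = 2 * delta, plus = delta, minus = delta)
    pct <- (hi - lo) / (denom * base) * 0.01 * 100  # % change per 1% change
    tibble::tibble(parameter = p, pct_change_auc = unname(pct["auc"]),
                   pct_change_cmax = unname(pct["cmax"]))
  })
  dplyr::bind_rows(rows)
}
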