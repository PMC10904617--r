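#' The 14 tissue compartments of the whole-body model
#'
#' Compartment names used throughout the package, in circulatory order.
#' The model additionally carries two blood pools (venous, arterial) and a
#' gut-lumen depot for oral dosing.
#'
#' @return Character vector of the 14 tissue names.
#' @export
pbpk_tissues <- function() {
  c("lung", "heart", "brain", "muscle", "adipose", "skin", "spleen",
    "pancreas", "liver", "stomach", "gut", "bone", "kidney", "rest_of_body")
}

# Tissues whose venous outflow drains through the portal vein into the liver
# inflow (series topology); everything else returns directly to mixed venous.
portal_tissues <- function() c("gut", "spleen", "pancreas", "stomach")

#' Load and validate a physiology configuration
#'
#' Builds the virtual subject used by [simulate_pk()]: body weight, the 14
#' tissue volumes and blood flows, the two blood-pool volumes, plasma volume
#' and cardiac output. Accepts a YAML or JSON file path, a nested list with
#' the same schema, or the name of a bundled set (currently
#' `"reference_adult"`).
#'
#' A missing `rest_of_body` volume or flow is computed by closure: its volume
#' makes total body volume match body weight (at unit density) and its flow
#' makes the systemic tissue flows sum to cardiac output. The lung is
#' perfused in series and carries the full cardiac output.
#'
#' @param config File path, nested list, or bundled set name.
#' @return A `physiology` object.
#' @examples
#' phys <- load_physiology("reference_adult")
#' phys$body_weight_kg
#' @export
load_physiology <- function(config = "reference_adult") {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      path <- system.file("extdata", paste0(config, "_physiology.yaml"),
                          package = "pcabsim")
      if (!nzchar(path)) {
        abort(paste0("physiology config '", config,
                     "' is neither a file nor a bundled set"))
      }
      config <- path
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("physiology config must be a file path or list")
  validate_physiology(config)
}

#' @rdname load_physiology
#' @export
reference_physiology <- function() {
  cached <- physiology_cache$reference_adult
  if (!is.null(cached)) return(cached)
  phys <- load_physiology("reference_adult")
  physiology_cache$reference_adult <- phys
  phys
}

physiology_cache <- new.env(parent = emptyenv())

validate_physiology <- function(cfg) {
  for (field in c("body_weight_kg", "cardiac_output_L_h")) {
    val <- cfg[[field]]
    if (is.null(val) || !is.numeric(val) || val <= 0) {
      abort(paste0("physiology field '", field, "' must be a positive number"))
    }
  }
  blood <- cfg$blood
  for (field in c("venous_L", "arterial_L", "plasma_L")) {
    val <- blood[[field]]
    if (is.null(val) || !is.numeric(val) || val <= 0) {
      abort(paste0("physiology field 'blood.", field,
                   "' must be a positive number"))
    }
  }
  radius <- cfg$gut_lumen_radius_cm %||% 1.25
  if (radius <= 0) abort("gut_lumen_radius_cm must be positive")

  tissues <- pbpk_tissues()
  given <- names(cfg$tissues)
  unknown <- setdiff(given, tissues)
  if (length(unknown) > 0) {
    abort(paste0("unknown tissue(s) in physiology: ",
                 paste(unknown, collapse = ", ")))
  }
  missing <- setdiff(tissues, c(given, "rest_of_body"))
  if (length(missing) > 0) {
    abort(paste0("physiology is missing tissue(s): ",
                 paste(missing, collapse = ", ")))
  }

  vol <- vapply(tissues, function(t) cfg$tissues[[t]]$volume_L %||% NA_real_,
                numeric(1))
  flow <- vapply(tissues, function(t) cfg$tissues[[t]]$flow_L_h %||% NA_real_,
                 numeric(1))
  co <- cfg$cardiac_output_L_h

  # closure for rest_of_body: volume against body mass, flow against cardiac
  # output (the lung row carries the whole cardiac output and is excluded
  # from the systemic sum)
  systemic <- setdiff(tissues, "lung")
  if (is.na(vol["rest_of_body"])) {
    blood_vol <- blood$venous_L + blood$arterial_L
    vol["rest_of_body"] <- cfg$body_weight_kg -
      sum(vol[setdiff(tissues, "rest_of_body")]) - blood_vol
  }
  if (is.na(flow["rest_of_body"])) {
    flow["rest_of_body"] <- co -
      sum(flow[setdiff(systemic, "rest_of_body")])
  }
  if (is.na(flow["lung"])) flow["lung"] <- co

  bad <- names(vol)[is.na(vol) | vol <= 0]
  if (length(bad) > 0) {
    abort(paste0("non-positive or missing tissue volume: ",
                 paste(bad, collapse = ", ")))
  }
  bad <- names(flow)[is.na(flow) | flow <= 0]
  if (length(bad) > 0) {
    abort(paste0("non-positive or missing tissue flow: ",
                 paste(bad, collapse = ", "),
                 " (systemic flows may not exceed cardiac output)"))
  }
  qsum <- sum(flow[systemic])
  if (abs(qsum - co) > 0.01 * co) {
    abort(sprintf(
      "systemic tissue flows (%.2f L/h) do not balance cardiac output (%.2f L/h) within 1%%",
      qsum, co))
  }

  structure(
    list(
      name = cfg$name %||% "custom",
      body_weight_kg = cfg$body_weight_kg,
      cardiac_output_L_h = co,
      gut_lumen_radius_cm = radius,
      venous_L = blood$venous_L,
      arterial_L = blood$arterial_L,
      plasma_L = blood$plasma_L,
      tissues = tibble::tibble(tissue = tissues, volume_L = unname(vol),
                               flow_L_h = unname(flow))
    ),
    class = "physiology"
  )
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology: %s>  BW %.1f kg, CO %.0f L/h, plasma %.2f L\n",
              x$name, x$body_weight_kg, x$cardiac_output_L_h, x$plasma_L))
  print(x$tissues, n = 14)
  invisible(x)
}

tissue_volumes <- function(phys) {
  setNames(phys$tissues$volume_L, phys$tissues$tissue)
}

tissue_flows <- function(phys) {
  setNames(phys$tissues$flow_L_h, phys$tissues$tissue)
}

#' Fill in partition coefficients for tissues without literature values
#'
#' Compound tables typically report Kp for 11 tissues; the whole-body model
#' needs all 14. Missing entries default to physiological look-alikes:
#' stomach takes the gut value, pancreas the spleen value, and rest-of-body
#' a neutral 1.0.
#'
#' @param kp Named numeric vector or list of tissue:plasma partition
#'   coefficients (subset of [pbpk_tissues()]).
#' @return Named numeric vector covering all 14 tissues.
#' @export
complete_kp <- function(kp) {
  kp <- unlist(kp)
  unknown <- setdiff(names(kp), pbpk_tissues())
  if (length(unknown) > 0) {
    abort(paste0("unknown tissue(s) in kp: ", paste(unknown, collapse = ", ")))
  }
  if (any(kp <= 0)) abort("all kp values must be positive")
  if (!"stomach" %in% names(kp) && "gut" %in% names(kp)) {
    kp["stomach"] <- kp[["gut"]]
  }
  if (!"pancreas" %in% names(kp) && "spleen" %in% names(kp)) {
    kp["pancreas"] <- kp[["spleen"]]
  }
  if (!"rest_of_body" %in% names(kp)) kp["rest_of_body"] <- 1.0
  missing <- setdiff(pbpk_tissues(), names(kp))
  if (length(missing) > 0) {
    abort(paste0("kp is missing tissue(s): ", paste(missing, collapse = ", ")))
  }
  kp[pbpk_tissues()]
}

#' Solve the uniform Kp scaler from a target volume of distribution
#'
#' The scaler multiplies every tissue partition coefficient in equal
#' proportion so that the model's steady-state distribution volume matches
#' the predicted per-kilogram value:
#' \deqn{V_{ss} = V_{plasma} + s \sum_t V_t \, Kp_t}
#' Solved in closed form; the round trip through [vss_from_scaler()]
#' reproduces the input to machine precision.
#'
#' @param vss_per_kg Target steady-state volume of distribution (L/kg).
#' @param kp Named partition coefficients (completed via [complete_kp()]).
#' @param phys A `physiology` object.
#' @param bpr,fup Accepted for forward compatibility with blood-referenced
#'   distribution formulas; unused by the default plasma-referenced formula.
#' @return The positive scaler `s`.
#' @examples
#' phys <- reference_physiology()
#' s <- solve_kp_scaler(3.497, vonoprazan_parameters()$kp, phys)
#' vss_from_scaler(s, vonoprazan_parameters()$kp, phys) # 3.497
#' @export
solve_kp_scaler <- function(vss_per_kg, kp, phys, bpr = NULL, fup = NULL) {
  kp <- complete_kp(kp)
  if (vss_per_kg <= 0) abort("vss_per_kg must be positive")
  target_L <- vss_per_kg * phys$body_weight_kg
  if (target_L <= phys$plasma_L) {
    abort(sprintf(
      "infeasible: target Vss (%.2f L) does not exceed plasma volume (%.2f L)",
      target_L, phys$plasma_L))
  }
  denom <- sum(tissue_volumes(phys) * kp)
  (target_L - phys$plasma_L) / denom
}

#' @rdname solve_kp_scaler
#' @param s Kp scaler as returned by `solve_kp_scaler()`.
#' @export
vss_from_scaler <- function(s, kp, phys) {
  kp <- complete_kp(kp)
  if (s <= 0) abort("kp scaler must be positive")
  (phys$plasma_L + s * sum(tissue_volumes(phys) * kp)) / phys$body_weight_kg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
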