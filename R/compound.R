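#' Assemble and validate a compound parameter set
#'
#' Bundles the per-compound ADME inputs of the PBPK model: fraction unbound
#' in plasma (`fup`), blood-to-plasma ratio (`bpr`), first-order
#' gastrointestinal absorption rate (`gi_ka`, 1/h), apparent plasma
#' clearance (`clapp`, L/h), steady-state volume of distribution
#' (`vss_per_kg`, L/kg), fraction absorbed (`fa`) and the tissue:plasma
#' partition block with its uniform scaler. When `kp_scaler` is `NULL` it is
#' solved from `vss_per_kg` via [solve_kp_scaler()].
#'
#' @param name Compound name.
#' @param fup,bpr,gi_ka,clapp,vss_per_kg,fa ADME parameters (see above).
#' @param kp Named tissue:plasma partition coefficients; missing tissues are
#'   filled by [complete_kp()].
#' @param kp_scaler Uniform multiplier on all Kp values, or `NULL` to solve
#'   it from `vss_per_kg`.
#' @param smiles,mw Optional structure metadata and molecular weight (g/mol);
#'   `mw` is required downstream by [simulate_pd()] for the ng/mL to uM
#'   conversion.
#' @param phys Physiology used when solving the scaler.
#' @return A `compound_params` object.
#' @export
compound_parameters <- function(name, fup, bpr, gi_ka, clapp, vss_per_kg, fa,
                                kp, kp_scaler = NULL, smiles = NA_character_,
                                mw = NA_real_, phys = reference_physiology()) {
  stopifnot(is.character(name), length(name) == 1)
  check_in <- function(x, what, lo = 0, hi = Inf, open_lo = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        (open_lo && x <= lo) || (!open_lo && x < lo) || x > hi) {
      abort(sprintf("'%s' must be a number in (%s, %s]", what, lo, hi))
    }
  }
  check_in(fup, "fup", 0, 1)
  check_in(fa, "fa", 0, 1)
  check_in(bpr, "bpr")
  check_in(gi_ka, "gi_ka")
  check_in(clapp, "clapp")
  check_in(vss_per_kg, "vss_per_kg")
  kp <- complete_kp(kp)
  if (is.null(kp_scaler) || is.na(kp_scaler)) {
    kp_scaler <- solve_kp_scaler(vss_per_kg, kp, phys)
  }
  check_in(kp_scaler, "kp_scaler")
  structure(
    list(name = name, smiles = smiles, mw = mw, fup = fup, bpr = bpr,
         gi_ka = gi_ka, clapp = clapp, vss_per_kg = vss_per_kg, fa = fa,
         kp = kp, kp_scaler = kp_scaler, calibration = NULL),
    class = "compound_params"
  )
}

#' @export
print.compound_params <- function(x, ...) {
  cat(sprintf(
    "<compound_params: %s>\n  fup %.5g  bpr %.5g  gi_ka %.5g /h  clapp %.5g L/h\n  vss %.4g L/kg  fa %.4g  kp_scaler %.4g%s\n",
    x$name, x$fup, x$bpr, x$gi_ka, x$clapp, x$vss_per_kg, x$fa, x$kp_scaler,
    if (is.null(x$calibration)) "" else
      sprintf("  [calibrated: %s]", x$calibration$preset %||% "custom")))
  invisible(x)
}

#' @export
tidy.compound_params <- function(x, ...) {
  tibble::tibble(
    parameter = c("fup", "bpr", "gi_ka", "clapp", "vss_per_kg", "fa",
                  "kp_scaler", paste0("kp_", names(x$kp))),
    value = c(x$fup, x$bpr, x$gi_ka, x$clapp, x$vss_per_kg, x$fa,
              x$kp_scaler, unname(x$kp))
  )
}

#' Read a single-compound parameter file
#'
#' JSON schema: `name`, `smiles`, `mw_g_mol`, `fup`, `bpr`, `gi_ka_1_h`,
#' `clapp_L_h`, `vss_L_kg`, `fa`, `kp` (named block), `kp_scaler` (omit or
#' null to solve it from `vss_L_kg`).
#'
#' @param path Path to a JSON file.
#' @param phys Physiology used when the scaler must be solved.
#' @return A `compound_params` object.
#' @export
read_compound_json <- function(path, phys = reference_physiology()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("name", "fup", "bpr", "gi_ka_1_h", "clapp_L_h", "vss_L_kg",
            "fa", "kp")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    abort(paste0("compound file is missing field(s): ",
                 paste(missing, collapse = ", ")))
  }
  compound_parameters(
    name = cfg$name, smiles = cfg$smiles %||% NA_character_,
    mw = cfg$mw_g_mol %||% NA_real_, fup = cfg$fup, bpr = cfg$bpr,
    gi_ka = cfg$gi_ka_1_h, clapp = cfg$clapp_L_h, vss_per_kg = cfg$vss_L_kg,
    fa = cfg$fa, kp = cfg$kp, kp_scaler = cfg$kp_scaler %||% NULL,
    phys = phys
  )
}

#' The vonoprazan reference parameter set
#'
#' The predicted ADME and partition parameters for vonoprazan that drive the
#' worked example, bundled as a data file. With `calibrated = TRUE` the
#' published adjustment preset (`"vonoprazan_2024"`: fraction absorbed
#' halved, clearance scaled 3.08-fold, absorption rate divided by 3.5) is
#' applied via [apply_calibration()].
#'
#' @param calibrated Apply the calibration preset?
#' @param phys Physiology (used only if the scaler had to be solved).
#' @return A `compound_params` object.
#' @examples
#' vonoprazan_parameters()
#' vonoprazan_parameters(calibrated = TRUE)$clapp  # 35.689
#' @export
vonoprazan_parameters <- function(calibrated = FALSE,
                                  phys = reference_physiology()) {
  path <- system.file("extdata", "vonoprazan_table1.json", package = "pcabsim")
  cmp <- read_compound_json(path, phys = phys)
  if (calibrated) {
    cmp <- apply_calibration(cmp, calibration_factors("vonoprazan_2024"))
  }
  cmp
}
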