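# Shared fixtures built in code. All compounds here are synthetic probes
# except the bundled vonoprazan set, which tests load via
# vonoprazan_parameters().

ref_phys <- reference_physiology()

# coarse output grid for tests where 0.01 h resolution is not needed
quick_solver <- solver_options(dt_out = 0.05)

# kinetically unstructured probe: unit partitioning everywhere
probe_compound <- function(clapp = 2, gi_ka = 1, fa = 0.8, bpr = 1,
                           fup = 0.5, kp_value = 1, mw = 300) {
  compound_parameters(
    "probe", fup = fup, bpr = bpr, gi_ka = gi_ka, clapp = clapp,
    vss_per_kg = 1, fa = fa,
    kp = setNames(rep(kp_value, 14), pbpk_tissues()),
    kp_scaler = 1, mw = mw, phys = ref_phys)
}

# low-partitioning reference compound for slope-ratio recovery: tissue
# washout is orders of magnitude faster than elimination, so the terminal
# eigenvalue scales linearly in clearance
recovery_compound <- function() {
  probe_compound(clapp = 0.3, gi_ka = 1, fa = 1, bpr = 1, fup = 0.5,
                 kp_value = 0.02)
}

vono_potency <- function(intersys = 1e3) {
  potency_parameters("vonoprazan", ic50_uM = 0.019,
                     dissociation_half_life_h = 4.7, intersys = intersys)
}

# one-row screening table assembled from a compound_params + potency inputs
screening_row <- function(cmp, ic50_uM, half_life_h = 4.7) {
  kp <- as.list(setNames(unname(cmp$kp), paste0("kp_", names(cmp$kp))))
  tibble::as_tibble(c(
    list(name = cmp$name, mw_g_mol = cmp$mw, fup = cmp$fup, bpr = cmp$bpr,
         gi_ka_1_h = cmp$gi_ka, clapp_L_h = cmp$clapp,
         vss_L_kg = cmp$vss_per_kg, fa = cmp$fa, kp_scaler = cmp$kp_scaler,
         ic50_uM = ic50_uM, dissociation_half_life_h = half_life_h),
    kp))
}

# pk_profile scaffold with a prescribed constant gut-tissue amount, for
# closed-form PD checks (Ce is then constant in time)
constant_ce_profile <- function(ce_ng_ml, duration_h = 5, dt = 0.001,
                                mw = 100) {
  cmp <- probe_compound(bpr = 1, fup = 1, kp_value = 1, mw = mw)
  v_gut <- ref_phys$tissues$volume_L[ref_phys$tissues$tissue == "gut"]
  time_h <- seq(0, duration_h, by = dt)
  amounts <- matrix(0, length(time_h), 18,
                    dimnames = list(NULL, c(pbpk_tissues(), "venous",
                                            "arterial", "gut_lumen",
                                            "eliminated")))
  amounts[, "gut"] <- ce_ng_ml * v_gut   # kp_eff = bpr = fup = 1
  structure(
    list(data = tibble::tibble(time_h = time_h,
                               plasma_ng_mL = 0 * time_h,
                               stomach_free_ng_mL = ce_ng_ml),
         amounts = amounts, compound = cmp,
         regimen = dose_regimen(1, duration_h = duration_h),
         phys = ref_phys, solver = quick_solver, topology = "portal",
         mass_balance_rel_err = 0),
    class = "pk_profile")
}
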