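test_that("potency derivations match the published receptor kinetics", {
  expect_equal(signif(kd_from_half_life(4.7), 3), 0.147)
  expect_equal(kd_from_half_life(log(2)), 1)
  expect_equal(kd_from_half_life(0.3466), 2, tolerance = 1e-4)
  expect_error(kd_from_half_life(0), "positive")

  expect_equal(ki_from_ic50(0.019), 0.0095)
  expect_equal(ki_from_ic50(1), 0.5)
  x <- c(0.3, 1.7, 42)
  expect_equal(ki_from_ic50(2 * x), x)
  expect_error(ki_from_ic50(-1), "positive")

  expect_equal(binding_rate_constant(1, 1), 1)
  expect_equal(round(binding_rate_constant(log(2) / 4.7, 0.0095), 3), 15.524)
  expect_equal(round(binding_rate_constant(log(2) / 4.7, 0.0145), 3), 10.171)
  expect_error(binding_rate_constant(1, 0), "positive")
})

test_that("potency sets are internally consistent and reject mismatches", {
  pot <- potency_parameters("x", ic50_uM = 0.019,
                            dissociation_half_life_h = 4.7)
  expect_equal(pot$kd_1_h, log(2) / 4.7, tolerance = 1e-12)
  expect_equal(pot$k_per_uM_h, pot$kd_1_h / pot$ki_uM, tolerance = 1e-12)
  expect_error(
    potency_parameters("x", ic50_uM = 0.019, dissociation_half_life_h = 4.7,
                       kd_1_h = 0.2),
    "inconsistent")
  expect_error(
    potency_parameters("x", dissociation_half_life_h = 4.7),
    "ic50_uM or ki_uM")
})

test_that("the bundled potency table parses and its derived columns recompute", {
  tab <- pcab_potency()
  expect_equal(nrow(tab), 7)
  expect_true(all(c("name", "smiles", "ic50_uM", "ki_uM", "kd_1_h",
                    "k_per_uM_h") %in% names(tab)))
  # every row satisfies ki = ic50/2 exactly
  expect_equal(tab$ki_uM, tab$ic50_uM / 2, tolerance = 1e-12)
  # printed 3 s.f. columns agree with the full-precision recomputation
  expect_equal(tab$kd_printed_1_h / tab$kd_1_h, rep(1, 7), tolerance = 0.005)
  expect_equal(tab$k_printed_per_uM_h / tab$k_per_uM_h, rep(1, 7),
               tolerance = 0.005)
})

test_that("the linear pH mapping interpolates between baseline and ceiling", {
  cfg <- pd_config()
  expect_equal(ph_mapping(0, cfg), 1.2)
  expect_equal(ph_mapping(1, cfg), 7)
  expect_equal(ph_mapping(0.5, cfg), 4.1)
  expect_error(pd_config(ph_baseline = 5, ph_max = 4), "exceed")
  expect_error(pd_config(ph_max = 15), "0, 14")
})

test_that("no drug means no inhibition and baseline pH", {
  pk0 <- simulate_pk(probe_compound(), dose_regimen(0, duration_h = 6),
                     ref_phys, quick_solver)
  pd <- simulate_pd(pk0, vono_potency(), mw = 300)
  expect_true(all(pd$data$inhibition == 0))
  expect_true(all(pd$data$ph == 1.2))
  expect_equal(pd$data$residual_secretion, 1 - pd$data$inhibition)
})

test_that("constant exposure relaxes to the closed-form steady state", {
  pot <- potency_parameters("probe", ki_uM = 0.4,
                            dissociation_half_life_h = 2, intersys = 1)
  k <- pot$k_per_uM_h
  kd <- pot$kd_1_h
  ce_uM <- 0.8          # mw 100 makes 80 ng/mL = 0.8 uM
  pk <- constant_ce_profile(80, duration_h = 10 / (k * ce_uM + kd), mw = 100)
  pd <- simulate_pd(pk, pot, mw = 100)
  expect_equal(max(pd$data$ce_uM), ce_uM, tolerance = 1e-12)
  i_inf <- k * ce_uM / (k * ce_uM + kd)
  expect_equal(tail(pd$data$inhibition, 1), i_inf, tolerance = 1e-3)
})

test_that("inhibition stays within [0, imax] and is monotone when kd -> 0", {
  pk <- simulate_pk(vonoprazan_parameters(calibrated = TRUE),
                    dose_regimen(20, duration_h = 30), ref_phys, quick_solver)
  pd <- simulate_pd(pk, vono_potency())
  expect_true(all(pd$data$inhibition >= 0))
  expect_true(all(pd$data$inhibition <= 1))

  # irreversible-binding limit: effectively zero dissociation
  slow <- potency_parameters("irreversible", ic50_uM = 0.019,
                             dissociation_half_life_h = 1e12)
  pd_slow <- simulate_pd(pk, slow)
  expect_true(all(diff(pd_slow$data$inhibition) >= -1e-12))
})

test_that("holding time integrates threshold crossings by interpolation", {
  flat_high <- tibble::tibble(time_h = 0:24, ph = rep(7, 25))
  expect_equal(holding_time_percentage(flat_high), 100)
  flat_low <- tibble::tibble(time_h = 0:24, ph = rep(1.2, 25))
  expect_equal(holding_time_percentage(flat_low), 0)

  # triangle: crosses 4 upward at t = 0.5 and downward at t = 1.5
  tri <- tibble::tibble(time_h = 0:2, ph = c(3, 5, 3))
  expect_equal(holding_time_percentage(tri, window_h = 2), 50)
  expect_equal(onset_time(tri), 0.5)

  expect_error(holding_time_percentage(tri, window_h = 24), "beyond")
})

test_that("onset is the first interpolated crossing or NA", {
  expect_equal(onset_time(tibble::tibble(time_h = 0:5, ph = rep(7, 6))), 0)
  expect_true(is.na(onset_time(tibble::tibble(time_h = 0:5, ph = rep(2, 6)))))
})

test_that("higher binding rate constants never shorten the holding time", {
  pk <- simulate_pk(vonoprazan_parameters(calibrated = TRUE),
                    dose_regimen(20, duration_h = 30), ref_phys, quick_solver)
  tab <- pcab_potency()
  ks <- sort(tab$k_per_uM_h)
  cfg <- pd_config(ph_max = 4.2)
  holding <- vapply(ks, function(k_val) {
    pot <- potency_parameters("sweep", ki_uM = kd_from_half_life(4.7) / k_val,
                              dissociation_half_life_h = 4.7)
    holding_time_percentage(simulate_pd(pk, pot, cfg))
  }, numeric(1))
  expect_true(all(diff(holding) >= -1e-9))
})

test_that("the pH-ceiling calibration hits a reachable target and warns otherwise", {
  pk <- simulate_pk(vonoprazan_parameters(calibrated = TRUE),
                    dose_regimen(20, duration_h = 30), ref_phys, quick_solver)
  pot <- vono_potency()
  cfg <- calibrate_ph_mapping(pk, pot, target_holding_pct = 80)
  expect_equal(attr(cfg, "calibration")$achieved_holding_pct, 80,
               tolerance = 0.01)
  pd <- simulate_pd(pk, pot, cfg)
  expect_equal(holding_time_percentage(pd), 80, tolerance = 0.01)

  tiny <- simulate_pk(vonoprazan_parameters(calibrated = TRUE),
                      dose_regimen(1e-4, duration_h = 30), ref_phys,
                      quick_solver)
  expect_warning(calibrate_ph_mapping(tiny, pot, target_holding_pct = 99.9),
                 "unreachable")
})
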