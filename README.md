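# pcabsim

Whole-body PBPK/PD simulation and dose screening for potassium-competitive
acid blockers (P-CABs).

P-CABs (vonoprazan, revaprazan, and newer candidates) suppress gastric acid
by reversibly blocking the H+/K+-ATPase proton pump. Their clinical endpoint
is pharmacodynamic: the percentage of a 24-hour window during which gastric
pH stays above 4, and how quickly that threshold is reached after a dose.
`pcabsim` is for modellers who want to connect a compound's predicted ADME
parameters to those endpoints *before* clinical data exist: it simulates the
plasma and gastric exposure of an oral dose with a mechanistic whole-body
model, drives a receptor-binding model of pump inhibition with the gastric
concentration, and screens compounds across doses on the resulting
endpoints.

## The model

**PK.** A 14-tissue whole-body PBPK model (lung, heart, brain, muscle,
adipose, skin, spleen, pancreas, liver, stomach, gut, bone, kidney,
rest-of-body) plus venous and arterial blood pools. Each well-stirred tissue
obeys

    dA_T/dt = Q_T · C_art − Q_T · A_T / (V_T · Kp_T · s)

with a uniform partition-coefficient scaler `s` reconciling the tissue Kp
block with the predicted steady-state distribution volume
(`Vss = V_plasma + s · Σ V_T Kp_T`). Oral doses enter the gut lumen gated by
the fraction absorbed `Fa` and transfer to gut tissue at the first-order
rate `gi_ka`; gut, spleen, pancreas and stomach drain through the portal
vein into the liver, where all elimination occurs, wired so that the
emergent whole-body plasma clearance equals the apparent clearance `CLapp`
(hence `AUC0-inf = Fa·Dose/CLapp`, which the test suite verifies to 0.5%).

**PD.** Fractional pump inhibition `I` follows the binding kinetics

    dI/dt = k · Ce · (Imax − I) − kd · I

with `k = kd/Ki`, `kd = ln(2)/dissociation half-life`, `Ki = IC50/2`, and
`Ce` the free drug concentration at the gastric site of action, computed
from the gut-tissue amount and enriched 1000-fold (`intersys`) at the
proton pump. Gastric pH maps linearly from `I` between a fasting baseline
(pH 1.2) and a ceiling calibrated once against a clinical holding-time
endpoint. The endpoints are `holding_time_percentage()` (% of 24 h with
pH > 4) and `onset_time()` (first crossing of pH 4).

**Parameter machinery.** The package also ships compact, fully tested
implementations of the upstream parameter-prediction tooling: a
message-passing neural network forward pass on molecular graphs
(permutation-invariant by construction), an m5p model-tree random forest
(variance-minimising splits, OLS linear leaves, bagging), 10-fold model
selection by MAE, and the deterministic derived-ADME formulas
(`fup = 1 − ppbr`, `CLapp = Vss·0.693/t½`, `gi_ka = 2·Papp/r` with
r = 1.25 cm).

## Worked example

The bundled vonoprazan parameter set, with the published calibration preset
(fraction absorbed halved, clearance ×3.08, absorption rate ÷3.5), 20 mg
single oral dose:

```r
library(pcabsim)

von  <- vonoprazan_parameters(calibrated = TRUE)
pk   <- simulate_pk(von, dose_regimen(20, duration_h = 48))
glance(pk)
#> # A tibble: 1 × 10
#>   compound   dose_mg auc_0_t auc_0_inf  cmax  tmax terminal_half_life ...
#> 1 vonoprazan      20    241.      248.  19.9  1.80               10.5

max(pk$data$stomach_free_ng_mL)      # peak gastric concentration, ng/mL
#> [1] 449.0118  (about 22.6-fold the plasma Cmax)

pot <- potency_parameters("vonoprazan", ic50_uM = 0.019,
                          dissociation_half_life_h = 4.7)
cfg <- calibrate_ph_mapping(pk, pot, target_holding_pct = 88.88)
pd  <- simulate_pd(pk, pot, cfg)
glance(pd)
#> # A tibble: 1 × 6
#>   compound   dose_mg holding_time_pct onset_h threshold window_h
#> 1 vonoprazan      20             88.9  0.0200         4       24
```

Reading the numbers: a 20 mg dose yields a plasma peak of ~19.9 ng/mL at
1.8 h with a 10.5 h terminal half-life and 48-h exposure of ~241 ng·h/mL;
the gastric compartment concentrates the drug ~23-fold over plasma; with
the pH ceiling calibrated to the clinical 88.88% holding-time endpoint, the
model holds gastric pH above 4 for ~21.3 of 24 hours. Dose screening across
compounds uses `run_screen()` and `rank_compounds()`; plots come from
`autoplot()` on any result object.

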