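# fosfopk

Population pharmacokinetics and dose optimization of intravenous
fosfomycin for critically ill patients with and without kidney replacement
therapy (KRT).

Fosfomycin is a hydrophilic, renally cleared, highly dialyzable
broad-spectrum antibiotic. In intensive-care patients its exposure is
shaped simultaneously by residual kidney function and by the dialysis
circuit — continuous KRT (CKRT, low dialysate flow for days) or
prolonged-intermittent KRT (PIKRT, high flow for 6–8 h sessions). This
package implements, as a tested and reusable pipeline, a population PK
analysis of pooled data from four clinical studies in this setting:

* **Model** — a two-compartment infusion model with two parallel
  elimination pathways acting on the central compartment,

  CL_body = θ_CL · (eGFR_MDRD / 48.4)^θ_KF · e^η  (zero for anuric
  patients), and CL_KRT = θ_DIAL · (Q_D / 42)^θ_QD while dialysis runs
  (zero between sessions); in anuric patients the peripheral volume grows
  linearly with time since first dose, V_P(t) = θ_VP (1 + TSFD·θ_T).
  At the published estimates the typical clearances are 1.6 L/h (body,
  at the reference eGFR) and 2.0 L/h (dialysis, at the reference
  dialysate flow), and V_P grows by 0.07 %/min.
* **Simulation** — exact piecewise bi-exponential propagation (compiled,
  vectorized over subjects) cross-checked against a `deSolve` integrator;
  Monte Carlo probability of target attainment (PTA) for AUC₂₄₋₄₈/MIC
  targets 22.7 (bacteriostatic) and 83.3 (bactericidal) and %T₂₄₋₄₈>MIC
  target 69.0, over MICs 4–512 mg/L; dose recommendation tables (lowest
  adequate of 4/5/8 g TID, 8 g BID, 4 g QID at PTA ≥ 90 %, fallback 80 %).
* **Estimation** — Laplace-approximation maximum marginal likelihood for
  the nonlinear mixed-effects model on NONMEM-style event datasets,
  likelihood-ratio model comparison (ΔOFV 3.84 / 6.63), stepwise covariate
  search, empirical Bayes estimates, conditional weighted residuals and
  prediction-corrected visual predictive checks.
* **Synthetic data** — a generator emulating the four studies' designs
  (45 subjects, 10/8/15/12; study-specific regimens, infusion durations,
  KRT schedules, sampling times and covariate distributions), since the
  clinical data are available only on request.
* **Covariate toolbox** — MDRD, CKD-EPI and Cockcroft–Gault kidney
  function equations, Mosteller body surface area, KDIGO categories, the
  anuria rule, and carry-forward/median imputation.

## Worked example

Probability of target attainment for 5 g three-times-daily dosing in a
CKRT patient population with eGFR 31–60 mL/min/1.73 m²:

```r
library(fosfopk)

fx <- fosfo_fixed_effects()   # published typical values
re <- fosfo_random_effects()  # published variability

typical_cl_body(48.4, anuric = FALSE, study_b = FALSE, fx)
#> [1] 1.6
typical_cl_krt(42, krt_active = TRUE, fx)
#> [1] 2

sc  <- fosfo_scenario("5gTID", "ckrt", "31-60", n_subjects = 2000)
res <- run_scenario(sc, fx, re, seed = 1)
subset(res, mic %in% c(32, 64) & target == "auc_bacteriostatic",
       select = c(regimen, krt_type, egfr_stratum, mic, pta))
#>   regimen krt_type egfr_stratum mic    pta
#> 4   5gTID     ckrt        31-60  32 0.9995
#> 5   5gTID     ckrt        31-60  64 0.9895
```

So 5 g TID keeps ~99 % of this virtual population above the
bacteriostatic AUC₂₄₋₄₈/MIC target up to MIC 64 mg/L — the kind of cell
from which the recommendation tables are assembled
(`run_scenario_grid()` + `recommend_doses()`).

Re-estimating the model from a synthetic cohort:

```r
ds  <- generate_cohort(seed = 1)      # 45 subjects, four study designs
fit <- fosfo_fit(ds, compute_rse = FALSE)
round(fit$estimates[c("theta_cl", "theta_vc", "theta_dial", "theta_kf")], 3)
#>   theta_cl   theta_vc theta_dial   theta_kf
#>      1.897     22.003      2.243      0.997
```

(Generating values: 1.6, 23.1, 2.0, 0.869 — recovery within the sampling
and approximation uncertainty of a 45-subject design.)

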