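---
title: "Population PK of IV fosfomycin under kidney replacement therapy: model, simulation and estimation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK of IV fosfomycin under kidney replacement therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosfopk)
```

## The problem

Fosfomycin is a small, hydrophilic, essentially protein-unbound antibiotic
that is cleared almost entirely by the kidneys and is therefore highly
dialyzable. In critically ill patients, kidney function ranges from anuria
to augmented clearance, and many patients receive kidney replacement
therapy (KRT) — either continuous (CKRT, low dialysate flow for days) or
prolonged-intermittent (PIKRT, high dialysate flow for 6–8 h sessions).
Both the patient's own elimination and the dialysis circuit then act on the
drug at the same time, and a fixed label dose can be substantially off in
either direction. `fosfopk` implements a population pharmacokinetic (PK)
model that separates these two elimination pathways, a Monte Carlo
simulation layer that converts the model into probability-of-target-
attainment (PTA) tables and dose recommendations, a mixed-effects estimator
able to re-fit the model to NONMEM-style datasets, and a synthetic-data
generator that emulates the four pooled clinical studies behind the model.

## The structural model

Drug amounts in a central (volume $V_C$) and a peripheral (volume $V_P$)
compartment follow

$$
\frac{dA_c}{dt} = r(t)
  - \frac{CL_{body} + CL_{KRT}(t)}{V_C} A_c
  - \frac{Q}{V_C} A_c + \frac{Q}{V_P(t)} A_p, \qquad
\frac{dA_p}{dt} = \frac{Q}{V_C} A_c - \frac{Q}{V_P(t)} A_p,
$$

with $r(t)$ the zero-order infusion rate and both elimination pathways
acting on the central compartment, as in the model's schematic. The
covariate model is

* $CL_{body} = \theta_{CL} \,(eGFR_{MDRD}/48.4)^{\theta_{KF}}\, e^{\eta_{CL}}$,
  forced to exactly zero for anuric patients (24-h urine output < 100 mL)
  and for the study whose patients showed no elimination between dialysis
  sessions (a dataset flag, not an automatic rule, because the
  classification was made on the observed concentration profiles);
* $CL_{KRT} = \theta_{DIAL}\,(Q_D/42)^{\theta_{QD}}$ while dialysis runs and
  exactly zero otherwise — dialysis windows are half-open $[start, end)$;
* $V_P(t) = \theta_{VP}\,(1 + TSFD \cdot \theta_T)\, e^{\eta_{VP}}$ for
  anuric patients (time since first dose in minutes; 0.07 %/min at the
  default estimate), constant otherwise. The growing volume reflects fluid
  retention during severely reduced kidney function.

Inter-individual variability is lognormal on $CL_{body}$, $V_C$ and $V_P$
with a diagonal covariance (no correlations are reported for the source
model); residual error is combined proportional + additive on the
concentration scale, $Var = (\sigma_{prop}\,C)^2 + \sigma_{add}^2$. The
shipped parameter presets are the published full-data-set estimates
(`fosfo_fixed_effects()`, `fosfo_random_effects()`), with the reduced-data-set
column available as `preset = "reduced"`.

Two readings of the published table required a decision. First, the
proportional residual "%CV" is interpreted as an SD fraction (0.147), the
standard reporting convention. Second, $\eta_{VP}$ multiplies the whole
time-varying peripheral volume, so slope and intercept scale together —
the literal reading of the published equation.

## Numerical engine

All internal time is hours; $\theta_T$ (per minute) is converted once at
the model boundary. Dose events and KRT windows are compiled into maximal
segments on which the infusion rate and dialysis clearance are constant
(`build_segments()`). Within a segment the system is linear with constant
coefficients, and the package advances it with the exact spectral
(bi-exponential) solution of the $2\times2$ rate matrix — the same closed
form exposed as `analytic_twocpt()`. A repeated-eigenvalue guard
(discriminant floored at $10^{-12}$) covers the measure-zero degenerate
configurations. For anuric subjects the peripheral volume grows in time,
so segments are subdivided into steps of at most 0.1 h (simulation) or
0.25 h (estimation) with $V_P$ frozen at the step midpoint; at the default
growth rate of 0.07 %/min the volume changes by under 0.5 % within a step
and the induced error is well below the 0.1 % verification tolerance used
in the tests. The propagation loop is compiled code, vectorized over a
batch of subjects (Monte Carlo) or over a batch of candidate random-effect
vectors (estimation), which is what makes 2,000-subject scenarios and
45-subject Laplace fits run in seconds to minutes. Working in amounts
rather than concentrations conserves mass while $V_P(t)$ grows; the
peripheral flux uses the instantaneous volume, the literal reading of the
published equation.

`simulate_profile()` is an independent implementation of the same model by
stiff-capable numerical integration (`deSolve::lsoda`, tolerances
$10^{-10}$ relative), restarted at every segment breakpoint so that
discontinuities are never interpolated across. The test suite holds the
closed-form path and the integrator to within $10^{-3}$ relative deviation
over randomized parameter batteries, and checks mass balance
($\int CL(t)\,C\,dt$ + drug on board = dose infused) to 0.5 %.

## PK/PD indices, PTA and dose recommendation

Two indices are evaluated over the second treatment day (24–48 h):
$AUC_{24-48}/MIC$ (bacteriostatic threshold 22.7, bactericidal 83.3) and
$\%T_{24-48>MIC}$ (bactericidal threshold 69.0). AUC uses trapezoidal
integration on the 0.1 h output grid with interpolated window endpoints;
time-above-MIC locates crossings by linear interpolation between grid
nodes. Attainment is evaluated as $\ge$ the printed threshold; under
continuous inter-individual variability ties have probability zero, so the
choice of $\ge$ versus $>$ is immaterial but documented. PTA is computed
on individual-predicted concentrations with residual error excluded —
standard pharmacometric practice, since residual error represents assay
noise rather than true exposure.

A scenario (`fosfo_scenario()`) crosses a regimen (4/5/8 g TID, 8 g BID,
4 g QID; TID = q8h, BID = q12h, QID = q6h, clocks starting at 0 h), a KRT
modality (none; CKRT at $Q_D$ = 42 mL/min over 0–48 h; PIKRT at 250 mL/min
for 8 h starting at 24 h) and a kidney-function stratum. eGFR within a
stratum is drawn uniformly over the stratum interval — the source analysis
simulated eGFR 0–120 and reports band-level results without stating the
within-band sampling scheme, so this is the main reproduction uncertainty
and is configuration-exposed. The anuria stratum forces $CL_{body} = 0$
and activates the growing $V_P$. The simulated infusion duration defaults
to 60 min (the studies used 30–120 min and the simulated value is not
stated); it is a scenario argument. PIKRT scenarios have no dialysis
before 24 h. Default 2,000 subjects per scenario over a MIC doubling grid
4–512 mg/L.

`recommend_doses()` picks, per KRT type, stratum, target and MIC, the
lowest regimen by daily dose reaching PTA $\ge$ 90 %, falling back to
$\ge$ 80 % (flagged), else `"N/A"`. Daily-dose order is 12 (4 g TID) <
15 (5 g TID) < 16 (8 g BID before 4 g QID — fewer administrations wins the
tie) < 24 g (8 g TID).

## Estimation

`fosfo_fit()` maximizes the marginal likelihood with a Laplace
approximation: per subject, the conditional $-2\log$ joint density (with
the residual variance evaluated at the conditional prediction, i.e. with
interaction) is minimized over $\eta$ by a damped Newton iteration whose
finite-difference gradients and Hessians are obtained from one batched
19-point stencil evaluation; the mode is the empirical Bayes estimate and
the log-determinant curvature term completes the subject's contribution.
This replaces the FOCE-I algorithm of the original analysis, whose exact
interaction terms are internal to NONMEM; a quadrature oracle in the test
suite bounds the approximation error on a one-dimensional toy at 0.5
objective-function units.

Positive parameters are estimated on the log scale, the two power-law
exponents unbounded, variances via their logarithms. Inner optimizations
are warm-started at the previous outer iteration's empirical Bayes
estimates; because that makes the objective very slightly
history-dependent, the outer optimizer (`nlminb`) is given an explicit
central-difference gradient with a step ($10^{-3}$ on the internal scale)
chosen to dominate that noise. Default initial values are deliberately
generic (e.g. $CL$ 1 L/h, volumes 20 L, exponents 0.5) rather than the
published estimates. Relative standard errors come from the
finite-difference Hessian of the objective at the optimum
($\mathrm{Cov} = 2H^{-1}$), reported on the natural scale by the delta
method. Dose rows and KRT state rows never enter the likelihood;
below-quantification-limit handling is not implemented because none is
reported for the source data.

Model comparison uses the objective function ($-2\log L$) with chi-square
criteria (3.84 at $p$ = 0.05, 6.63 at $p$ = 0.01, 1 df);
`stepwise_covariate_search()` runs forward inclusion at 0.05 and backward
elimination at 0.01 over linear/power/Emax candidate effects, skipping and
logging candidates whose fits fail. Conditional weighted residuals use the
first-order approximation at the empirical Bayes estimates. The
prediction-corrected visual predictive check (`pcvpc()`) rescales
observations and re-simulated replicates by bin-median population
predictions over quantile time bins (empty bins merge with a neighbour)
and compares 5th/50th/95th percentiles against the simulation envelope.

## The synthetic cohort

No clinical data are distributed with the analysis (they are available
only on request), so `generate_cohort()` emulates the four study designs
as first-class, tested code: 45 subjects split 10/8/15/12.

* Study A: 5 g TID, 30–60 min infusions, one 8-h PIKRT session on day 2
  ($Q_D$ around 190 mL/min), samples anchored to the session start (0, 15,
  30, 60, 120, 240, 480 min); 3 anuric subjects. The offset between dosing
  and session start is not printed in the source; the session is placed at
  the 24 h dose, configurable.
* Study B: 5 g TID, a first-dose profile (30–390 min) plus samples around
  a 6-h PIKRT session on day 2 ($Q_D \approx$ 250 mL/min); the
  zero-body-clearance flag is set, and height and serum creatinine (hence
  eGFR) are missing by design, mirroring the source data and exercising
  the imputation rules.
* Study C: 5 g TID as 2-h infusions under CKRT ($Q_D \approx$ 33–42
  mL/min); dialysis covers 0–30 h and 40–48 h with a dialysis-free episode
  between, and two nine-sample series are anchored to the 24 h (on CKRT)
  and 32 h (off CKRT) doses so that both elimination pathways are
  observable, as the pooled data allowed; 7 anuric subjects.
* Study D: no KRT, 4 g QID (two subjects 6 g TID, mirroring the stated
  regimen heterogeneity), three sample series across 48 h.

Covariates are lognormal, matched by the method of quantiles to the
published per-study medians and interquartile ranges, with physiological
clamps and the implied BMI held to 15–50; anuric subjects draw urine
output uniformly below 100 mL. eGFR is computed from the sampled
creatinine, age and sex through the same MDRD function used by the model,
keeping the covariate set internally consistent. Sampling times are
jittered ±2 min by default (real sampling is never exact; switchable off
for exact-schedule tests). Observations are truncated at zero after
residual error is added. The generator reproduces the designs and
covariate structure; it does not emulate assay quantification limits,
dropout, correlated covariates beyond the BMI clamp, or within-subject
kidney-function dynamics (a random-walk eGFR stress mode is out of scope
by design) — so passing tests demonstrate correct model machinery on
design-faithful data, not performance on real clinical data.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 2,000 subjects per
simulated scenario (binomial SE ≈ 0.7 % near 90 % PTA), the full
45-subject synthetic cohort for the recovery fit, and reduced replicate
counts for the pcVPC self-consistency check (the published evaluation used
1,000 replicates; `n_rep` is an argument). Every stochastic entry point
requires an explicit seed, and identical seeds give bit-identical results;
scenario grids derive per-scenario seeds deterministically from the base
seed.

## Known limitations

* The Laplace approximation differs from FOCE-I; on sparse subjects with
  large variances the objective values are not expected to match NONMEM's
  to the unit, though parameter recovery is verified by simulation.
* $\omega^2_{CL}$ is informed only by the ~27 subjects with a nonzero body
  clearance and is the least precisely recovered variance.
* The dialyzer mass-transfer (Michaels/$K_oA$) formulation is deliberately
  not implemented: the source analysis tested and rejected it in favour of
  the $Q_D$ power law, and per-dialyzer coefficients would not generalize.
* Dialysate-side concentrations, fecal elimination and electrolyte safety
  endpoints are out of scope.

## A worked example

```{r example, eval = FALSE}
fx <- fosfo_fixed_effects()
re <- fosfo_random_effects()

# typical clearances at the reference covariate values
typical_cl_body(48.4, anuric = FALSE, study_b = FALSE, fx)  # 1.6 L/h
typical_cl_krt(42, krt_active = TRUE, fx)                   # 2.0 L/h

# PTA of 5 g TID at MIC 64 for CKRT patients with eGFR 31-60
sc <- fosfo_scenario("5gTID", "ckrt", "31-60", n_subjects = 2000)
res <- run_scenario(sc, fx, re, seed = 1)
subset(res, mic == 64)

# synthetic cohort and re-estimation
ds <- generate_cohort(seed = 1)
fit <- fosfo_fit(ds, compute_rse = FALSE)
fit$estimates
```
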