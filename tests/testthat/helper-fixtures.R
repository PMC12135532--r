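# Shared fixtures: all inputs are generated in code at test time.

fx_pub <- fosfo_fixed_effects()
re_pub <- fosfo_random_effects()

# a typical non-anuric subject at the reference eGFR
params_ref <- function(eta = c(0, 0, 0), egfr = 48.4, anuric = FALSE) {
  individual_params(fx_pub, eta, list(egfr = egfr, anuric = anuric))
}

# single 1-h infusion of 4 g, 8-h horizon
reg_single <- fosfo_regimen(start_times = 0, amounts = 4000, duration_h = 1)

# cumulative infused amount of a regimen evaluated on a time grid
cumsum_infused <- function(reg, grid) {
  vapply(grid, function(t) {
    sum(pmin(pmax(t - reg$start, 0), reg$duration) *
          reg$amount / reg$duration)
  }, numeric(1))
}

# a small rich-design subject for likelihood-level tests
toy_subject <- function(dv, obs_times = c(1, 3, 6), egfr = 48.4,
                        anuric = FALSE, study_b = FALSE,
                        krt = krt_schedule("none")) {
  regimen <- fosfo_regimen(start_times = 0, amounts = 4000, duration_h = 1)
  fosfopk:::make_subject(
    1L, regimen, krt,
    cov = list(egfr = egfr, anuric = anuric, study_b = study_b,
               wt = 80, ht = 175, age = 60, sex = "male", uo24 = 500,
               qd = if (nrow(krt)) krt$qd[1] else NA_real_),
    obs_times = obs_times, dv = dv, horizon_h = max(obs_times) + 1)
}
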