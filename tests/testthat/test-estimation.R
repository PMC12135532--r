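test_that("conditional -2LL matches a term-by-term oracle on a toy subject", {
  dv <- c(120, 60, 30)
  s <- toy_subject(dv)
  eta <- c(0.2, -0.1, 0.3)
  p <- individual_params(fx_pub, eta, list(egfr = 48.4, anuric = FALSE))
  pred <- analytic_twocpt(p, s$regimen, s$obs_times)$conc
  v <- residual_variance(pred, re_pub)
  oracle <- -2 * (sum(dnorm(dv, pred, sqrt(v), log = TRUE)) +
                    sum(dnorm(eta, 0,
                              sqrt(unlist(re_pub[c("omega2_cl", "omega2_vc",
                                                   "omega2_vp")])),
                              log = TRUE)))
  expect_equal(conditional_minus2ll(s, fx_pub, re_pub, eta), oracle,
               tolerance = 1e-6)
  # a flat prior limit leaves the pure residual fit
  re_flat <- fosfo_random_effects(omega2_cl = 1e6, omega2_vc = 1e6,
                                  omega2_vp = 1e6)
  res_only <- -2 * sum(dnorm(dv, pred, sqrt(residual_variance(pred, re_flat)),
                             log = TRUE))
  prior <- -2 * sum(dnorm(eta, 0, sqrt(1e6), log = TRUE))
  expect_equal(conditional_minus2ll(s, fx_pub, re_flat, eta),
               res_only + prior, tolerance = 1e-6)
})

test_that("degenerate residual error is guarded", {
  s <- toy_subject(c(120, 60, 30))
  re0 <- fosfo_random_effects(sigma_prop = 0.1, sigma_add = 0)
  # proportional-only variance collapses where the prediction is zero
  # (pre-dose observation at t = 0)
  s0 <- toy_subject(c(0, 60, 30), obs_times = c(0, 1, 2))
  expect_error(conditional_minus2ll(s0, fx_pub, re0, c(0, 0, 0)),
               "degenerate")
})

test_that("Laplace marginal agrees with a quadrature oracle on a 1-eta toy", {
  s <- toy_subject(c(130, 70, 35))
  # clearance eta only; volume etas pinned by a near-degenerate prior
  re1 <- fosfo_random_effects(omega2_cl = 0.4, omega2_vc = 1e-8,
                              omega2_vp = 1e-8)
  lap <- laplace_marginal(s, fx_pub, re1)
  # integrate the conditional density over eta_cl; the pinned etas
  # contribute their own (sharp) Gaussian integrals exactly
  # strip the pinned etas' prior density terms: their dimensions
  # integrate to one over their own sharp Gaussians
  f1 <- Vectorize(function(e) {
    exp(-0.5 * (conditional_minus2ll(s, fx_pub, re1, c(e, 0, 0)) +
                  2 * sum(dnorm(c(0, 0), 0, sqrt(1e-8), log = TRUE))))
  })
  marg <- integrate(f1, -4, 4, rel.tol = 1e-10)$value
  oracle <- -2 * log(marg)
  expect_equal(as.numeric(lap), oracle, tolerance = 0.5)
})

test_that("a vanishing prior reduces the marginal to the eta = 0 residual fit", {
  s <- toy_subject(c(130, 70, 35))
  re0 <- fosfo_random_effects(omega2_cl = 1e-8, omega2_vc = 1e-8,
                              omega2_vp = 1e-8)
  lap <- laplace_marginal(s, fx_pub, re0)
  p <- individual_params(fx_pub, c(0, 0, 0), list(egfr = 48.4,
                                                  anuric = FALSE))
  pred <- analytic_twocpt(p, s$regimen, s$obs_times)$conc
  res_fit <- -2 * sum(dnorm(s$dv, pred,
                            sqrt(residual_variance(pred, re_pub)),
                            log = TRUE))
  expect_equal(as.numeric(lap), res_fit, tolerance = 0.1)
})

test_that("likelihood-ratio thresholds match the chi-square quantiles", {
  expect_equal(round(qchisq(0.95, 1), 2), 3.84)
  expect_equal(round(qchisq(0.99, 1), 2), 6.63)
  expect_true(as.logical(lrt(1004, 1000, df = 1, alpha = 0.05)))
  expect_false(as.logical(lrt(1003.8, 1000, df = 1, alpha = 0.05)))
  expect_false(as.logical(lrt(1006, 1000, df = 1, alpha = 0.01)))
  expect_true(as.logical(lrt(1006.7, 1000, df = 1, alpha = 0.01)))
  expect_warning(sig <- lrt(1000, 1002, df = 1), "worse")
  expect_false(as.logical(sig))
  expect_equal(attr(lrt(1010, 1000, 1), "dofv"), 10)
})

test_that("fixed effects are recovered from near-noise-free data", {
  # rich designs, no IIV, tiny residual error: the structural parameters
  # must come back to well under 1% relative error
  specs <- study_specs()[c("C", "D")]
  specs$C$n <- 4; specs$D$n <- 4
  specs$C$n_anuric <- 1
  re_tiny <- fosfo_random_effects(omega2_cl = 1e-6, omega2_vc = 1e-6,
                                  omega2_vp = 1e-6, sigma_prop = 1e-3,
                                  sigma_add = 0.05)
  ds <- generate_cohort(specs, fx_pub, re_tiny, seed = 61, residual = TRUE,
                        jitter_min = 0)
  fit <- fosfo_fit(ds, compute_rse = FALSE,
                   init = c(omega2_cl = 1e-6, omega2_vc = 1e-6,
                            omega2_vp = 1e-6, sigma_prop = 1e-3,
                            sigma_add = 0.05),
                   fixed = c("omega2_cl", "omega2_vc", "omega2_vp",
                             "sigma_prop", "sigma_add"),
                   control = list(rel.tol = 1e-10, iter.max = 250))
  for (nm in c("theta_cl", "theta_vc", "theta_vp", "theta_q", "theta_dial",
               "theta_kf", "theta_qd")) {
    expect_equal(unname(fit$estimates[nm]), fx_pub[[nm]],
                 tolerance = 0.01, label = nm)
  }
})

test_that("the fit reports RSEs and serializes its report", {
  specs <- study_specs()["C"]
  specs$C$n <- 5
  specs$C$n_anuric <- 2
  ds <- generate_cohort(specs, fx_pub, re_pub, seed = 71)
  fit <- fosfo_fit(ds, compute_rse = TRUE,
                   fixed = c("theta_kf", "theta_t"),
                   init = c(theta_kf = fx_pub$theta_kf,
                            theta_t = fx_pub$theta_t),
                   control = list(rel.tol = 1e-6, iter.max = 60))
  free <- setdiff(names(fit$estimates), c("theta_kf", "theta_t"))
  expect_true(all(is.finite(fit$rse[free])))
  expect_true(all(fit$rse[free] >= 0))
  expect_equal(dim(fit$ebe), c(5L, 3L))
  path <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(fit, path)
  expect_true(any(grepl("^ofv", readLines(path))))
  expect_true(file.exists(sub("\\.txt$", "_ebe.tsv", path)))
})

test_that("conditional weighted residuals are standardized under the true model", {
  ds <- generate_cohort(seed = 81)
  subs <- split_subjects(impute_covariates(
    ds, columns = c("EGFR", "WT", "HT", "AGE", "UO24")))
  ebe <- do.call(rbind, lapply(subs, function(s) {
    attr(laplace_marginal(s, fx_pub, re_pub), "eta")
  }))
  pseudo_fit <- structure(
    list(fx = fx_pub, re = re_pub, spec = fosfo_model_spec(),
         extra_beta = list(), ebe = ebe, subjects = subs),
    class = "fosfo_fit")
  cw <- weighted_residuals(pseudo_fit)
  expect_equal(nrow(cw), sum(ds$EVID == 0))
  expect_lt(abs(mean(cw$CWRES)), 0.15)
  expect_equal(var(cw$CWRES), 1, tolerance = 0.2)
  # degenerate residual error is refused
  re0 <- fosfo_random_effects(sigma_prop = 0, sigma_add = 0)
  pf0 <- pseudo_fit; pf0$re <- re0
  expect_error(weighted_residuals(pf0), "degenerate|singular")
})

test_that("stepwise search finds a strong simulated eGFR effect and prunes noise", {
  # data generated with the eGFR power law on; base model starts without
  # it; candidates: the true eGFR effect and an irrelevant age effect
  specs <- study_specs()["D"]
  specs$D$n <- 8
  re_small <- fosfo_random_effects(omega2_cl = 0.05, omega2_vc = 0.05,
                                   omega2_vp = 0.05, sigma_prop = 0.05,
                                   sigma_add = 2)
  ds <- generate_cohort(specs, fx_pub, re_small, seed = 91)
  base <- fosfo_model_spec(egfr_on_cl = FALSE, qd_on_clkrt = FALSE,
                           tsfd_on_vp = FALSE)
  first <- ds[!duplicated(ds$ID), ]
  cands <- list(
    covariate_candidate("cl", "egfr", "power", ref = median(first$EGFR)),
    covariate_candidate("vc", "age", "linear", ref = median(first$AGE)))
  res <- stepwise_covariate_search(
    ds, base, cands,
    init = c(omega2_cl = 0.05, omega2_vc = 0.05, omega2_vp = 0.05,
             sigma_prop = 0.05, sigma_add = 2),
    control = list(rel.tol = 1e-6, iter.max = 80))
  expect_true("cl-egfr-power" %in% res$selected)
  expect_false("vc-age-linear" %in% res$selected)
  expect_true(all(c("step", "candidate", "dofv", "action") %in%
                    names(res$trace)))
  # the recovered exponent should be in the vicinity of the truth
  beta <- res$fit$estimates[grep("cl-egfr-power", names(res$fit$estimates))]
  expect_equal(unname(beta), fx_pub$theta_kf, tolerance = 0.5)
})
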