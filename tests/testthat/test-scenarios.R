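test_that("population simulation matches per-subject integration", {
  grid <- seq(0, 48, by = 0.1)
  reg <- fosfo_regimen("4gTID")
  krt <- krt_schedule("pikrt")
  etas <- draw_etas(re_pub, 3, seed = 33)
  egfr <- c(20, 55, 0)
  anuric <- c(FALSE, FALSE, TRUE)
  pop <- simulate_population(3, reg, krt, fx_pub, re_pub, egfr = egfr,
                             anuric = anuric, etas = etas, grid = grid)
  for (i in 1:3) {
    p <- individual_params(fx_pub, etas[i, ],
                           list(egfr = egfr[i], anuric = anuric[i]))
    ref <- simulate_profile(p, reg, grid, krt)
    expect_lt(max(abs(pop$conc[i, ] - ref$conc) / pmax(ref$conc, 1e-3)),
              1e-3)
  }
})

test_that("scenario runs are seed-reproducible with valid stratified inputs", {
  sc <- fosfo_scenario("4gTID", "ckrt", "31-60", n_subjects = 100)
  r1 <- run_scenario(sc, fx_pub, re_pub, seed = 5)
  r2 <- run_scenario(sc, fx_pub, re_pub, seed = 5)
  attr(r1, "population") <- attr(r2, "population") <- NULL
  expect_identical(r1, r2)
  expect_error(run_scenario(sc, fx_pub, re_pub), "seed")
  expect_error(fosfo_scenario("9gXID", "ckrt", "31-60"), "unknown")
  expect_error(fosfo_scenario("4gTID", "ckrt", "40-70"), "stratum")
})

test_that("anuric dialysis scenarios have no clearance IIV pathway", {
  # with volume IIV suppressed, all anuric CKRT subjects share one profile
  re0 <- fosfo_random_effects(omega2_cl = re_pub$omega2_cl,
                              omega2_vc = 0, omega2_vp = 0)
  pop <- simulate_population(20, fosfo_regimen("4gTID"),
                             krt_schedule("ckrt"), fx_pub, re0, egfr = 0,
                             anuric = TRUE, seed = 8)
  spread <- apply(pop$conc[, -1], 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-8)
})

test_that("anuric CKRT exposure stays below the steady-state bound", {
  sc <- fosfo_scenario("4gTID", "ckrt", "anuria", n_subjects = 400)
  res <- run_scenario(sc, fx_pub, re_pub, seed = 12)
  pop <- attr(res, "population")
  auc <- fosfopk:::auc_rows(pop$times, pop$conc, 24, 48)
  # daily dose / CL_KRT = 12000 / 2.0; accumulation incomplete by 24-48 h
  expect_lt(median(auc), 12000 / 2.0)
})

test_that("PTA is monotone in dose at fixed scenario and MIC", {
  tab <- do.call(rbind, lapply(c("4gTID", "8gBID", "8gTID"), function(rg) {
    sc <- fosfo_scenario(rg, "ckrt", "31-60", n_subjects = 500)
    run_scenario(sc, fx_pub, re_pub,
                 targets = list(cid = pkpd_target("auc_over_mic", 83.3)),
                 mic_grid = c(32, 64), seed = 40)
  }))
  for (m in c(32, 64)) {
    p <- tab$pta[tab$mic == m]   # daily doses 12, 16, 24 g
    expect_true(all(diff(p) >= -0.02))  # monotone up to MC noise
  }
})

test_that("dose recommendation picks the lowest adequate regimen with 80% fallback", {
  base <- expand.grid(krt_type = "ckrt", egfr_stratum = "31-60",
                      target = "cid", mic = 32,
                      regimen = c("4gTID", "5gTID", "8gBID", "4gQID",
                                  "8gTID"), stringsAsFactors = FALSE)
  tab <- transform(base, pta = c(0.85, 0.92, 0.95, 0.94, 0.99))
  rec <- recommend_doses(tab)
  expect_equal(rec$regimen, "5gTID")
  expect_equal(rec$level, 0.9)
  tab$pta <- c(0.70, 0.81, 0.86, 0.85, 0.89)   # only the 80% level works
  rec <- recommend_doses(tab)
  expect_equal(rec$regimen, "5gTID")
  expect_equal(rec$level, 0.8)
  tab$pta <- rep(0.5, 5)
  expect_equal(recommend_doses(tab)$regimen, "N/A")
  tab$pta <- c(0.95, 0.99, 0.99, 0.99, 0.99)   # lowest dose wins
  expect_equal(recommend_doses(tab)$regimen, "4gTID")
  expect_error(recommend_doses(tab[-1, ]), "missing")
})

test_that("recommended dose is non-increasing as kidney function falls", {
  tab <- run_scenario_grid(regimens = c("4gTID", "5gTID", "8gBID", "4gQID",
                                        "8gTID"),
                           krt_types = "ckrt",
                           strata_krt = c("anuria", "0-30", "31-60"),
                           n_subjects = 400,
                           targets = list(cid = pkpd_target("auc_over_mic",
                                                            83.3)),
                           mic_grid = 32, seed = 99)
  rec <- recommend_doses(tab)
  daily <- c("4gTID" = 12, "5gTID" = 15, "8gBID" = 16, "4gQID" = 16,
             "8gTID" = 24, "N/A" = Inf)
  doses <- daily[rec$regimen[match(c("anuria", "0-30", "31-60"),
                                   rec$egfr_stratum)]]
  expect_true(all(diff(doses) >= 0))  # more kidney function, same or more dose
})

test_that("pcVPC is self-consistent when the data come from the model", {
  specs <- study_specs()[c("C", "D")]
  ds <- generate_cohort(specs, fx_pub, re_pub, seed = 77)
  res <- pcvpc(ds, fx_pub, re_pub, n_rep = 120, bins = 6, seed = 14)
  expect_true(all(c("bin", "percentile", "observed", "sim_lower",
                    "sim_upper") %in% names(res)))
  inside <- with(res, observed >= sim_lower & observed <= sim_upper)
  # observed percentiles fall inside the simulated 90% envelope in the
  # vast majority of bins (binomial tolerance at 18 bin x percentile cells)
  expect_gte(mean(inside), 0.75)
  # with one replicate the envelope degenerates to that replicate
  smoke <- pcvpc(ds, fx_pub, re_pub, n_rep = 1, bins = 3, seed = 2)
  expect_equal(smoke$sim_lower, smoke$sim_upper)
})
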