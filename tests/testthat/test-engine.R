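test_that("segment compilation breaks exactly at dose and KRT event times", {
  seg <- build_segments(reg_single, krt_schedule("none"), 8)
  expect_equal(seg$start, c(0, 1))
  expect_equal(seg$end, c(1, 8))
  expect_equal(seg$rate, c(4000, 0))

  # TID over 48 h with a PIKRT window [24, 32]: breakpoints enumerated
  # brute-force from the event times
  reg <- fosfo_regimen("5gTID", horizon_h = 48)
  krt <- krt_schedule("pikrt")
  bp <- sort(unique(c(0, 48, reg$start, reg$start + reg$duration, 24, 32)))
  seg <- build_segments(reg, krt, 48)
  expect_equal(nrow(seg), length(bp) - 1)
  expect_equal(seg$start, bp[-length(bp)])
  expect_equal(seg$end, bp[-1])
  # union of segments covers [0, 48] without gaps
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  # KRT windows are half-open [start, end)
  expect_true(seg$krt_active[seg$start == 24][1])
  expect_false(any(seg$krt_active[seg$start >= 32]))

  empty <- build_segments(NULL, krt_schedule("none"), 12)
  expect_equal(nrow(empty), 1)
  expect_equal(empty$rate, 0)

  bad <- data.frame(start = c(0, 4), end = c(6, 10), qd = 42)
  expect_error(krt_schedule(windows = bad), "overlap")
  expect_error(build_segments(reg_single, krt_schedule("none"), 0.5),
               "horizon")
})

test_that("numeric integrator matches the closed-form two-compartment solution", {
  grid <- seq(0, 24, by = 0.25)
  reg <- fosfo_regimen(dose_mg = 5000, interval_h = 8, duration_h = 0.5,
                       horizon_h = 24)
  set.seed(101)
  for (rep in 1:6) {
    p <- params_ref(eta = rnorm(3, 0, 0.5), egfr = runif(1, 10, 120))
    krt <- if (rep %% 2) krt_schedule("ckrt", horizon_h = 24) else
      krt_schedule("none")
    a <- analytic_twocpt(p, reg, grid, krt)
    s <- simulate_profile(p, reg, grid, krt)
    expect_lt(max(abs(a$conc - s$conc) / pmax(abs(s$conc), 1e-3)), 1e-3)
  }
})

test_that("the anuric growing peripheral volume is integrated consistently", {
  grid <- seq(0, 48, by = 0.1)
  p <- individual_params(fx_pub, c(0, 0.2, -0.1),
                         list(egfr = 0, anuric = TRUE))
  krt <- krt_schedule("pikrt")
  reg <- fosfo_regimen("5gTID")
  s <- simulate_profile(p, reg, grid, krt)
  a <- fosfopk:::propagate_twocpt(
    grid, fosfopk:::segment_clearances(build_segments(reg, krt, 48), fx_pub),
    p$cl_body, p$v_c, p$v_p0, p$vp_slope, p$q, dt_max = 0.1)
  expect_lt(max(abs(drop(a$conc) - s$conc) / pmax(s$conc, 1e-3)), 1e-3)
})

test_that("mass balance: eliminated plus remaining drug equals the infused dose", {
  grid <- seq(0, 48, by = 0.05)
  reg <- fosfo_regimen("4gTID")
  krt <- krt_schedule("ckrt")
  p <- params_ref(egfr = 60)
  s <- simulate_profile(p, reg, grid, krt)
  seg <- fosfopk:::segment_clearances(build_segments(reg, krt, 48), fx_pub)
  cl_t <- p$cl_body + seg$cl_krt[findInterval(grid, seg$start)]
  elim <- sum(diff(grid) * (cl_t * s$conc)[-length(grid)] +
                diff(cl_t * s$conc) * diff(grid) / 2)
  infused <- sum(reg$amount)
  remaining <- sum(s$amounts[length(grid), ])
  expect_equal((elim + remaining) / infused, 1, tolerance = 5e-3)
})

test_that("no-elimination anuric subject accumulates exactly the infused amount", {
  p <- individual_params(fx_pub, c(0, 0, 0), list(egfr = 0, anuric = TRUE))
  grid <- seq(0, 30, by = 0.1)
  s <- simulate_profile(p, fosfo_regimen("5gTID", horizon_h = 30), grid)
  infused <- cumsum_infused(fosfo_regimen("5gTID", horizon_h = 30), grid)
  expect_equal(rowSums(s$amounts), infused, tolerance = 1e-5)
})

test_that("constant-parameter kinetics are linear and superposable", {
  grid <- seq(0, 48, by = 0.2)
  p <- params_ref(egfr = 40)
  reg2 <- fosfo_regimen(start_times = c(0, 8), amounts = c(4000, 4000),
                        duration_h = 1)
  both <- analytic_twocpt(p, reg2, grid)
  d1 <- analytic_twocpt(p, fosfo_regimen(start_times = 0, amounts = 4000,
                                         duration_h = 1), grid)
  d2 <- analytic_twocpt(p, fosfo_regimen(start_times = 8, amounts = 4000,
                                         duration_h = 1), grid)
  expect_equal(both$conc, d1$conc + d2$conc, tolerance = 1e-9)
  dbl <- analytic_twocpt(p, fosfo_regimen(start_times = c(0, 8),
                                          amounts = c(8000, 8000),
                                          duration_h = 1), grid)
  expect_equal(dbl$conc, 2 * both$conc, tolerance = 1e-9)
})

test_that("single-dose AUC to infinity equals dose over total clearance", {
  p <- params_ref(egfr = 48.4)   # CL_body = 1.6 L/h, no KRT
  grid <- seq(0, 700, by = 0.5)
  prof <- analytic_twocpt(p, reg_single, grid)
  expect_equal(auc_window(prof, 0, 700), 4000 / 1.6, tolerance = 1e-3)
})

test_that("steady-state AUC over a dosing interval equals dose over clearance", {
  p <- params_ref(egfr = 80)
  cl <- p$cl_body
  grid <- seq(0, 400, by = 0.1)
  prof <- analytic_twocpt(p, fosfo_regimen("4gTID", horizon_h = 400), grid)
  auc_ss <- auc_window(prof, 384, 392)   # > 10 half-lives in
  expect_equal(auc_ss, 4000 / cl, tolerance = 5e-3)
})

test_that("more dialysis clearance never increases exposure", {
  grid <- seq(0, 48, by = 0.1)
  p <- params_ref(egfr = 30)
  reg <- fosfo_regimen("5gTID")
  auc <- vapply(c(0, 25, 42, 100, 250), function(qd) {
    krt <- if (qd == 0) krt_schedule("none") else
      krt_schedule("ckrt", qd = qd)
    auc_window(analytic_twocpt(p, reg, grid, krt), 24, 48)
  }, numeric(1))
  expect_true(all(diff(auc) < 0))
})

test_that("analytic solution refuses a time-varying peripheral volume", {
  p <- individual_params(fx_pub, c(0, 0, 0), list(egfr = 0, anuric = TRUE))
  expect_error(analytic_twocpt(p, reg_single, seq(0, 8, 0.5)), "constant")
})

test_that("profiles export as two-column delimited text", {
  p <- params_ref()
  prof <- analytic_twocpt(p, reg_single, seq(0, 8, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(prof, path)
  back <- read.delim(path)
  expect_equal(back$time_h, prof$times)
  expect_equal(back$conc_mg_L, prof$conc, tolerance = 1e-12)
})
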