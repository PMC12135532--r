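#' Design specifications of the four emulated studies
#'
#' Encodes, per study, the sample size, dosing regimen, infusion duration,
#' KRT modality and schedule, sampling schedule, covariate distributions
#' (lognormal, parameterized by the published cohort medians and
#' interquartile ranges) and the anuria count. Study A samples are anchored
#' to the start of an 8-h prolonged-intermittent KRT (PIKRT) session on the
#' second treatment day; study B to the first dose and to a 6-h PIKRT
#' session; study C runs continuous KRT with a dialysis-free episode so
#' that both elimination pathways are observable; study D has no KRT.
#' Study B's subjects carry the zero-body-clearance flag and are missing
#' height and serum creatinine (hence eGFR), mirroring the source data.
#'
#' @return Named list of study specification lists (classes `A`-`D`).
#' @export
study_specs <- function() {
  min2h <- function(m) m / 60
  list(
    A = list(label = "A", n = 10, dose_mg = 5000, interval_h = 8,
             infusion_h = c(0.5, 1),
             krt = list(type = "pikrt", start = 24, duration = 8),
             qd = list(median = 190, sdlog = 0.12, lo = 100, hi = 280),
             # sampling: KRT start and 15-480 min after
             obs_times = function(krt_start)
               krt_start + min2h(c(0, 15, 30, 60, 120, 240, 480)),
             n_anuric = 3, male_frac = 0.9,
             age = c(75.5, 71, 79.2), wt = c(76.5, 72.8, 79.5),
             ht = c(176, 173, 180), scr = c(1.4, 0.98, 1.6),
             uo24 = c(410, 150, 2200)),
    B = list(label = "B", n = 8, dose_mg = 5000, interval_h = 8,
             infusion_h = c(0.5, 1),
             krt = list(type = "pikrt", start = 24, duration = 6),
             qd = list(median = 250, sdlog = 0.03, lo = 200, hi = 300),
             # first-dose series without PIKRT, then around the session
             obs_times = function(krt_start)
               c(min2h(c(30, 60, 90, 150, 270, 390)),
                 krt_start - min2h(5),
                 krt_start + min2h(c(30, 120, 240, 360))),
             n_anuric = 0, male_frac = 0.5, study_b = TRUE,
             age = c(64, 61.5, 77), wt = c(99.5, 78.8, 107),
             ht = NULL, scr = NULL, uo24 = c(700, 500, 1000)),
    C = list(label = "C", n = 15, dose_mg = 5000, interval_h = 8,
             infusion_h = c(2, 2),
             krt = list(type = "ckrt", windows = data.frame(
               start = c(0, 40), end = c(30, 48))),
             qd = list(median = 36, sdlog = 0.09, lo = 30, hi = 50),
             # one series on CKRT (24 h dose), one off (32 h dose)
             obs_times = function(krt_start) {
               series <- function(t0) c(t0 - min2h(5),
                                        t0 + min2h(c(15, 30, 60, 90, 180,
                                                     240, 300, 360)))
               c(series(24), series(32))
             },
             n_anuric = 7, male_frac = 0.87,
             age = c(57, 55, 62), wt = c(89, 75, 105),
             ht = c(176, 172, 180), scr = c(1.5, 1, 2.2),
             uo24 = c(600, 150, 820)),
    D = list(label = "D", n = 12, dose_mg = 4000, interval_h = 6,
             infusion_h = c(0.5, 1),
             krt = list(type = "none"),
             qd = NULL,
             # up to three series around the 0, 24 and 42 h doses
             obs_times = function(krt_start) {
               post <- function(t0) t0 + min2h(c(30, 45, 60, 90, 120, 240,
                                                 360))
               c(post(0), 24 - min2h(5), post(24), 42 - min2h(5), post(42))
             },
             n_anuric = 0, male_frac = 0.67, n_tid = 2,
             age = c(62.5, 57.8, 75), wt = c(71.5, 69.5, 80),
             ht = c(166, 160, 178), scr = c(0.95, 0.6, 1.7),
             uo24 = c(3400, 2600, 5800))
  )
}

# lognormal draw matched to a published median and interquartile range
rlnorm_iqr <- function(n, median, q1, q3, lo = -Inf, hi = Inf) {
  sdlog <- log(q3 / q1) / (2 * stats::qnorm(0.75))
  pmin(pmax(stats::rlnorm(n, log(median), sdlog), lo), hi)
}

#' Generate a synthetic pooled four-study cohort
#'
#' Samples covariates from the study-specific distributions, assigns KRT
#' schedules and dosing regimens, simulates the true concentration-time
#' profiles through the population model at the supplied parameters (etas
#' drawn per subject), adds combined proportional + additive residual
#' error and emits a validated NM-style dataset. Defaults reproduce the
#' pooled design: 45 subjects (10/8/15/12), treatment over 48 h,
#' study-specific sampling schedules.
#'
#' @param specs Study specifications ([study_specs()]).
#' @param fx,re True parameter values (default: published full-data-set
#'   estimates).
#' @param seed Integer seed; required, reproducibility is contractual.
#' @param residual Add residual error to observations (disable for
#'   noise-free designs in tests).
#' @param jitter_min Uniform sampling-time jitter in minutes (default 2;
#'   0 disables).
#' @param horizon_h Treatment duration, h.
#' @return NM-style data frame (see [nm_columns()]); the per-subject truth
#'   (etas, individual parameters) is attached as attribute `"truth"`.
#' @export
generate_cohort <- function(specs = study_specs(),
                            fx = fosfo_fixed_effects(),
                            re = fosfo_random_effects(), seed,
                            residual = TRUE, jitter_min = 2,
                            horizon_h = 48) {
  if (missing(seed) || is.null(seed)) {
    stop("generate_cohort(): an explicit seed is required")
  }
  set.seed(seed)
  rows <- list()
  truth <- list()
  id <- 0L
  for (sp in specs) {
    if (sp$n_anuric > sp$n) {
      stop("generate_cohort(): study ", sp$label, " has n_anuric > n")
    }
    anuric_flags <- sample(rep(c(TRUE, FALSE),
                               c(sp$n_anuric, sp$n - sp$n_anuric)))
    tid_flags <- rep(FALSE, sp$n)
    if (!is.null(sp$n_tid)) tid_flags[sample.int(sp$n, sp$n_tid)] <- TRUE
    for (j in seq_len(sp$n)) {
      id <- id + 1L
      sex <- if (stats::runif(1) < sp$male_frac) "male" else "female"
      age <- rlnorm_iqr(1, sp$age[1], sp$age[2], sp$age[3], 18, 100)
      wt <- rlnorm_iqr(1, sp$wt[1], sp$wt[2], sp$wt[3], 40, 180)
      ht <- if (is.null(sp$ht)) NA_real_ else
        rlnorm_iqr(1, sp$ht[1], sp$ht[2], sp$ht[3], 145, 210)
      if (!is.na(ht)) {  # keep the implied BMI physiological
        bmi <- wt / (ht / 100)^2
        wt <- wt * min(max(bmi, 15), 50) / bmi
      }
      scr <- if (is.null(sp$scr)) NA_real_ else
        rlnorm_iqr(1, sp$scr[1], sp$scr[2], sp$scr[3], 0.3, 8)
      anuric <- anuric_flags[j]
      uo24 <- if (anuric) stats::runif(1, 0, 99) else
        rlnorm_iqr(1, sp$uo24[1], sp$uo24[2], sp$uo24[3], 100, 8000)
      egfr <- if (is.na(scr)) NA_real_ else egfr_mdrd(scr, age, sex)
      study_b <- isTRUE(sp$study_b)
      # dosing regimen
      if (isTRUE(tid_flags[j])) {
        regimen <- fosfo_regimen(dose_mg = 6000, interval_h = 8,
                                 duration_h = stats::runif(1, sp$infusion_h[1],
                                                           sp$infusion_h[2]),
                                 horizon_h = horizon_h)
      } else {
        regimen <- fosfo_regimen(dose_mg = sp$dose_mg,
                                 interval_h = sp$interval_h,
                                 duration_h = stats::runif(1, sp$infusion_h[1],
                                                           sp$infusion_h[2]),
                                 horizon_h = horizon_h)
      }
      # KRT schedule
      qd <- if (is.null(sp$qd)) NA_real_ else
        pmin(pmax(stats::rlnorm(1, log(sp$qd$median), sp$qd$sdlog),
                  sp$qd$lo), sp$qd$hi)
      krt <- switch(sp$krt$type,
        none = krt_schedule("none"),
        pikrt = krt_schedule("pikrt", qd = qd, start_h = sp$krt$start,
                             duration_h = sp$krt$duration),
        ckrt = krt_schedule(windows = cbind(sp$krt$windows, qd = qd)))
      obs_times <- sort(sp$obs_times(if (sp$krt$type == "pikrt")
        sp$krt$start else 24))
      if (jitter_min > 0) {
        obs_times <- obs_times +
          stats::runif(length(obs_times), -jitter_min, jitter_min) / 60
        obs_times <- sort(pmax(obs_times, 0.01))
      }
      cov <- list(egfr = if (is.na(egfr)) 0 else egfr, anuric = anuric,
                  study_b = study_b, wt = wt, ht = ht, age = age,
                  sex = sex, uo24 = uo24, qd = qd)
      s <- make_subject(id, regimen, krt, cov, obs_times,
                        horizon_h = horizon_h + 1)
      eta <- drop(draw_etas(re, 1))
      ipred <- predict_subject(s, fx, eta, dt_max = 0.1)
      dv <- if (residual) {
        pmax(ipred * (1 + stats::rnorm(length(ipred), 0, re$sigma_prop)) +
               stats::rnorm(length(ipred), 0, re$sigma_add), 0)
      } else ipred
      covrow <- data.frame(
        EGFR = egfr, ANUR = as.integer(anuric), QD = qd,
        STUDYB = as.integer(study_b), WT = wt, HT = ht, AGE = age,
        SEX = as.integer(sex == "female"), UO24 = uo24, STUDY = sp$label)
      ev <- rbind(
        data.frame(TIME = regimen$start, AMT = regimen$amount,
                   RATE = regimen$amount / regimen$duration, EVID = 1,
                   MDV = 1, DV = NA_real_, KRTON = NA_real_),
        data.frame(TIME = obs_times, AMT = 0, RATE = NA_real_, EVID = 0,
                   MDV = 0, DV = dv, KRTON = NA_real_),
        if (nrow(krt)) data.frame(
          TIME = c(krt$start, krt$end),
          AMT = 0, RATE = NA_real_, EVID = 2, MDV = 1, DV = NA_real_,
          KRTON = rep(c(1, 0), each = nrow(krt))))
      ev <- ev[order(ev$TIME, -ev$EVID), ]
      ev <- cbind(ID = id, ev, CMT = 1, covrow, row.names = NULL)
      rows[[id]] <- ev
      truth[[id]] <- list(id = id, study = sp$label, eta = eta, cov = cov,
                          ipred = ipred)
    }
  }
  ds <- do.call(rbind, rows)
  ds <- ds[nm_columns()]
  rownames(ds) <- NULL
  validate_nm_dataset(ds)
  attr(ds, "truth") <- truth
  ds
}
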