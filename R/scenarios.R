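#' Simulate a virtual population of concentration-time profiles
#'
#' Draws lognormal inter-individual random effects, applies the covariate
#' model (body clearance from eGFR with the anuria / zero-body-clearance
#' rules; dialysis clearance from the KRT schedule) and propagates every
#' subject through the dosing and dialysis schedule with the closed-form
#' piecewise two-compartment solution (midpoint-frozen substeps carry the
#' growing peripheral volume of anuric subjects). Concentrations are
#' individual predictions without residual error, the standard basis for
#' probability-of-target-attainment analysis.
#'
#' @param n Number of virtual subjects.
#' @param regimen A [fosfo_regimen()].
#' @param krt A [krt_schedule()].
#' @param fx,re Parameter sets ([fosfo_fixed_effects()],
#'   [fosfo_random_effects()]).
#' @param egfr eGFR values, mL/min/1.73 m^2; scalar or length-`n` vector.
#' @param anuric Logical (scalar or length `n`); anuric subjects have zero
#'   body clearance and a growing peripheral volume.
#' @param seed Optional integer seed.
#' @param grid Output time grid, h (default 0 to 48 by 0.1).
#' @param etas Optional pre-drawn `n x 3` eta matrix (overrides `seed`).
#' @return List with `times` (grid) and `conc` (`n x length(grid)` matrix,
#'   mg/L), directly consumable by [pta()].
#' @export
simulate_population <- function(n, regimen, krt, fx = fosfo_fixed_effects(),
                                re = fosfo_random_effects(), egfr,
                                anuric = FALSE, seed = NULL,
                                grid = seq(0, 48, by = 0.1), etas = NULL) {
  stopifnot(n >= 1)
  if (is.null(etas)) etas <- draw_etas(re, n, seed)
  egfr <- rep_len(egfr, n)
  anuric <- rep_len(anuric, n)
  cl_body <- typical_cl_body(egfr, anuric, FALSE, fx) * exp(etas[, 1])
  v_c <- fx$theta_vc * exp(etas[, 2])
  v_p0 <- fx$theta_vp * exp(etas[, 3])
  vp_slope <- ifelse(anuric, fx$theta_t * 60, 0)
  seg <- segment_clearances(build_segments(regimen, krt, max(grid)), fx)
  pr <- propagate_twocpt(grid, seg, cl_body, v_c, v_p0, vp_slope,
                         fx$theta_q, dt_max = 0.1)
  list(times = grid, conc = pr$conc, etas = etas, egfr = egfr,
       anuric = anuric)
}

#' Define a simulation scenario
#'
#' One cell of the simulation study: a dosing regimen, a KRT modality and a
#' kidney-function stratum. eGFR within a stratum is drawn uniformly over
#' the stratum interval per subject; the anuria stratum forces zero body
#' clearance (and the growing peripheral volume) regardless of eGFR.
#'
#' @param regimen_name One of `"4gTID"`, `"5gTID"`, `"8gTID"`, `"8gBID"`,
#'   `"4gQID"`.
#' @param krt_type `"none"`, `"ckrt"` (dialysate flow 42 mL/min over the
#'   full horizon) or `"pikrt"` (250 mL/min for 8 h starting at 24 h).
#' @param egfr_stratum `"anuria"` or one of `"0-30"`, `"31-60"`, `"61-90"`,
#'   `"91-120"` (uniform sampling over the closed interval).
#' @param n_subjects Virtual subjects per scenario (default 2000).
#' @param horizon_h Simulation horizon, h (default 48).
#' @param infusion_duration_h Infusion duration, h (default 1).
#' @param qd Dialysate flow override, mL/min.
#' @param pikrt_start_h PIKRT session start, h (default 24).
#' @return An object of class `fosfo_scenario`.
#' @export
fosfo_scenario <- function(regimen_name, krt_type = c("none", "ckrt", "pikrt"),
                           egfr_stratum, n_subjects = 2000, horizon_h = 48,
                           infusion_duration_h = 1, qd = NULL,
                           pikrt_start_h = 24) {
  krt_type <- match.arg(krt_type)
  if (!regimen_name %in% c("4gTID", "5gTID", "8gTID", "8gBID", "4gQID")) {
    stop("fosfo_scenario(): unknown regimen name '", regimen_name, "'")
  }
  strata <- list("anuria" = c(0, 0), "0-30" = c(0, 30), "31-60" = c(31, 60),
                 "61-90" = c(61, 90), "91-120" = c(91, 120))
  if (!egfr_stratum %in% names(strata)) {
    stop("fosfo_scenario(): unknown eGFR stratum '", egfr_stratum, "'")
  }
  if (identical(egfr_stratum, "anuria") && krt_type == "none") {
    warning("anuria without KRT: no elimination pathway is active")
  }
  structure(list(regimen_name = regimen_name, krt_type = krt_type,
                 egfr_stratum = egfr_stratum, egfr_range = strata[[egfr_stratum]],
                 n_subjects = n_subjects, horizon_h = horizon_h,
                 infusion_duration_h = infusion_duration_h, qd = qd,
                 pikrt_start_h = pikrt_start_h,
                 id = paste(regimen_name, krt_type, egfr_stratum, sep = "/")),
            class = "fosfo_scenario")
}

#' Run one Monte Carlo scenario
#'
#' Simulates the scenario's virtual population and evaluates the PK/PD
#' targets over the MIC grid.
#'
#' @param scenario A [fosfo_scenario()].
#' @param fx,re Parameter sets.
#' @param targets Named list of [pkpd_target()]s (default [default_targets()]).
#' @param mic_grid MIC grid, mg/L.
#' @param seed Integer seed (required for reproducibility).
#' @return Tidy data frame with columns `scenario`, `regimen`, `krt_type`,
#'   `egfr_stratum`, `target`, `mic`, `pta`, `n_subjects`; the simulated
#'   population is attached as attribute `"population"`.
#' @export
run_scenario <- function(scenario, fx = fosfo_fixed_effects(),
                         re = fosfo_random_effects(),
                         targets = default_targets(),
                         mic_grid = mic_doublings(), seed) {
  stopifnot(inherits(scenario, "fosfo_scenario"))
  if (missing(seed)) stop("run_scenario(): an explicit seed is required")
  set.seed(seed)
  anuric <- identical(scenario$egfr_stratum, "anuria")
  egfr <- if (anuric) 0 else
    stats::runif(scenario$n_subjects, scenario$egfr_range[1],
                 scenario$egfr_range[2])
  regimen <- fosfo_regimen(scenario$regimen_name,
                           duration_h = scenario$infusion_duration_h,
                           horizon_h = scenario$horizon_h)
  krt <- krt_schedule(scenario$krt_type, qd = scenario$qd,
                      horizon_h = scenario$horizon_h,
                      start_h = scenario$pikrt_start_h)
  pop <- simulate_population(scenario$n_subjects, regimen, krt, fx, re,
                             egfr = egfr, anuric = anuric,
                             grid = seq(0, scenario$horizon_h, by = 0.1))
  res <- do.call(rbind, lapply(names(targets), function(nm) {
    tab <- pta(pop, targets[[nm]], mic_grid)
    data.frame(scenario = scenario$id, regimen = scenario$regimen_name,
               krt_type = scenario$krt_type,
               egfr_stratum = scenario$egfr_stratum,
               target = nm, mic = tab$mic, pta = tab$pta,
               n_subjects = tab$n_subjects)
  }))
  attr(res, "population") <- pop
  res
}

#' Run a grid of scenarios
#'
#' The default grid mirrors the published simulation study: five regimens,
#' three KRT modalities and the kidney-function strata (anuria only with
#' KRT; 91-120 only without KRT).
#'
#' @param regimens Character vector of regimen names.
#' @param krt_types Character vector among `"none"`, `"ckrt"`, `"pikrt"`.
#' @param strata_krt,strata_nokrt eGFR strata used with and without KRT.
#' @param n_subjects Subjects per scenario.
#' @param seed Base seed; each scenario uses a distinct deterministic
#'   offset.
#' @inheritParams run_scenario
#' @return Tidy PTA table over all scenarios (one row per
#'   scenario x target x MIC).
#' @export
run_scenario_grid <- function(regimens = c("4gTID", "5gTID", "8gBID",
                                           "4gQID", "8gTID"),
                              krt_types = c("none", "ckrt", "pikrt"),
                              strata_krt = c("anuria", "0-30", "31-60",
                                             "61-90"),
                              strata_nokrt = c("0-30", "31-60", "61-90",
                                               "91-120"),
                              n_subjects = 2000,
                              fx = fosfo_fixed_effects(),
                              re = fosfo_random_effects(),
                              targets = default_targets(),
                              mic_grid = mic_doublings(), seed) {
  if (missing(seed)) stop("run_scenario_grid(): an explicit seed is required")
  out <- list()
  k <- 0L
  for (krt_type in krt_types) {
    strata <- if (krt_type == "none") strata_nokrt else strata_krt
    for (stratum in strata) {
      for (reg in regimens) {
        k <- k + 1L
        sc <- fosfo_scenario(reg, krt_type, stratum, n_subjects = n_subjects)
        res <- run_scenario(sc, fx, re, targets, mic_grid,
                            seed = (seed + 7L * k) %% .Machine$integer.max)
        attr(res, "population") <- NULL
        out[[k]] <- res
      }
    }
  }
  do.call(rbind, out)
}

#' Dose recommendations from a PTA table
#'
#' For every KRT type x eGFR stratum x target x MIC cell, the lowest
#' regimen (by daily dose, ties broken toward fewer administrations)
#' reaching PTA >= the primary level (default 90%); failing that, the
#' lowest reaching the secondary level (default 80%, flagged in the
#' `level` column); otherwise `"N/A"`.
#'
#' @param pta_table Tidy table from [run_scenario_grid()].
#' @param pta_levels Numeric length-2, primary and secondary PTA levels.
#' @param regimen_order Regimen names in ascending daily-dose order.
#' @return Data frame with columns `krt_type`, `egfr_stratum`, `target`,
#'   `mic`, `regimen`, `level` (`0.9`, `0.8` or `NA`).
#' @export
recommend_doses <- function(pta_table, pta_levels = c(0.90, 0.80),
                            regimen_order = c("4gTID", "5gTID", "8gBID",
                                              "4gQID", "8gTID")) {
  need <- c("krt_type", "egfr_stratum", "target", "mic", "regimen", "pta")
  stopifnot(all(need %in% names(pta_table)))
  cells <- unique(pta_table[c("krt_type", "egfr_stratum", "target", "mic")])
  rownames(cells) <- NULL
  pick <- function(cell) {
    sub <- pta_table[pta_table$krt_type == cell$krt_type &
                     pta_table$egfr_stratum == cell$egfr_stratum &
                     pta_table$target == cell$target &
                     pta_table$mic == cell$mic, ]
    missing_reg <- setdiff(regimen_order, sub$regimen)
    if (length(missing_reg)) {
      stop("recommend_doses(): PTA missing for regimen(s) ",
           paste(missing_reg, collapse = ", "), " in cell ",
           paste(unlist(cell), collapse = "/"))
    }
    p <- sub$pta[match(regimen_order, sub$regimen)]
    for (lev in pta_levels) {
      i <- which(p >= lev)
      if (length(i)) return(list(regimen = regimen_order[i[1]], level = lev))
    }
    list(regimen = "N/A", level = NA_real_)
  }
  res <- lapply(seq_len(nrow(cells)), function(i) pick(cells[i, ]))
  cells$regimen <- vapply(res, `[[`, character(1), "regimen")
  cells$level <- vapply(res, `[[`, numeric(1), "level")
  cells
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model simulations are rescaled by the ratio of the
#' bin-median population prediction to each record's own population
#' prediction, then binned percentiles (5th/50th/95th) of the corrected
#' observations are compared with the simulation envelope from `n_rep`
#' replicate data sets re-simulated under the study designs of the original
#' data.
#'
#' @param dataset An NM-style dataset (see [generate_cohort()]).
#' @param fx,re Parameter sets used for re-simulation.
#' @param n_rep Number of replicate data sets (published analysis: 1000).
#' @param bins Number of time bins (quantile-based; empty bins are merged
#'   with their neighbour).
#' @param seed Integer seed.
#' @param envelope Coverage of the simulation envelope for each percentile
#'   (default 0.90).
#' @return Data frame with one row per bin and percentile: observed value,
#'   envelope bounds and bin metadata.
#' @export
pcvpc <- function(dataset, fx = fosfo_fixed_effects(),
                  re = fosfo_random_effects(), n_rep = 1000, bins = 8,
                  seed, envelope = 0.90) {
  if (missing(seed)) stop("pcvpc(): an explicit seed is required")
  set.seed(seed)
  dataset <- impute_covariates(
    dataset, columns = intersect(c("EGFR", "WT", "HT", "AGE", "UO24"),
                                 names(dataset)))
  subjects <- split_subjects(dataset)
  obs_rows <- dataset$EVID == 0
  tsfd <- dataset$TIME[obs_rows]
  dv <- dataset$DV[obs_rows]
  # population predictions (eta = 0) under the subjects' own designs
  pred <- unlist(lapply(subjects, function(s) {
    predict_subject(s, fx, eta = c(0, 0, 0))
  }))
  # quantile time bins, merged when degenerate
  edges <- unique(stats::quantile(tsfd, probs = seq(0, 1, length.out = bins + 1)))
  if (length(edges) < 3) edges <- range(tsfd) + c(-1e-9, 1e-9)
  bin <- cut(tsfd, breaks = edges, include.lowest = TRUE)
  pcorr <- function(values, pred, bin) {
    med <- tapply(pred, bin, stats::median)
    values * as.numeric(med[bin]) / pred
  }
  probs <- c(0.05, 0.5, 0.95)
  obs_pc <- pcorr(dv, pred, bin)
  obs_q <- do.call(rbind, tapply(obs_pc, bin, stats::quantile, probs = probs))
  sim_q <- array(NA_real_, c(n_rep, nlevels(bin), 3))
  for (r in seq_len(n_rep)) {
    sim_dv <- unlist(lapply(subjects, function(s) {
      eta <- drop(draw_etas(re, 1))
      ip <- predict_subject(s, fx, eta)
      ip * (1 + stats::rnorm(length(ip), 0, re$sigma_prop)) +
        stats::rnorm(length(ip), 0, re$sigma_add)
    }))
    sim_pc <- pcorr(sim_dv, pred, bin)
    sim_q[r, , ] <- do.call(rbind,
                            tapply(sim_pc, bin, stats::quantile, probs = probs))
  }
  a <- (1 - envelope) / 2
  out <- do.call(rbind, lapply(seq_len(nlevels(bin)), function(b) {
    data.frame(bin = levels(bin)[b],
               bin_mid = stats::median(tsfd[bin == levels(bin)[b]]),
               percentile = c(5, 50, 95),
               observed = obs_q[b, ],
               sim_lower = apply(sim_q[, b, , drop = FALSE], 3,
                                 stats::quantile, probs = a),
               sim_median = apply(sim_q[, b, , drop = FALSE], 3,
                                  stats::median),
               sim_upper = apply(sim_q[, b, , drop = FALSE], 3,
                                 stats::quantile, probs = 1 - a))
  }))
  rownames(out) <- NULL
  out
}
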