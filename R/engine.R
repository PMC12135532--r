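#' Construct an intravenous dosing regimen
#'
#' Either a named standard regimen (`"4gTID"`, `"5gTID"`, `"8gTID"`,
#' `"8gBID"`, `"4gQID"`) expanded over the horizon, or explicit dose events.
#' Regimen clocks start at time 0: TID = every 8 h, BID = every 12 h,
#' QID = every 6 h.
#'
#' @param name Standard regimen name, or `NULL` to pass explicit events.
#' @param dose_mg,interval_h Dose amount (mg) and dosing interval (h) for a
#'   custom repeated regimen.
#' @param duration_h Zero-order infusion duration, h (default 1).
#' @param horizon_h Treatment horizon, h; doses start at 0, 1 interval apart,
#'   up to (not including) the horizon.
#' @param start_times,amounts Explicit event specification (overrides the
#'   repeated-schedule arguments); vectors of equal length.
#' @return Data frame of class `fosfo_regimen` with columns `start`, `amount`
#'   (mg) and `duration` (h), sorted by start time.
#' @examples
#' fosfo_regimen("5gTID", horizon_h = 48)
#' @export
fosfo_regimen <- function(name = NULL, dose_mg = NULL, interval_h = NULL,
                          duration_h = 1, horizon_h = 48,
                          start_times = NULL, amounts = NULL) {
  if (!is.null(name)) {
    std <- list("4gTID" = c(4000, 8), "5gTID" = c(5000, 8),
                "8gTID" = c(8000, 8), "8gBID" = c(8000, 12),
                "4gQID" = c(4000, 6))
    if (!name %in% names(std)) {
      stop("fosfo_regimen(): unknown regimen name '", name, "'")
    }
    dose_mg <- std[[name]][1]
    interval_h <- std[[name]][2]
  }
  if (is.null(start_times)) {
    stopifnot(!is.null(dose_mg), !is.null(interval_h))
    n_doses <- ceiling(horizon_h / interval_h - 1e-9)  # last dose < horizon
    start_times <- (seq_len(n_doses) - 1) * interval_h
    amounts <- rep(dose_mg, length(start_times))
  }
  stopifnot(length(start_times) == length(amounts),
            all(amounts > 0), all(duration_h > 0))
  out <- data.frame(start = start_times, amount = amounts,
                    duration = rep_len(duration_h, length(start_times)))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fosfo_regimen", "data.frame"), name = name)
}

#' Construct a kidney-replacement-therapy schedule
#'
#' Windows are half-open `[start, end)`: dialysis clearance is active at the
#' session start and inactive from the session end.
#'
#' @param type `"none"`, `"ckrt"` (continuous, covers the whole horizon,
#'   default dialysate flow 42 mL/min) or `"pikrt"` (one prolonged
#'   intermittent session, default 8 h starting at 24 h with 250 mL/min).
#' @param qd Dialysate flow rate, mL/min (defaults by type).
#' @param horizon_h Horizon, h.
#' @param start_h,duration_h Session start and duration for `"pikrt"`.
#' @param windows Explicit data frame with columns `start`, `end`, `qd`
#'   (overrides `type`).
#' @return Data frame of class `fosfo_krt` with columns `start`, `end`, `qd`;
#'   zero rows for `"none"`.
#' @examples
#' krt_schedule("pikrt")  # 250 mL/min for 8 h on the second day
#' @export
krt_schedule <- function(type = c("none", "ckrt", "pikrt"), qd = NULL,
                         horizon_h = 48, start_h = 24, duration_h = 8,
                         windows = NULL) {
  if (is.null(windows)) {
    type <- match.arg(type)
    windows <- switch(type,
      none = data.frame(start = numeric(0), end = numeric(0), qd = numeric(0)),
      ckrt = data.frame(start = 0, end = horizon_h,
                        qd = if (is.null(qd)) 42 else qd),
      pikrt = data.frame(start = start_h, end = start_h + duration_h,
                         qd = if (is.null(qd)) 250 else qd))
  }
  stopifnot(all(c("start", "end", "qd") %in% names(windows)))
  windows <- windows[order(windows$start), , drop = FALSE]
  if (nrow(windows)) {
    stopifnot(all(windows$end > windows$start), all(windows$qd > 0))
    if (nrow(windows) > 1 &&
        any(windows$start[-1] < windows$end[-nrow(windows)])) {
      stop("krt_schedule(): overlapping KRT windows")
    }
  }
  rownames(windows) <- NULL
  structure(windows, class = c("fosfo_krt", "data.frame"))
}

#' Compile dose events and KRT windows into piecewise-constant segments
#'
#' Returns the maximal intervals on which both the total infusion rate and
#' the dialysis state are constant. Breakpoints sit exactly at dose
#' start/stop and KRT start/stop times; the segments partition
#' `[0, horizon]`.
#'
#' @param regimen A [fosfo_regimen()] (may be empty).
#' @param krt A [krt_schedule()].
#' @param horizon_h Horizon, h; must cover all events.
#' @return Data frame with columns `start`, `end`, `rate` (mg/h), `qd`
#'   (mL/min, `NA` off dialysis) and `krt_active` (logical).
#' @export
build_segments <- function(regimen, krt = krt_schedule("none"),
                           horizon_h = 48) {
  if (is.null(regimen) || nrow(regimen) == 0) {
    regimen <- data.frame(start = numeric(0), amount = numeric(0),
                          duration = numeric(0))
  }
  krt <- krt_schedule(windows = as.data.frame(krt))  # re-validate
  ends <- regimen$start + regimen$duration
  if (length(ends) && max(c(ends, krt$end, 0)) > horizon_h + 1e-9) {
    stop("build_segments(): horizon does not cover all events")
  }
  bp <- sort(unique(round(
    c(0, horizon_h, regimen$start, ends, krt$start, krt$end), 9)))
  bp <- bp[bp >= 0 & bp <= horizon_h + 1e-8]
  seg <- data.frame(start = bp[-length(bp)], end = bp[-1])
  mid <- (seg$start + seg$end) / 2
  seg$rate <- vapply(mid, function(t) {
    on <- regimen$start <= t & t < regimen$start + regimen$duration
    sum(regimen$amount[on] / regimen$duration[on])
  }, numeric(1))
  widx <- vapply(mid, function(t) {
    w <- which(krt$start <= t & t < krt$end)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  seg$qd <- krt$qd[widx]
  seg$krt_active <- !is.na(widx)
  seg
}

# Attach the dialysis clearance (L/h) implied by the covariate model to each
# segment. No IIV is carried on CL_KRT.
segment_clearances <- function(segments, fx) {
  segments$cl_krt <- ifelse(segments$krt_active,
                            typical_cl_krt(ifelse(is.na(segments$qd), 0,
                                                  segments$qd),
                                           segments$krt_active, fx), 0)
  segments
}

# One closed-form step of the two-compartment system with constant
# coefficients and a constant zero-order input, via the spectral
# decomposition of the 2x2 rate matrix. Vectorized element-wise over every
# argument (amounts, rate, step and micro-constants may all be vectors).
#   dAc/dt = rate - (k10 + k12) Ac + k21 Ap
#   dAp/dt = k12 Ac - k21 Ap
twocpt_step <- function(Ac, Ap, rate, h, k10, k12, k21) {
  s <- k10 + k12 + k21
  disc <- pmax(s * s - 4 * k10 * k21, 0)
  rt <- sqrt(disc)
  l1 <- (-s + rt) / 2
  l2 <- (-s - rt) / 2
  d <- pmax(rt, 1e-12)            # repeated-eigenvalue guard
  a <- k10 + k12
  p11 <- (-a - l2) / d            # P1 = (A - l2 I)/(l1 - l2); P2 = I - P1
  p12 <- k21 / d
  p21 <- k12 / d
  p22 <- (-k21 - l2) / d
  e1 <- exp(l1 * h)
  e2 <- exp(l2 * h)
  phi <- function(l) ifelse(abs(l) > 1e-12, expm1(l * h) / l, h)
  f1 <- phi(l1)
  f2 <- phi(l2)
  list(
    Ac = (e1 * p11 + e2 * (1 - p11)) * Ac + (e1 - e2) * p12 * Ap +
      (f1 * p11 + f2 * (1 - p11)) * rate,
    Ap = (e1 - e2) * p21 * Ac + (e1 * p22 + e2 * (1 - p22)) * Ap +
      (f1 - f2) * p21 * rate
  )
}

# Piecewise propagation workhorse shared by analytic_twocpt(), the Monte
# Carlo population simulator and the estimation likelihood. Parameters may
# be vectors of length m (a batch of subjects or eta candidates sharing one
# event schedule). A growing peripheral volume is handled by substepping
# with the volume frozen at each substep midpoint (dt_max); with a constant
# V_P each segment is advanced in a single exact step. Backed by compiled
# code; propagate_twocpt_r is the plain-R reference used in unit tests.
#
# segments must carry columns start, end, rate, cl_krt.
# Returns list(conc, Ac, Ap): m x length(times) matrices.
propagate_twocpt <- function(times, segments, cl_body, v_c, v_p0,
                             vp_slope = 0, q, dt_max = 0.25) {
  stopifnot(!is.unsorted(times), all(times >= segments$start[1] - 1e-9))
  m <- max(length(cl_body), length(v_c), length(v_p0), length(vp_slope))
  .propagate_cpp(times, segments$start, segments$end, segments$rate,
                 segments$cl_krt, rep_len(cl_body, m), rep_len(v_c, m),
                 rep_len(v_p0, m), rep_len(vp_slope, m), q, dt_max)
}

propagate_twocpt_r <- function(times, segments, cl_body, v_c, v_p0,
                               vp_slope = 0, q, dt_max = 0.25) {
  stopifnot(!is.unsorted(times), all(times >= segments$start[1] - 1e-9))
  m <- max(length(cl_body), length(v_c), length(v_p0), length(vp_slope))
  cl_body <- rep_len(cl_body, m); v_c <- rep_len(v_c, m)
  v_p0 <- rep_len(v_p0, m); vp_slope <- rep_len(vp_slope, m)
  varying <- any(vp_slope > 0)
  k12 <- q / v_c
  nt <- length(times)
  Ac <- matrix(NA_real_, m, nt)
  Ap <- matrix(NA_real_, m, nt)
  ac <- numeric(m); ap <- numeric(m)
  t_cur <- segments$start[1]
  hit <- which(abs(times - t_cur) < 1e-9)
  if (length(hit)) { Ac[, hit] <- ac; Ap[, hit] <- ap }
  for (i in seq_len(nrow(segments))) {
    s0 <- segments$start[i]; s1 <- segments$end[i]
    k10 <- (cl_body + segments$cl_krt[i]) / v_c
    inside <- times[times > s0 + 1e-9 & times <= s1 + 1e-9]
    stops <- sort(unique(c(inside, s1)))
    for (tn in stops) {
      # substep when V_P grows in time; exact single step otherwise
      pts <- if (varying && tn - t_cur > dt_max) {
        c(seq(t_cur, tn, by = dt_max)[-1], tn)
      } else tn
      pts <- pts[pts > t_cur + 1e-12]
      for (tp in unique(pts)) {
        tmid <- (t_cur + tp) / 2
        vp <- v_p0 * (1 + vp_slope * tmid)
        st <- twocpt_step(ac, ap, segments$rate[i], tp - t_cur,
                          k10, k12, q / vp)
        ac <- st$Ac; ap <- st$Ap
        t_cur <- tp
      }
      hit <- which(abs(times - tn) < 1e-9)
      if (length(hit)) { Ac[, hit] <- ac; Ap[, hit] <- ap }
    }
  }
  list(conc = Ac / v_c, Ac = Ac, Ap = Ap)
}

#' Closed-form two-compartment infusion solution (constant parameters)
#'
#' Exact piecewise solution of the linear constant-coefficient
#' two-compartment system via the spectral decomposition of the rate matrix
#' (equivalent to superposition of bi-exponential zero-order-infusion
#' solutions). Serves as the analytic reference for [simulate_profile()];
#' refuses time-varying peripheral volumes.
#'
#' @param params [individual_params()] with `vp_slope = 0`.
#' @param regimen A [fosfo_regimen()].
#' @param grid Output time grid, h (sorted, within `[0, horizon]`).
#' @param krt A [krt_schedule()] (dialysis windows add the covariate-model
#'   dialysis clearance).
#' @param fx [fosfo_fixed_effects()] (for the dialysis-clearance power law).
#' @param horizon_h Horizon, h.
#' @return A `fosfo_profile`: list with `times`, `conc` (mg/L central),
#'   `amounts` (2-column matrix, mg) and `v_c`.
#' @export
analytic_twocpt <- function(params, regimen, grid,
                            krt = krt_schedule("none"),
                            fx = fosfo_fixed_effects(),
                            horizon_h = max(grid)) {
  if (params$vp_slope != 0) {
    stop("analytic_twocpt(): closed form requires a constant peripheral ",
         "volume (vp_slope = 0)")
  }
  seg <- segment_clearances(build_segments(regimen, krt, horizon_h), fx)
  pr <- propagate_twocpt(grid, seg, params$cl_body, params$v_c, params$v_p0,
                         0, params$q, dt_max = Inf)
  new_profile(grid, drop(pr$conc), cbind(drop(pr$Ac), drop(pr$Ap)),
              params$v_c)
}

#' Simulate a concentration-time profile by numerical integration
#'
#' Integrates the two-compartment system in amounts with both elimination
#' pathways (body and dialysis clearance) acting on the central compartment
#' and, for anuric subjects, a peripheral volume growing linearly in time
#' since first dose:
#' \deqn{dA_c/dt = rate(t) - \frac{CL_{body}+CL_{KRT}(t)}{V_C} A_c
#'   - \frac{Q}{V_C} A_c + \frac{Q}{V_P(t)} A_p}
#' \deqn{dA_p/dt = \frac{Q}{V_C} A_c - \frac{Q}{V_P(t)} A_p}
#' The integrator (`deSolve::lsoda`) is restarted at every segment
#' breakpoint so that rate and clearance discontinuities are never
#' interpolated across. Working in amounts conserves mass while the
#' peripheral volume grows.
#'
#' @inheritParams analytic_twocpt
#' @param params [individual_params()].
#' @param rtol,atol Integrator tolerances (defaults 1e-10, 1e-8 mg).
#' @return A `fosfo_profile` (see [analytic_twocpt()]).
#' @export
simulate_profile <- function(params, regimen, grid,
                             krt = krt_schedule("none"),
                             fx = fosfo_fixed_effects(),
                             horizon_h = max(grid),
                             rtol = 1e-10, atol = 1e-8) {
  stopifnot(!is.unsorted(grid), all(grid >= 0), max(grid) <= horizon_h + 1e-9)
  seg <- segment_clearances(build_segments(regimen, krt, horizon_h), fx)
  deriv <- function(t, y, p) {
    vp <- p$v_p0 * (1 + p$vp_slope * t)
    list(c(p$rate - (p$cl_tot / p$v_c) * y[1] -
             (p$q / p$v_c) * y[1] + (p$q / vp) * y[2],
           (p$q / p$v_c) * y[1] - (p$q / vp) * y[2]))
  }
  y <- c(0, 0)
  out_t <- numeric(0); out_y <- NULL
  for (i in seq_len(nrow(seg))) {
    inside <- grid[grid >= seg$start[i] - 1e-9 & grid <= seg$end[i] + 1e-9]
    tt <- sort(unique(c(seg$start[i], inside, seg$end[i])))
    p <- list(rate = seg$rate[i], cl_tot = params$cl_body + seg$cl_krt[i],
              v_c = params$v_c, v_p0 = params$v_p0,
              vp_slope = params$vp_slope, q = params$q)
    sol <- deSolve::lsoda(y, tt, deriv, p, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("simulate_profile(): integrator failure in segment ", i,
           " [", seg$start[i], ", ", seg$end[i], "] h; state = ",
           paste(signif(y, 6), collapse = ", "))
    }
    keep <- tt %in% inside
    out_t <- c(out_t, tt[keep])
    out_y <- rbind(out_y, unname(sol[keep, 2:3, drop = FALSE]))
    y <- unname(sol[nrow(sol), 2:3])
  }
  ord <- !duplicated(round(out_t, 9))
  new_profile(out_t[ord], out_y[ord, 1] / params$v_c,
              out_y[ord, , drop = FALSE], params$v_c)
}

new_profile <- function(times, conc, amounts, v_c) {
  structure(list(times = times, conc = conc, amounts = amounts, v_c = v_c),
            class = "fosfo_profile")
}

#' @export
print.fosfo_profile <- function(x, ...) {
  cat("Concentration-time profile:", length(x$times), "nodes over [",
      min(x$times), ",", max(x$times), "] h; Cmax",
      signif(max(x$conc), 4), "mg/L\n")
  invisible(x)
}

#' Export a profile as delimited text
#'
#' Writes a two-column (time, concentration) tab-separated file.
#'
#' @param profile A `fosfo_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(time_h = profile$times, conc_mg_L = profile$conc),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
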