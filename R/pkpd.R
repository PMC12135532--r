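#' Define a PK/PD target
#'
#' Two index kinds are supported over an evaluation window (default the
#' second treatment day, 24-48 h):
#' * `"auc_over_mic"` - the ratio of the area under the concentration-time
#'   curve over the window to the MIC; published thresholds 22.7
#'   (bacteriostatic) and 83.3 (bactericidal) for Enterobacteriaceae.
#' * `"pct_time_above_mic"` - the percentage of the window with
#'   concentration above the MIC; published bactericidal threshold 69.0.
#'
#' @param index_kind `"auc_over_mic"` or `"pct_time_above_mic"`.
#' @param threshold Target threshold (attainment is `>=` the threshold).
#' @param window Numeric length-2, evaluation window in h.
#' @param label Optional display label.
#' @return An object of class `fosfo_target`.
#' @examples
#' pkpd_target("auc_over_mic", 83.3)
#' @export
pkpd_target <- function(index_kind = c("auc_over_mic", "pct_time_above_mic"),
                        threshold, window = c(24, 48), label = NULL) {
  index_kind <- match.arg(index_kind)
  stopifnot(threshold > 0, length(window) == 2, window[1] < window[2])
  structure(list(index_kind = index_kind, threshold = threshold,
                 window = window,
                 label = label %||% sprintf("%s>=%.3g", index_kind, threshold)),
            class = "fosfo_target")
}

#' The published fosfomycin PK/PD targets
#'
#' Bacteriostatic AUC/MIC 22.7, bactericidal AUC/MIC 83.3 and bactericidal
#' %T>MIC 69.0, all evaluated over 24-48 h.
#'
#' @return Named list of three [pkpd_target()] objects.
#' @export
default_targets <- function() {
  list(
    auc_bacteriostatic = pkpd_target("auc_over_mic", 22.7,
                                     label = "bacteriostatic AUC24-48/MIC"),
    auc_bactericidal = pkpd_target("auc_over_mic", 83.3,
                                   label = "bactericidal AUC24-48/MIC"),
    t_above_bactericidal = pkpd_target("pct_time_above_mic", 69.0,
                                       label = "bactericidal %T24-48>MIC")
  )
}

#' Area under the concentration-time curve over a window
#'
#' Trapezoidal integration on the profile grid, with the window endpoints
#' located by linear interpolation when they fall between grid nodes.
#'
#' @param profile A `fosfo_profile` (or any list with `times` and `conc`).
#' @param t0,t1 Window bounds, h; must lie within the profile grid.
#' @return AUC in mg h/L.
#' @export
auc_window <- function(profile, t0, t1) {
  stopifnot(t0 < t1)
  if (t0 < min(profile$times) - 1e-9 || t1 > max(profile$times) + 1e-9) {
    stop("auc_window(): window [", t0, ", ", t1, "] outside the profile grid")
  }
  drop(auc_rows(profile$times, matrix(profile$conc, nrow = 1), t0, t1))
}

# Row-wise trapezoidal AUC for a matrix of profiles (rows = subjects)
# sharing one time grid. Window endpoints interpolated linearly.
auc_rows <- function(times, conc, t0, t1) {
  cgrid <- clip_grid(times, conc, t0, t1)
  tt <- cgrid$times
  w <- c(0, diff(tt)) / 2 + c(diff(tt), 0) / 2
  drop(cgrid$conc %*% w)
}

# restrict (times, conc-matrix) to [t0, t1] with interpolated endpoints
clip_grid <- function(times, conc, t0, t1) {
  interp_col <- function(t) {
    i <- findInterval(t, times, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(times) - 1L)
    w <- (t - times[i]) / (times[i + 1] - times[i])
    conc[, i] * (1 - w) + conc[, i + 1] * w
  }
  inside <- which(times > t0 + 1e-12 & times < t1 - 1e-12)
  list(times = c(t0, times[inside], t1),
       conc = cbind(interp_col(t0), conc[, inside, drop = FALSE],
                    interp_col(t1)))
}

#' Percentage of a window with concentration above the MIC
#'
#' The measure of `{t in [t0, t1] : C(t) > mic}` as a percentage of the
#' window length; crossing times between adjacent grid nodes are located by
#' linear interpolation.
#'
#' @inheritParams auc_window
#' @param mic MIC, mg/L (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
pct_time_above <- function(profile, mic, t0, t1) {
  if (mic <= 0) stop("pct_time_above(): mic must be positive")
  stopifnot(t0 < t1)
  if (t0 < min(profile$times) - 1e-9 || t1 > max(profile$times) + 1e-9) {
    stop("pct_time_above(): window outside the profile grid")
  }
  drop(pct_above_rows(profile$times, matrix(profile$conc, nrow = 1),
                      mic, t0, t1))
}

# Row-wise %T>MIC with linear interpolation at crossings.
pct_above_rows <- function(times, conc, mic, t0, t1) {
  cgrid <- clip_grid(times, conc, t0, t1)
  tt <- cgrid$times
  cc <- cgrid$conc
  n <- length(tt)
  above <- numeric(nrow(cc))
  for (i in seq_len(n - 1)) {
    dt <- tt[i + 1] - tt[i]
    c0 <- cc[, i]; c1 <- cc[, i + 1]
    lo <- pmin(c0, c1); hi <- pmax(c0, c1)
    # fraction of the interval above mic for a linear segment
    frac <- ifelse(lo > mic, 1,
            ifelse(hi <= mic, 0, (hi - mic) / pmax(hi - lo, 1e-300)))
    above <- above + frac * dt
  }
  100 * above / (t1 - t0)
}

#' Does a profile attain a PK/PD target at a given MIC?
#'
#' Attainment is evaluated as `>=` the threshold (ties have probability
#' zero under continuous inter-individual variability).
#'
#' @inheritParams auc_window
#' @param target A [pkpd_target()].
#' @param mic MIC, mg/L.
#' @return Logical.
#' @export
attains <- function(profile, target, mic) {
  stopifnot(inherits(target, "fosfo_target"))
  w <- target$window
  switch(target$index_kind,
    auc_over_mic = auc_window(profile, w[1], w[2]) / mic >= target$threshold,
    pct_time_above_mic =
      pct_time_above(profile, mic, w[1], w[2]) >= target$threshold)
}

#' Probability of target attainment over a MIC grid
#'
#' Fraction of profiles attaining the target at each MIC.
#'
#' @param profiles List of `fosfo_profile` objects sharing a grid covering
#'   the target window, or a list with `times` and a `conc` matrix
#'   (rows = subjects).
#' @param target A [pkpd_target()].
#' @param mic_grid MIC doubling grid, default `4, 8, ..., 512` mg/L.
#' @return Data frame of class `fosfo_pta` with columns `mic`, `pta`
#'   (fraction in `[0, 1]`) and `n_subjects`.
#' @export
pta <- function(profiles, target, mic_grid = mic_doublings()) {
  stopifnot(inherits(target, "fosfo_target"))
  if (is.list(profiles) && !is.null(profiles$conc) &&
      is.matrix(profiles$conc)) {
    times <- profiles$times
    conc <- profiles$conc
  } else {
    if (length(profiles) == 0) stop("pta(): empty profile list")
    times <- profiles[[1]]$times
    conc <- do.call(rbind, lapply(profiles, `[[`, "conc"))
  }
  w <- target$window
  frac <- if (target$index_kind == "auc_over_mic") {
    auc <- auc_rows(times, conc, w[1], w[2])
    vapply(mic_grid, function(m) mean(auc / m >= target$threshold),
           numeric(1))
  } else {
    vapply(mic_grid, function(m) {
      mean(pct_above_rows(times, conc, m, w[1], w[2]) >= target$threshold)
    }, numeric(1))
  }
  structure(data.frame(mic = mic_grid, pta = frac, n_subjects = nrow(conc)),
            class = c("fosfo_pta", "data.frame"), target = target)
}

#' MIC doubling grid from 4 to 512 mg/L
#' @return Numeric vector `c(4, 8, 16, 32, 64, 128, 256, 512)`.
#' @export
mic_doublings <- function() 2^(2:9)

`%||%` <- function(a, b) if (is.null(a)) b else a
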