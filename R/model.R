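#' Typical body clearance under the final covariate model
#'
#' \deqn{CL_{body} = \theta_{CL} \times (eGFR_{MDRD}/48.4)^{\theta_{KF}}}
#' with the clearance forced to exactly zero for anuric subjects (24-h urine
#' output < 100 mL) and for subjects of the study whose patients showed no
#' elimination between dialysis sessions (`study_b`).
#'
#' @param egfr eGFR (MDRD), mL/min/1.73 m^2; vectorized.
#' @param anuric Logical; anuria flag (recycled).
#' @param study_b Logical; zero-body-clearance study flag (recycled).
#' @param fx [fosfo_fixed_effects()] parameter set.
#' @return Typical body clearance, L/h.
#' @examples
#' fx <- fosfo_fixed_effects()
#' typical_cl_body(48.4, FALSE, FALSE, fx)  # 1.6 L/h at the reference eGFR
#' @export
typical_cl_body <- function(egfr, anuric = FALSE, study_b = FALSE,
                            fx = fosfo_fixed_effects()) {
  if (any(!is.finite(egfr)) || any(egfr < 0)) {
    stop("typical_cl_body(): egfr must be non-negative")
  }
  cl <- fx$theta_cl * (egfr / fx$egfr_ref)^fx$theta_kf
  cl[egfr == 0] <- 0  # power law limit; avoids 0^negative-exponent NaN
  cl * ifelse(anuric | study_b, 0, 1)
}

#' Typical dialysis clearance under the final covariate model
#'
#' \deqn{CL_{KRT} = \theta_{DIAL} \times (Q_D/42)^{\theta_{QD}}}
#' when dialysis is running, and exactly zero for subjects not receiving
#' KRT or during periods between KRT sessions.
#'
#' @param qd Dialysate flow rate, mL/min; vectorized.
#' @param krt_active Logical; whether a KRT session is running (recycled).
#' @param fx [fosfo_fixed_effects()] parameter set.
#' @return Dialysis clearance, L/h.
#' @export
typical_cl_krt <- function(qd, krt_active = TRUE, fx = fosfo_fixed_effects()) {
  if (any(!is.finite(qd)) || any(qd < 0)) {
    stop("typical_cl_krt(): qd must be non-negative")
  }
  if (any(krt_active & qd <= 0)) {
    stop("typical_cl_krt(): active KRT requires a positive dialysate flow")
  }
  n <- max(length(qd), length(krt_active))
  ifelse(rep_len(krt_active, n),
         fx$theta_dial * (rep_len(qd, n) / fx$qd_ref)^fx$theta_qd, 0)
}

#' Peripheral volume at a given time since first dose
#'
#' \deqn{V_P(t) = \theta_{VP} \times (1 + TSFD \times \theta_T)}
#' for anuric subjects, whose peripheral volume grows linearly with time
#' since the first dose (0.07%/min at the published estimate); constant
#' \eqn{\theta_{VP}} otherwise.
#'
#' @param tsfd Time since first dose, minutes (vectorized, >= 0).
#' @param anuric Logical; anuria flag.
#' @param fx [fosfo_fixed_effects()] parameter set.
#' @return Peripheral volume, L.
#' @export
vp_at <- function(tsfd, anuric = FALSE, fx = fosfo_fixed_effects()) {
  if (any(!is.finite(tsfd)) || any(tsfd < 0)) {
    stop("vp_at(): tsfd must be non-negative")
  }
  n <- max(length(tsfd), length(anuric))
  ifelse(rep_len(anuric, n),
         fx$theta_vp * (1 + rep_len(tsfd, n) * fx$theta_t), fx$theta_vp)
}

#' Individual parameters from typical values, random effects and covariates
#'
#' Applies the exponential inter-individual variability model:
#' `cl_body = typical_cl_body * exp(eta_cl)` (still exactly zero for anuric
#' or zero-body-clearance-study subjects), `v_c = theta_vc * exp(eta_vc)`,
#' `v_p0 = theta_vp * exp(eta_vp)`. The peripheral-volume time slope is
#' active only for anuric subjects and scales with `exp(eta_vp)` through
#' `v_p0`.
#'
#' @param fx [fosfo_fixed_effects()] parameter set.
#' @param eta Numeric vector `c(eta_cl, eta_vc, eta_vp)`.
#' @param cov List or one-row data frame with at least `egfr`, `anuric`,
#'   and optionally `study_b` (default `FALSE`).
#' @return A list of class `fosfo_individual_params` with fields `cl_body`
#'   (L/h), `v_c` (L), `v_p0` (L), `q` (L/h), `vp_slope` (per hour; 0 if not
#'   anuric) and `anuric`.
#' @export
individual_params <- function(fx, eta = c(0, 0, 0), cov) {
  stopifnot(length(eta) == 3, all(is.finite(eta)))
  study_b <- isTRUE(cov$study_b)
  anuric <- isTRUE(cov$anuric)
  cl_body <- typical_cl_body(cov$egfr, anuric, study_b, fx) * exp(eta[1])
  structure(list(
    cl_body = unname(cl_body),
    v_c = fx$theta_vc * exp(eta[2]),
    v_p0 = fx$theta_vp * exp(eta[3]),
    q = fx$theta_q,
    # theta_t is per minute; internal engine time is hours
    vp_slope = if (anuric) fx$theta_t * 60 else 0,
    anuric = anuric
  ), class = "fosfo_individual_params")
}

#' Residual-error variance of an observed concentration
#'
#' Combined proportional + additive model on the concentration scale:
#' \deqn{Var = (\sigma_{prop} \cdot pred)^2 + \sigma_{add}^2.}
#'
#' @param pred Model-predicted concentration, mg/L (vectorized, >= 0).
#' @param re [fosfo_random_effects()] parameter set.
#' @return Variance in (mg/L)^2.
#' @export
residual_variance <- function(pred, re = fosfo_random_effects()) {
  if (any(!is.finite(pred)) || any(pred < 0)) {
    stop("residual_variance(): pred must be non-negative")
  }
  (re$sigma_prop * pred)^2 + re$sigma_add^2
}

#' Draw inter-individual random effects
#'
#' Rows are i.i.d. trivariate normal with mean zero and diagonal covariance
#' `(omega2_cl, omega2_vc, omega2_vp)`.
#'
#' @param re [fosfo_random_effects()] parameter set.
#' @param n Number of subjects.
#' @param seed Optional integer seed for reproducibility.
#' @return `n x 3` matrix with columns `eta_cl`, `eta_vc`, `eta_vp`.
#' @export
draw_etas <- function(re, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- cbind(
    eta_cl = stats::rnorm(n, 0, sqrt(re$omega2_cl)),
    eta_vc = stats::rnorm(n, 0, sqrt(re$omega2_vc)),
    eta_vp = stats::rnorm(n, 0, sqrt(re$omega2_vp))
  )
  m
}
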