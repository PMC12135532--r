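#' Typical-value (fixed-effect) parameters of the final fosfomycin model
#'
#' Returns the eight typical values of the final two-compartment model with
#' parallel body and dialysis clearance, together with the reference
#' normalizers used by the covariate power laws. Two presets are shipped:
#' the estimates from the full pooled data set (45 subjects, the default)
#' and from the reduced data set that excludes the study whose subjects show
#' no body clearance.
#'
#' Fields (units):
#' \describe{
#'   \item{theta_cl}{typical body clearance, L/h}
#'   \item{theta_kf}{eGFR exponent on body clearance (unitless)}
#'   \item{theta_vc}{central volume, L}
#'   \item{theta_vp}{peripheral volume at first dose, L}
#'   \item{theta_t}{linear growth of the peripheral volume per minute since
#'     first dose (anuric subjects only)}
#'   \item{theta_q}{intercompartmental clearance, L/h}
#'   \item{theta_dial}{typical dialysis clearance at the reference dialysate
#'     flow, L/h}
#'   \item{theta_qd}{dialysate-flow exponent on dialysis clearance}
#'   \item{egfr_ref}{reference eGFR, 48.4 mL/min/1.73 m^2}
#'   \item{qd_ref}{reference dialysate flow, 42 mL/min}
#' }
#'
#' @param preset `"full"` (default) or `"reduced"`.
#' @param ... Named overrides for individual fields.
#' @return An object of class `fosfo_fixed_effects` (named list).
#' @examples
#' fx <- fosfo_fixed_effects()
#' typical_cl_krt(42, TRUE, fx)  # 2.0 L/h at the reference dialysate flow
#' @export
fosfo_fixed_effects <- function(preset = c("full", "reduced"), ...) {
  preset <- match.arg(preset)
  fx <- switch(preset,
    full = list(theta_cl = 1.6, theta_kf = 0.869, theta_vc = 23.1,
                theta_vp = 15.4, theta_t = 0.0007, theta_q = 12.0,
                theta_dial = 2.0, theta_qd = 0.587,
                egfr_ref = 48.4, qd_ref = 42),
    reduced = list(theta_cl = 1.6, theta_kf = 0.875, theta_vc = 25.0,
                   theta_vp = 14.6, theta_t = 0.0008, theta_q = 10.7,
                   theta_dial = 2.05, theta_qd = 0.488,
                   egfr_ref = 48.4, qd_ref = 42))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(fx))
  if (length(unknown)) {
    stop("fosfo_fixed_effects(): unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  fx[names(dots)] <- dots
  bad <- names(fx)[!vapply(fx, function(v) is.numeric(v) && is.finite(v) && v > 0,
                           logical(1))]
  # exponents may in principle be any sign, but volumes/clearances/refs must
  # be strictly positive; the shipped presets are all positive
  for (p in setdiff(bad, c("theta_kf", "theta_qd", "theta_t"))) {
    stop("fosfo_fixed_effects(): '", p, "' must be a positive number")
  }
  structure(fx, class = "fosfo_fixed_effects", preset = preset)
}

#' Random-effect (variability) parameters of the final fosfomycin model
#'
#' Inter-individual variability is lognormal on body clearance and the two
#' volumes (diagonal covariance); residual variability is a combined
#' proportional + additive model on the concentration scale. Presets store
#' the published percent CVs converted to variances via [cv_to_omega2()].
#'
#' @param preset `"full"` (default) or `"reduced"`.
#' @param ... Named overrides (`omega2_cl`, `omega2_vc`, `omega2_vp`,
#'   `sigma_prop` as an SD fraction, `sigma_add` in mg/L).
#' @return An object of class `fosfo_random_effects` (named list).
#' @export
fosfo_random_effects <- function(preset = c("full", "reduced"), ...) {
  preset <- match.arg(preset)
  re <- switch(preset,
    full = list(omega2_cl = cv_to_omega2(84.6), omega2_vc = cv_to_omega2(74.8),
                omega2_vp = cv_to_omega2(71.1),
                sigma_prop = 0.147, sigma_add = 21.9),
    reduced = list(omega2_cl = cv_to_omega2(84.7), omega2_vc = cv_to_omega2(81.6),
                   omega2_vp = cv_to_omega2(51.1),
                   sigma_prop = 0.150, sigma_add = 21.9))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(re))
  if (length(unknown)) {
    stop("fosfo_random_effects(): unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  re[names(dots)] <- dots
  if (any(unlist(re) < 0)) {
    stop("fosfo_random_effects(): variances and error terms must be >= 0")
  }
  structure(re, class = "fosfo_random_effects", preset = preset)
}

#' Convert a lognormal variance to a percent coefficient of variation
#'
#' For a lognormal random effect with variance `omega2` the CV of
#' `exp(eta)` is \eqn{\sqrt{\exp(\omega^2) - 1}}; reported as a percentage.
#' [cv_to_omega2()] is the exact inverse, `log(1 + (cv/100)^2)`.
#'
#' @param omega2 Variance of the normal random effect (>= 0).
#' @return Percent CV.
#' @examples
#' omega2_to_cv(cv_to_omega2(84.6))  # 84.6
#' @export
omega2_to_cv <- function(omega2) {
  if (any(!is.finite(omega2)) || any(omega2 < 0)) {
    stop("omega2_to_cv(): omega2 must be non-negative")
  }
  100 * sqrt(exp(omega2) - 1)
}

#' @rdname omega2_to_cv
#' @param cv Percent coefficient of variation (>= 0).
#' @export
cv_to_omega2 <- function(cv) {
  if (any(!is.finite(cv)) || any(cv < 0)) {
    stop("cv_to_omega2(): cv must be non-negative")
  }
  log(1 + (cv / 100)^2)
}

#' Serialize parameter sets to a flat key-value text file
#'
#' One `name = value` line per parameter, values printed with 17 significant
#' digits so that a write/read roundtrip is bit-exact. Lines starting with
#' `#` are comments.
#'
#' @param fx A `fosfo_fixed_effects` object.
#' @param re A `fosfo_random_effects` object (optional).
#' @param path Output file path.
#' @export
write_parameters <- function(fx, re = NULL, path) {
  lines <- c("# fosfopk parameter set",
             "# clearances L/h; volumes L; theta_t 1/min; sigma_add mg/L",
             sprintf("%s = %.17g", names(fx), unlist(fx)))
  if (!is.null(re)) {
    lines <- c(lines, sprintf("%s = %.17g", names(re), unlist(re)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_parameters
#' @return `read_parameters()` returns a list with elements `fx` and `re`
#'   rebuilt from the file (missing random-effect fields are left at the
#'   full-data-set preset).
#' @export
read_parameters <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- trimws(keys)
  fx_names <- names(fosfo_fixed_effects())
  re_names <- names(fosfo_random_effects())
  fx <- do.call(fosfo_fixed_effects, as.list(vals[intersect(names(vals), fx_names)]))
  re <- do.call(fosfo_random_effects, as.list(vals[intersect(names(vals), re_names)]))
  list(fx = fx, re = re)
}

#' @export
print.fosfo_fixed_effects <- function(x, ...) {
  cat("Fosfomycin fixed effects (", attr(x, "preset"), " data set preset)\n",
      sep = "")
  cat(sprintf("  CL_body %.3g L/h (eGFR exponent %.3g, ref %.3g)\n",
              x$theta_cl, x$theta_kf, x$egfr_ref))
  cat(sprintf("  V_C %.3g L, V_P %.3g L (+%.3g%%/min if anuric), Q %.3g L/h\n",
              x$theta_vc, x$theta_vp, 100 * x$theta_t, x$theta_q))
  cat(sprintf("  CL_KRT %.3g L/h at Q_D %.3g mL/min (exponent %.3g)\n",
              x$theta_dial, x$qd_ref, x$theta_qd))
  invisible(x)
}

#' @export
print.fosfo_random_effects <- function(x, ...) {
  cat("Fosfomycin random effects (", attr(x, "preset"), " data set preset)\n",
      sep = "")
  cat(sprintf("  IIV %%CV: CL %.1f, V_C %.1f, V_P %.1f\n",
              omega2_to_cv(x$omega2_cl), omega2_to_cv(x$omega2_vc),
              omega2_to_cv(x$omega2_vp)))
  cat(sprintf("  Residual: %.1f %%CV proportional + %.1f mg/L additive\n",
              100 * x$sigma_prop, x$sigma_add))
  invisible(x)
}
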