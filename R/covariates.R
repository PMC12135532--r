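#' Body surface area by the Mosteller formula
#'
#' \deqn{BSA = \sqrt{weight \times height / 3600}}
#'
#' @param weight Body weight in kg.
#' @param height Body height in cm.
#' @return Body surface area in m^2. Vectorized over both arguments.
#' @examples
#' bsa_mosteller(80, 175)
#' @export
bsa_mosteller <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0)) {
    stop("bsa_mosteller(): weight and height must be positive and finite")
  }
  sqrt(weight * height / 3600)
}

#' Estimated GFR by the 4-variable IDMS-traceable MDRD equation
#'
#' \deqn{eGFR = 175 \times Scr^{-1.154} \times age^{-0.203} \times 0.742
#' \ \mathrm{[if\ female]}}
#'
#' The race term is omitted (not applicable to the modelled cohorts); the
#' coefficients are configurable should a different variant be required.
#'
#' @param scr Serum creatinine, mg/dL.
#' @param age Age in years.
#' @param sex `"male"` or `"female"` (vectorized, recycled).
#' @param coef Leading coefficient, default 175 (IDMS-traceable).
#' @param female_factor Multiplier applied for females, default 0.742.
#' @return eGFR in mL/min/1.73 m^2 (body-surface-area normalized).
#' @examples
#' egfr_mdrd(1.0, 60, "male")
#' @export
egfr_mdrd <- function(scr, age, sex, coef = 175, female_factor = 0.742) {
  sex <- match_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("egfr_mdrd(): serum creatinine must be positive")
  }
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop("egfr_mdrd(): age must be positive")
  }
  out <- coef * scr^(-1.154) * age^(-0.203)
  out * ifelse(sex == "female", female_factor, 1)
}

#' Estimated GFR by the CKD-EPI 2009 creatinine equation
#'
#' Included as the screening alternative to [egfr_mdrd()]; the final model
#' uses the MDRD estimate.
#'
#' @inheritParams egfr_mdrd
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi <- function(scr, age, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("egfr_ckdepi(): serum creatinine must be positive")
  }
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  ratio <- scr / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) * 0.993^age *
    ifelse(sex == "female", 1.018, 1)
}

#' Convert body-surface-area normalized eGFR to an absolute clearance
#'
#' @param egfr_rel eGFR in mL/min/1.73 m^2.
#' @param bsa Individual body surface area, m^2.
#' @return Absolute eGFR in mL/min: `egfr_rel * bsa / 1.73`.
#' @export
egfr_relative_to_absolute <- function(egfr_rel, bsa) {
  if (any(!is.finite(egfr_rel)) || any(egfr_rel < 0)) {
    stop("egfr_relative_to_absolute(): egfr_rel must be non-negative")
  }
  if (any(!is.finite(bsa)) || any(bsa <= 0)) {
    stop("egfr_relative_to_absolute(): bsa must be positive")
  }
  egfr_rel * bsa / 1.73
}

#' Estimated creatinine clearance by Cockcroft-Gault
#'
#' \deqn{eCrCL = (140 - age) \times weight / (72 \times Scr) \times 0.85
#' \ \mathrm{[if\ female]}}
#'
#' @inheritParams egfr_mdrd
#' @param weight Body weight, kg.
#' @return Estimated creatinine clearance in mL/min.
#' @export
ecrcl_cg <- function(scr, age, weight, sex) {
  sex <- match_sex(sex)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("ecrcl_cg(): serum creatinine must be positive")
  }
  if (any(age < 0)) stop("ecrcl_cg(): age must be non-negative")
  pmax(140 - age, 0) * weight / (72 * scr) *
    ifelse(sex == "female", 0.85, 1)
}

#' KDIGO eGFR category
#'
#' Categories `<15`, `15-29`, `30-44`, `45-59`, `60-89`, `>=90`
#' mL/min/1.73 m^2, with half-open boundaries `[lower, upper + 1)` so that
#' the printed inclusive ranges are honoured (29 falls in `15-29`, 30 in
#' `30-44`, fractional values such as 44.5 in `30-44`).
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (vectorized).
#' @return Factor with the six ordered category labels.
#' @export
classify_kdigo <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr < 0)) {
    stop("classify_kdigo(): egfr must be non-negative")
  }
  labs <- c("<15", "15-29", "30-44", "45-59", "60-89", ">=90")
  cut(egfr, breaks = c(0, 15, 30, 45, 60, 90, Inf), labels = labs,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Anuria classification
#'
#' Anuria is defined as a 24-hour urine output strictly below 100 mL.
#'
#' @param urine_output_24h 24-hour urine output, mL.
#' @return Logical vector.
#' @export
is_anuric <- function(urine_output_24h) {
  if (any(!is.finite(urine_output_24h)) || any(urine_output_24h < 0)) {
    stop("is_anuric(): urine output must be non-negative")
  }
  urine_output_24h < 100
}

#' Impute missing covariates in a longitudinal table
#'
#' Within-subject gaps are filled by last-observation-carried-forward (and,
#' for leading gaps, next-observation-carried-backward); covariates entirely
#' missing for a subject receive the cohort median of the other subjects'
#' baseline values. Idempotent: applying it twice changes nothing.
#'
#' @param records Data frame with an `ID` column and covariate columns; rows
#'   ordered in time within subject.
#' @param columns Character vector of covariate columns to complete.
#'   Defaults to every column other than `ID` and the event columns of the
#'   NONMEM-style dataset layout.
#' @return The completed data frame (same shape, no `NA` in `columns`).
#' @export
impute_covariates <- function(records, columns = NULL) {
  stopifnot(is.data.frame(records), "ID" %in% names(records))
  if (is.null(columns)) {
    skip <- c("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "DV", "CMT", "STUDY")
    columns <- setdiff(names(records), skip)
  }
  missing_cols <- setdiff(columns, names(records))
  if (length(missing_cols)) {
    stop("impute_covariates(): unknown column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ids <- unique(records$ID)
  for (col in columns) {
    x <- records[[col]]
    if (!anyNA(x)) next
    # per-subject LOCF / NOCB
    for (id in ids) {
      idx <- which(records$ID == id)
      x[idx] <- locf(x[idx])
    }
    # cohort median for subjects with the covariate entirely missing
    if (anyNA(x)) {
      baseline <- vapply(ids, function(id) x[which(records$ID == id)[1]],
                         numeric(1))
      if (all(is.na(baseline))) {
        stop("impute_covariates(): covariate '", col,
             "' is missing for every subject")
      }
      med <- stats::median(baseline, na.rm = TRUE)
      x[is.na(x)] <- med
    }
    records[[col]] <- x
  }
  records
}

# carry last observation forward, then first observation backward
locf <- function(x) {
  if (!anyNA(x) || all(is.na(x))) return(x)
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  filled <- ifelse(idx > 0L, x[pmax(idx, 1L)], NA)
  if (anyNA(filled)) filled[is.na(filled)] <- filled[which(!is.na(filled))[1]]
  filled
}

match_sex <- function(sex) {
  if (is.numeric(sex)) sex <- ifelse(sex > 0, "female", "male")
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female' (or 0 = male / 1 = female)")
  }
  sex
}
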