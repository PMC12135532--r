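# NONMEM-style event dataset: comma-delimited text, fixed column order.
# Dose rows: EVID = 1, AMT > 0, RATE = AMT / infusion duration, MDV = 1.
# Observation rows: EVID = 0, MDV = 0, DV >= 0 (mg/L), AMT = 0.
# KRT state rows: EVID = 2, KRTON toggling 1/0 with QD on the start row.
nm_columns <- function() {
  c("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "DV", "CMT",
    "EGFR", "ANUR", "QD", "KRTON", "STUDYB",
    "WT", "HT", "AGE", "SEX", "UO24", "STUDY")
}

#' Validate a NONMEM-style event dataset
#'
#' Enforces the event-record invariants: dose rows (`EVID = 1`) carry
#' `AMT > 0`, `MDV = 1` and a `RATE` consistent with a finite infusion;
#' observation rows (`EVID = 0`) carry `DV >= 0` and `AMT = 0`; times are
#' non-decreasing within subject.
#'
#' @param ds Data frame with the columns of [nm_columns()] (`STUDY` and the
#'   covariates may contain `NA`).
#' @param rate_tol Relative tolerance for the `RATE` vs amount/duration
#'   consistency check.
#' @return `ds`, invisibly, or an error naming the offending row.
#' @export
validate_nm_dataset <- function(ds, rate_tol = 1e-3) {
  need <- setdiff(nm_columns(), "STUDY")
  miss <- setdiff(need, names(ds))
  if (length(miss)) {
    stop("validate_nm_dataset(): missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) stop("validate_nm_dataset(): ", msg, " (row ", i[1], ")")
  }
  bad_row(!ds$EVID %in% c(0, 1, 2), "EVID must be 0, 1 or 2")
  dose <- ds$EVID == 1
  obs <- ds$EVID == 0
  bad_row(dose & (is.na(ds$AMT) | ds$AMT <= 0), "dose rows need AMT > 0")
  bad_row(dose & (is.na(ds$RATE) | ds$RATE <= 0), "dose rows need RATE > 0")
  bad_row(dose & ds$MDV != 1, "dose rows need MDV = 1")
  bad_row(obs & !(is.na(ds$AMT) | ds$AMT == 0),
          "observation rows must have AMT = 0")
  bad_row(obs & (is.na(ds$DV) | ds$DV < 0),
          "observation rows need DV >= 0")
  bad_row(obs & ds$MDV != 0, "observation rows need MDV = 0")
  for (id in unique(ds$ID)) {
    tt <- ds$TIME[ds$ID == id]
    if (is.unsorted(tt)) {
      stop("validate_nm_dataset(): non-monotone times for subject ", id)
    }
  }
  invisible(ds)
}

#' Read / write a NONMEM-style dataset
#'
#' Comma-delimited text with a header row and the fixed column order of
#' [nm_columns()]; missing numeric covariates are empty fields. The
#' write/read roundtrip is lossless to full double precision.
#'
#' @param path File path.
#' @return `read_nm_dataset()`: the validated data frame.
#' @export
read_nm_dataset <- function(path) {
  ds <- utils::read.csv(path, na.strings = c("", "NA", "."),
                        colClasses = c(STUDY = "character"))
  validate_nm_dataset(ds)
}

#' @rdname read_nm_dataset
#' @param ds Dataset to write (validated first).
#' @export
write_nm_dataset <- function(ds, path) {
  validate_nm_dataset(ds)
  ds <- ds[nm_columns()[nm_columns() %in% names(ds)]]
  num <- vapply(ds, is.numeric, logical(1))
  ds[num] <- lapply(ds[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.17g", x))
  })
  utils::write.csv(ds, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# Compile one subject's rows into the design object used by the likelihood,
# the VPC and the generator: observation times/DV, dose events, KRT windows
# and baseline covariates.
make_subject <- function(id, regimen, krt, cov, obs_times, dv = NULL,
                         horizon_h = NULL) {
  horizon_h <- horizon_h %||%
    max(c(obs_times, regimen$start + regimen$duration, krt$end, 0)) + 1e-6
  ord <- order(obs_times)
  list(id = id, regimen = regimen, krt = krt, cov = cov,
       obs_times = obs_times[ord],
       dv = if (is.null(dv)) NULL else dv[ord],
       segments = build_segments(regimen, krt, horizon_h),
       horizon = horizon_h)
}

#' Split an NM-style dataset into per-subject design objects
#'
#' Reconstructs, for each subject, the dosing regimen (from `EVID = 1`
#' rows), the KRT windows (from `EVID = 2` `KRTON` transitions), the
#' baseline covariates and the observation vectors. Used internally by the
#' fit, the weighted residuals and the pcVPC.
#'
#' @param ds Validated NM-style dataset.
#' @return Named list of subject objects.
#' @export
split_subjects <- function(ds) {
  validate_nm_dataset(ds)
  lapply(split(ds, factor(ds$ID, levels = unique(ds$ID))), function(sub) {
    dose <- sub[sub$EVID == 1, ]
    obs <- sub[sub$EVID == 0, ]
    regimen <- if (nrow(dose)) {
      fosfo_regimen(start_times = dose$TIME, amounts = dose$AMT,
                    duration_h = dose$AMT / dose$RATE)
    } else NULL
    kr <- sub[sub$EVID == 2, ]
    windows <- data.frame(start = numeric(0), end = numeric(0),
                          qd = numeric(0))
    open_t <- NA_real_; open_qd <- NA_real_
    for (i in seq_len(nrow(kr))) {
      if (kr$KRTON[i] == 1) {
        open_t <- kr$TIME[i]; open_qd <- kr$QD[i]
      } else if (!is.na(open_t)) {
        windows <- rbind(windows,
                         data.frame(start = open_t, end = kr$TIME[i],
                                    qd = open_qd))
        open_t <- NA_real_
      }
    }
    horizon <- max(c(sub$TIME, if (!is.null(regimen))
      regimen$start + regimen$duration)) + 1e-6
    if (!is.na(open_t)) {          # session still running at last record
      windows <- rbind(windows, data.frame(start = open_t, end = horizon,
                                           qd = open_qd))
    }
    first <- sub[1, ]
    cov <- list(egfr = first$EGFR, anuric = isTRUE(first$ANUR == 1),
                study_b = isTRUE(first$STUDYB == 1), wt = first$WT,
                ht = first$HT, age = first$AGE, sex = first$SEX,
                uo24 = first$UO24,
                qd = if (nrow(windows)) windows$qd[1] else NA_real_)
    make_subject(first$ID, regimen, krt_schedule(windows = windows), cov,
                 obs_times = obs$TIME, dv = obs$DV, horizon_h = horizon)
  })
}
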