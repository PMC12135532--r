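#' Stepwise covariate search (forward inclusion, backward elimination)
#'
#' Forward step: among the remaining candidates, repeatedly add the one
#' with the largest statistically significant OFV drop (chi-square
#' criterion at `alpha_forward` per added parameter, 3.84 for one
#' parameter at 0.05). Backward step: candidates whose removal worsens the
#' OFV by less than the `alpha_backward` criterion (6.63 for one parameter
#' at 0.01) are eliminated, least-significant first. Candidates whose fit
#' fails are skipped and logged in the trace.
#'
#' @param dataset NM-style dataset or subject list.
#' @param base_spec [fosfo_model_spec()] of the starting model.
#' @param candidates List of [covariate_candidate()]s.
#' @param alpha_forward,alpha_backward Significance levels.
#' @param init,control Passed to [fosfo_fit()].
#' @return List with `spec` (selected model), `fit` (its `fosfo_fit`),
#'   `selected` (candidate labels) and `trace` (data frame of every
#'   decision: step, candidate, dOFV, action).
#' @export
stepwise_covariate_search <- function(dataset, base_spec = fosfo_model_spec(),
                                      candidates,
                                      alpha_forward = 0.05,
                                      alpha_backward = 0.01,
                                      init = NULL, control = list()) {
  subjects <- if (is.data.frame(dataset)) {
    split_subjects(impute_covariates(
      dataset, columns = intersect(c("EGFR", "WT", "HT", "AGE", "UO24"),
                                   names(dataset))))
  } else dataset
  refit <- function(spec) {
    tryCatch(fosfo_fit(subjects, spec, init = init, compute_rse = FALSE,
                       control = control),
             error = function(e) NULL)
  }
  trace <- data.frame(step = character(0), candidate = character(0),
                      dofv = numeric(0), action = character(0))
  log_row <- function(step, cand, dofv, action) {
    trace[nrow(trace) + 1L, ] <<- list(step, cand, dofv, action)
  }
  spec <- base_spec
  fit <- refit(spec)
  if (is.null(fit)) stop("stepwise_covariate_search(): base model fit failed")
  included <- list()
  remaining <- candidates
  # forward inclusion
  repeat {
    best <- NULL
    for (cand in remaining) {
      cand_spec <- spec
      cand_spec$extra <- c(spec$extra, list(cand))
      cand_fit <- refit(cand_spec)
      if (is.null(cand_fit)) {
        log_row("forward", cand$label, NA_real_, "fit failed, skipped")
        next
      }
      dofv <- fit$ofv - cand_fit$ofv
      sig <- is.finite(dofv) &&
        dofv > stats::qchisq(1 - alpha_forward, cand$n_par)
      log_row("forward", cand$label, dofv,
              if (sig) "significant" else "not significant")
      if (sig && (is.null(best) || dofv > best$dofv)) {
        best <- list(cand = cand, fit = cand_fit, spec = cand_spec,
                     dofv = dofv)
      }
    }
    if (is.null(best)) break
    log_row("forward", best$cand$label, best$dofv, "included")
    spec <- best$spec
    fit <- best$fit
    included <- c(included, list(best$cand))
    remaining <- Filter(function(cc) cc$label != best$cand$label, remaining)
  }
  # backward elimination
  repeat {
    if (!length(spec$extra)) break
    worst <- NULL
    for (k in seq_along(spec$extra)) {
      cand <- spec$extra[[k]]
      red_spec <- spec
      red_spec$extra <- spec$extra[-k]
      red_fit <- refit(red_spec)
      if (is.null(red_fit)) {
        log_row("backward", cand$label, NA_real_, "fit failed, kept")
        next
      }
      dofv <- red_fit$ofv - fit$ofv   # penalty for deleting the candidate
      crit <- stats::qchisq(1 - alpha_backward, cand$n_par)
      log_row("backward", cand$label, dofv,
              if (dofv < crit) "removable" else "retained")
      if (dofv < crit && (is.null(worst) || dofv < worst$dofv)) {
        worst <- list(k = k, fit = red_fit, spec = red_spec, dofv = dofv,
                      label = cand$label)
      }
    }
    if (is.null(worst)) break
    log_row("backward", worst$label, worst$dofv, "removed")
    spec <- worst$spec
    fit <- worst$fit
  }
  list(spec = spec, fit = fit,
       selected = vapply(spec$extra, `[[`, character(1), "label"),
       trace = trace)
}
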