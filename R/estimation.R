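#' Structural/covariate model specification for estimation
#'
#' Controls which covariate relationships of the final model are active and
#' carries extra candidate effects during covariate search. The final
#' published model has all three structural relationships on and no extras.
#'
#' @param egfr_on_cl Power relationship of eGFR on body clearance
#'   (parameter `theta_kf`).
#' @param qd_on_clkrt Power relationship of dialysate flow on dialysis
#'   clearance (parameter `theta_qd`).
#' @param tsfd_on_vp Linear growth of the peripheral volume with time since
#'   first dose in anuric subjects (parameter `theta_t`).
#' @param extra List of [covariate_candidate()] effects added on top.
#' @return Object of class `fosfo_model_spec`.
#' @export
fosfo_model_spec <- function(egfr_on_cl = TRUE, qd_on_clkrt = TRUE,
                             tsfd_on_vp = TRUE, extra = list()) {
  structure(list(egfr_on_cl = egfr_on_cl, qd_on_clkrt = qd_on_clkrt,
                 tsfd_on_vp = tsfd_on_vp, extra = extra),
            class = "fosfo_model_spec")
}

#' A candidate covariate effect for stepwise search
#'
#' The effect multiplies the typical value of a structural parameter:
#' linear `1 + beta (x - ref)`, power `(x / ref)^beta`, or Emax
#' `1 + emax x / (ec50 + x)`.
#'
#' @param param Target parameter: `"cl"`, `"vc"`, `"vp"`, `"q"` or `"dial"`.
#' @param cov Covariate name as stored in the subject covariate list
#'   (e.g. `"egfr"`, `"wt"`, `"age"`, `"qd"`).
#' @param form `"linear"`, `"power"` or `"emax"`.
#' @param ref Centering value (defaults to 1; the search recentres at the
#'   cohort median).
#' @return Object of class `fosfo_candidate`.
#' @export
covariate_candidate <- function(param = c("cl", "vc", "vp", "q", "dial"),
                                cov, form = c("linear", "power", "emax"),
                                ref = 1) {
  param <- match.arg(param)
  form <- match.arg(form)
  structure(list(param = param, cov = cov, form = form, ref = ref,
                 n_par = if (form == "emax") 2L else 1L,
                 label = paste(param, cov, form, sep = "-")),
            class = "fosfo_candidate")
}

candidate_multiplier <- function(cand, x, beta) {
  switch(cand$form,
    linear = 1 + beta[1] * (x - cand$ref),
    power = (x / cand$ref)^beta[1],
    emax = 1 + beta[1] * x / (exp(beta[2]) + x))  # ec50 kept positive
}

# Individual prediction at the subject's observation times for a batch of
# eta vectors (m x 3). All batch members share the subject's event
# schedule, so the closed-form propagator is vectorized over the batch.
predict_subject_multi <- function(s, fx, etas, re = NULL,
                                  spec = fosfo_model_spec(),
                                  extra_beta = list(), dt_max = 0.25) {
  cov <- s$cov
  tv_cl <- if (cov$anuric || cov$study_b) 0
           else if (spec$egfr_on_cl)
             fx$theta_cl * (max(cov$egfr, 0) / fx$egfr_ref)^fx$theta_kf
           else fx$theta_cl
  tv_vc <- fx$theta_vc
  tv_vp <- fx$theta_vp
  tv_q <- fx$theta_q
  dial_mult <- 1
  for (i in seq_along(spec$extra)) {
    cand <- spec$extra[[i]]
    mult <- candidate_multiplier(cand, cov[[cand$cov]], extra_beta[[i]])
    if (cand$param == "cl") tv_cl <- tv_cl * mult
    if (cand$param == "vc") tv_vc <- tv_vc * mult
    if (cand$param == "vp") tv_vp <- tv_vp * mult
    if (cand$param == "q") tv_q <- tv_q * mult
    if (cand$param == "dial") dial_mult <- mult
  }
  seg <- s$segments
  seg$cl_krt <- dial_mult * ifelse(
    seg$krt_active,
    if (spec$qd_on_clkrt) {
      fx$theta_dial * (ifelse(is.na(seg$qd), 1, seg$qd) / fx$qd_ref)^fx$theta_qd
    } else fx$theta_dial,
    0)
  vp_slope <- if (cov$anuric && spec$tsfd_on_vp) fx$theta_t * 60 else 0
  pr <- propagate_twocpt(s$obs_times, seg,
                         cl_body = tv_cl * exp(etas[, 1]),
                         v_c = tv_vc * exp(etas[, 2]),
                         v_p0 = tv_vp * exp(etas[, 3]),
                         vp_slope = vp_slope, q = tv_q, dt_max = dt_max)
  pr$conc
}

predict_subject <- function(s, fx, eta = c(0, 0, 0), ...) {
  drop(predict_subject_multi(s, fx, matrix(eta, nrow = 1), ...))
}

#' Conditional -2 log-likelihood of one subject at a given eta
#'
#' The inner objective of the marginal likelihood: the Gaussian residual
#' log-density of the observations at the eta-conditional predictions
#' (with the combined proportional + additive residual variance evaluated
#' at the prediction, i.e. with interaction) plus the Gaussian log-density
#' of eta under the diagonal IIV covariance, both on the -2 log scale.
#'
#' @param s Subject object from [split_subjects()].
#' @param fx,re Parameter sets.
#' @param eta Numeric length-3 random-effect vector.
#' @param spec [fosfo_model_spec()].
#' @param extra_beta Coefficients for `spec$extra`, as a list.
#' @return Scalar -2 log joint density.
#' @export
conditional_minus2ll <- function(s, fx, re, eta, spec = fosfo_model_spec(),
                                 extra_beta = list()) {
  drop(conditional_minus2ll_multi(s, fx, re, matrix(eta, nrow = 1),
                                  spec, extra_beta))
}

conditional_minus2ll_multi <- function(s, fx, re, etas,
                                       spec = fosfo_model_spec(),
                                       extra_beta = list(),
                                       penalize = FALSE) {
  pred <- predict_subject_multi(s, fx, etas, re, spec, extra_beta)
  ok <- apply(is.finite(pred), 1, all)
  if (!all(ok) && !penalize) {
    stop("conditional_minus2ll(): non-finite prediction for subject ", s$id)
  }
  pred[!is.finite(pred)] <- 0
  pred <- pmax(pred, 0)
  v <- (re$sigma_prop * pred)^2 + re$sigma_add^2
  if (any(v <= 0)) {
    stop("conditional_minus2ll(): degenerate residual variance ",
         "(sigma_prop and sigma_add cannot both be zero at a zero prediction)")
  }
  res2 <- sweep(pred, 2, s$dv)^2
  ll_res <- rowSums(log(2 * pi * v) + res2 / v)
  om <- c(re$omega2_cl, re$omega2_vc, re$omega2_vp)
  om <- pmax(om, 1e-10)
  ll_eta <- colSums(t(etas^2) / om) + sum(log(2 * pi * om))
  out <- ll_res + ll_eta
  # off-manifold trial points (overflowed predictions) get a finite barrier
  out[!ok] <- 1e12 + ll_eta[!ok]
  out
}

#' Laplace approximation to a subject's -2 log marginal likelihood
#'
#' Minimizes [conditional_minus2ll()] over eta (the mode is the empirical
#' Bayes estimate) with a damped Newton iteration using batched
#' finite-difference gradients and Hessians, then applies the Laplace
#' curvature correction:
#' \deqn{-2\log L_i \approx f(\hat\eta) - d\log(2\pi) +
#'   \log\det\left(\tfrac{1}{2}\nabla^2 f(\hat\eta)\right)}
#'
#' @inheritParams conditional_minus2ll
#' @param start_eta Warm-start value for the inner optimization.
#' @param tol Gradient-norm convergence tolerance.
#' @return Scalar contribution to the objective function value, with
#'   attributes `eta` (the EBE) and `hessian`.
#' @export
laplace_marginal <- function(s, fx, re, spec = fosfo_model_spec(),
                             extra_beta = list(), start_eta = c(0, 0, 0),
                             tol = 1e-6) {
  f <- function(em) conditional_minus2ll_multi(s, fx, re, em, spec,
                                               extra_beta, penalize = TRUE)
  eta <- start_eta
  h <- 1e-4
  # FD stencil: center, +/- h e_i, and the four corners per (i, j) pair
  stencil <- rbind(c(0, 0, 0),
                   diag(3) * h, -diag(3) * h,
                   h * matrix(c(1, 1, 0, 1, -1, 0, -1, 1, 0, -1, -1, 0,
                                1, 0, 1, 1, 0, -1, -1, 0, 1, -1, 0, -1,
                                0, 1, 1, 0, 1, -1, 0, -1, 1, 0, -1, -1),
                              ncol = 3, byrow = TRUE))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  converged <- FALSE
  f0 <- f(matrix(eta, nrow = 1))
  for (it in 1:50) {
    vals <- f(sweep(stencil, 2, eta, `+`))
    f0 <- vals[1]
    g <- (vals[2:4] - vals[5:7]) / (2 * h)
    H <- diag((vals[2:4] - 2 * f0 + vals[5:7]) / h^2)
    for (p in 1:3) {
      corner <- vals[8 + (p - 1) * 4 + 0:3]
      H[pairs[p, 1], pairs[p, 2]] <- H[pairs[p, 2], pairs[p, 1]] <-
        (corner[1] - corner[2] - corner[3] + corner[4]) / (4 * h^2)
    }
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    ridge <- 0
    ev_min <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 1e-8) ridge <- 1e-8 - ev_min
    step <- -solve(H + diag(ridge, 3), g)
    # backtracking line search (batched candidate evaluation)
    lams <- c(1, 0.5, 0.25, 0.1, 0.02)
    cand <- sweep(outer(lams, step), 2, eta, `+`)
    cv <- f(cand)
    best <- which.min(cv)
    if (cv[best] >= f0 - 1e-12) {      # line search stalled
      converged <- max(abs(g)) < 1e-4
      break
    }
    eta <- cand[best, ]
  }
  if (!converged) {
    # fall back on a derivative-free polish from the best point so far
    op <- stats::optim(eta, function(e) f(matrix(e, nrow = 1)),
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    eta <- op$par
    vals <- f(sweep(stencil, 2, eta, `+`))
    f0 <- vals[1]
    H <- diag((vals[2:4] - 2 * f0 + vals[5:7]) / h^2)
    for (p in 1:3) {
      corner <- vals[8 + (p - 1) * 4 + 0:3]
      H[pairs[p, 1], pairs[p, 2]] <- H[pairs[p, 2], pairs[p, 1]] <-
        (corner[1] - corner[2] - corner[3] + corner[4]) / (4 * h^2)
    }
  }
  Hg <- H / 2                      # Hessian of the log joint density
  ev <- eigen(Hg, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-10)
  val <- f0 - 3 * log(2 * pi) + sum(log(ev))
  attr(val, "eta") <- eta
  attr(val, "hessian") <- H
  val
}

# parameter transform bookkeeping -------------------------------------------

# Builds the estimated-parameter table for a model spec: name, transform
# (log / identity), and how to map into fx / re.
param_table <- function(spec) {
  tab <- data.frame(
    name = c("theta_cl", "theta_vc", "theta_vp", "theta_q", "theta_dial",
             if (spec$egfr_on_cl) "theta_kf",
             if (spec$qd_on_clkrt) "theta_qd",
             if (spec$tsfd_on_vp) "theta_t",
             "omega2_cl", "omega2_vc", "omega2_vp",
             "sigma_prop", "sigma_add"),
    stringsAsFactors = FALSE)
  tab$transform <- ifelse(tab$name %in% c("theta_kf", "theta_qd"),
                          "identity", "log")
  for (i in seq_along(spec$extra)) {
    cand <- spec$extra[[i]]
    nm <- paste0("beta_", cand$label, if (cand$n_par == 2) c("_emax", "_ec50")
                 else "")
    tab <- rbind(tab, data.frame(name = nm, transform = "identity"))
  }
  tab
}

to_internal <- function(values, tab) {
  ifelse(tab$transform == "log", log(pmax(values, 1e-12)), values)
}

from_internal <- function(par, tab) {
  v <- ifelse(tab$transform == "log", exp(par), par)
  names(v) <- tab$name
  v
}

unpack_params <- function(values, spec, template_fx = fosfo_fixed_effects()) {
  fx <- template_fx
  for (nm in intersect(names(values),
                       c("theta_cl", "theta_kf", "theta_vc", "theta_vp",
                         "theta_t", "theta_q", "theta_dial", "theta_qd"))) {
    fx[[nm]] <- unname(values[[nm]])
  }
  if (!spec$egfr_on_cl) fx$theta_kf <- 0
  if (!spec$qd_on_clkrt) fx$theta_qd <- 0
  if (!spec$tsfd_on_vp) fx$theta_t <- 0
  re <- fosfo_random_effects(
    omega2_cl = unname(values[["omega2_cl"]]),
    omega2_vc = unname(values[["omega2_vc"]]),
    omega2_vp = unname(values[["omega2_vp"]]),
    sigma_prop = unname(values[["sigma_prop"]]),
    sigma_add = unname(values[["sigma_add"]]))
  extra_beta <- list()
  i <- 1
  for (cand in spec$extra) {
    nms <- paste0("beta_", cand$label,
                  if (cand$n_par == 2) c("_emax", "_ec50") else "")
    extra_beta[[i]] <- unname(values[nms])
    i <- i + 1
  }
  list(fx = fx, re = re, extra_beta = extra_beta)
}

default_initials <- function(spec) {
  init <- c(theta_cl = 1.0, theta_vc = 20, theta_vp = 20, theta_q = 8,
            theta_dial = 1.5, theta_kf = 0.5, theta_qd = 0.5,
            theta_t = 5e-4, omega2_cl = 0.3, omega2_vc = 0.3,
            omega2_vp = 0.3, sigma_prop = 0.2, sigma_add = 15)
  for (cand in spec$extra) {
    nms <- paste0("beta_", cand$label,
                  if (cand$n_par == 2) c("_emax", "_ec50") else "")
    add <- if (cand$n_par == 2) c(0.1, log(cand$ref)) else
      if (cand$form == "power") 0.1 else 0.01
    names(add) <- nms
    init <- c(init, add)
  }
  init
}

#' Fit the population model by Laplace maximum marginal likelihood
#'
#' Minimizes the sum of per-subject Laplace-approximated -2 log marginal
#' likelihoods over the fixed effects, IIV variances and residual-error
#' parameters. Positive parameters are estimated on the log scale; the
#' power-law exponents are unbounded. Inner eta optimizations are
#' warm-started at the previous outer iteration's empirical Bayes
#' estimates. Missing model covariates are imputed first (within-subject
#' carry-forward, then cohort medians).
#'
#' @param dataset NM-style dataset (see [generate_cohort()]), or a list of
#'   subject objects from [split_subjects()].
#' @param spec [fosfo_model_spec()].
#' @param init Named vector of initial values on the natural scale
#'   (defaults are deliberately generic, not the published estimates).
#' @param fixed Character vector of parameter names to hold at their
#'   initial values.
#' @param compute_rse Compute relative standard errors from the
#'   finite-difference Hessian of the objective (adds noticeable runtime).
#' @param control Passed to [stats::nlminb()] (`iter.max`, `rel.tol`, ...).
#' @return Object of class `fosfo_fit`: list with `estimates` (named,
#'   natural scale), `fx`, `re`, `ofv`, `rse` (percent, `NA` if not
#'   computed), `ebe` (subjects x 3), `convergence`, `trace`.
#' @export
fosfo_fit <- function(dataset, spec = fosfo_model_spec(), init = NULL,
                      fixed = character(), compute_rse = TRUE,
                      control = list()) {
  subjects <- if (is.data.frame(dataset)) {
    ds <- impute_covariates(dataset,
                            columns = intersect(c("EGFR", "WT", "HT", "AGE",
                                                  "UO24"), names(dataset)))
    split_subjects(ds)
  } else dataset
  tab <- param_table(spec)
  init_full <- default_initials(spec)
  if (!is.null(init)) init_full[names(init)] <- init
  init_full <- init_full[tab$name]
  free <- !(tab$name %in% fixed)
  par0 <- to_internal(init_full, tab)
  ebe_env <- new.env()
  ebe_env$etas <- lapply(subjects, function(s) c(0, 0, 0))
  n_eval <- 0L
  objective <- function(par_free) {
    par <- par0
    par[free] <- par_free
    vals <- from_internal(par, tab)
    up <- unpack_params(vals, spec)
    total <- 0
    for (i in seq_along(subjects)) {
      li <- tryCatch(
        laplace_marginal(subjects[[i]], up$fx, up$re, spec, up$extra_beta,
                         start_eta = ebe_env$etas[[i]]),
        error = function(e) NA_real_)
      if (is.na(li)) return(1e10)
      ebe_env$etas[[i]] <- attr(li, "eta")
      total <- total + as.numeric(li)
    }
    n_eval <<- n_eval + 1L
    if (!is.finite(total)) 1e10 else total
  }
  # central-difference gradient with a step wide enough to dominate the
  # small history dependence introduced by the warm-started inner solves
  gradient <- function(par_free) {
    h <- 1e-3
    vapply(seq_along(par_free), function(k) {
      up <- par_free; up[k] <- up[k] + h
      dn <- par_free; dn[k] <- dn[k] - h
      (objective(up) - objective(dn)) / (2 * h)
    }, numeric(1))
  }
  ctrl <- utils::modifyList(list(iter.max = 200, eval.max = 1200,
                                 rel.tol = 1e-8), control)
  opt <- stats::nlminb(par0[free], objective, gradient = gradient,
                       control = ctrl)
  par_hat <- par0
  par_hat[free] <- opt$par
  vals <- from_internal(par_hat, tab)
  up <- unpack_params(vals, spec)
  ofv <- objective(opt$par)   # refresh EBEs at the optimum
  rse <- rep(NA_real_, nrow(tab))
  names(rse) <- tab$name
  if (compute_rse) {
    Hs <- tryCatch(stats::optimHess(opt$par, objective),
                   error = function(e) NULL)
    if (!is.null(Hs)) {
      cov_int <- tryCatch(2 * solve(Hs), error = function(e) NULL)
      if (!is.null(cov_int)) {
        se_int <- sqrt(pmax(diag(cov_int), 0))
        k <- 1
        for (i in which(free)) {
          rse[i] <- if (tab$transform[i] == "log") 100 * se_int[k]
                    else 100 * se_int[k] / abs(vals[i])
          k <- k + 1
        }
      }
    }
  }
  ebe <- do.call(rbind, ebe_env$etas)
  colnames(ebe) <- c("eta_cl", "eta_vc", "eta_vp")
  rownames(ebe) <- vapply(subjects, function(s) as.character(s$id),
                          character(1))
  structure(list(estimates = vals, fx = up$fx, re = up$re,
                 extra_beta = up$extra_beta, ofv = ofv, rse = rse,
                 ebe = ebe, spec = spec,
                 convergence = list(code = opt$convergence,
                                    message = opt$message,
                                    iterations = opt$iterations,
                                    evaluations = n_eval),
                 subjects = subjects),
            class = "fosfo_fit")
}

#' @export
print.fosfo_fit <- function(x, ...) {
  cat("Laplace population fit: OFV", sprintf("%.3f", x$ofv), "\n")
  est <- data.frame(estimate = signif(x$estimates, 4),
                    rse_pct = round(x$rse, 1))
  print(est)
  cat("Convergence code", x$convergence$code, "after",
      x$convergence$iterations, "iterations\n")
  invisible(x)
}

#' Write a fit report as structured text
#'
#' @param fit A `fosfo_fit`.
#' @param path Output path; an EBE table is written next to it with suffix
#'   `_ebe.tsv`.
#' @export
write_fit_report <- function(fit, path) {
  lines <- c("# fosfopk fit report",
             sprintf("ofv = %.6f", fit$ofv),
             sprintf("convergence = %d", fit$convergence$code),
             sprintf("%s = %.8g (rse %.1f%%)", names(fit$estimates),
                     fit$estimates, fit$rse))
  writeLines(lines, path)
  ebe_path <- sub("(\\.[^.]*)?$", "_ebe.tsv", path)
  utils::write.table(data.frame(ID = rownames(fit$ebe), fit$ebe),
                     ebe_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Likelihood-ratio test on objective function values
#'
#' Significance of a `df`-parameter richer model at level `alpha` by the
#' chi-square criterion on the OFV difference (3.84 for `df = 1` at 0.05;
#' 6.63 at 0.01).
#'
#' @param ofv_reduced,ofv_full OFVs of the nested models.
#' @param df Number of additional parameters in the full model.
#' @param alpha Significance level.
#' @return Logical (with a warning, and `FALSE`, when the richer model has
#'   the worse OFV). The OFV difference and critical value are attached as
#'   attributes.
#' @export
lrt <- function(ofv_reduced, ofv_full, df = 1, alpha = 0.05) {
  stopifnot(df >= 1)
  dofv <- ofv_reduced - ofv_full
  crit <- stats::qchisq(1 - alpha, df)
  if (dofv < 0) {
    warning("lrt(): the full model has the worse OFV (dOFV = ",
            signif(dofv, 4), "); not significant")
    out <- FALSE
  } else {
    out <- dofv > crit
  }
  structure(out, dofv = dofv, critical = crit)
}

#' Conditional weighted residuals
#'
#' First-order approximation at the empirical Bayes estimates: residuals
#' are decorrelated by `V = G Omega G' + diag(residual variance)` with `G`
#' the finite-difference sensitivity of the prediction to eta at the EBE,
#' using the FOCE-style mean correction `DV - IPRED + G eta_hat`.
#' Approximately zero-mean unit-variance under the true model.
#'
#' @param fit A `fosfo_fit`.
#' @return Data frame with `ID`, `TIME`, `DV`, `IPRED` and `CWRES`.
#' @export
weighted_residuals <- function(fit) {
  re <- fit$re
  if (re$sigma_prop == 0 && re$sigma_add == 0) {
    stop("weighted_residuals(): residual error is degenerate (both zero)")
  }
  om <- diag(c(re$omega2_cl, re$omega2_vc, re$omega2_vp))
  h <- 1e-4
  out <- lapply(seq_along(fit$subjects), function(i) {
    s <- fit$subjects[[i]]
    eta <- fit$ebe[i, ]
    em <- rbind(eta, sweep(diag(3) * h, 2, eta, `+`),
                sweep(-diag(3) * h, 2, eta, `+`))
    pred <- predict_subject_multi(s, fit$fx, em, re, fit$spec,
                                  fit$extra_beta)
    ipred <- pred[1, ]
    G <- t((pred[2:4, , drop = FALSE] - pred[5:7, , drop = FALSE]) / (2 * h))
    V <- G %*% om %*% t(G) + diag(residual_variance(pmax(ipred, 0), re),
                                  nrow = length(ipred))
    L <- tryCatch(chol(V), error = function(e)
      stop("weighted_residuals(): singular observation covariance for subject ",
           s$id))
    res <- s$dv - ipred + drop(G %*% eta)
    data.frame(ID = s$id, TIME = s$obs_times, DV = s$dv, IPRED = ipred,
               CWRES = drop(backsolve(L, res, transpose = TRUE)))
  })
  do.call(rbind, out)
}
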