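#' Fit one cause-specific Cox model
#'
#' Cox partial-likelihood fit for cause `k`: records whose event is of
#' another cause (or censored) are treated as censored at their observed
#' time. Efron tie handling (inert for continuous simulated times).
#'
#' @param data complete data.frame with the covariates, `time`, `event`.
#' @param cause event type k in 1..3.
#' @param covariate_names covariates entering the model.
#' @return list of class `cause_fit`: `cause`, `beta`, `se`, `vcov`,
#'   `n`, `nevent`.
#' @export
fit_cause_specific <- function(data, cause,
                               covariate_names =
                                 default_covariate_model()$names) {
  if (anyNA(data[covariate_names]))
    stop("covariates must be complete; use complete_case_fit() or impute")
  status <- as.integer(data$event == cause)
  if (sum(status) < 1) stop(sprintf("no events of cause %d", cause))
  X <- as.matrix(data[covariate_names])
  fit <- survival::coxph(survival::Surv(data$time, status) ~ X,
                         ties = "efron")
  if (any(!is.finite(fit$coefficients))) {
    bad <- covariate_names[!is.finite(fit$coefficients)]
    stop(sprintf("cause-%d fit did not converge (monotone likelihood?): %s",
                 cause, paste(bad, collapse = ", ")))
  }
  beta <- stats::setNames(as.numeric(fit$coefficients), covariate_names)
  V <- fit$var
  dimnames(V) <- list(covariate_names, covariate_names)
  structure(list(cause = cause, beta = beta,
                 se = stats::setNames(sqrt(diag(V)), covariate_names),
                 vcov = V, n = fit$n, nevent = fit$nevent),
            class = "cause_fit")
}

#' Rubin's rules with Barnard-Rubin degrees of freedom
#'
#' Pools M point estimates and their variances:
#' \eqn{\bar Q = mean(Q_m)}, \eqn{\bar U = mean(U_m)},
#' \eqn{B = var(Q_m)}, total variance \eqn{T = \bar U + (1 + 1/M)B}.
#' The fraction \eqn{\lambda = (1+1/M)B/T} gives the classical df
#' \eqn{\nu_{old} = (M-1)/\lambda^2} and the observed-data df
#' \eqn{\nu_{obs} = \frac{\nu_{com}+1}{\nu_{com}+3}\nu_{com}(1-\lambda)};
#' the Barnard-Rubin df is their harmonic combination
#' \eqn{\nu = (1/\nu_{old} + 1/\nu_{obs})^{-1}}. The 95% CI uses the t
#' quantile with \eqn{\nu} df. When \eqn{B = 0} (no between-imputation
#' variation) the limit \eqn{\nu = \nu_{obs}} with \eqn{\lambda = 0}
#' applies.
#'
#' @param estimates length-M vector of point estimates.
#' @param variances length-M vector of squared standard errors.
#' @param nu_com complete-data degrees of freedom (records minus
#'   parameters).
#' @param conf confidence level.
#' @return list of class `pooled_estimate`: `qbar`, `ubar`, `b`,
#'   `t_var`, `df`, `ci_low`, `ci_high`, `M`.
#' @export
pool_rubin <- function(estimates, variances, nu_com, conf = 0.95) {
  M <- length(estimates)
  stopifnot(M >= 2, length(variances) == M, all(variances > 0),
            nu_com > 0)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  t_var <- ubar + (1 + 1 / M) * b
  lambda <- if (b == 0) 0 else (1 + 1 / M) * b / t_var
  nu_obs <- ((nu_com + 1) / (nu_com + 3)) * nu_com * (1 - lambda)
  df <- if (lambda == 0) nu_obs else {
    nu_old <- (M - 1) / lambda^2
    1 / (1 / nu_old + 1 / nu_obs)
  }
  half <- stats::qt(1 - (1 - conf) / 2, df) * sqrt(t_var)
  structure(list(qbar = qbar, ubar = ubar, b = b, t_var = t_var,
                 df = df, ci_low = qbar - half, ci_high = qbar + half,
                 M = M),
            class = "pooled_estimate")
}

#' Pool cause-specific fits across an imputed stack
#'
#' Fits the three cause-specific Cox models in each of the M completed
#' datasets and pools each coefficient with [pool_rubin()].
#'
#' @param stack an `imputed_stack`.
#' @param nu_com complete-data df; defaults to n - (number of
#'   covariates).
#' @param covariate_names covariates entering the models.
#' @return data.frame with one row per (cause, variable): `qbar`, `se`
#'   (sqrt of total variance), `df`, `ci_low`, `ci_high`, `b`, `ubar`.
#' @export
pool_cause_specific <- function(stack, nu_com = NULL,
                                covariate_names =
                                  default_covariate_model()$names) {
  stopifnot(inherits(stack, "imputed_stack"))
  n <- nrow(stack$datasets[[1]])
  if (is.null(nu_com)) nu_com <- n - length(covariate_names)
  rows <- list()
  for (k in 1:3) {
    fits <- lapply(stack$datasets, fit_cause_specific, cause = k,
                   covariate_names = covariate_names)
    est <- sapply(fits, `[[`, "beta")
    se2 <- sapply(fits, function(f) f$se^2)
    for (v in covariate_names) {
      p <- pool_rubin(est[v, ], se2[v, ], nu_com)
      rows[[length(rows) + 1L]] <- data.frame(
        cause = k, variable = v, qbar = p$qbar, se = sqrt(p$t_var),
        df = p$df, ci_low = p$ci_low, ci_high = p$ci_high,
        b = p$b, ubar = p$ubar, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Complete-case cause-specific analysis
#'
#' Drops records with any missing covariate cell and fits the three
#' cause-specific Cox models on the remainder. Confidence intervals use
#' t quantiles with (remaining records - number of covariates) df.
#'
#' @param data data.frame with possibly missing covariate cells.
#' @param covariate_names covariates entering the models.
#' @param conf confidence level.
#' @return data.frame as [pool_cause_specific()] (with `b = 0`), plus
#'   attribute `n_complete`.
#' @export
complete_case_fit <- function(data,
                              covariate_names =
                                default_covariate_model()$names,
                              conf = 0.95) {
  cc <- stats::complete.cases(data[covariate_names])
  sub <- data[cc, , drop = FALSE]
  if (nrow(sub) < length(covariate_names) + 2)
    stop("too few complete records for a complete-case fit")
  out <- single_fit_table(sub, covariate_names, conf)
  attr(out, "n_complete") <- nrow(sub)
  out
}

# One fit per cause on fully complete data, CIs with t(n - p) df.
single_fit_table <- function(data, covariate_names, conf = 0.95) {
  nu <- nrow(data) - length(covariate_names)
  tq <- stats::qt(1 - (1 - conf) / 2, nu)
  rows <- list()
  for (k in 1:3) {
    f <- fit_cause_specific(data, k, covariate_names)
    rows[[k]] <- data.frame(
      cause = k, variable = covariate_names, qbar = unname(f$beta),
      se = unname(f$se), df = nu,
      ci_low = unname(f$beta - tq * f$se),
      ci_high = unname(f$beta + tq * f$se),
      b = 0, ubar = unname(f$se^2), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
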