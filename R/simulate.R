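#' Simulate competing-risks event times and types
#'
#' Inversion-based generation for three cause-specific constant hazards.
#' The all-cause hazard for a subject with linear predictors
#' \eqn{lp_1, lp_2, lp_3} is \eqn{\sum_k \lambda_k e^{lp_k}}, so the
#' event time is \eqn{T = -\log(u_1) / \sum_k \lambda_k e^{lp_k}} and the
#' event type is drawn with probabilities proportional to
#' \eqn{\lambda_k e^{lp_k}}, by inverting `u2` against the cumulative
#' probabilities in the fixed order (1, 2, 3).
#'
#' @param linpreds n x 3 matrix of linear predictors (columns = causes
#'   cardiovascular, cancer, other).
#' @param rates positive length-3 vector of baseline rates.
#' @param u1,u2 optional uniform(0,1) vectors of length n; drawn from the
#'   current RNG stream when omitted.
#' @return list with `time` (positive numeric) and `event` (integer in
#'   1..3).
#' @export
simulate_events <- function(linpreds, rates, u1 = NULL, u2 = NULL) {
  linpreds <- as.matrix(linpreds)
  stopifnot(ncol(linpreds) == 3, length(rates) == 3, all(rates > 0))
  if (!all(is.finite(linpreds))) stop("non-finite linear predictor")
  n <- nrow(linpreds)
  if (is.null(u1)) u1 <- stats::runif(n)
  if (is.null(u2)) u2 <- stats::runif(n)
  stopifnot(length(u1) == n, length(u2) == n)
  haz <- sweep(exp(linpreds), 2, rates, `*`)   # lambda_k * exp(lp_k)
  tot <- rowSums(haz)
  time <- -log(u1) / tot
  p1 <- haz[, 1] / tot
  p12 <- (haz[, 1] + haz[, 2]) / tot
  event <- 1L + (u2 > p1) + (u2 > p12)
  list(time = time, event = as.integer(event))
}

#' Calibrate an exponential censoring rate by bisection
#'
#' Finds the rate \eqn{\lambda_c} of an exponential censoring
#' distribution such that, with per-subject censoring times
#' \eqn{C_i = -\log(u_i)/\lambda_c} and observed time
#' \eqn{\min(T_i, C_i)}, the realized proportion of censored subjects
#' equals `target`. The per-subject uniforms are drawn once and held
#' fixed across bisection iterations, so the objective is a deterministic
#' nondecreasing step function of \eqn{\lambda_c} and bisection (on the
#' log scale, with bracket expansion) converges to the target within
#' `tol`.
#'
#' @param event_time positive vector of uncensored event times T.
#' @param target desired censored proportion, in (0, 1).
#' @param tol tolerance on the realized censored proportion.
#' @param max_iter maximum bisection iterations.
#' @param u optional uniform(0,1) vector (length of `event_time`); drawn
#'   once internally when omitted.
#' @return list with `lambda_c`, `censor_time` (the calibrated C_i),
#'   `censored` (logical), and `realized` (censored fraction).
#' @export
calibrate_censoring <- function(event_time, target, tol = 0.001,
                                max_iter = 100L, u = NULL) {
  n <- length(event_time)
  if (n == 0) stop("no event times supplied")
  stopifnot(all(event_time > 0), target > 0, target < 1)
  if (is.null(u)) u <- stats::runif(n)
  stopifnot(length(u) == n)
  # censored iff -log(u)/lambda_c < T, i.e. lambda_c > -log(u)/T
  frac <- function(loglam) mean(-log(u) / exp(loglam) < event_time)
  lo <- log(1 / stats::median(event_time)) - 5
  hi <- lo + 10
  expand <- 0L
  while (frac(lo) > target && expand < 60L) { lo <- lo - 2; expand <- expand + 1L }
  while (frac(hi) < target && expand < 120L) { hi <- hi + 2; expand <- expand + 1L }
  if (frac(lo) > target || frac(hi) < target)
    stop(sprintf(
      "censoring target %.3f not bracketed: f(%.2f)=%.4f, f(%.2f)=%.4f",
      target, lo, frac(lo), hi, frac(hi)))
  mid <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- frac(mid)
    if (abs(fm - target) <= tol) break
    if (fm < target) lo <- mid else hi <- mid
  }
  lambda_c <- exp(mid)
  realized <- frac(mid)
  if (abs(realized - target) > tol)
    stop(sprintf(
      "bisection did not reach target %.3f within tol %.3g (got %.4f)",
      target, tol, realized))
  cens_time <- -log(u) / lambda_c
  list(lambda_c = lambda_c, censor_time = cens_time,
       censored = cens_time < event_time, realized = realized)
}

#' Build a complete super-population and its 'true' coefficients
#'
#' Generates covariates from the covariate model, competing-risks
#' outcomes from the three cause-specific exponential hazards with the
#' supplied log-hazard-ratio vectors, applies exponential censoring
#' calibrated to the scenario's censoring target, and (optionally) fits
#' the three cause-specific Cox models to the full super-population. The
#' fitted coefficients are the scenario's "true" values against which
#' per-replicate estimates are compared.
#'
#' @param cfg a [scenario_config()].
#' @param cov_model a `covariate_model`.
#' @param betas a `coefficient_set`.
#' @param fit_true fit the super-population Cox models (default TRUE).
#' @return list with `data` (data.frame: 10 covariates, `time`, `event`
#'   coded 0=censored/1/2/3), `true_values` (10 x 3 matrix or NULL),
#'   `lambda_c`, and `realized_censoring`.
#' @export
build_superpopulation <- function(cfg,
                                  cov_model = default_covariate_model(),
                                  betas = default_coefficients(),
                                  fit_true = TRUE) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  X <- generate_covariates(cov_model, cfg$n_super)
  B <- coef_matrix(betas)
  lp <- as.matrix(X) %*% B
  rates <- c(cfg$lambda_cvd, cfg$lambda_cancer, cfg$lambda_other)
  ev <- simulate_events(lp, rates)
  cal <- calibrate_censoring(ev$time, cfg$censor_target)
  dat <- X
  dat$time <- pmin(ev$time, cal$censor_time)
  dat$event <- ifelse(cal$censored, 0L, ev$event)
  true_values <- NULL
  if (fit_true) {
    true_values <- sapply(1:3, function(k) fit_cause_specific(dat, k)$beta)
    colnames(true_values) <- c("cvd", "cancer", "other")
  }
  list(data = dat, true_values = true_values,
       lambda_c = cal$lambda_c, realized_censoring = cal$realized)
}
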