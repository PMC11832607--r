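#' Predictive mean matching for one variable
#'
#' Bayesian linear-regression PMM with type-1 matching. A linear model
#' of the observed target values on the predictors is fit; the residual
#' variance is drawn from its scaled inverse-chi-squared posterior and
#' the coefficients from their conditional normal posterior. Predicted
#' means use the point estimates for observed rows and the drawn
#' parameters for missing rows; each missing row receives the observed
#' value of one of its `donors` nearest observed rows (by predicted
#' mean), chosen uniformly at random. Because donors are observed
#' values, imputations always lie within the observed range, and binary
#' targets stay binary.
#'
#' Exactly collinear predictor columns are dropped (with a warning)
#' using the pivoted QR of the design.
#'
#' @param y numeric vector with NAs to impute.
#' @param X complete numeric predictor matrix (no intercept; one is
#'   added internally).
#' @param donors size of the donor pool (k >= 1).
#' @return `y` with NAs replaced by donor values.
#' @export
impute_pmm <- function(y, X, donors = 5L) {
  miss <- is.na(y)
  if (!any(miss)) return(y)
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (anyNA(X[!miss, , drop = FALSE]))
    stop("predictors must be complete for rows with observed target")
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  fit <- stats::lm.fit(Xo, yo)
  r <- fit$rank
  if (length(yo) < ncol(Xo) + 1 || length(yo) - r < 1)
    stop(sprintf(
      "too few observed rows (%d) for %d predictors (design rank %d)",
      length(yo), ncol(Xo) - 1L, r))
  piv <- fit$qr$pivot
  keep <- piv[seq_len(r)]
  if (r < ncol(Xo))
    warning(sprintf("dropping %d aliased predictor column(s): %s",
                    ncol(Xo) - r,
                    paste(colnames(Xo)[piv[(r + 1):ncol(Xo)]],
                          collapse = ", ")))
  beta <- fit$coefficients[keep]
  res <- fit$residuals
  df <- length(yo) - r
  if (df < 1) stop("no residual degrees of freedom for variance draw")
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  V <- chol2inv(R)                       # (X'X)^-1 on the kept columns
  beta_star <- beta + drop(crossprod(chol(V), stats::rnorm(r))) *
    sqrt(sigma2_star)
  yhat_obs <- drop(Xo[, keep, drop = FALSE] %*% beta)
  yhat_mis <- drop(X[miss, keep, drop = FALSE] %*% beta_star)
  k <- min(donors, length(yo))
  out <- y
  out[miss] <- vapply(yhat_mis, function(m) {
    d <- abs(yhat_obs - m)
    pool <- order(d)[seq_len(k)]
    yo[pool[sample.int(k, 1L)]]
  }, numeric(1))
  out
}

#' Multiple imputation by chained equations with PMM
#'
#' Imputes the incomplete covariates of a competing-risks dataset by
#' fully conditional specification. The imputation model for each
#' variable uses the predictor construction of
#' [imputation_predictors()]: the other nine covariates plus
#' cause-specific cumulative hazards, event indicators and
#' hazard-by-covariate interactions (all three causes, or the
#' cardiovascular cause only). Hazard features are computed once from
#' the observed time/event (always complete); interaction columns are
#' recomputed from the current imputed values in every cycle. Missing
#' cells are initialized by random draws from the observed values of
#' the same variable; variables are visited in ascending order of
#' missingness count. The M chains are independent.
#'
#' @param data data.frame with the 10 covariates (NAs allowed), `time`
#'   and `event` (complete).
#' @param strategy `"all_causes"` or `"primary_only"`.
#' @param M number of imputed datasets.
#' @param cycles chained-equation iterations per chain.
#' @param donors PMM donor-pool size.
#' @param seed optional integer seed.
#' @param covariate_names the 10 analysis covariates.
#' @return an object of class `imputed_stack`: list with `datasets`
#'   (list of M complete data.frames), `strategy`, `iterations`,
#'   `donors`, `seed`, `M`.
#' @export
mice_pmm <- function(data, strategy = c("all_causes", "primary_only"),
                     M = 10L, cycles = 10L, donors = 5L, seed = NULL,
                     covariate_names = default_covariate_model()$names) {
  strategy <- match.arg(strategy)
  stopifnot(M >= 2, cycles >= 1)
  if (anyNA(data$time) || anyNA(data$event))
    stop("time and event must be complete")
  if (!is.null(seed)) set.seed(seed)
  feats <- hazard_features(data$time, data$event)
  nmiss <- vapply(data[covariate_names], function(x) sum(is.na(x)),
                  integer(1))
  visit <- names(sort(nmiss[nmiss > 0]))
  datasets <- vector("list", M)
  for (m in seq_len(M)) {
    cur <- data
    for (v in visit) {
      mis <- is.na(cur[[v]])
      cur[[v]][mis] <- sample(cur[[v]][!mis], sum(mis), replace = TRUE)
    }
    if (length(visit) > 0) {
      for (cyc in seq_len(cycles)) {
        for (v in visit) {
          Xp <- imputation_predictors(cur, feats, v, strategy,
                                      covariate_names)
          y <- data[[v]]                 # original NAs mark what to impute
          cur[[v]] <- impute_pmm(y, Xp, donors)
        }
      }
    }
    datasets[[m]] <- cur
  }
  structure(list(datasets = datasets, strategy = strategy,
                 iterations = as.integer(cycles),
                 donors = as.integer(donors),
                 seed = seed, M = as.integer(M)),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack:", x$M, "datasets, strategy", x$strategy,
      ",", x$iterations, "cycles\n")
  invisible(x)
}
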