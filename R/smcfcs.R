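#' Breslow baseline cumulative hazard for one cause
#'
#' \eqn{H_{0k}(t) = \sum_{s \le t, cause k} d_k(s) / \sum_{l: T_l \ge s}
#' e^{lp_{k,l}}}, evaluated at each record's observed time. Other-cause
#' events count as censored.
#'
#' @param time,event observed time and event code vectors.
#' @param cause the cause k.
#' @param lp linear predictor vector for cause k.
#' @param eval_times evaluation times (default: each record's time).
#' @return nonnegative numeric vector, nondecreasing in `eval_times`.
#' @export
breslow_cumhaz <- function(time, event, cause, lp, eval_times = time) {
  stopifnot(length(lp) == length(time))
  ut <- sort(unique(time))
  idx <- match(time, ut)
  w <- exp(lp)
  wrisk <- rev(cumsum(rev(unname(drop(rowsum(w, idx))))))
  dk <- tabulate(idx[event == cause], length(ut))
  H <- cumsum(ifelse(wrisk > 0, dk / wrisk, 0))
  unname(c(0, H)[findInterval(eval_times, ut) + 1L])
}

#' Outcome-likelihood factor of the cause-specific substantive models
#'
#' For covariate row x with observed (time, event) and current
#' substantive-model state (three coefficient vectors `beta`, three
#' baseline cumulative hazards evaluated at the record's time `H0`),
#' returns \eqn{\prod_k (e^{x\beta_k})^{I(event=k)} \exp(-H_{0k}(t)
#' e^{x\beta_k})}. Baseline hazard jump factors independent of x are
#' omitted; they cancel in rejection-acceptance ratios. This is the
#' acceptance weight for substantive-model-compatible imputation.
#'
#' @param lp length-3 vector (or n x 3 matrix) of linear predictors
#'   \eqn{x \beta_k}.
#' @param event event code (0 = censored).
#' @param H0 length-3 vector (or n x 3 matrix) of baseline cumulative
#'   hazards at the record's time.
#' @return nonnegative weight(s).
#' @export
cause_specific_likelihood <- function(lp, event, H0) {
  lp <- matrix(lp, ncol = 3)
  H0 <- matrix(H0, ncol = 3)
  if (any(H0 < 0)) stop("negative baseline cumulative hazard")
  elp <- exp(lp)
  haz <- rep(1, nrow(lp))
  ev <- as.integer(event)
  sel <- which(ev %in% 1:3)
  haz[sel] <- elp[cbind(sel, ev[sel])]
  haz * exp(-rowSums(H0 * elp))
}

draw_norm_posterior <- function(coef, vcov) {
  L <- chol(vcov)
  coef + drop(crossprod(L, stats::rnorm(length(coef))))
}

# Bayesian draws for the covariate models used as SMCFCS proposal
# distributions: linear for continuous targets, logistic for binary.
covariate_model_draw <- function(y_obs, X_obs, X_all, binary) {
  Xo <- cbind(1, X_obs)
  Xa <- cbind(1, X_all)
  if (binary) {
    fit <- suppressWarnings(
      stats::glm.fit(Xo, y_obs, family = stats::binomial()))
    qrr <- qr.R(fit$qr)
    V <- chol2inv(qrr)                   # (X'WX)^-1 at convergence
    bstar <- draw_norm_posterior(fit$coefficients, V)
    list(type = "binary", p = stats::plogis(drop(Xa %*% bstar)))
  } else {
    fit <- stats::lm.fit(Xo, y_obs)
    r <- fit$rank
    if (r < ncol(Xo)) stop("collinear covariate model design")
    df <- length(y_obs) - r
    sigma2 <- sum(fit$residuals^2) / stats::rchisq(1, df)
    V <- chol2inv(qr.R(fit$qr)) * sigma2
    bstar <- draw_norm_posterior(fit$coefficients, V)
    list(type = "continuous", mu = drop(Xa %*% bstar),
         sigma = sqrt(sigma2))
  }
}

propose_values <- function(model, rows, n_each = 1L) {
  if (model$type == "binary") {
    matrix(stats::rbinom(length(rows) * n_each, 1L,
                         rep(model$p[rows], n_each)),
           nrow = length(rows))
  } else {
    matrix(stats::rnorm(length(rows) * n_each,
                        rep(model$mu[rows], n_each), model$sigma),
           nrow = length(rows))
  }
}

#' Substantive-model-compatible FCS for cause-specific Cox models
#'
#' Imputes missing covariates so that the imputations are compatible
#' with all three cause-specific hazard models. Each cycle: (a) the
#' three cause-specific Cox models are refit on the current completed
#' data, coefficients are drawn from their asymptotic normal posterior,
#' and Breslow baseline cumulative hazards are recomputed at the drawn
#' coefficients; (b) each incomplete covariate is imputed by rejection
#' sampling — proposals come from a Bayesian covariate model given the
#' other nine covariates only (linear for continuous, logistic for
#' binary targets) and are accepted with probability proportional to
#' the outcome-likelihood factor [cause_specific_likelihood()].
#'
#' The per-record rejection bound is 1.5 times the largest weight among
#' an initial batch of 20 proposals (a documented approximation; weights
#' above the bound simply accept). A record exhausting `max_rejections`
#' proposals keeps the highest-weight proposal seen; exhaustion counts
#' are recorded in the result.
#'
#' @param data data.frame with the 10 covariates (NAs allowed), `time`
#'   and `event` (complete).
#' @param M number of imputed datasets.
#' @param cycles iterations per chain.
#' @param max_rejections proposal cap per missing cell per cycle.
#' @param seed optional integer seed.
#' @param covariate_names the 10 analysis covariates.
#' @param null_substantive diagnostic mode: force all substantive-model
#'   coefficients to zero, making acceptance independent of the
#'   proposal, so imputations follow the covariate model alone.
#' @return an `imputed_stack`; element `exhausted` counts rejection-cap
#'   hits per variable.
#' @export
smcfcs_cr <- function(data, M = 10L, cycles = 10L, max_rejections = 1000L,
                      seed = NULL,
                      covariate_names = default_covariate_model()$names,
                      null_substantive = FALSE) {
  stopifnot(M >= 2, cycles >= 1)
  if (anyNA(data$time) || anyNA(data$event))
    stop("time and event must be complete")
  if (!is.null(seed)) set.seed(seed)
  nmiss <- vapply(data[covariate_names], function(x) sum(is.na(x)),
                  integer(1))
  visit <- names(sort(nmiss[nmiss > 0]))
  binary <- vapply(data[covariate_names], function(x)
    all(stats::na.omit(x) %in% c(0, 1)), logical(1))
  exhausted <- stats::setNames(integer(length(visit)), visit)
  n_bound <- 20L
  bound_factor <- 1.5
  datasets <- vector("list", M)
  for (m in seq_len(M)) {
    cur <- init_from_observed(data, visit)
    for (cyc in seq_len(cycles)) {
      state <- tryCatch(
        draw_substantive_state(cur, covariate_names, null_substantive),
        error = function(e) e)
      if (inherits(state, "error")) {    # one restart with fresh init
        cur <- init_from_observed(data, visit)
        state <- draw_substantive_state(cur, covariate_names,
                                        null_substantive)
      }
      for (v in visit) {
        mis_idx <- which(is.na(data[[v]]))
        others <- setdiff(covariate_names, v)
        Xoth <- as.matrix(cur[others])
        cm <- covariate_model_draw(cur[[v]][-mis_idx],
                                   Xoth[-mis_idx, , drop = FALSE],
                                   Xoth, binary[[v]])
        # linear predictors excluding the target's contribution
        Xall <- as.matrix(cur[covariate_names])
        lp_minus <- Xall[mis_idx, , drop = FALSE] %*% state$beta -
          outer(cur[[v]][mis_idx], state$beta[v, ])
        bv <- state$beta[v, ]
        H0m <- state$H0[mis_idx, , drop = FALSE]
        evm <- data$event[mis_idx]
        weight_of <- function(x, rows)  # x: proposals for `rows` of mis_idx
          cause_specific_likelihood(
            lp_minus[rows, , drop = FALSE] + outer(as.numeric(x), bv),
            evm[rows], H0m[rows, , drop = FALSE])
        nmis <- length(mis_idx)
        # initial batch: establish bounds and best-so-far
        P0 <- propose_values(cm, seq_len(nmis), n_each = n_bound)
        W0 <- matrix(0, nmis, n_bound)
        for (j in seq_len(n_bound))
          W0[, j] <- weight_of(P0[, j], seq_len(nmis))
        best_w <- apply(W0, 1, max)
        best_x <- P0[cbind(seq_len(nmis), max.col(W0))]
        bound <- pmax(bound_factor * best_w, .Machine$double.xmin)
        accepted <- rep(NA_real_, nmis)
        active <- seq_len(nmis)
        tries <- rep(n_bound, nmis)
        while (length(active) > 0) {
          x <- drop(propose_values(cm, active))
          w <- weight_of(x, active)
          upd <- w > best_w[active]
          best_w[active[upd]] <- w[upd]
          best_x[active[upd]] <- x[upd]
          acc <- stats::runif(length(active)) < w / bound[active]
          accepted[active[acc]] <- x[acc]
          tries[active] <- tries[active] + 1L
          give_up <- !acc & tries[active] >= max_rejections
          if (any(give_up)) exhausted[v] <- exhausted[v] + sum(give_up)
          active <- active[!acc & !give_up]
        }
        fallback <- is.na(accepted)
        accepted[fallback] <- best_x[fallback]
        cur[[v]][mis_idx] <- accepted
      }
    }
    datasets[[m]] <- cur
  }
  structure(list(datasets = datasets, strategy = "smcfcs",
                 iterations = as.integer(cycles),
                 max_rejections = as.integer(max_rejections),
                 exhausted = exhausted, seed = seed, M = as.integer(M)),
            class = "imputed_stack")
}

init_from_observed <- function(data, visit) {
  cur <- data
  for (v in visit) {
    mis <- is.na(cur[[v]])
    cur[[v]][mis] <- sample(cur[[v]][!mis], sum(mis), replace = TRUE)
  }
  cur
}

# Fit the three cause-specific Cox models on completed data, draw
# coefficients from N(MLE, vcov), and evaluate Breslow baselines at the
# drawn coefficients for every record's observed time.
draw_substantive_state <- function(cur, covariate_names, null_substantive) {
  Xall <- as.matrix(cur[covariate_names])
  beta <- matrix(0, length(covariate_names), 3,
                 dimnames = list(covariate_names, NULL))
  H0 <- matrix(0, nrow(cur), 3)
  for (k in 1:3) {
    if (!null_substantive) {
      fit <- fit_cause_specific(cur, k)
      beta[, k] <- draw_norm_posterior(fit$beta, fit$vcov)
    }
    H0[, k] <- breslow_cumhaz(cur$time, cur$event, k,
                              drop(Xall %*% beta[, k]))
  }
  list(beta = beta, H0 = H0)
}
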