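# Small simulated populations shared across tests. Everything is built
# in code at test time; sizes are kept modest so the default run stays
# fast.

make_population <- function(n = 5000, rates = c(1, 1, 1), seed = 1L,
                            p_missing = 0, fit_true = FALSE) {
  cfg <- scenario_config(rates = rates, p_missing = max(p_missing, 0.1),
                         n_super = n, n_sample = min(1000L, n),
                         n_reps = 1L, M = 2L, seed = seed)
  pop <- build_superpopulation(cfg, fit_true = fit_true)
  amputed <- if (p_missing > 0)
    ampute_mar(pop$data, p_missing = p_missing, seed = seed + 1L)
  else pop$data
  list(cfg = cfg, pop = pop, data = pop$data, amputed = amputed)
}

# Hand-coded Cox partial likelihood (no ties in simulated data, so
# Breslow = Efron) used as an independent oracle for coxph-based fits.
oracle_cox_coef <- function(time, status, X) {
  negll <- function(beta) {
    lp <- drop(X %*% beta)
    ll <- 0
    for (i in which(status == 1)) {
      risk <- time >= time[i]
      ll <- ll + lp[i] - log(sum(exp(lp[risk])))
    }
    -ll
  }
  grad <- function(beta) {
    lp <- drop(X %*% beta)
    g <- numeric(ncol(X))
    for (i in which(status == 1)) {
      risk <- which(time >= time[i])
      w <- exp(lp[risk])
      g <- g + X[i, ] - colSums(X[risk, , drop = FALSE] * w) / sum(w)
    }
    -g
  }
  stats::optim(rep(0, ncol(X)), negll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-15))$par
}
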