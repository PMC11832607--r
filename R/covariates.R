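#' Canonical synthetic covariate model
#'
#' Ten covariates on clinically plausible scales for a post-myocardial-
#' infarction cohort: five continuous (age in years, systolic blood
#' pressure in mmHg, heart rate in beats/min, hemoglobin in g/L,
#' cholesterol in mmol/L) and five binary (female, angina, diabetes,
#' previous AMI, current smoker). The binary variables are represented on
#' a standard-normal latent scale and dichotomized at the analytic
#' quantile matching their target prevalence. Correlations are mild
#' (|r| <= 0.5) by design. The model is fixed: repeated calls return the
#' identical object.
#'
#' @return an object of class `covariate_model`: a list with `names`
#'   (10 labels), `mean` (10-vector), `covariance` (10x10 positive
#'   definite), and `binary_prevalence` (5-vector, variables 6-10).
#' @export
default_covariate_model <- function() {
  nm <- c("age", "sbp", "heart_rate", "hemoglobin", "cholesterol",
          "female", "angina", "diabetes", "prev_ami", "smoker")
  mu <- c(65, 145, 80, 140, 4.8, 0, 0, 0, 0, 0)
  sd <- c(12, 25, 18, 18, 1.1, 1, 1, 1, 1, 1)
  R <- diag(10)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("age", "sbp", 0.20)
  set_r("age", "hemoglobin", -0.20)
  set_r("age", "cholesterol", -0.10)
  set_r("age", "female", 0.15)
  set_r("age", "prev_ami", 0.15)
  set_r("age", "smoker", -0.30)
  set_r("sbp", "heart_rate", 0.15)
  set_r("sbp", "diabetes", 0.10)
  set_r("heart_rate", "hemoglobin", -0.10)
  set_r("hemoglobin", "female", -0.30)
  set_r("hemoglobin", "diabetes", -0.15)
  set_r("cholesterol", "smoker", 0.10)
  set_r("female", "smoker", -0.15)
  set_r("diabetes", "prev_ami", 0.15)
  Sigma <- diag(sd) %*% R %*% diag(sd)
  dimnames(Sigma) <- list(nm, nm)
  out <- list(
    names = nm,
    mean = stats::setNames(mu, nm),
    covariance = Sigma,
    binary_prevalence = stats::setNames(
      c(0.35, 0.25, 0.22, 0.15, 0.30), nm[6:10])
  )
  class(out) <- "covariate_model"
  out
}

#' Generating log-hazard-ratio vectors for the three cause-specific models
#'
#' Coefficients of the three multivariable cause-specific hazard models
#' (cardiovascular, cancer, other-cause mortality) used to generate
#' outcomes, in the order of [default_covariate_model()] names.
#'
#' @return an object of class `coefficient_set`: list of three named
#'   10-vectors `beta_cvd`, `beta_cancer`, `beta_other`.
#' @export
default_coefficients <- function() {
  nm <- default_covariate_model()$names
  b <- list(
    beta_cvd = c(0.075, -0.007, 0.009, -0.008, -0.051,
                 -0.045, 0.147, 0.297, 0.398, 0.226),
    beta_cancer = c(0.062, -0.001, 0.007, -0.016, -0.042,
                    -0.343, -0.203, 0.057, 0.0154, 0.584),
    beta_other = c(0.077, -0.004, 0.009, -0.016, -0.073,
                   -0.122, -0.038, 0.893, 0.297, 0.308)
  )
  out <- lapply(b, stats::setNames, nm)
  class(out) <- "coefficient_set"
  out
}

#' Coefficient set as a 10 x 3 matrix
#'
#' @param betas a `coefficient_set`.
#' @return matrix with rows = covariates, columns = causes 1..3.
#' @export
coef_matrix <- function(betas = default_coefficients()) {
  m <- cbind(betas$beta_cvd, betas$beta_cancer, betas$beta_other)
  colnames(m) <- c("cvd", "cancer", "other")
  m
}

validate_covariate_model <- function(model) {
  stopifnot(length(model$names) == 10, length(model$mean) == 10,
            all(dim(model$covariance) == c(10, 10)),
            length(model$binary_prevalence) == 5)
  if (any(model$binary_prevalence <= 0 | model$binary_prevalence >= 1))
    stop("binary prevalences must lie strictly inside (0, 1)")
  S <- model$covariance
  if (max(abs(S - t(S))) > 1e-8)
    stop("covariance matrix is not symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "covariance matrix is not positive definite (smallest eigenvalue %.3g)",
      min(ev)))
  invisible(model)
}

#' Generate a covariate table from a covariate model
#'
#' Draws `n` rows from the 10-dimensional multivariate normal and
#' dichotomizes variables 6-10 at the analytic marginal quantile
#' `mean_j + sd_j * qnorm(1 - prevalence_j)` (values strictly above the
#' threshold become 1), so that the expected prevalence equals the target
#' regardless of `n`.
#'
#' @param model a `covariate_model`.
#' @param n number of rows (>= 1).
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible.
#' @return data.frame of 10 columns named as `model$names`; columns 1-5
#'   continuous, columns 6-10 in \{0, 1\}.
#' @export
generate_covariates <- function(model = default_covariate_model(), n,
                                seed = NULL) {
  stopifnot(n >= 1)
  validate_covariate_model(model)
  if (!is.null(seed)) set.seed(seed)
  X <- MASS::mvrnorm(n, mu = model$mean, Sigma = model$covariance)
  if (n == 1) X <- matrix(X, nrow = 1)
  colnames(X) <- model$names
  sds <- sqrt(diag(model$covariance))
  for (j in 6:10) {
    prev <- model$binary_prevalence[[j - 5L]]
    thr <- model$mean[[j]] + sds[j] * stats::qnorm(1 - prev)
    X[, j] <- as.numeric(X[, j] > thr)
  }
  as.data.frame(X)
}
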