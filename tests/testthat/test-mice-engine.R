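test_that("PMM copies observed donor values", {
  set.seed(41)
  # widely separated predicted means: the duplicate row is the certain
  # nearest donor with k = 1
  x <- c(0, 100, 200, 100)
  y <- c(1.5, 7.2, 13.9, NA)
  out <- impute_pmm(y, matrix(x), donors = 1L)
  expect_equal(out[4], 7.2)
  expect_equal(out[1:3], y[1:3])
  # binary target stays binary, whatever the linear predictions do
  set.seed(42)
  xb <- rnorm(200)
  yb <- rbinom(200, 1, plogis(xb))
  yb[sample(200, 50)] <- NA
  imp <- impute_pmm(yb, matrix(xb), donors = 5L)
  expect_true(all(imp %in% 0:1))
  # nothing to do -> unchanged
  expect_identical(impute_pmm(yb[!is.na(yb)], matrix(xb[!is.na(yb)])),
                   yb[!is.na(yb)])
})

test_that("PMM imputations stay within the observed range", {
  set.seed(43)
  for (rep in 1:20) {
    n <- 120
    X <- matrix(rnorm(n * 3), n, 3)
    y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n)
    y[sample(n, 35)] <- NA
    imp <- impute_pmm(y, X, donors = sample(1:10, 1))
    obs <- y[!is.na(y)]
    expect_true(all(imp >= min(obs) & imp <= max(obs)))
    expect_true(all(imp[!is.na(y)] == obs))
  }
})

test_that("PMM diagnoses rank problems", {
  set.seed(44)
  X <- cbind(rnorm(30), rnorm(30))
  X <- cbind(X, X[, 1] + X[, 2])          # exactly collinear
  y <- rnorm(30)
  y[1:5] <- NA
  expect_warning(impute_pmm(y, X), "aliased")
  yshort <- c(rnorm(3), rep(NA, 27))
  expect_error(suppressWarnings(impute_pmm(yshort, X)), "observed rows")
})

test_that("chained imputation preserves observed data and is
          reproducible", {
  pp <- make_population(n = 1500, seed = 45, p_missing = 0.4)
  samp <- pp$amputed[1:600, ]
  st <- mice_pmm(samp, "all_causes", M = 3, cycles = 2, seed = 46)
  expect_s3_class(st, "imputed_stack")
  expect_length(st$datasets, 3)
  for (d in st$datasets) {
    expect_false(anyNA(d))
    # observed cells bit-identical to the input
    for (v in amputable_variables()) {
      obs <- !is.na(samp[[v]])
      expect_identical(d[[v]][obs], samp[[v]][obs])
    }
  }
  # binary variables stay binary after imputation
  for (v in c("angina", "diabetes", "prev_ami", "smoker"))
    expect_true(all(st$datasets[[1]][[v]] %in% 0:1))
  st2 <- mice_pmm(samp, "all_causes", M = 3, cycles = 2, seed = 46)
  expect_identical(st$datasets, st2$datasets)
  # between-imputation variation exists where data were missing
  v <- "cholesterol"
  mis <- is.na(samp[[v]])
  imps <- sapply(st$datasets, function(d) d[[v]][mis])
  expect_gt(mean(apply(imps, 1, stats::var)), 0)
})

test_that("complete data yield M identical copies", {
  pp <- make_population(n = 400, seed = 47)
  st <- mice_pmm(pp$data, "primary_only", M = 2, cycles = 2, seed = 48)
  expect_identical(st$datasets[[1]], pp$data)
  expect_identical(st$datasets[[2]], pp$data)
})

test_that("imputation beats complete case under outcome-dependent MAR", {
  # linear substantive model y = x1 + x2 + e with x1 missing at random
  # given y: complete-case selection on the outcome biases the x1
  # coefficient, while PMM imputation using (x2, y) removes most of it
  set.seed(49)
  R <- 200
  n <- 2000
  bias_mi <- bias_cc <- numeric(R)
  for (r in seq_len(R)) {
    x2 <- rnorm(n)
    x1 <- 0.3 * x2 + rnorm(n)
    y <- x1 + x2 + rnorm(n)
    x1m <- ifelse(runif(n) < plogis(1.5 * y), NA, x1)
    cc <- !is.na(x1m)
    bias_cc[r] <- coef(lm(y[cc] ~ x1m[cc] + x2[cc]))[2] - 1
    est <- vapply(1:5, function(m) {
      xi <- impute_pmm(x1m, cbind(x2, y), donors = 5)
      coef(lm(y ~ xi + x2))[2]
    }, numeric(1))
    bias_mi[r] <- mean(est) - 1
  }
  expect_lt(abs(mean(bias_mi)), abs(mean(bias_cc)))
  expect_gt(abs(mean(bias_cc)), 0.05)   # selection really does bias CC
})
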