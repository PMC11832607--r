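#' Names of the amputable covariates
#'
#' All covariates except age and sex (female) can be set missing;
#' event time and event type are never missing.
#'
#' @return character vector of 8 names.
#' @export
amputable_variables <- function() {
  c("sbp", "heart_rate", "hemoglobin", "cholesterol",
    "angina", "diabetes", "prev_ami", "smoker")
}

#' Canonical synthetic missing-data pattern library
#'
#' A deterministic library of 67 missingness patterns over the 8
#' amputable covariates, emulating the pattern structure of a large
#' registry cohort in which cholesterol is by far the most frequently
#' missing variable, current smoking status is a distant second, and the
#' remaining six variables are missing only occasionally. Patterns are
#' the 8 single-variable masks, all 28 pairs, the 21 triples containing
#' cholesterol, and the first 10 (in combination order) quadruples
#' containing both cholesterol and smoker. Each pattern's relative
#' frequency is the product of the marginal missingness targets of its
#' masked variables plus a small floor (0.001), normalized to sum to 1;
#' the floor keeps every pattern realizable in moderate samples while
#' preserving the marginal ranking.
#'
#' @return an object of class `pattern_library`: list with `patterns`
#'   (67 x 8 binary matrix, 1 = set missing; columns named as
#'   [amputable_variables()]) and `frequencies` (length-67, sums to 1).
#' @export
default_pattern_library <- function() {
  vars <- amputable_variables()
  marg <- c(sbp = 0.009, heart_rate = 0.012, hemoglobin = 0.012,
            cholesterol = 0.405, angina = 0.014, diabetes = 0.004,
            prev_ami = 0.016, smoker = 0.134)
  mask_from <- function(idx) {
    m <- integer(8)
    m[idx] <- 1L
    m
  }
  masks <- lapply(1:8, mask_from)
  pairs <- utils::combn(8, 2, simplify = FALSE)
  masks <- c(masks, lapply(pairs, mask_from))
  chol <- match("cholesterol", vars)
  smk <- match("smoker", vars)
  others <- setdiff(1:8, chol)
  triples <- utils::combn(others, 2, simplify = FALSE)
  masks <- c(masks, lapply(triples, function(p) mask_from(c(chol, p))))
  rest <- setdiff(1:8, c(chol, smk))
  quads <- utils::combn(rest, 2, simplify = FALSE)[1:10]
  masks <- c(masks, lapply(quads, function(p) mask_from(c(chol, smk, p))))
  P <- do.call(rbind, masks)
  colnames(P) <- vars
  w <- apply(P, 1, function(m) prod(marg[m == 1])) + 0.001
  out <- list(patterns = P, frequencies = w / sum(w))
  class(out) <- "pattern_library"
  out
}

#' Implied marginal missingness shares of a pattern library
#'
#' For each amputable variable, the probability that an incomplete
#' record is missing that variable: the frequency-weighted sum of the
#' masks. Multiplying by the overall incomplete proportion gives the
#' expected marginal missingness of each variable.
#'
#' @param lib a `pattern_library`.
#' @return named numeric vector over the 8 amputable variables.
#' @export
pattern_marginals <- function(lib = default_pattern_library()) {
  drop(crossprod(lib$patterns, lib$frequencies))[, drop = TRUE]
}

validate_pattern_library <- function(lib) {
  P <- lib$patterns
  f <- lib$frequencies
  stopifnot(is.matrix(P), ncol(P) == 8, length(f) == nrow(P))
  if (any(rowSums(P) == 0)) stop("pattern library contains an all-zero mask")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("pattern frequencies must be nonnegative and sum to 1")
  invisible(lib)
}

#' MAR missingness mechanism specification
#'
#' Per-pattern predictor weights for the weighted-sum score driving
#' missingness: equal weights on the standardized covariates that the
#' pattern leaves observed (for a single-variable pattern, the nine
#' other covariates), zero weight on the amputed variables themselves
#' and on the outcome (time and event never enter the score, making the
#' mechanism MAR with missingness unrelated to the outcome).
#'
#' @param lib a `pattern_library`.
#' @param covariate_names the 10 covariate names.
#' @return matrix (patterns x 10 covariates) of score weights, rows
#'   summing to 1.
#' @export
mar_mechanism <- function(lib = default_pattern_library(),
                          covariate_names = default_covariate_model()$names) {
  validate_pattern_library(lib)
  W <- matrix(1, nrow(lib$patterns), length(covariate_names),
              dimnames = list(NULL, covariate_names))
  W[, colnames(lib$patterns)] <- 1 - lib$patterns
  sweep(W, 1, rowSums(W), `/`)
}

#' Induce calibrated multi-pattern MAR missingness
#'
#' Every record is assigned to a candidate pattern with probabilities
#' equal to the library frequencies. A record actually becomes
#' incomplete with probability `plogis(a + s)`, where `s` is its
#' standardized weighted-sum score (equal weights on the covariates its
#' pattern leaves observed, z-scored columns) and the intercept `a` is
#' calibrated by bisection — against a fixed vector of per-record
#' uniforms, so the objective is deterministic and monotone — until the
#' realized incomplete fraction matches `p_missing` within `tol`.
#' Higher scores mean higher missingness probability (a "RIGHT"-type
#' mechanism). Cells flagged by the record's pattern are then set to NA.
#' Time, event, age and sex are never amputed, and the outcome carries
#' no weight in the score, so the mechanism is MAR by construction.
#'
#' @param data complete data.frame with the 10 covariates (and possibly
#'   `time`/`event` columns, which are left untouched).
#' @param lib a `pattern_library`.
#' @param p_missing target incomplete-record proportion in `[0, 1)`.
#' @param seed optional integer seed.
#' @param tol calibration tolerance on the incomplete fraction.
#' @return the data.frame with NA cells; attribute `ampute_info` records
#'   the intercept, realized fraction, and per-record pattern index
#'   (NA for records left complete).
#' @export
ampute_mar <- function(data, lib = default_pattern_library(), p_missing,
                       seed = NULL, tol = 0.002) {
  validate_pattern_library(lib)
  stopifnot(p_missing >= 0, p_missing < 1)
  if (anyNA(data)) stop("input data must be complete")
  if (p_missing == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  vars <- colnames(lib$patterns)
  cov_names <- setdiff(names(data), c("time", "event"))
  if (!all(vars %in% cov_names))
    stop("pattern library names variables absent from the data")
  Z <- scale(as.matrix(data[cov_names]))
  W <- mar_mechanism(lib, cov_names)
  pat <- sample.int(nrow(lib$patterns), n, replace = TRUE,
                    prob = lib$frequencies)
  score_all <- Z %*% t(W)                 # n x patterns
  score <- score_all[cbind(seq_len(n), pat)]
  score <- as.numeric(scale(score))
  u <- stats::runif(n)
  frac <- function(a) mean(u < stats::plogis(a + score))
  lo <- -30; hi <- 30
  if (frac(lo) > p_missing || frac(hi) < p_missing)
    stop(sprintf("p_missing %.3f unattainable (range [%.4f, %.4f])",
                 p_missing, frac(lo), frac(hi)))
  a <- 0
  for (it in 1:200) {
    a <- (lo + hi) / 2
    fa <- frac(a)
    if (abs(fa - p_missing) <= tol) break
    if (fa < p_missing) lo <- a else hi <- a
  }
  if (abs(frac(a) - p_missing) > tol)
    stop(sprintf("intercept calibration failed: realized %.4f, target %.3f",
                 frac(a), p_missing))
  incomplete <- u < stats::plogis(a + score)
  out <- data
  for (j in seq_along(vars)) {
    hit <- incomplete & lib$patterns[pat, j] == 1
    out[[vars[j]]][hit] <- NA
  }
  attr(out, "ampute_info") <- list(
    intercept = a, realized = mean(incomplete),
    pattern = ifelse(incomplete, pat, NA_integer_))
  out
}
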