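#' Cause-specific Nelson-Aalen cumulative hazard
#'
#' The nonparametric estimator
#' \eqn{H_k(t) = \sum_{s \le t} d_k(s)/n(s)}, where \eqn{d_k(s)} counts
#' cause-k events at distinct time s and \eqn{n(s)} is the number at
#' risk at s. Ties are handled by aggregating at distinct times.
#'
#' @param time positive observed times.
#' @param event integer event codes 0 (censored), 1, 2, 3.
#' @param cause the cause k whose hazard is estimated.
#' @param eval_times times at which to evaluate the step function;
#'   defaults to each record's own observed time.
#' @return numeric vector of H_k at `eval_times`.
#' @export
cause_specific_cumhaz <- function(time, event, cause, eval_times = time) {
  n <- length(time)
  if (n == 0) stop("empty input")
  stopifnot(length(event) == n, all(time > 0), all(event %in% 0:3))
  ut <- sort(unique(time))
  counts <- tabulate(match(time, ut), length(ut))
  nrisk <- rev(cumsum(rev(counts)))
  dk <- tabulate(match(time[event == cause], ut), length(ut))
  H <- cumsum(dk / nrisk)
  idx <- findInterval(eval_times, ut)
  c(0, H)[idx + 1L]
}

#' Outcome-derived imputation features
#'
#' Per-record cause-specific cumulative hazards \eqn{H_k(T_i)} (the
#' Nelson-Aalen estimate evaluated at the record's own observed time)
#' and the three event-type indicators. Time and event are never
#' missing, so these features are always complete, and they depend only
#' on the outcome — they are invariant to covariate imputation.
#'
#' @param time,event observed time and event code vectors.
#' @return data.frame with columns H1, H2, H3, d1, d2, d3.
#' @export
hazard_features <- function(time, event) {
  out <- data.frame(
    H1 = cause_specific_cumhaz(time, event, 1L),
    H2 = cause_specific_cumhaz(time, event, 2L),
    H3 = cause_specific_cumhaz(time, event, 3L),
    d1 = as.numeric(event == 1L),
    d2 = as.numeric(event == 2L),
    d3 = as.numeric(event == 3L)
  )
  out
}

#' Imputation predictor matrix for one target variable
#'
#' Builds the design used to impute one covariate. Strategy
#' `"all_causes"` uses the nine other covariates, the three
#' cause-specific cumulative hazards with their event indicators, and
#' the 27 hazard-by-covariate interactions (42 columns). Strategy
#' `"primary_only"` uses the nine other covariates, the cardiovascular
#' cumulative hazard and its event indicator, and the 9 interactions of
#' that hazard with the other covariates (20 columns). Interaction
#' columns are plain products recomputed from the covariate values in
#' `data`, so inside chained equations they reflect the current
#' imputations.
#'
#' @param data data.frame holding the current (possibly imputed)
#'   covariate values.
#' @param features a [hazard_features()] data.frame aligned with `data`.
#' @param target name of the variable being imputed.
#' @param strategy `"all_causes"` or `"primary_only"`.
#' @param covariate_names names of the 10 analysis covariates.
#' @return numeric matrix (no intercept column).
#' @export
imputation_predictors <- function(data, features, target,
                                  strategy = c("all_causes", "primary_only"),
                                  covariate_names =
                                    default_covariate_model()$names) {
  strategy <- match.arg(strategy)
  others <- setdiff(covariate_names, target)
  Xo <- as.matrix(data[others])
  hz <- switch(strategy, all_causes = c("H1", "H2", "H3"),
               primary_only = "H1")
  ind <- switch(strategy, all_causes = c("d1", "d2", "d3"),
                primary_only = "d1")
  Hm <- as.matrix(features[hz])
  inter <- do.call(cbind, lapply(hz, function(h) {
    m <- Xo * features[[h]]
    colnames(m) <- paste(h, others, sep = ".")
    m
  }))
  cbind(Xo, Hm, as.matrix(features[ind]), inter)
}
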