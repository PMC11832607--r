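# crimpsim

Monte Carlo evaluation of multiple-imputation strategies for missing
covariates when the analysis model is a **cause-specific Cox model with
competing risks**.

Applied survival analyses routinely face both problems at once: subjects
can die of the cause under study (here cardiovascular disease) or of a
competing cause (cancer, other), and several covariates are incomplete.
Multiple imputation then has to decide *how the outcome enters the
imputation models*. With competing risks the outcome has several
components — the cause-specific cumulative hazards
H̃ₖ(Tᵢ) at the observed time and the event-type indicators — and the
candidate strategies differ in which of them they use:

| method | imputation model for each incomplete covariate |
|---|---|
| `mice_all` | PMM on the 9 other covariates + all three Nelson–Aalen cause-specific cumulative hazards, their event indicators, and the 27 hazard×covariate interactions |
| `mice_primary` | PMM on the 9 other covariates + the cardiovascular hazard, its indicator, and its 9 interactions |
| `smcfcs` | rejection sampling of covariate-model proposals against the joint likelihood ∏ₖ (e^{xβₖ})^{I(D=k)} exp(−H₀ₖ(T) e^{xβₖ}) of all three cause-specific Cox models |
| `complete_case` | drop incomplete records |
| `no_missing` | the same sampled records before amputation (reference) |

The package provides the whole pipeline as tested, reusable functions:

* `build_superpopulation()` — covariates from a fixed synthetic
  multivariate-normal model with analytic-quantile dichotomization;
  event times by inversion from three cause-specific exponential
  hazards, T = −log(u)/Σₖ λₖe^{xβₖ}; event types with probabilities
  λₖe^{xβₖ}/Σⱼλⱼe^{xβⱼ}; exponential censoring calibrated by bisection
  to 25%; "true" coefficients fit on the full super-population.
* `ampute_mar()` — 67-pattern MAR amputation with equal standardized
  weights, intercept-calibrated to the target incomplete fraction.
* `mice_pmm()`, `smcfcs_cr()` — the two imputation engines.
* `pool_cause_specific()` / `pool_rubin()` — Rubin's rules with
  Barnard–Rubin small-sample degrees of freedom.
* `run_scenario()` / `run_grid()` — replicates, metrics (relative bias,
  CI coverage, mean SE, Monte Carlo SEs), and the resumable 30-scenario
  factorial grid. A thin CLI lives at `inst/cli/crimpsim.R`.

## Worked example

```r
library(crimpsim)
cfg <- scenario_config(rates = c(1, 1, 1), p_missing = 0.5,
                       n_super = 1e5, n_sample = 1000, n_reps = 100,
                       M = 5, seed = 1)
sc  <- run_scenario(cfg, cycles = 5)
subset(sc$metrics, cause == 1 & variable == "cholesterol",
       c(method, relative_bias, coverage, mean_se))
```

```
        method relative_bias coverage    mean_se
 complete_case     1.2471988       94 0.06730944
      mice_all     4.1600299       96 0.05854504
  mice_primary     0.3659198       97 0.05817194
    no_missing    -0.7278336       96 0.04599676
        smcfcs    10.0280857       95 0.05859893
```

Cholesterol is the covariate with by far the most missingness (about
69% of incomplete records). Relative bias is 100·(mean estimate −
truth)/truth with truth taken from the super-population fit; coverage
is the percentage of 95% intervals containing the truth across the 100
replicates. At this scale all methods keep nominal coverage, the
relative-bias differences are within Monte Carlo error (the MC standard
error of relative bias here is about 10 percentage points — the true
log-hazard ratio is small), and the precision ordering is the
informative part: complete case pays the largest standard-error price
for discarding half the records, while the three imputation strategies
sit between the no-missing reference and complete case. Separating the
strategies' biases needs the full 1000-replicate design.

The methods vignette (`vignettes/competing-risks-imputation.Rmd`)
documents the data-generating process, the missingness mechanism, both
imputation engines, and all numerical choices.

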