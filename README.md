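# scalemiss

Benchmarking strategies for handling missing items in psychometric
questionnaires.

## The problem

Mental-health and quality-of-life instruments (self-esteem, self-acceptance,
activities-of-daily-living scales, ...) score a respondent by summing a set
of ordinal Likert items. A single skipped item invalidates the whole total
score, so even modest *item* nonresponse silently removes a large share of
*respondents*: at a cell-level missingness rate r over k independent items,
only about (1 − r)^k of respondents remain complete — roughly 11% at
r = 20%, k = 10. Analysts then face a choice between complete-case
deletion, single imputation (mode, hot-deck) and multiple imputation, and
the choice materially changes the estimated means, variabilities,
group comparisons and regression coefficients.

`scalemiss` turns that comparison into a controlled, reproducible
experiment:

1. **Generate** a synthetic survey population from an ordinal-threshold
   (graded probit) latent-trait model, with categorical/continuous
   covariates that load on the trait.
2. **Ampute** it under MCAR or a covariate-driven MAR mechanism whose
   logistic intercept is calibrated by bisection so the realized cell-level
   missingness hits a target rate (5, 10, 15, 20%, ...) exactly.
3. **Impute** with four strategies: complete-case deletion, per-item mode
   (smallest-value tie-break), random hot-deck within donor classes, and
   multiple imputation by chained equations with predictive mean matching
   (OLS conditional models with proper posterior draws; every imputed value
   is an observed donor value, hence in range).
4. **Evaluate** each strategy's recovery of the total-score mean, SD and a
   correlation coefficient over replicated experiments, with three error
   summaries for statistic y after imputation method j in replication i
   against its complete-data value:

   - absolute deviation `|y_ij − y_i0|`
   - root mean square error `RMSE = sqrt( Σ_i (y_ij − y_i0)² / n )`
   - average relative error `Σ_i ((y_i0 − y_ij) / y_i0) / n` (signed)

5. **Validate downstream**: group t/F tests of the total score and a
   logistic regression on the dichotomized score (total ≥ cutoff), run
   identically on complete and imputed data. Multiply imputed analyses are
   pooled by Rubin's rules: point `q̄ = mean(q)`, within-variance
   `ū = mean(u)`, between-variance `B = var(q)`, total
   `T = ū + (1 + 1/m)·B`, with small-sample degrees of freedom.

Three built-in populations (`rses_population()`, `saq_population()`,
`adl_population()`) emulate the structure of a middle-school self-esteem
survey (10 items scored 1–4, total dichotomized at 30, total-score
distribution calibrated to mean ≈ 28.2, SD ≈ 4.6), a college
self-acceptance survey (16 items) and an elderly daily-living survey
(14 items).

## Worked example

```r
library(scalemiss)

pop <- rses_population()
d <- generate_survey(pop$scale, pop$covariates, pop$items, n = 1000, seed = 42)
round(c(mean = mean(total_score(d)), sd = sd(total_score(d))), 2)
#>  mean    sd
#> 28.27  4.86

plan <- missingness_plan("MAR", 0.20, drivers = c(gender = 1.0, age = 0.5),
                         seed = 42)
amp <- ampute(d, plan, cov_specs = pop$covariates)
amp
#> <amputed_data> RSES-like: 1000 x 10 cells, MAR target 0.2,
#>   realized 0.2047 (complete cases 0.172)

mi <- impute_mi(amp, m = 20, n_iter = 10, seed = 42)
round(summary_statistics(mi), 3)
#>   mean     sd   corr
#> 28.285  4.864  0.030
round(summary_statistics(complete_case(amp)), 3)
#>   mean     sd   corr
#> 27.965  4.908  0.068
```

At a 20% MAR rate, only 17% of respondents are complete; multiple
imputation recovers the complete-data mean (28.27) to 0.015 while deletion
is off by 0.31 — missingness here is driven by gender and age, which also
predict the score, so the complete cases are a biased subsample.

The replicated benchmark makes that systematic:

```r
cfg <- run_config("saq", n_reps = 10, mi_m = 5, mi_iter = 5, master_seed = 1)
bench <- run_benchmark(cfg)
summary(bench, "mean")
#> Absolute deviation / RMSE of the total-score mean
#>    method rate statistic abs_dev_mean abs_dev_sd    rmse avg_rel_error  n
#>  deletion 0.05      mean      0.66473    0.40794 0.76919    -0.0142846 10
#>   hotdeck 0.05      mean      0.04690    0.04007 0.06037    -0.0005908 10
#>        mi 0.05      mean      0.02431    0.01660 0.02897    -0.0003846 10
#>      mode 0.05      mean      0.12588    0.03602 0.13043    -0.0027050 10
#>  ...
#>  deletion 0.20      mean      1.01111    0.90733 1.32788    -0.0025782 10
#>   hotdeck 0.20      mean      0.05512    0.05312 0.07469     0.0006516 10
#>        mi 0.20      mean      0.05469    0.04329 0.06839     0.0003539 10
#>      mode 0.20      mean      0.41132    0.09953 0.42202    -0.0088389 10
```

Deletion's error is an order of magnitude above hot-deck's and MI's and
grows with the rate; `plot(bench, "mean")` draws the RMSE-vs-rate curves,
and `summary(bench, "sd")` shows mode imputation's characteristic variance
shrinkage.

`run_simulation_tier(cfg, out_dir)` and `run_validation_tier(cfg, out_dir)`
run the two experiment tiers end to end and write `benchmark.csv`,
`evaluation_table.csv`, the group-test and odds-ratio comparison tables,
a YAML config and a checksummed manifest; `recompute_metrics()` re-derives
the evaluation table from stored records.

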