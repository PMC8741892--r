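# curemix

Mixture cure survival regression for cohorts in which a fraction of
patients will never experience the event. The motivating application is
distant metastasis-free survival (DMFS) in early-stage ER-positive breast
cancer: most tamoxifen-treated patients never develop a distant
metastasis, so an overall survival curve plateaus and a Cox model — which
implicitly assumes everyone is at risk forever — is the wrong tool. The
package is aimed at biostatisticians and computational biologists who want
to (i) estimate a cured fraction jointly with the event-time distribution
of the susceptible patients, (ii) dichotomize a continuous biomarker (for
example a gene's log2 expression) at the cutoff that best separates
survival, and (iii) run the accompanying expression-side group
comparisons.

## The model

Let `T` be the time in years from surgery to the event and `D` the latent
susceptibility indicator (`D = 1`: the patient will eventually experience
the event). For a covariate vector `Z`,

    Pr(T > t | Z) = Pr(D = 1 | Z) · Pr(T > t | D = 1, Z) + Pr(D = 0 | Z)

with a logistic submodel for susceptibility,

    logit Pr(D = 1 | Z) = β′Z,

and an accelerated failure time (AFT) location-scale submodel for the
susceptible event times,

    ln T = γ′Z + exp(α′Z) · ε,   ε ~ standard logistic,

so `T | D = 1` is log-logistic with median `exp(γ′Z)`. The cured fraction
is `Pr(D = 0 | Z) = 1/(1 + exp(β′Z))`. All of β, γ, α are estimated
jointly by maximum likelihood under right censoring (a censored patient
either has a later event or is cured). Inference is by Wald tests and
intervals from the inverse observed information, and by likelihood ratio
tests between nested placements of a covariate; competing placements of a
group covariate across the three regression parts are ranked by AIC.
Kaplan–Meier machinery is included for the nonparametric side: the overall
product-limit curve, and a probability-weighted conditional curve in which
each censored patient contributes their posterior probability of being
susceptible to the risk set, estimating the susceptible-only survival
curve.

## Worked example

Simulate a 359-patient cohort from the package's default generative
preset (cured fraction 0.672; susceptible medians 9.5 years for
low-expression and 3.4 years for high-expression patients; 15-year
follow-up window), then fit the mixture model with the high-expression
indicator in the location part:

```r
library(curemix)

cohort <- generate_cohort(cohort_config(n = 359, seed = 1))
fit <- cure_fit(cohort$records, cure_design(location = "high"), seed = 1)
fit
#> Logistic-AFT mixture cure model fit
#>   logistic: 1 | location: 1 + high | scale: 1
#>   n = 359 (55 events); logLik = -256.6456; AIC = 521.2912; converged: TRUE
#> # A tibble: 4 × 8
#>   part     term        estimate std.error statistic  p.value conf.low conf.high
#>   <chr>    <chr>          <dbl>     <dbl>     <dbl>    <dbl>    <dbl>     <dbl>
#> 1 logistic (Intercept)   -0.500     0.339     -1.47 1.40e- 1   -1.16      0.165
#> 2 location (Intercept)    2.32      0.265      8.75 2.23e-18    1.80      2.83
#> 3 location high          -1.04      0.316     -3.29 1.02e- 3   -1.66     -0.419
#> 4 scale    (Intercept)   -0.517     0.150     -3.45 5.67e- 4   -0.811    -0.223

likelihood_ratio_test(fit, cure_fit(cohort$records, cure_design(), seed = 1))
#> # A tibble: 1 × 3
#>   statistic    df p.value
#>       <dbl> <int>   <dbl>
#> 1      8.18     1 0.00423

predict(fit, data.frame(high = 0:1), type = "median")
#> # A tibble: 2 × 2
#>   profile median_years
#>     <int>        <dbl>
#> 1       1        10.1
#> 2       2         3.58
```

Reading the output: the logistic intercept −0.500 implies a fitted cured
fraction of `1/(1 + exp(−0.500)) ≈ 0.62` shared by both expression groups;
the negative location effect −1.04 means high-expression susceptible
patients metastasize earlier (median 3.6 vs 10.1 years); the LRT confirms
the expression group improves on the covariate-free model. True values in
this simulation were 0.672, 9.48 and 3.41 years.

Other entry points: `cutoff_scan()` dichotomizes a biomarker at each of
its nine deciles and selects the best-fitting cutoff by AIC with
Bonferroni-adjusted LRT p-values; `km_overall()` / `km_conditional()` plus
`susceptibility_weights()` produce the nonparametric curves
(`autoplot()`-able); `define_outcome_groups()`, `wilcoxon_rank_sum()`,
`kruskal_wallis()` and `fisher_exact_2x2()` cover the expression-side
comparisons; `read_survival_csv()` and friends handle the on-disk
formats. See the vignette in `vignettes/` for the methodology.

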