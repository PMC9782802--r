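# lifetabler

Age-stage, two-sex life table analysis for insect cohort bioassays, with
bootstrap inference and probit dose–response, in tidyverse-native R.

Insecticide and growth-regulator bioassays follow individually reared
insects day by day — stage occupied, survival, eggs laid — and summarise the
population-level consequences of a treatment through demographic parameters:
the net reproductive rate, the intrinsic rate of increase, the finite rate,
and the mean generation time. `lifetabler` implements that workflow for
individual-by-day cohort records of both sexes and all developmental stages
(the age-stage, two-sex framework), plus the companion probit analysis of
dose–mortality data.

From the age-stage survival matrix *S<sub>xj</sub>* (proportion of the
initial cohort alive in stage *j* at age *x* days) and fecundity matrix
*f<sub>xj</sub>* (mean eggs per stage-*j* individual at age *x*):

- *l<sub>x</sub>* = Σ<sub>j</sub> *S<sub>xj</sub>*,
  *m<sub>x</sub>* = Σ<sub>j</sub> *S<sub>xj</sub> f<sub>xj</sub>* / Σ<sub>j</sub> *S<sub>xj</sub>*
- *R*<sub>0</sub> = Σ<sub>x</sub> *l<sub>x</sub> m<sub>x</sub>*,
  GRR = Σ<sub>x</sub> *m<sub>x</sub>*
- *r* solves Σ<sub>x</sub> e<sup>−r(x+1)</sup> *l<sub>x</sub> m<sub>x</sub>* = 1
  (Euler–Lotka, bisection to residual 1e−10)
- λ = e<sup>r</sup>, *T* = ln *R*<sub>0</sub> / *r*, plus APOP/TPOP
  pre-oviposition periods

Uncertainty comes from bootstrap resampling of individuals (SEs, percentile
CIs, group comparisons). The probit module fits
P(dead) = Φ(α + β log₁₀ dose) by maximum likelihood and reports LC50/LC90
with 95% fiducial limits via Fieller's theorem, heterogeneity-adjusted. A
stage-structured cohort simulator with *exact* expected schedules
(`expected_schedules()`) provides ground truth for parameter-recovery
testing.

## Worked example

Simulate an untreated-like cohort of 60 larvae enrolled at the third instar,
fit the life table, and bootstrap the parameters:

```r
library(lifetabler)

cohort <- simulate_cohort(config_control_like(n = 60), seed = 2025)
fit <- lifetable(cohort)
fit
#> <lifetable_fit> treatment 'control', n = 60, ages 0-59
#>   R0      227.92
#>   GRR     433.79
#>   r       0.17
#>   lambda  1.18
#>   T       32.37
#>   APOP    3.00
#>   TPOP    30.12

boot <- bootstrap_lifetable(cohort, B = 2000, seed = 2026)
tidy(boot)
#> # A tibble: 7 × 6
#>   parameter estimate       se conf_low conf_high n_undefined
#>   <chr>        <dbl>    <dbl>    <dbl>     <dbl>       <dbl>
#> 1 R0         228.    38.1      159.      306.              0
#> 2 GRR        434.    56.2      323.      543.              0
#> 3 r            0.168  0.00609    0.154     0.178           0
#> 4 lambda       1.18   0.00720    1.17      1.20            0
#> 5 T           32.4    0.555     31.4      33.5             0
#> 6 APOP         3      0          3         3               0
#> 7 TPOP        30.1    0.546     29.1      31.2             0
```

Each row is one demographic parameter: 60 enrolled larvae produced on
average 228 eggs per enrolled individual (*R*<sub>0</sub>), the cohort grows
at 0.168/day (λ = 1.18, i.e. 18% per day) once stable, and a generation
spans about 32 days; the SE and 95% interval columns come from 2000
individual-level bootstrap replicates. With only 60 individuals the
reproductive rates are wide — exactly why the bootstrap matters.

Probit analysis of a dose–mortality table (60 exposed per dose):

```r
tab <- read.csv(system.file("extdata", "dose_mortality_example.csv",
                            package = "lifetabler"))
fit_probit(tab)
#> <probit_fit> 3 doses, n = 180
#>   slope 1.564 +/- 0.273, intercept -3.050
#>   chi2 = 0.011 on 1 df (p = 0.917), heterogeneity 1.00
#>   LC50 = 89.06 (59.85 - 119.6)
#>   LC90 = 587.4 (370.6 - 1385)
```

The slope is per log₁₀ dose unit; LC values inherit the dose unit of the
input, with Fieller fiducial limits in parentheses. `autoplot()` methods
draw the *l<sub>x</sub>*/*m<sub>x</sub>* curves, the fitted dose–response
curve, and bootstrap replicate distributions; `run_lifetable()` drives the
whole pipeline per treatment and writes estimates, endpoint summaries and
curve TSVs; `summarize_endpoints()` produces the stage-duration /
pupation / emergence / fecundity / fertility table.

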