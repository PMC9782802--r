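---
title: "Age-stage two-sex life tables: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stage two-sex life tables: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifetabler)
library(dplyr)
```

## The demographic model

`lifetabler` analyses insect rearing experiments in which a cohort of
individuals is observed daily from enrolment until death, recording the
developmental stage occupied each day and, for adult females, the number of
eggs laid. The framework is the age-stage, two-sex life table: rather than
following females only through age classes, it tracks every individual of
both sexes through an age-by-stage grid, which avoids the bias of
female-only tables when development time and survival differ between sexes
and stages.

From a validated cohort the package builds two matrices indexed by age `x`
(days since cohort entry, starting at 0) and stage `j`:

* `S[x, j]` — the proportion of the *initial* cohort alive and in stage `j`
  at age `x`;
* `f[x, j]` — the mean eggs laid at age `x` per individual then in stage `j`.

These collapse to the classical age schedules

$$l_x = \sum_j S_{xj}, \qquad
  m_x = \frac{\sum_j S_{xj} f_{xj}}{\sum_j S_{xj}},$$

with `m_x` defined as 0 at extinct ages (the denominator is zero there; the
convention keeps all downstream sums finite and corresponds to "no survivors
lay no eggs"). The demographic parameters are

* net reproductive rate $R_0 = \sum_x l_x m_x$;
* gross reproductive rate $GRR = \sum_x m_x$ (fecundity ignoring mortality,
  so $GRR \ge R_0$ always);
* intrinsic rate of increase $r$, the root of the discrete Euler–Lotka
  equation $\sum_x e^{-r(x+1)} l_x m_x = 1$;
* finite rate $\lambda = e^r$ and mean generation time $T = \ln(R_0)/r$;
* pre-oviposition periods APOP (adult emergence to first egg) and TPOP
  (cohort entry to first egg), averaged over reproducing females.

Because the matrices are built from raw counts, $R_0 \times N$ equals the
total number of eggs laid by the cohort *exactly* — an integer identity the
test suite asserts on every simulated cohort.

**Exponent convention.** The Euler–Lotka exponent is $e^{-r(x+1)}$ with ages
indexed from 0. This is the standard two-sex convention; the alternative
$e^{-rx}$ yields a different root (it effectively shifts every reproduction
event one day earlier) and is not offered, to avoid silently incomparable
results. A useful corollary used as a test oracle: if all net fecundity is
concentrated at a single age $a$, then $r = \ln(R_0)/(a+1)$ and $T = a+1$.

## Cohort records and their invariants

The on-disk format is a long CSV, one row per individual per day, with
columns `individual_id, treatment, dose_uM, day, stage, eggs`. Validation
enforces: days contiguous from 0, one stage per individual-day, entry stage
at day 0, forward-only stage transitions, eggs only on reproductive-stage
days, and a death label only as a terminal row. Ids are dataset-wide keys,
so cohorts of several treatments can live in one file.

Two conventions deserve emphasis:

* **Age origin.** Day 0 is cohort entry, not oviposition. The default stage
  list starts at the third larval instar because that is how such bioassays
  typically enrol; egg-start cohorts just use a different `stage_config()`.
* **Censoring.** An explicit death row distinguishes an observed death from
  a record that simply stops (escape, fungal kill, end of observation).
  Censored individuals are excluded from demographic computations with a
  warning — the conservative default given that a life table has no
  principled way to use a partially observed fecundity stream — or counted
  as deaths under `censored = "as_dead"`.

## Solving for the intrinsic rate

The Euler–Lotka left-hand side is strictly decreasing in `r` for any
non-negative schedule with positive mass, so the root is unique. It is found
by bisection from the bracket $[-1, 2]$ per day (far wider than any insect
growth rate), expanded geometrically if the residual does not change sign,
and iterated until the residual falls below `1e-10` (at most 200
iterations). `R0 = 1` returns `r = 0` exactly. A schedule with no
reproduction has no root and raises an error rather than returning a
sentinel. The test suite checks the solver against an independent fine-grid
scan of the residual (step `1e-7` near the root) on 100 random schedules.

All quantities are carried at full double precision; the two-decimal
rounding used in report tables happens only when writing the estimates TSV
(`digits` argument of `run_lifetable()`), never inside a computation.

## Bootstrap inference

Variance estimates resample *individuals* with replacement — the
exchangeable unit of the design; days within an individual are strongly
dependent and replicate jars are not recorded in the data format. Each
replicate rebuilds the schedules and recomputes every requested parameter.
The standard error is the SD of replicates and intervals are percentile
intervals. Replicates in which a parameter is undefined (e.g. a resample
with no reproducing female leaves `r` without a root) are recorded as `NA`,
counted, and excluded from the SE/CI; a comparison is refused when more than
half of either group's replicates are undefined.

The default is `B = 10000` replicates; published practice ranges up to
100,000, which this implementation supports (`R0`, APOP and TPOP are fully
vectorised; the Euler–Lotka parameters cost one bisection per replicate).
All resampling indices are drawn up-front from a single seeded stream, so a
result depends only on `(cohort, B, seed)` and not on evaluation order.

Group contrasts use the percentile-difference bootstrap: the difference of
point estimates, a percentile interval on paired replicate differences, and
the two-sided p-value `2 * min(P(d <= 0), P(d >= 0))`. Treating bootstrap
replicates as independent ANOVA observations — a convention that appears in
published tables with error degrees of freedom in the hundreds of thousands
— is deliberately *not* the default: it inflates the effective sample size
by a factor of `B` and produces astronomically significant F statistics for
any nonzero difference. It is available as `anova_on_replicates()` for
reproducing such table footnotes, and documented as anti-conservative.

## Probit dose–response

Mortality counts at each concentration are modelled as
$\mathrm{dead}_i \sim \mathrm{Binomial}(n_i, \Phi(\alpha + \beta \log_{10} d_i))$,
fitted by maximum likelihood (IRLS scoring via `stats::glm`; an independent
direct likelihood maximisation serves as a test oracle). The base-10 dose
metamer is used and the intercept is reported without the legacy +5 probit
offset. Goodness of fit is the Pearson chi-square on `#doses - 2` degrees of
freedom; when `chi2/df > 1` the coefficient covariance is scaled by the
heterogeneity factor `h = chi2/df` and fiducial limits switch from normal to
t critical values on `df` degrees of freedom — Finney's standard convention.

Lethal concentrations are $LC_p = 10^{(\Phi^{-1}(p) - \alpha)/\beta}$, with
95% fiducial limits from Fieller's theorem on the ratio
$(\Phi^{-1}(p) - \alpha)/\beta$. When $g = t^2\,\mathrm{var}(\beta)/\beta^2
\ge 1$ the interval is unbounded and reported as `NA` with `g` attached:
with three doses (`df = 1`) and any overdispersion this happens often, which
is exactly why published three-dose tables show enormous upper LC90 limits.
Useful identities: doses rescale equivariantly (multiplying all doses by `c`
multiplies every LC by `c` and changes nothing else), and any (LC50, LC90)
pair implies the slope via `implied_slope()` —
$\beta = \Phi^{-1}(0.9)/\log_{10}(LC_{90}/LC_{50})$ — which makes published
dose–response tables internally checkable even when the raw counts are not
printed.

Doses with 0% or 100% observed mortality are retained (the likelihood
handles them); only *complete* separation — every dose at 0% or 100% — is
rejected. No control-mortality correction is applied unless a control
mortality is supplied, in which case Abbott's correction is applied before
fitting.

## The synthetic cohort generator

`simulate_cohort()` draws individual life histories from an explicit
generative model: per-stage durations (shifted negative binomial, truncated
to finite support, or fixed), one survival Bernoulli per individual-day,
metamorphosis completion probabilities at the larva-to-pupa and
pupa-to-adult transitions, sex assignment at eclosion, sex-specific adult
daily survival with a hard lifespan cap, and daily egg counts that are
Poisson (optionally negative binomial) around a lognormal-shaped
fecundity-age curve — zero during the pre-oviposition period, rising to a
peak and decaying with a right tail, the shape empirical oviposition curves
show.

Its companion `expected_schedules()` propagates the same semi-Markov chain
*analytically* (discrete convolutions over the finite duration supports),
giving the exact `lx`, `mx`, $R_0$, $GRR$, $r$, $T$ and expected
pre-oviposition periods implied by a configuration. This is what makes the
generator a testing instrument rather than a demo: simulation output can be
checked against exact truth at binomial resolution, and the whole pipeline
against known parameters.

Two presets fix the study conditions used by the tests and the acceptance
script. `config_control_like()` represents an untreated rearing regime:
roughly 13 larval plus 15 pupal days, 97% molt completion rates, a 1:1 sex
ratio, and a fecundity curve peaking two to three days after a 3-day
pre-oviposition period. Its exact expectations sit at a net reproductive
rate near 180, intrinsic rate near 0.157/day and generation time near 33
days — the regime reported for untreated cohorts of this species on
artificial diet. `config_treated_like()` mirrors a strongly
growth-disrupting treatment qualitatively: larval stadia compressed to a few
days, emergence cut to ~50%, shorter adult lives and roughly a quarter of
the control's net reproduction. These parameter values were chosen once,
from the published endpoint ranges, and are not tuning knobs for tests.

What the generator does **not** emulate: replicate-jar structure (individuals
are iid given the configuration), mating limitation and male effects on
fecundity, density dependence, time-varying rearing conditions, measurement
error in stage calls, and overdispersion beyond the negative-binomial egg
option. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to real-data violations
of it.

## Problem sizes and calibration checks

The test suite runs at sizes chosen to give the assertions real statistical
teeth while staying desk-scale: bootstrap CI calibration uses 300 simulated
cohorts of n = 200 with B = 1000 (coverage asserted within 0.95 ± 0.04);
the bootstrap SE of $R_0$ is compared against the sampling SD across 300
independent cohorts (within 20%); probit calibration uses 1000 Monte-Carlo
bioassays at the three-dose, 60-per-dose design scale (slope bias under
0.05, fiducial coverage within 0.95 ± 0.03, computed over replicates with
bounded limits — an unbounded interval trivially covers); and intrinsic-rate
recovery uses a single cohort of 100,000 individuals (absolute error under
0.005/day against the exact expectation).

## Known limitations

* Age-stage life expectancy $e_{xj}$ and reproductive value $v_{xj}$ — the
  usual extensions of the two-sex framework — are not computed.
* Fecundity counts total eggs, not female offspring; $R_0$ therefore carries
  the "eggs per newborn" interpretation used in the bioassay literature
  rather than the strict demographic "daughters per female".
* Percentile intervals only; no BCa or studentised bootstrap.
* The probit module fits a single link (probit); logit and
  complementary-log-log comparisons are out of scope, as is natural-response
  (mixture) estimation.
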