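# jmclaims

Joint modelling of yearly emergency-claims trajectories and time to death
for insured subjects aged 65 and over.

Health insurers and biostatisticians working with elderly portfolios face
two entangled processes: a longitudinal record of non-routine medical
claims (hospital admissions, emergency-room visits, ambulance services)
and heavily censored survival times (roughly 92% of subjects leave the
study alive).  Modelling them separately truncates the claims trajectory
informatively at death and denies the survival model its best health
marker.  `jmclaims` fits the two jointly through shared random effects,
with the claims history entering the hazard as a *recency-weighted
cumulative effect*, and turns the fitted model into personalized survival
curves that update each year as new claims are recorded.

## Model

On the log1p scale, subject *i*'s yearly claims follow a linear mixed
model, linked to a proportional-hazards model through the expected
trajectory *m<sub>i</sub>*:

```
y_i(t) = m_i(t) + e_i(t),   m_i(t) = (b0 + b_i0) + (b1 + b_i1) t,
b_i ~ N(0, D),  e_i(t) ~ N(0, s^2)

h_i(t) = h0(t) exp{ g1 sex_i + g2 age0_i + g3 sex_i*age0_i + a F(m_i(t)) }

F(m_i(t)) = \int_0^t wbar(t - s) m_i(s) ds
```

with an exponentiated cubic B-spline log-baseline `h0` and a fading
kernel `wbar` (exponential by default, rate set so the most recent year
carries 95% of the weight; uniform and linear-decay windows are
available, and kernels are compared by AIC).  The association `a` is the
log-hazard change per unit of weighted cumulative claims effect.
Estimation is by maximum likelihood with adaptive Gauss–Hermite
quadrature (the Gaussian longitudinal factor integrated in closed form, a
compiled kernel for the rest); dynamic predictions `pi(u | t)` are Monte
Carlo estimates over the asymptotic parameter posterior and the
conditional random-effects posterior.  A synthetic-cohort generator
reproduces the portfolio regime (entry ages 65+, eight-year window,
yearly occasions, ~8% deaths) so the whole pipeline is testable without
proprietary data.

## Worked example

```r
library(jmclaims)

cohort <- simulate_cohort(simulation_config(n_subjects = 500), seed = 11)
cohort
#> <claims cohort: 500 subjects, 53 deaths (10.6%), 3288 records>

fit <- fit_joint(cohort)
fit
#> Joint model fit (weighted-cumulative feature, random intercept + slope)
#>   500 subjects, 53 deaths; logLik = -2817.863, AIC = 5667.726
#>   beta0             0.3389  (SE 0.0203)
#>   beta1             0.0122  (SE 0.0044)
#>   sd_b0             0.3303  (SE 0.0199)
#>   sd_b1             0.0498  (SE 0.0054)
#>   corr_b            0.0471  (SE 0.1332)
#>   sigma             0.4643  (SE 0.0066)
#>   gamma_sex        -6.2807  (SE 2.9853)
#>   gamma_age0        0.0832  (SE 0.0288)
#>   gamma_sex_age0    0.0841  (SE 0.0363)
#>   alpha1            1.7338  (SE 0.4171)
```

The generator's defaults place the truth at `beta = (0.319, 0.014)`,
`sd_b0 = 0.329`, `sd_b1 = 0.050`, `sigma = 0.471`,
`gamma = (-4.648, 0.095, 0.059)` and `alpha = 1.462`; every estimate
above sits within its reported uncertainty of the truth — note how wide
the survival-side intervals are with only 53 observed deaths, which is
exactly the 92%-censoring difficulty the model is built for.  The
positive `alpha1` (1.73, SE 0.42) is the headline quantity: higher
recency-weighted claims demand means a higher death hazard.

A personalized, annually updatable survival curve for a new 80-year-old
woman whose claims are rising:

```r
sub <- new_subject(sex = 1, age0 = 80,
                   records = data.frame(t = 0:2, count = c(1, 2, 4)))
predict_survival(fit, sub, t = 3, u_grid = seq(3, 8, 1),
                 n_draws = 200, seed = 1)
#> Dynamic survival prediction from t = 3.00 (200 draws)
#>   u  mean median lower95 upper95
#> 1 3 1.000  1.000   1.000   1.000
#> 2 4 0.952  0.959   0.876   0.985
#> 3 5 0.906  0.921   0.767   0.971
#> 4 6 0.852  0.874   0.611   0.951
#> 5 7 0.766  0.798   0.411   0.920
#> 6 8 0.655  0.693   0.233   0.874
```

The curve starts at 1 at the conditioning time and declines as the
weighted claims history accumulates; `update_prediction()` appends the
next year's count and reconditions.  Forecast quality under absolute
loss:

```r
prediction_error(fit, cohort, t = 5, u = 7)
#> PE(7|5) = 0.0684 over 322 subjects at risk
```

Other entry points: `fit_lmm()` / `fit_cox_separate()` (the separate
analyses), `compare_weightings()` (AIC ranking of fading kernels),
`lrt_random_slope()` (boundary-mixture test for slope heterogeneity),
`cohort_summary()` (stratified portfolio description),
`read_cohort()` / `write_cohort()` (long-format CSV), and a command-line
front end (`inst/cli/jmclaims.R`) with `simulate`, `fit-separate`,
`fit-joint`, `predict`, `evaluate` and `summarize` subcommands driven by
a YAML config.

See the vignette (`vignettes/joint-claims-survival.Rmd`) for the model's
assumptions, numerical choices and the scope of the verification studies.

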