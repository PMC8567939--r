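# cgmresponse

Hierarchical Bayesian estimation of postprandial glucose responses from
continuous glucose monitor (CGM) traces and self-reported food diaries.

Self-reported meal times are unreliable, and a glucose excursion matched
against the wrong timestamp destroys the apparent relationship between
carbohydrate intake and the glucose curve. `cgmresponse` models each
patient-period's CGM trace as

    y(t) = b_p + Σ_m β_p · c_m · exp(−(t − r_m − δ_m)² / (2 α_p²)) + ε,
    ε ~ N(0, σ_p²)

a constant baseline `b_p` plus one Gaussian response bump per meal,
scaled by the meal's carbohydrate grams `c_m`, where

- **β_p** (mmol/l per g) is the rise in the response peak per gram of
  carbohydrate — the quantity of interest,
- **α_p** (minutes) is the response length-scale (smaller = faster
  clearance),
- **δ_m** is a *latent offset* correcting the reported meal time `r_m`
  (an errors-in-variables treatment of diary timing error).

Patients are pooled hierarchically within a group-period
(β_p ~ N⁺(β_g, sd_β²), log α_p ~ N(log α_g, sd_α²)) and everything is
fitted jointly by an adaptive Metropolis-within-Gibbs MCMC sampler
(Rcpp) with split-R̂ / effective-sample-size convergence gating.

The package is aimed at pre/post intervention cohort designs (two
surgery groups, each patient measured before and after an operation),
and also provides:

- a synthetic cohort generator with known ground truth
  (`generate_cohort()`), used for all recovery and calibration checks,
- CSV readers/writers for a documented CGM + diary dialect and
  diary-window alignment (`read_cgm_csv()`, `read_food_diary()`,
  `align_period()`),
- glycemic profile metrics: time-in-band percentages, min/mean/max/CV,
  pooled normalized histograms (`time_in_bands()`, `trace_summary()`,
  `aggregate_histogram()`),
- the comparison battery: paired t, Welch t, Mann-Whitney U,
  chi-squared, degree-of-change tests and a group summary table
  (`build_group_table()`),
- an end-to-end pipeline (`run_pipeline()`).

## Worked example

Simulate the default two-group cohort (10 + 7 patients, two periods,
3-day diaries, 15-minute CGM) whose ground-truth group means are the
published pre/post estimates, then fit the pre- and post-operative
models for one group:

```r
library(cgmresponse)

cohort <- generate_cohort(sim_config(seed = 42))
pre  <- fit_response_model(cohort_datasets(cohort, "RYGB", "pre"),  seed = 1)
post <- fit_response_model(cohort_datasets(cohort, "RYGB", "post"), seed = 2)
pre
#> <cgm_fit> 10 patients, 4 chains x 2000 draws; converged
#>   beta_g     0.0349  [0.0086, 0.0516]
#>   alpha_g   23.0972  [20.1557, 26.2790]
#>   sd_beta    0.0252  [0.0130, 0.0504]
#>   sd_alpha   0.1903  [0.1130, 0.3283]
post
#> <cgm_fit> 10 patients, 4 chains x 2000 draws; converged
#>   beta_g     0.0905  [0.0552, 0.1137]
#>   alpha_g   18.3950  [16.0965, 20.9708]
#>   sd_beta    0.0377  [0.0222, 0.0743]
#>   sd_alpha   0.2100  [0.1275, 0.3593]
```

The population response height roughly doubles after the operation
(β_g 0.035 → 0.091 mmol/l per gram; generating values 0.046 → 0.086)
while the response shortens (α_g 23.1 → 18.4 min; truth 22.8 → 19.6):
the same carbohydrate load produces a higher but quicker glucose
excursion. Per-patient posteriors, with convergence diagnostics, come
from `summary()`:

```r
s <- summary(post)
head(s[grepl("^beta\\[", s$parameter), ], 3)
#>     parameter   mean   q2.5  q97.5 rhat  ess
#>  beta[RYGB01] 0.0917 0.0880 0.0954    1 3039
#>  beta[RYGB02] 0.0569 0.0522 0.0616    1 2623
#>  beta[RYGB03] 0.1333 0.1294 0.1374    1 2779
```

and the within-group pre/post change in β_p is tested with the paired
battery:

```r
ids <- pre$patients
paired_change_test(coef(pre)[sprintf("beta[%s]", ids)],
                   coef(post)[sprintf("beta[%s]", ids)])
#> paired-t: statistic = 4.575, p = 0.001337 (n = 10)
```

The population-average response to a 30 g meal, with a pointwise 95%
band (this is the fitted-curve export the pipeline writes as CSV):

```r
head(population_response_curve(post, carbs = 30, grid = seq(0, 60, 20)), 4)
#>   time_min   mean   lower  upper
#> 1        0 2.7151 1.65629 3.4106
#> 2       20 1.4963 0.88788 1.9622
#> 3       40 0.2601 0.10270 0.4695
#> 4       60 0.0158 0.00222 0.0462
```

Glycemic profile metrics work on any trace:

```r
trace_summary(cohort$patients[["RYGB01.pre"]]$trace)
#> glucose mean 5.89, min 4.55, max 9.65 mmol/l; CV 15.4% (n=288)
#>    <4 [4,5) [5,6) [6,7)   >=7
#>   0.0   4.2  70.1  13.9  11.8
```

`run_pipeline(list(out_dir = "out", seed = 1))` chains all of the above
(simulate → fit per group×period → metrics → comparison table) and
writes CSVs plus a plain-text manifest.

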