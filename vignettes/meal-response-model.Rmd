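---
title: "Modelling postprandial glucose responses from CGM traces and food diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postprandial glucose responses from CGM traces and food diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Flash glucose monitors sample interstitial glucose every 15 minutes for
weeks at a time; food diaries record what was eaten and when. Relating
the two is harder than it looks: diary timestamps are self-reported and
often wrong by tens of minutes, and a glucose excursion attributed to
the wrong time dilutes any estimate of how strongly carbohydrate intake
drives glucose. `cgmresponse` implements a hierarchical Bayesian
errors-in-variables model for exactly this setting: it estimates, per
patient and per group, how much the postprandial glucose peak rises per
gram of reported carbohydrate, while treating the true meal times as
latent quantities to be corrected during inference.

The package was built around the pre/post comparison design of bariatric
surgery studies — two surgery groups, each patient measured before and
after the operation, with a 3-day diary inside each two-week CGM wear —
but nothing in the model is specific to surgery.

## The model

For patient $p$ with CGM observations $y_{p,i}$ at times $t_{p,i}$
(minutes) and reported meals $m = 1 \dots M_p$ with carbohydrate
$c_{p,m}$ grams at reported times $r_{p,m}$:

$$y_{p,i} \sim \mathcal N\!\left(b_p + \sum_m \beta_p\, c_{p,m}\,
\exp\!\left\{-\frac{(t_{p,i} - r_{p,m} - \delta_{p,m})^2}
{2\alpha_p^2}\right\},\; \sigma_p^2\right)$$

* $\beta_p \ge 0$ (mmol/l per g) — the response **height** per
  carbohydrate gram: the quantity of main scientific interest.
* $\alpha_p > 0$ (minutes) — the response **length-scale**; smaller
  values mean faster glucose clearance.
* $b_p > 0$ (mmol/l) — a constant between-meal baseline. A constant
  baseline is a deliberate simplification: with a slowly varying
  baseline (say a Gaussian-process regression) the baseline and the
  meal-driven variation become hard to separate, and the causal reading
  of $\beta_p$ is lost.
* $\sigma_p > 0$ (mmol/l) — homoscedastic Gaussian observation noise
  per patient-period.
* $\delta_{p,m}$ (minutes) — the latent meal-time offset; the true meal
  time is $r_{p,m} + \delta_{p,m}$. The offsets carry the
  errors-in-variables correction for unreliable diary timings.

The response basis is a unit-peak Gaussian bump. It is deliberately
isolated in one function (`response_basis()`), so a different bump shape
(asymmetric rise/decay, say) would be a one-function change. The mean
curve is linear in each meal's carbohydrates, and coincident meals
superpose additively.

Patients within a group-period are pooled hierarchically:

$$\beta_p \sim \mathcal N^+(\beta_g, sd_\beta^2), \qquad
\log \alpha_p \sim \mathcal N(\log \alpha_g, sd_\alpha^2), \qquad
\delta_{p,m} \sim \mathcal N(0, \tau^2)\ \text{truncated to } |\delta| \le 60.$$

One hierarchical fit is run per group $\times$ period, matching how the
design reports group means and per-patient values per period; $\alpha_p$
is estimated per patient (hierarchically), not only per group.

### Priors and tunable parameters

All priors are weakly informative and configurable via
`prior_config()`:

| parameter | prior | default | why |
|---|---|---|---|
| $\beta_g$ | $\mathcal N^+(0.05, 0.05^2)$ mmol/l/g | — | centred on the magnitude CGM studies report, sd spans 0–0.15 |
| $\alpha_g$ | LogNormal$(\log 20, 0.5^2)$ min | — | glucose peaks resolve on a tens-of-minutes scale |
| $b_p$ | $\mathcal N^+(5.3, 1.0^2)$ mmol/l | — | normal fasting glycaemia |
| $\sigma_p$ | half-$\mathcal N(1.0)$ mmol/l | — | generous for sensor + model error |
| $sd_\beta$ | half-$\mathcal N(0.05)$ | — | between-patient spread of the same order as $\beta_g$ |
| $sd_\alpha$ | half-$\mathcal N(0.5)$ (log scale) | — | allows ±65% patient variation in $\alpha$ |
| $\tau$ (`jitter_sd`) | fixed | 20 min | plausible diary timing error; fixing it keeps the offsets identified |
| offset truncation | fixed | ±60 min | an offset beyond an hour would re-assign a meal to a different excursion; the truncation bounds the label-switching ambiguity |

`jitter_sd = 0` disables the correction entirely (all offsets fixed at
zero); `mcmc_control(estimate_offsets = FALSE)` is the equivalent
ablation switch, used to quantify what the correction buys.

## Inference

No general-purpose gradient-based MCMC engine is assumed; the sampler
is part of the package (C++ via Rcpp): adaptive Metropolis-within-Gibbs
with incremental likelihood updates. An $N \times M$ basis matrix per
patient is cached, so a beta/baseline/noise move costs $O(N)$, an
offset move $O(N)$ (one column), and an $\alpha$ move $O(NM)$. Four
non-obvious kernel ingredients matter:

* **Prior-independence proposals for offsets** (30% of offset moves).
  A jittered meal time induces a multimodal conditional for
  $\delta_{p,m}$; random-walk moves alone get trapped in one mode, which
  showed up as slow mixing of $\sigma_p$. Proposals drawn from the
  offset prior hop between modes, and their acceptance ratio reduces to
  the likelihood ratio.
* **A joint $(\log\beta_p, \log\alpha_p)$ move** along the
  constant-area direction: the data pin down the area (height ×
  width) of a response much more tightly than either factor, so the
  posterior is a ridge; the directed move walks along it.
* **A joint $(b_p, \beta_p)$ move** along the least-squares trade-off
  between baseline level and bump height.
* **Interweaving rescale moves** for $(sd_\beta, \beta_{1..P})$ and
  $(sd_\alpha, \log\alpha_{1..P})$, which break the usual funnel between
  a hierarchical scale and its group deviations.

Defaults are 4 chains, 1000 warmup and 2000 kept iterations. 2000
rather than 1000 kept draws: with this kernel the slowest parameters
(the hierarchy scales) need roughly 8000 pooled draws to clear an
effective-sample-size floor of 400 reliably on a 10-patient fit; the
extra iterations cost a few seconds. Proposal scales adapt during warmup
only (Robbins–Monro toward 44% acceptance), so the kept draws come from
a fixed kernel. Chains start from dispersed draws around the priors with
data-driven baseline and noise initials.

Convergence is gated, not assumed: split-$\hat R$ and a Geyer
initial-positive-sequence ESS are computed for every parameter, and a
fit whose reported parameters (group level plus per-patient $\beta$,
$\alpha$, baseline, $\sigma$) miss the thresholds
($\hat R \le 1.05$, ESS $\ge 400$) raises a typed condition that carries
the full fit object for inspection. Posterior intervals are equal-tailed
2.5%/97.5% quantiles with type-7 linear interpolation, chains pooled.
The per-patient 95% intervals are posterior credible intervals.

## The synthetic cohort generator

Because real patient-level CGM + diary data of this kind cannot be
shared, the package ships a generator (`generate_cohort()`) that
produces cohorts *from the model's own assumptions* with known ground
truth: constant per-patient baselines, additive Gaussian response bumps
scaled by carbohydrates, Gaussian observation noise, and Gaussian
reporting error on meal times. Its defaults encode the study design the
package targets: 10 + 7 patients in two groups, two periods, 3 recording
days at 15-minute sampling, and group-level means set to the published
pre/post estimates (β 0.046→0.086 and 0.034→0.088 mmol/l/g; α
22.80→19.60 and 20.56→18.33 min).

Generator choices the design left open, fixed here once:

* **Meal schedule** — meals uniform inside waking hours (07:00–21:00)
  with a ≥90-minute gap, 5 meals/day by default (between the 4–5 meals
  of a typical pre-operative diary and the 6–8 small meals recommended
  post-operatively); carbohydrates uniform on 10–60 g.
* **Heterogeneity** — $\beta_p$ truncated-normal around the group mean
  with sd = 30% of the mean; $\alpha_p$ log-normal with sd(log) = 0.15;
  baselines normal with sd 0.4 mmol/l.
* **Noise levels** — observation noise 0.3 mmol/l; reporting jitter sd
  15 min.
* **Device floor** — simulated glucose clipped at 2.2 mmol/l,
  mimicking sensor range (inactive under default settings).

What the generator does **not** emulate — and hence what passing
recovery tests do and do not show: there is no circadian or slowly
drifting baseline, no insulin/incretin dynamics, no nutrient effects
beyond carbohydrate, no autocorrelated sensor error, and a single
baseline mean for both periods, so the simulated cohorts do not
reproduce the overall post-operative drop in glycaemia (or its
time-in-hypoglycaemia signature) — only the meal-response structure.
Recovery on these cohorts demonstrates that the inference machinery is
correct and well calibrated *under the model's assumptions*, not that
the model is adequate for any particular real dataset; on real data the
constant-baseline assumption is the first thing to scrutinize (the
per-trace variance-explained metric is the built-in check).

## Numerical and boundary conventions

* Time is real-valued minutes internally; timestamps only at the I/O
  boundary (ISO-8601, UTC).
* Missing CGM samples are excluded from the likelihood and from every
  metric denominator; they are never imputed.
* Glycemic bands are half-open $[a, b)$: a reading of exactly 4.0
  mmol/l is not hypoglycaemic.
* Diary lines within 15 minutes (configurable) of a cluster's first
  line merge into one meal with summed carbohydrates — the model's unit
  is a meal, a diary's unit is a food.
* Meals up to 3 hours before an analysis window are retained, since
  their response tails overlap the window.
* Out-of-support parameters give `log_posterior() == -Inf` (a documented
  sentinel), not an error; zero-variance inputs to the comparison tests
  return a flagged degenerate result rather than a spurious p-value.
* All comparison tests are two-sided; independent comparisons use the
  Welch form (group sizes differ); raw p-values, no multiplicity
  correction.

## Problem sizes used in the checks

The package's statistical checks run at desk scale, chosen as the
smallest sizes that still exercise the full hierarchy: density oracles
on 100 random instances; noise-free identifiability on one 12-meal
patient; recovery and calibration on 10-patient and 5×10-patient
cohorts (2–3 days); the ablation comparison on 20 single-patient
replicates with a 25% held-out grid; and the pre/post directionality
run on ten full 10+7 cohorts with halved chains. Seeds are fixed
throughout.

## Known limitations

* The constant baseline is wrong whenever glycaemia drifts on the hour
  scale (dawn phenomenon, exercise); $\beta_p$ then absorbs some drift.
* Offsets are a priori independent across meals; a diary that is
  systematically shifted (clock error) would be better served by a
  shared offset component.
* The Gaussian bump is symmetric, while real excursions rise faster
  than they decay; the basis is replaceable but only one shape ships.
* The Metropolis-within-Gibbs sampler is practical to a few dozen
  patients per fit; hundreds of patients would warrant a
  gradient-based sampler.
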