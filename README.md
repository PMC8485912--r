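# nof1cgm

Bayesian analysis of **series-of-n-of-1 dietary crossover trials** monitored
by continuous glucose monitoring (CGM). The package is aimed at researchers
running within-person feeding experiments — each participant repeatedly
crosses over between a high-fat/low-carbohydrate (HF-LC) and a
low-fat/high-carbohydrate (LF-HC) diet period — who want to know, for each
individual, *which* diet raises their postprandial glycemia, and what the
cohort shows in aggregate.

## What it computes

From 15-minute CGM traces, a meal log and the crossover design, the package
extracts the three standard glycemic outcomes:

- **MPG** — maximum postprandial glucose: the peak CGM value within 3 h of a
  meal's first bite, truncated at the next meal when the gap is shorter;
- **MAGE** — mean amplitude of glycemic excursions: the mean of consecutive
  peak–nadir amplitudes exceeding one standard deviation of the day's
  readings;
- **AUC24** — the trapezoidal area under the glucose–time curve over
  00:00–24:00, in mmol/L·h.

Each participant's outcome series is then fit with the individual model

```
y = α + β x + ε,    ε ~ N(0, σ²),   x = 0 (HF-LC), 1 (LF-HC)
```

by a conjugate Gibbs sampler with noninformative priors
(α, β ~ N(0, 10⁶); σ² ~ Inv-Gamma(0.001, 0.001)). The posterior tail
probabilities P(β > +δ) and P(β < −δ) against a prespecified clinically
meaningful difference δ (0.167 mmol/L for MPG, 0.072 for MAGE,
13.889 mmol/L·h for AUC24) classify each participant as an
**HC-responder** (P(β > +δ) > 80%), an **HF-responder**
(P(β < −δ) > 80%), or a nonresponder.

Across participants, a Bayesian hierarchical model
(β_i ~ N(b₀ + b_age·age + b_sex·sex + b_BMI·BMI, τ²), inverse-gamma prior
on τ²) yields the population effect, its two-tailed meaningful-difference
probability at a stricter 90% threshold, shrunken per-participant effects,
and the four standard missing-data sensitivity subsets. A simulation-based
power calculator reproduces the design-level power of the aggregated
30 × 3 × 2 × 18 layout, and a synthetic-cohort generator with known ground
truth (responder mixture, effect sizes, AR(1) sensor noise, realistic
missingness) makes the whole pipeline testable without any raw sensor data.

## Worked example

```r
library(nof1cgm)

spec   <- cohort_spec(n_participants = 6, n_withdrawals = 0,
                      n_low_valid = 0, n_flagged = 0, seed = 2024)
coh    <- generate_cohort(spec)
mm     <- compute_meal_metrics(coh$cgm, coh$meals)
dm     <- compute_daily_metrics(coh$cgm, coh$meals, meal_metrics = mm)
series <- build_outcome_series(mm, dm, coh$design)

fit <- fit_individual(subset(series, outcome == "MPG" & participant_id == "P01"),
                      delta = meaningful_thresholds()[["MPG"]],
                      spec = nof1_model_spec(seed = 1))
fit
#> n-of-1 fit: participant P01, outcome MPG
#>   beta (LF-HC minus HF-LC): 0.054 [-0.071, 0.180]
#>   P(beta > +0.167) = 0.039, P(beta < -0.167) = 0.000
#>   n per arm: 54 HF-LC / 52 LF-HC; split R-hat 1.000
```

P01 was generated as a nonresponder (true β = 0): the posterior mean is near
zero and neither tail reaches the 80% rule. Fitting and classifying the
whole cohort:

```r
posterior <- fit_cohort(subset(series, outcome == "MPG"),
                        spec = nof1_model_spec(seed = 2))
classify_responders(posterior)[, c("participant_id", "beta_mean", "p_above", "p_below", "call")]
#>   participant_id beta_mean p_above  p_below call
#> 1 P01               0.054   0.037  0.00025  nonresponder
#> 2 P02               0.320   0.988  0        HC-responder
#> 3 P03               0.058   0.049  0.00053  nonresponder
#> 4 P04              -0.376   0      0.999    HF-responder
#> 5 P05               0.091   0.097  0        nonresponder
#> 6 P06               0.194   0.670  0        nonresponder
```

Five of six calls match the generative truth; P06 carries a true +0.3 mmol/L
effect but, at below twice the threshold, its posterior tail (67%) misses
the 80% rule — the expected behaviour for borderline effects. The group
level and the design-level power:

```r
fit_hierarchical(series, coh$meta, delta = 0.167,
                 spec = hier_spec(seed = 3), outcome = "MPG")
#> Hierarchical n-of-1 meta-analysis: outcome MPG, 6 participants
#>   population effect (LF-HC minus HF-LC): 0.056 [-0.103, 0.215]
#>   P(|effect| > 0.167) = 0.062 (threshold 0.90); between-participant sd 0.141

run_power(power_config(seed = 4))
#> Simulation-based power: 1.000 [0.982, 1.000] over 200 trials
#>   design 30 participants x 3 sets x 2 periods x 18 obs; effect 0.167, residual sd 0.80, between sd 0.10
#>   type-I error at zero effect: 0.050 [0.024, 0.090]
```

A mixed cohort of opposing responders averages out: the population interval
covers zero even though individual responders are confidently detected —
the core argument for analysing such trials at the individual level.

`run_pipeline(default_config(), "out/")` chains every stage
(simulate → metrics → individual fits → classification → hierarchical
meta-analysis → dose–response → power) and writes the result tables, a
markdown report and a reproducibility manifest;
`inst/cli/nof1cgm.R` exposes the same stages as shell subcommands.

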