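---
title: "Models and methods behind nof1cgm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nof1cgm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

nof1cgm analyses series-of-n-of-1 dietary crossover trials: each
participant alternates between a high-fat/low-carbohydrate (HF-LC) and a
low-fat/high-carbohydrate (LF-HC) 6-day feeding period, in randomized order
within each of several sets, wearing a CGM sensor that reports interstitial
glucose every 15 minutes. This vignette records the models, the defaults and
the numerical decisions, in enough detail that a maintainer can judge each
one.

## Glycemic outcomes

**MPG** (maximum postprandial glucose, mmol/L) is defined per consumed meal
as the maximum CGM reading in the half-open window from the first bite to
3 h later, truncated at the next consumed meal's first bite when meals are
closer than 3 h. The window is half-open so that a sample falling exactly on
the next meal's start is attributed to the next meal, and ties in the
maximum take the earliest timestamp. Meals marked not consumed produce no
MPG observation at all; consumed meals whose window contains no CGM sample
yield a missing value that counts against the participant's valid-data
fraction.

**MAGE** (mean amplitude of glycemic excursions, mmol/L) is computed per
calendar day: (1) the day's sample standard deviation (n−1 denominator —
the classical definition does not specify the denominator; the sample form
was chosen) is taken over all readings; (2) plateaus (runs of identical
values, common on a 0.1 mmol/L-quantized sensor) are collapsed to a single
point and turning points are located at strict sign changes of successive
differences; (3) amplitudes between consecutive turning points qualify when
they exceed one standard deviation; (4) MAGE is the mean of qualifying
absolute amplitudes. Both directions (peak→nadir and nadir→peak) are
counted by default, matching the "differences between consecutive peaks and
nadirs" reading of the definition; the classic first-direction-only
convention is available as `direction = "ascending"`. A constant day has no
turning points and therefore no MAGE (missing, not zero). Computing MAGE
per day rather than per 6-day period matches the day-level outcome
structure; both conventions exist in the literature and the per-period
variant can be obtained by concatenating days before calling
`compute_mage()`. No smoothing is applied before turning-point detection by
default; a 3-point running median is available (`smooth = TRUE`) for
noisier sensors.

**AUC24** (mmol/L·h) is the trapezoidal integral of glucose over
00:00–24:00 of a calendar day. The right boundary uses the next day's 00:00
sample when present; otherwise the first/last readings are extended
horizontally to the day boundaries. This makes a constant 5 mmol/L day
integrate to exactly 120 mmol/L·h and keeps the integral linear in a
constant offset (both are tested identities). Days are timezone-naive
calendar days; timestamps are parsed as local time and never shifted.

Day-level metrics are reported as missing when CGM coverage falls below 70%
of the 96 expected samples (the definition of "enough of a day" is not
standardized; 70% is configurable via `coverage_min` and recorded in the
run manifest) or when the day is fully missed (no valid meal). Following
the trial's missing-data rule, a day on which all three intervention meals
were missed is excluded from the MAGE and AUC24 series; partially-missed
days are retained.

## The individual treatment-effect model

Observations (meal-level MPG; day-level MAGE/AUC24) are regressed on the
treatment indicator, `y = α + β·x + ε` with `x = 0` for HF-LC and `1` for
LF-HC, so positive β means higher glycemia on the high-carbohydrate diet.
Priors are noninformative: `α, β ~ N(0, 10⁶)` on the outcome's mmol/L
scale and `σ² ~ Inv-Gamma(0.001, 0.001)`. A Gibbs sampler alternates the
exact bivariate-normal draw of (α, β) given σ² with the conjugate
inverse-gamma draw of σ²; defaults are 4 chains × 10,000 iterations with
2,000 burn-in, overdispersed initialization of σ², and a split-chain R̂
threshold of 1.05 (fits above it are flagged, not silently returned). With
these priors the β posterior is effectively the flat-prior scaled-t, and
the sampler is routinely validated against that closed form (tails within
±0.02, which at 32,000 retained draws is several Monte-Carlo standard
errors wide).

Responder classification applies the prespecified clinically meaningful
differences δ — 0.167 mmol/L (MPG), 0.072 mmol/L (MAGE), 13.889 mmol/L·h
(AUC24); these are the 3, 1.3 and 15,000/60 mg/dL conventions divided by
exactly 18.0, and the AUC24 value is stored at the 3-decimal precision used
in reported tables rather than the coarser 13.9 rounding. A participant is
an HC-responder on an outcome when P(β > +δ) > 80%, an HF-responder when
P(β < −δ) > 80%, otherwise a nonresponder; at any threshold above 50% the
two conditions are exclusive. Overall labels take the union over MPG and
MAGE; a participant called HC on one outcome and HF on the other is flagged
for manual review rather than silently resolved. The 80% rule is applied to
each one-sided tail separately, consistent with reporting both tail columns
per outcome.

Two framings of the individual analysis circulate — observation-level
regression and set-wise paired mean differences. The observation-level fit
is the default (it uses all 18 observations per period and matches the
power calculation's layout); `method = "paired"` collapses each set into
one LF-HC-minus-HF-LC mean difference and models those, at the cost of very
few effective observations. Dose–response contrasts reuse the same model,
comparing each higher-carbohydrate day type (25, 65, 75 %E) against the
15 %E days, plus a monotonicity summary of the posterior means.

## The hierarchical model

The population analysis is a two-level normal model: observations
`y = α_i + β_i·x + ε`, participant intercepts `α_i ~ N(a₀, τ_α²)` and
effects `β_i ~ N(b₀ + Z_i γ, τ²)` with covariates age, sex and BMI.
Covariates are standardized (z-scored; sex as a 0/1 indicator) so that the
shared `N(0, 10⁶)` priors are comparably diffuse; singular covariates
(e.g. a single-sex subset) are dropped with a warning. Variances get
`Inv-Gamma(0.001, 0.001)` priors — the inverse-gamma family is the
conjugate convention for variance parameters, and the hyperparameters are
flagged in the output rather than hidden. "Generalized linear mixed
regression" is taken at its identity-link normal-family case, as the
outcomes are continuous.

The Gibbs sampler uses *blocked* updates: the population coefficients
(a₀; b₀, γ) are drawn with the participant effects marginalized out
(each per-participant estimate contributes weight 1/(τ² + σ²/n_i)),
then the α_i, β_i are redrawn conditionally. The naive one-site sweep is
correct but degenerates into a random walk when N is small — with a single
participant, b₀ and β₁ drift together unbounded — whereas the blocked form
anchors the population level to the data directly. With one participant the
population effect remains weakly identified (nothing constrains τ²; its
posterior inherits the prior's heavy upper tail) — this is a property of
the model, not the sampler — but the participant-level posterior reproduces
the individual fit, which is what the single-participant consistency check
asserts.

The group-level meaningful-difference probability is two-sided,
P(effect > +δ) + P(effect < −δ), judged against a stricter 90% threshold
(group conclusions warrant tighter type-I control than individual
screening; both the two-sided mass and the dominant single tail are
reported). Four sensitivity subsets are built from the metadata: all
available participants; excluding early withdrawals; additionally excluding
participants with under 50% valid intervention-meal data; additionally
excluding those with chronic disease or prescription medication.

Serial correlation of within-period residuals is supported as a fixed-ρ
AR(1) quasi-differencing transform applied within (set, treatment) blocks
before fitting (`hier_spec(ar1_rho = )`), default off: day-level outcomes
show little residual autocorrelation, and there is no published structure
to calibrate a ρ posterior against. The switch is recorded in the run
manifest.

## Power simulation

The power calculator simulates the aggregated design — by default 30
participants × 3 sets × 2 periods × 18 observations per period — drawing
participant effects `β_i ~ N(effect, between_sd²)` and adding residual
noise per observation. The group fit inside the loop is the exact conjugate
marginal, no MCMC: under the balanced design the per-participant mean
differences are i.i.d. normal with unknown mean and variance, so the
flat-prior posterior of the pooled effect is the one-sample t — its 95%
interval rule is exactly calibrated (type-I error = α), which the
null-calibration test verifies at 500 simulations. Agreement of this fast
path with the Gibbs hierarchical fit is itself a test.

The within- and between-participant noise magnitudes are not observable
design quantities; the package's stated defaults are a residual SD of
0.8 mmol/L per observation and a between-participant effect SD of
0.1 mmol/L, chosen as conservative values for meal-level MPG in a
normoglycemic cohort. Because the choice matters, `power_band()` reports
power across a residual-SD sweep (0.5–1.0 mmol/L) rather than a single
number; the headline ≥99% detection of a 0.167 mmol/L effect is evaluated
at the stated defaults.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable with known
ground truth. Its trace model is
`baseline + circadian + Σ meal excursions + AR(1) noise`:

- baseline 4.5 mmol/L (per-participant jitter, truncated to the
  normoglycemic 3.5–6.0 band, so fasting values sit near the low-4s typical
  of healthy young adults);
- a 24-h sinusoid of amplitude 0.3 mmol/L (overnight minimum near 04:00);
- per consumed meal, a compact-support excursion kernel rising to its peak
  45 min after the first bite and returning to exactly zero at 3 h (a
  gamma-shaped pulse, floor-shifted so kernels of meals ≥3 h apart never
  overlap — this is what makes noise-free effect recovery exact rather than
  approximate); peak height 2.0 mmol/L on HF-LC;
- AR(1) sensor noise with stationary SD 0.3 mmol/L and lag-1 correlation
  0.7 at 15-min spacing, initialized from the stationary distribution.

The diet effect enters as a shift of the excursion *peak height* during
LF-HC periods, not of the basal level, so MPG and MAGE respond while AUC24
responds only weakly — matching the qualitative pattern that AUC24 produces
no responders. Responder classes are allocated in exact counts (largest
remainder) from the mixture, default (9, 6, 13)/28 with effect magnitudes
±0.3 mmol/L. The defaults emulate the reference study conditions: 30
enrolled, two early withdrawals (truncated after 1 or 2 completed sets) so
28 contribute, one completer with a long sensor failure pushing valid data
below 50%, one chronic-disease flag, 2% missed meals (≈98% adherence),
block-of-2 randomized diet order, and a washout before every intervention
period (four 6-day periods per set, 72 study days). An optional linear
dose–response slope per carbohydrate %E above 15 supports the contrast
analyses. All draws flow from one integer seed through deterministic child
streams; regenerating with the same seed is byte-identical.

What the generator does *not* emulate: glucose–insulin physiology (no ODE
dynamics, no meal-composition kinetics beyond peak height), circadian
phase heterogeneity, sensor drift or calibration error, or any microbiome/
metabolome covariates. Within-person outcome variances in the real trial
are unpublished, so the noise defaults are plausible placeholders —
passing recovery tests demonstrates the pipeline's correctness under its
own generative assumptions, not fidelity to the unreleased raw data.

## Numerical choices and degenerate inputs

- Unit conversion divides mg/dL by exactly 18.0 (reproducing all three
  printed threshold pairs to 3 decimals); the conversion is an involution
  to 1e-12.
- Timestamps are timezone-naive local time stored as UTC internally, so a
  "day" is always 00:00–24:00 with no DST surprises.
- Duplicate timestamps, unknown units under auto-detection, negative
  glucose, out-of-range values (≥30 mmol/L), meal slots outside
  breakfast/lunch/dinner, and design tables violating the crossover block
  structure are all hard errors naming the offending row or participant.
- Fewer than 3 readings → MAGE missing; fewer than 2 → AUC24 missing; an
  arm with fewer than 2 observations → an explicit insufficient-data error
  from the individual model.
- Gibbs label-flip symmetry (swapping arm labels negates β and swaps the
  tails) holds to Monte-Carlo error, not bit-exactly: the joint (α, β)
  update consumes the RNG stream differently under recoding. Similarly,
  rescaling all observations and δ by a common factor leaves calls
  unchanged to MC error, since the fixed-scale priors are only
  asymptotically flat.
- Sampler seeds derive deterministically from one user seed via an integer
  stream (always below 2³¹), so cohort fits are reproducible participant by
  participant.

## Problem sizes used by the test suite

Unit tests run reduced samplers (2 chains × 3,000 iterations); the
package-default 4 × 10,000 configuration is exercised by the
acceptance-level tests: 50 simulated datasets for the closed-form tail
comparison, a 28-participant known-mixture cohort (effects ±0.4 mmol/L,
twice the MPG threshold) for responder sensitivity/specificity and
hierarchical recovery, 1,000 random traces for the MAGE brute-force oracle,
and 200–500 simulated trials for the power and type-I checks. These sizes
keep the full suite to a few minutes on one core while leaving Monte-Carlo
error well inside each asserted tolerance.

## Known limitations

- MAGE is reported per calendar day; excursions spanning midnight are split
  between days (the day-level outcome structure requires a per-day
  convention).
- The individual model ignores within-day serial correlation of meal-level
  MPG; the hierarchical AR(1) option mitigates this only at fixed ρ.
- No multiplicity adjustment across participants is applied (individual
  screening deliberately mirrors the per-participant decision rule).
- The Libre-style export reader is a best-effort convenience for one common
  dialect, not a validated device parser.
- Group-level conclusions from opposing-responder cohorts are intentionally
  conservative: the population mean is a poor summary when effects are
  bimodal, which is the package's motivating argument for the n-of-1
  design rather than a defect of the model.
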