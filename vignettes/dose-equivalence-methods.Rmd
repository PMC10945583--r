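---
title: "Methods: triad dose-response fitting, cross-route dose equivalence, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triad dose-response fitting, cross-route dose equivalence, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadose)
```

## The model

The package's core is a response-surface comparison between two routes of
THC administration. Each cannabimimetic triad behavior — hypolocomotion
(open-field distance, cm over 15 min), analgesia (tail-flick latency, s, in
52.5 °C water) and hypothermia (core temperature, °C) — is measured
immediately before and after exposure, and analyzed as a difference score
`post − pre` (`difference_score()`; a `post − VEH-post` mode exists for
assays where a pre-test would confound the measurement, such as open-field
habituation).

The i.p. arm of each behavior is fitted with the three-parameter Emax
model on linear dose,

$$y(d) = B + (T - B)\frac{d}{d + \mathrm{ED}_{50}},$$

the Hill-slope-1 form. We use linear dose rather than log-dose because the
design includes a true vehicle (dose 0), where the log-logistic
parameterization is undefined; on `d >= 0` the two forms with Hill = 1 are
the same curve. Decreasing responses are fitted on signed difference
scores with `T < B` — no magnitude transform, so a fitted curve predicts
the sign of the effect as well as its size.

Dose equivalence is inverse prediction: given the group-mean difference
score `y_obs` of an oral-consumption condition, the i.p.-equivalent dose is
the exact inverse of the Emax curve,

$$d^{*} = \mathrm{ED}_{50}\frac{y_{obs} - B}{T - y_{obs}},$$

computed per behavior, then aggregated across the `k = 3` behaviors as an
arithmetic mean with SEM = SD/sqrt(k). That SEM measures *across-behavior
spread* of the prediction; the distinct *statistical* uncertainty of a
single behavior's inversion is available as a nonparametric bootstrap
(`bootstrap_predicted_dose()`: resample animals within dose groups, refit,
re-invert), and the two are deliberately not mixed in the report.

Validation is out-of-sample: the aggregate predicted dose is pushed through
a second-order polynomial `V_max = a0 + a1 d + a2 d^2` fitted per sex to
the 120 dB acoustic-startle i.p. dose-response (group means, vehicle
included as dose 0), and compared with the measured startle of orally
exposed animals; the verdict is `within_sem` when the prediction falls
inside one SEM of the measured mean.

## Numerical choices

* **Multistart Emax fitting.** `fit_emax()` runs `stats::nls` (port
  algorithm, `ED50 >= 1e-9`) from 9 starts with ED50 on a log grid spanning
  `[min positive dose/10, max dose x 10]`; `minpack.lm::nlsLM` is the
  fallback engine at any start where `nls` fails. The lowest residual sum
  of squares wins; RSS ties (within 1e-12) break toward the smaller ED50.
* **Degenerate data.** Flat responses make `T - B` collapse and the ED50
  unidentifiable; the fit is flagged non-converged (span below 1e-8 of the
  response scale, or ED50 beyond 1e4 times the largest dose) and every
  downstream operation (`ed50()`, `predict()`, `invert_emax()`) refuses it.
* **Non-plateauing curves.** When the largest tested dose is below
  2 x ED50 the fit carries `extrapolated_top = TRUE`: the asymptote is an
  extrapolation, which is exactly the situation of analgesia and
  hypothermia here. Inversion still uses the fitted `T`, but responses
  outside the fitted dynamic range, or implied doses beyond the largest
  tested dose, fail loudly instead of clamping; an explicit
  `allow_extrapolation = TRUE` permits implied doses up to twice the
  largest tested dose. Silent extrapolation on a non-plateauing curve
  would place unbounded trust in the asymptote.
* **Floors.** Predicted startle is floored at 0 cm/min with a warning
  (V_max is a speed); `grams_consumed()` clamps apparent mass changes in
  `(-0.05, 0)` g to zero (drying/scale noise) and rejects larger gains as
  data errors.
* **Rounding.** Full precision is kept everywhere internally; the JSON
  report adds a `display` block at report precision (doses and fold ratios
  at 1 decimal, startle at integer cm/min).
* **Intake rates.** `piecewise_rates()` uses a *fixed* 40-min changepoint
  by default — the observed plateau onset, treated as a design constant —
  with `estimate_changepoint()` available as an optional least-squares
  search over interior minute marks. Rates are computed per animal and
  then averaged; the percent reduction `100 (r1 - r2)/r1` is taken on the
  mean rates.
* **p-values** below 1e-15 print as `< 1e-15`; report formatting follows
  the `p < 0.001` threshold style.

## The statistics layer

`sem()`, `one_way_anova()`, `two_way_anova()`, `sidak_adjust()` and
`linreg_ftest()` are deliberately self-contained sums-of-squares
implementations rather than wrappers, so every number the pipeline reports
can be traced to an explicit decomposition; the test suite cross-checks
them against `aov`/`lm` and brute-force projection oracles to 1e-10.
Repeated-measures designs are handled as balanced split-plot ANOVA (factor
A between subjects, factor B within): A is tested against the
subject-within-A stratum, B and A:B against the subject-by-B residual.
Unbalanced designs are rejected rather than approximated — Type-II/III
machinery is out of scope.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the analyses assume, at the
conditions the study reports. Its defaults are calibration constants, not
tuning knobs:

| Parameter | Default | Units | Basis |
|---|---|---|---|
| ED50 (hypolocomotion / analgesia / hypothermia) | 1.3 / 3.9 / 14.4 | mg/kg | reported i.p. potencies |
| Emax span T (same order) | -3500 / +8 / -8.64 | cm, s, °C | -8.64 reproduces the reported -5.84 °C at 30 mg/kg; locomotion/analgesia spans are plausible assay scales (baseline ~4000 cm; latency ceiling ~10 s) |
| intake rates THC-gel | 13.0 → 4.2 at 40 min | mg/min | reported time course (67.7 % reduction) |
| intake rates VEH-gel | 16.3 → 9.9 at 40 min | mg/min | reported time course (39.3 % reduction) |
| mean consumed dose (2/5/10 mg per 15 ml E-gel) | 10.5 / 17.2 / 29.2 | mg/kg | reported group means |
| control-gel non-consumers | 7/17 | — | reported count at 4 mg CTR-gel |
| oral:i.p. potency | 3.7/29.2 ≈ 0.127 | — | the 2 hr condition's equivalent dose |
| startle quadratic (male) | through (0, 1450), (3.7, 1733), (8.8, 558) | cm/min | anchored to the predicted startle values; baseline chosen so the curve rises at 1–5 mg/kg and stays ≥ 0 at 10 |
| startle quadratic (female) | through (0, 700), (3.7, 688), (8.8, 310) | cm/min | flat-then-falling female profile |
| brain THC kinetics | ka 1.2, ke 0.18 /hr, scale 26.4 pmol/g per mg/kg | — | peak 500–600 pmol/g near the 2 hr access end; < 50 pmol/g at 26 h |
| body mass | Normal(25 g, 2 g), truncated at 18 g | g | typical adult C57BL/6J; no masses are reported |
| noise SDs (locomotion / tail flick / temperature) | 700 cm / 1.6 s / 1.7 °C | response scale | ≈ 20 % of each dynamic range, a plausible behavioral CV |
| consumed-dose CV / PK CV / intake-rate CV | 0.25 / 0.20 / 0.30 | — | calibration choices reproducing the wide per-animal dose spread |

Structural choices worth stating:

* **Two anchored streams.** The reported intake *rates* (13.0 → 4.2 mg/min,
  i.e. ~0.86 g per 2 h) and the reported *mean consumed dose* (29.2 mg/kg,
  i.e. ~1.1 g at 25 g body mass) come from different cohorts and are not
  mutually consistent under any one body mass. The generator therefore
  anchors the per-animal dosimetry table to the dose means and the 10-min
  time-course table to the rate profile, rather than forcing both through
  a single profile.
* **Oral potency.** Oral-group triad responses are generated on the i.p.
  Emax curves at `oral_potency x consumed dose`. This reproduces the
  central phenomenon — consumption is right-shifted relative to injection
  (29.2 mg/kg consumed ≈ 3.7 mg/kg i.p.) — and is precisely the structure
  the dose-equivalence model is supposed to recover; without it, the top
  oral condition would invert beyond the tested i.p. range.
* **Noise placement.** Triad noise is additive Gaussian on the
  difference-score scale (the analyses consume group mean ± SEM summaries,
  so this is the scale that matters); consumption heterogeneity is a
  per-animal lognormal rate multiplier with mean 1 (keeps every cumulative
  series nonnegative and nondecreasing); startle noise is additive,
  scaled with the tone, floored at 0.
* **PK.** A one-compartment first-order absorption model with a
  sequential metabolite chain (THC → 11-OH-THC → 11-COOH-THC), solved
  analytically (generalized Bateman), *calibrated* — not fitted — to the
  printed concentration windows. The source data report concentrations
  only, no kinetic model; this component is plumbing that reproduces range
  behavior. One known approximation: with the parent's terminal rate
  dominating, the metabolites peak at ~3.3 h and ~5 h, slightly later than
  the reported 1–2.5 h window, though their 2.5 h concentrations fall in
  the printed ranges and all analytes are < 50 pmol/g at 26 h. Moving the
  metabolite peaks earlier would require faster parent elimination,
  breaking the THC 2-h anchor. PK and behavior streams are generated
  independently (no pharmacodynamic link), matching the absence of any
  significant PK-behavior correlation in the source data.
* **Sex effects** enter only where they are reported: the startle
  quadratics are per sex; triad and consumption parameters are shared
  across sexes.

What passing tests on this generator do and do not show: they demonstrate
that the estimators are consistent and correctly implemented *under the
generator's assumptions* — Gaussian additive triad noise, exact Emax mean
structure, lognormal dose spread, independent animals. Real data add
floor/ceiling censoring (tail-flick cutoffs), within-session tolerance,
correlated repeated measures and non-Gaussian tails, none of which are
emulated; recovery performance here is an upper bound.

## Simulation study conditions

The stochastic suites run at the design scale of the study: 6 i.p. dose
levels (0, 0.3, 1, 3, 10, 30 mg/kg), n = 10 per dose, 200 replicates, with
20 % coefficient-of-variation noise — per-dose SD equal to 0.2 x |mean
response at that dose|, the literal CV definition. Under these conditions
median absolute ED50 recovery error is ~12 % (ED50 1.3), ~15 % (3.9) and
~19 % (14.4) — the last largest because the top dose reaches only 68 % of
that curve's span — and the end-to-end aggregate predicted dose recovers
true oral-equivalent doses of 3.7 and 8.8 mg/kg to well within 20 %.
Statistical calibration (type-I error of the from-scratch ANOVA and
regression F tests) is checked at 1000 Gaussian-null replicates against a
3-sigma binomial band around 0.05. The acceptance script runs the full
pipeline at n = 20 per sex per group.

## Known limitations

* Inversion consumes the *group-mean* oral response (matching how the
  dotted-line construction is done graphically); per-animal inversion
  exists only behind the bootstrap.
* Which sex's triad curves feed the sex-specific startle polynomials is
  underdetermined in the source design; the package uses pooled-sex triad
  fits with sex-specific startle, and states so in the report.
* The 1 hr reference samples used by `normalize_to_reference()` come from
  a shorter-access condition; ratios are reported with that provenance
  note. Normalization is on group means, not per animal.
* No four-parameter (free Hill slope) fitting, no mixed-effects
  dose-response, no unbalanced ANOVA, no caloric-intake modelling, no
  tail-flick censoring.
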