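---
title: "Season-level training analysis for triathletes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Season-level training analysis for triathletes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triseason)
```

## What the package computes

`triseason` implements the analysis chain used to describe a full training
season of a short-distance triathlete:

1. **Incremental-test processing.** A cycling ramp test (100 W start,
   +5 W every 12 s), a running track test (12.1 km/h start, +0.3 km/h every
   200 m) and a 7×200 m swim lactate test are reduced to physiological
   markers: VO~2max~, the two ventilatory thresholds (VT1/VT2) with their
   work rates/speeds and heart rates, and the two lactate thresholds
   (LT1/LT2) with their swim speeds.
2. **Zone and load models.** Eight training zones per discipline are
   anchored at the thresholds; the triphasic model maps zones to phase 1
   (at or below VT1/LT1), phase 2 (between thresholds) and phase 3 (at or
   beyond VT2/LT2). Sessions are scored in ECOs — minutes-in-zone × zone
   score (an integer in 1–50) × discipline factor (run 1.0, swim 0.75,
   bike 0.5) — and rolled up to weekly and season load, training-intensity
   distribution (TID) and the polarization index
   PI = log₁₀((%Z1 / %Z2) · %Z3), with PI > 2.00 a.u. labelling a week or
   season "polarized".
3. **Body composition.** ISAK measurements (6 skinfolds, 4 girths) yield
   the fold sum, fat % (Withers female density equation + Siri transform)
   and skeletal muscle mass (Lee model on fold-corrected girths), tracked
   across the season.
4. **Test-to-test comparison.** Percent changes
   `100·(test2 − test1)/test1`, half-up rounded to one decimal, for the
   full marker set, and cross-athlete TID averages.

A synthetic-season generator produces all inputs with *planted truth*, so
each stage is validated by plant-and-recover studies rather than by
unavailable raw logs.

## Threshold detection: operationalizing the Davis criteria

The gas-exchange criteria are qualitative: VT1 is an increase of VE/VO₂ and
P~ET~O₂ with no increase of VE/VCO₂; VT2 adds the VE/VCO₂ increase and a
P~ET~CO₂ decrease. The package makes them concrete in two steps:

* **Gating.** The trace is binned (30 s for cycling; one bin per 200 m
  stage for running, since stages are natural averaging units and the 12 s
  ramp steps are too short to be bins). Windows of 3 consecutive bins are
  scanned; a channel counts as *rising* when its fitted rise over the
  window exceeds a tolerance, and as *flat* when it stays within a larger
  one. Both tolerances floor at 5% of the channel's interquartile range and
  scale with the channel's bin-level noise, estimated robustly from second
  differences (MAD/√6). On noiseless data the noise estimate is ~0, so the
  tolerances collapse and the gate is strict. If no window qualifies the
  detector returns a *not-detected* value rather than an error.
* **Localization.** Once a qualifying region exists, the threshold time is
  the breakpoint of a single-hinge segmented regression
  `y = a + m·max(0, t − τ)` fitted to the *raw* samples of the relevant
  channel (VE/VO₂ for VT1, VE/VCO₂ for VT2), with candidate breakpoints on
  a 1 s grid plus the protocol's own step times, and VT2 constrained to
  τ ≥ VT1. Work rate or speed is then read from the analytic protocol
  schedule at τ, not from a bin average.

The sub-bin localization is what makes noise-free recovery *exact*: a bin
of 30 s spans 12.5 W of the ramp, so any purely bin-resolution detector
would be quantized away from a planted work rate such as 155 W. With the
hinge fit, the noiseless breakpoint has zero residual exactly at the
planted step time and the schedule lookup returns the planted value
verbatim. Under the generator's calibrated noise (σ = 1.5 mL/kg/min on
VO₂), the median work-rate error across Monte-Carlo replicates is about
5 W (one ramp step), well below a physiologically meaningful difference.

VO~2max~ is the maximum over all continuous 60 s windows (anchored at
sample times) of the time-weighted trapezoidal mean of VO₂; HRmax is the
maximum recorded heart-rate sample.

The lactate rules are value-based and need no smoothing: LT1 is the first
stage exceeding the stage-1 baseline by ≥ 0.5 mmol/L, LT2 the first later
stage rising > 1.0 mmol/L above its predecessor; speeds are interpolated
linearly to the exact crossing concentration. LT1 is referenced to baseline
but LT2 to the previous stage: the fixed-rise wording is ambiguous, and
this reading matches common lactate-threshold practice. Both rises are
configurable (`detect_lactate_thresholds(curve, rise1, rise2)`), and
raising either can only move a threshold later — never earlier.

## Zone model choices

The data constrain only the phase boundaries (VT1/LT1 and VT2/LT2) and the
score range. The remaining structure is configuration with these defaults:

* Phase 1 splits into zones 1–3 at 60% and 80% of the first-threshold
  intensity; phase 2 into two equal halves; phase 3 into zones 6–8 at the
  midpoint between the second threshold and the maximal intensity (power
  or speed at VO~2max~, extrapolated from the VT2 VO₂ ratio when needed).
* The default score table {1, 2, 3, 5, 8, 15, 30, 50} is an arbitrary
  monotone choice inside the documented 1–50 range. Absolute ECO totals
  therefore depend on this configuration entry, and no validation in this
  package depends on the specific table — only on ECO linearity,
  additivity and the discipline-factor ordering, which hold for any
  monotone table.
* The season polarization index is the **mean of the defined weekly PIs**,
  not the PI of the season-mean TID. The two differ (Jensen's inequality),
  and only weekly averaging reconciles a season labelled non-polarized
  with a mean TID whose direct PI would exceed 2.0 — the behaviour
  observed in practice when single weeks turn pyramidal.
* Sample standard deviations (n − 1) throughout. Strength and core work
  carries zero ECOs and no TID minutes.

## The synthetic season: what it emulates

The generator's defaults are the study conditions the analysis is meant
for; they are fixed once, not tuned per run.

* **Profiles** (`generate_profile`): uniform draws inside the ranges
  spanned by elite U23 female triathletes — VO~2max~ 59–68 mL/kg/min, peak
  power 260–315 W, peak running speed 16.9–18.4 km/h, swim LT2 1.25–1.35
  m/s, LT1 0.05–0.10 m/s below LT2, HRmax 180–197 bpm by discipline, body
  mass 49–62 kg, threshold fractions ~0.70/0.85 of VO~2max~.
* **Traces**: VO₂ rises piecewise-linearly from rest (8 mL/kg/min) to
  VO~2max~, then plateaus ≥ 60 s (so the 1-min rule recovers the planted
  maximum exactly); exponential on-kinetics would add parameters without
  changing what the breakpoint detectors see. Ventilatory equivalents and
  end-tidal pressures are flat-then-linear with kinks exactly at the
  planted thresholds, and the planted crossing times snap to the
  protocol's own step grid so the planted work rates/speeds are clean
  protocol values. Samples every 5 s (a typical mixing-chamber averaging
  interval; the true analyzer rate is device-dependent). Noise is additive
  Gaussian: σ as given on VO₂, the same *relative* σ on VE and VCO₂
  (ventilation scales with metabolism), and the same *absolute* σ in mmHg
  on the end-tidal pressures (instrument-level noise).
* **Lactate curves**: baseline + exponential rise in speed,
  `la(v) = la₀ + c₁(exp(c₂(v − v₁)) − 1)`, with (c₁, c₂) calibrated
  numerically (Nelder–Mead on the detector output) so that the fixed-rise
  rules recover the profile's planted LT speeds on the noiseless 7-stage
  curve; optional multiplicative lognormal noise keeps concentrations
  positive. Noise defaults to off so that plant-and-recover studies define
  the generator's contract.
* **Seasons** (`default_season_plan` + `generate_season`): 50 weeks,
  traditional periodization to a first competition block (general
  preparation weeks 1–16, specific 17–26, competitions 27–34) then a short
  block sequence (accumulation 35–37 peaking at 17.6 h, transformation
  38–40, taper), mean 12.2 h/week with recovery weeks every fourth week.
  Weekly target TID 82/6/12% of time with occasional pyramidal weeks.
  Realized weekly hours jitter within ±2% of target and realized TID
  within ~±1.5 pp; the discipline time split (34.5/41/24.5% swim/bike/run)
  is chosen so the ECO split lands near one third per leg with cycling
  lowest, as its 0.5 factor implies. Zone minutes within a phase use fixed
  weights (phase 1 mostly zones 2–3, phase 3 mostly zone 6); the sum of a
  session's zone minutes *is* its duration, so time conservation is
  structural.
* **Anthropometric series**: five measurements (weeks 1, 12, 22, 33, 44),
  skinfolds declining ~12% with a ~3% final rebound, stable girths and
  body mass — the typical season pattern.

What the generator does **not** emulate: breath-by-breath variability
structure (noise is white), cardiovascular drift, inter-device bias,
missed training days/injury gaps, or real GPS/HR session files. Passing
recovery tests therefore demonstrates the *algorithms* are correct and
noise-tolerant at realistic magnitudes, not that any specific field
data set will be detected flawlessly.

## Body-composition equations

The Withers female-athlete density equation
(D = 1.20953 − 0.08294·log₁₀(triceps + subscapular + supraspinal + medial
calf, mm)) and the Lee skeletal-muscle model
(SM = Ht·(0.00744·CAG² + 0.00088·CTG² + 0.00441·CCG²) + 2.4·sex −
0.048·age + race + 7.8, girths corrected by π·fold/10) are vendored as a
constants file (`inst/extdata/anthro_equations.yaml`) with a frozen worked
example, so the coefficients are auditable and swappable. The four-fold
female equation is used because its folds are a subset of the six measured
ISAK sites. Densities outside (0.9, 1.2) g/mL are flagged implausible and
returned as `NA`. Fat % uses the Siri transform by default (Brozek
available). Lean mass is reported as body mass × (1 − fat%/100), which is
fat-free mass, not the Lee muscle mass.

## Numerical conventions and edge cases

* Percent changes are half-up rounded ("commercial" rounding) to one
  decimal for display, matching printed precision conventions; exact
  values are available with `digits = NULL`. Note the exact antisymmetry
  identity is `pc(a,b) = −pc(b,a)·b/a`.
* PI is undefined (NA, never an exception) when any phase share is zero;
  undefined weeks are skipped in the season mean.
* Ties in breakpoint search resolve to the earliest candidate, with
  protocol step times preferred among near-equal minima.
* Dates are ISO-8601; weeks are 1-based indices carried in the log itself
  (Monday-anchored when generated). Durations are minutes; speeds m/s for
  swim, km/h for run, W for bike.
* All generators derive an independent RNG stream from the user seed plus
  a purpose tag and restore the caller's RNG state afterwards, so
  identical seeds reproduce artifacts bit-for-bit without disturbing the
  session.

## Worked example

```{r example, eval = FALSE}
profile <- generate_profile(seed = 1)
bike <- generate_cycle_trace(profile, noise_sd = 0, seed = 1)
run <- generate_run_trace(profile, noise_sd = 0, seed = 1)
swim <- generate_lactate_curve(profile, seed = 1)

report <- threshold_report(bike_trace = bike, run_trace = run,
                           lactate = swim, body_mass = profile$body_mass)
report$bike$vt1$intensity          # equals planted_truth(bike)$vt1$intensity

sessions <- generate_season(profile, default_season_plan(), seed = 1)
season <- summarize_season(summarize_weeks(sessions))
season[, c("hours_mean", "pct_time_z1_mean", "polarization_index")]

bundle <- run_pipeline(list(
  test1 = list(bike = bike, run = run, swim = swim,
               body_mass = profile$body_mass),
  sessions = sessions,
  anthro = generate_anthro_series(profile, seed = 1)))
```

Problem sizes in the shipped validation suite — 50-week seasons, 25–50
Monte-Carlo trace replicates, 20 lactate curves, 100-trace oracle sweeps —
were chosen as the smallest sizes at which the aggregate statistics
(medians, means, rates) are stable across seeds.

## Known limitations

* The Davis criteria are implemented as slope tests plus hinge
  regression; alternative operationalizations (V-slope on VCO₂ vs VO₂,
  D-max or log-log lactate methods, respiratory-compensation modelling)
  are deliberately out of scope.
* ECO absolute scale depends on the configurable score table; only
  relative and structural ECO statements are validated.
* The season generator draws sessions independently within a week; it has
  no day-to-day autocorrelation or competition-day modelling.
* Anthropometric estimates inherit the population assumptions of the
  vendored equations (adult female athletes; white/Hispanic race
  coefficient 0 by default) and carry no measurement-error (TEM) model.
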