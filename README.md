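# triseason

Season-level training analysis for short-distance triathletes: an R
package for coaches and sports scientists who quantify a full season of
swim/bike/run training from incremental tests, a minutes-in-zone training
log and ISAK anthropometry.

## What it computes

**Incremental-test markers.** From a cycling ramp test (100 W + 5 W every
12 s), a running track test (12.1 km/h + 0.3 km/h every 200 m) and a
7×200 m swim lactate test:

- VO₂max — the highest VO₂ sustained over any continuous 1-min window;
- VT1/VT2 — the ventilatory thresholds by the Davis gas-exchange criteria
  (VT1: VE/VO₂ and P_ET_O₂ rise while VE/VCO₂ stays flat; VT2: VE/VCO₂
  rises and P_ET_CO₂ falls), localized sub-bin by single-hinge segmented
  regression and reported with their work rate / speed and HR;
- LT1/LT2 — swim lactate thresholds by the fixed-rise rules (+0.5 mmol/L
  over baseline; >1.0 mmol/L over the previous stage), with speeds
  interpolated to the exact crossing concentration.

**Zones, load and TID.** Eight training zones anchored at the thresholds;
the triphasic model (phase 1 ≤ VT1/LT1 < phase 2 < VT2/LT2 ≤ phase 3);
session training load in ECOs,

    ECO = discipline factor × Σ_zones minutes_z × score_z,

with factors 1.0 (run), 0.75 (swim), 0.5 (bike) and integer zone scores in
1–50; weekly and season summaries of hours, ECOs, the training-intensity
distribution (TID) and the polarization index
PI = log₁₀((%Z1/%Z2)·%Z3), where PI > 2.00 a.u. is "polarized".

**Body composition.** Sum of six skinfolds, fat % (Withers female density
equation + Siri transform), skeletal muscle mass (Lee model with
fold-corrected girths) and their season evolution.

**Comparison tables.** Percent changes between two test sessions per
discipline (half-up rounded to 1 decimal) and cross-athlete TID averages.

**Synthetic seasons.** A generator plants athlete profiles, gas-exchange
traces, lactate curves, training logs and anthropometric series with known
truth, so every stage above is validated by plant-and-recover studies.

## Worked example

```r
library(triseason)

profile <- generate_profile(seed = 1)
bike <- generate_cycle_trace(profile, noise_sd = 0, seed = 1)
v1 <- detect_vt1(bike); v2 <- detect_vt2(bike, vt1 = v1)
sprintf("VO2max %.1f | VT1 %.0f W @ HR %.0f | VT2 %.0f W",
        detect_vo2max(bike), v1$intensity, v1$hr, v2$intensity)
#> "VO2max 59.3 | VT1 215 W @ HR 162 | VT2 250 W"
planted_truth(bike)$vt1$intensity   # the generator planted VT1 at 215 W
#> [1] 215

sessions <- generate_season(profile, default_season_plan(), seed = 1)
season <- summarize_season(summarize_weeks(sessions))
round(season[, c("hours_mean", "hours_max", "pct_time_z1_mean",
                 "pct_time_z2_mean", "pct_time_z3_mean",
                 "polarization_index")], 2)
#>   hours_mean hours_max pct_time_z1_mean pct_time_z2_mean pct_time_z3_mean polarization_index
#> 1      12.24     17.98               82             6.71            11.29               2.14
season$tid_class
#> [1] "polarized"
```

The season averages 12.2 h/week with a >15 h peak and a polarized TID of
roughly 82/7/11% of time in phases 1/2/3 — the weekly structure the
default plan encodes. On the bundled example data of three elite U23
female triathletes:

```r
average_tid(example_season_summary())$rounded
#> z1 z2 z3
#> 82  6 12
classify_tid(example_season_summary()$polarization_index)
#> [1] "non-polarized" "polarized" "polarized"
percent_change(260, 280, digits = 1)   # power at VO2max, test 1 -> test 2
#> [1] 7.7
```

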