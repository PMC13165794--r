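# wheelmetrics

Processing and statistics for instrumented manual wheelchairs. The target
system carries three sensors: gyroscopes on both wheel hubs (100 Hz,
±2000 °/s), a 4 × 4 piezoresistive pressure mat on the seat (100 Hz, on its
own free-running clock) and a smartphone GPS receiver (1 Hz,
micro-degrees). From a single ride over an urban course the package
answers: how fast was the rider on each stretch of the route, where was the
seated centre of pressure (COP), and how much of that behaviour was imposed
by the course versus chosen by the rider?

It is written for researchers in wheelchair biomechanics and mobility
analytics who want the full processing chain — clock synchronisation,
odometry, COP estimation, distance-domain alignment and the rank-based
compliance statistics — as tested, reusable functions, together with a
synthetic-run generator so that everything can be exercised and validated
without access to raw recordings.

## Methods at a glance

* **Clock synchronisation.** Both streams record two pentads of five wheel
  strikes. With anchor timestamps $(t_{Bm}, t_{Bs})$ and $(t_{Em}, t_{Es})$
  the mat's slave clock maps to the IMU master clock through the affine
  model $t_{sm} = m\,t_s + \Delta t_B + b$, where
  $m = (t_{Bm}-t_{Em})/(t_{Bs}-t_{Es})$, $\Delta t_B = t_{Bm}-t_{Bs}$ and
  $b$ makes both anchors map exactly. The spare spikes estimate the
  residual SD.
* **Odometry.** Cambered differential drive: effective rolling radius
  $r\cos\theta$, ground-contact track $w + 2r\sin\theta$; frame speed
  $v = r\cos\theta\,(\omega_L+\omega_R)/2$, yaw rate
  $(\omega_R-\omega_L)\,r\cos\theta/w_g$, distance by trapezoidal
  integration with a roll-out correction factor.
* **Seat mat.** Divider voltages → conductance → pressure via a 6th-order
  calibration polynomial per cell → force; COP as the force-weighted
  centroid of the cell positions.
* **GPS.** 10 µ° latitude = 1.11 m; longitude scaled by cos(latitude);
  path distance, crude speed, and ramp-based integer-second alignment to
  the IMU clock.
* **Section statistics.** Signals resampled onto a 1 m distance grid and
  segmented into the 13 course sections; one-way ANOVA + Tukey HSD over all
  78 section pairs; Cohen's d with pooled SD; a network edge wherever the
  participant-averaged d ≥ 0.8 (weight capped at d ≥ 2).
* **Route compliance.** Pairwise R² of participant profiles per parameter;
  per-participant median/IQR; low-side outlier rule (Q1 − 1.5 IQR); rank
  sums across the three parameters; Kendall's W with its χ² test.

## Worked example

Simulate a strongly route-driven rider on the default 13-section, 789 m
course, push the recording through the full pipeline, and inspect the
per-section table:

```r
library(wheelmetrics)
course  <- build_course()
profile <- make_cohort_profiles()$P5        # compliance weight 0.9
run     <- simulate_run(course, profile,
                        distortion = clock_distortion(1.01, 5), seed = 42)
report  <- process_run(run, course)
report
#> Run report: 789.0 m in 779 s (mean 1.01 m/s); sync SD 0.00521 s
head(report$sections[, c("section", "n", "v_mean", "v_sd", "copx_mean", "copy_mean")], 5)
#>   section   n v_mean v_sd copx_mean copy_mean
#> 1       1  47   0.76 0.20     -1.23    -18.82
#> 2       2 124   0.91 0.20     -2.58    -18.47
#> 3       3  99   1.15 0.25     -4.02    -17.60
#> 4       4  55   1.25 0.27     -1.81    -16.53
#> 5       5  39   0.96 0.18     -2.87    -20.11
```

The run covered the full course; the planted 1.01 clock skew was recovered
(residual SD ≈ 5 ms), and the per-section speeds follow the course profile
(slow start in the car park, downhill sections faster) scaled by this
rider's 0.9 speed factor.

Cohort-level analysis on a simulated seven-rider cohort:

```r
aligned <- simulate_aligned_cohort(course, make_cohort_profiles(), seed = 42)
cohort  <- cohort_report(aligned)
cohort$compliance
#> Route-compliance report
#> Median R^2 (participant x parameter):
#>        v  copx  copy
#> P1 0.039 0.072 0.039
#> P2 0.363 0.319 0.237
#> ...
#> P5 0.525 0.456 0.379
#> Rank sums:
#> P1 P2 P3 P4 P5 P6 P7
#>  3 11  9  8 20 19 14
#> Kendall's W = 0.8889 (chi2 = 16.000, df = 6, p = 0.0138)
sum(cohort$networks$v$edge)
#> [1] 28
```

The rank sums identify P5 (compliance weight 0.9) as the most route-driven
rider and P1 (weight 0.2) as the most individualistic, and 28 of the 78
section pairs differ in speed with a large-or-bigger average effect.

## Analysis workflow

The numbered scripts under `analysis/` run the full study pipeline over a
simulated cohort, writing all tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1   # raw recordings (CSV) per rider
Rscript analysis/02_process_runs.R        # sync, kinematics, COP, alignment
Rscript analysis/03_section_effects.R     # ANOVA/Tukey/Cohen's d + networks
Rscript analysis/04_route_compliance.R    # R², medians, ranks, Kendall's W
```

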