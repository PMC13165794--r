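---
title: "Multi-sensor wheelchair analytics: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor wheelchair analytics: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wheelmetrics)
```

wheelmetrics processes recordings from a manual wheelchair instrumented with
wheel-hub gyroscopes (100 Hz), a 16-cell piezoresistive seat mat (100 Hz, on
its own free-running clock) and a 1 Hz GPS receiver, and quantifies how
strongly an urban course drives the rider's speed and seated posture. This
vignette documents the models, every tunable parameter that matters, the
synthetic-run generator used in place of raw recordings, and the numerical
and design choices that were genuinely open.

## Clock synchronisation

The mat clock and the IMU clock differ by an offset and a skew (they run at
different rates). Both streams record the same physical events — two pentads
of five deliberate wheel strikes, at the start and at the end of a session —
as high-amplitude spikes. Assuming a linear clock model, a slave timestamp
$t_s$ converts to the master scale as

$$t_{sm} = m\,t_s + \Delta t_B + b,$$

with skew $m = (t_{Bm}-t_{Em})/(t_{Bs}-t_{Es})$ the ratio of the anchor
spans, $\Delta t_B = t_{Bm}-t_{Bs}$ the start-anchor differential, and
$b = t_{Bm} - \Delta t_B - m\,t_{Bs}$ chosen so that *both* anchor pairs map
exactly (the unique affine map through the two anchors). The anchor of each
pentad is its maximum-amplitude spike. The remaining eight spikes estimate
the synchronisation error as the SD of master-minus-mapped-slave differences
(`sync_residuals()`).

Spike detection thresholds at 6 robust SDs (MAD) above the median, with a
0.2 s de-bounce that keeps the largest sample of a burst. For the mat the
detector runs on the absolute first difference of the summed channels, which
removes the seated-load baseline; candidate events in each window are pruned
to the five largest. Two precision regimes follow from 100 Hz sampling:
the fitted map reproduces its anchors to machine precision always, while the
*planted* skew of a simulated distortion is recovered to about $10^{-5}$
relative — the slave-side strike times are quantised to the nearest 10 ms
sample, and no sub-sample spike interpolation is attempted. On the exact
(unquantised) event times the two-point inversion recovers skew and offset
to better than $10^{-6}$.

## Wheel odometry

The source system computes frame kinematics from the two wheel gyroscopes
with a method whose equations are not republished here; `frame_kinematics()`
is therefore a documented reconstruction using the standard cambered
differential-drive model. With wheel radius $r$, camber $\theta$ (wheels
tilted tops-in) and hub track width $w$:

* effective rolling radius $r_\mathrm{eff} = r\cos\theta$ ("true wheel
  speed"),
* ground-contact track $w_g = w + 2r\sin\theta$ (contact points sit wider
  than the hubs),
* $v = r_\mathrm{eff}(\omega_L+\omega_R)/2$, yaw rate
  $\dot\psi = r_\mathrm{eff}(\omega_R-\omega_L)/w_g$ (counter-clockwise
  positive), turning radius $v/|\dot\psi|$.

Defaults $r = 0.305$ m, $\theta = 3.2°$, $w = 0.56$ m. Whether the original
method uses $r$ or $r\cos\theta$ as rolling radius is not recoverable;
$\cos 3.2° = 0.9984$, and the roll-out calibration absorbs the difference:
rolling the chair over a 300 m reference distance yields a correction factor
(reference/computed) applied multiplicatively to speed, acceleration and
distance. Numerical choices: acceleration is the central difference of a
0.5 s moving-average-smoothed copy of $v$ (100 Hz gyro noise would dominate
a raw derivative; the reported $v$ stays raw), distance is the trapezoidal
integral, and the turning radius is reported as `NA` when
$|\dot\psi| < 10^{-3}$ rad/s to avoid division blow-up on straights.

## GPS

Micro-degree fixes convert to local metres with the study's printed scale —
10 µ° latitude = 1.11 m north, 10 µ° longitude = 1.11 m × cos(latitude)
≈ 0.88 m east at the course latitude — deliberately reproducing the printed
arithmetic rather than the WGS-84 ellipsoid value (the difference is
irrelevant over 800 m). One fixed cosine at the track's mean latitude is
used; the error over this course is below 0.01%. Path distance is the sum of
segment lengths; speed is the per-second resultant of the coordinate
differences.

GPS-to-IMU time alignment uses the standstill ramps at the start and end:
the IMU speed is averaged to 1 Hz and the integer-second offset maximising
the windowed correlation over the two ramps is returned. Because the
magnitude of a noisy velocity vector is biased high near standstill, the
estimator first subtracts the standstill noise power from the squared speed
($E|{\bf v}+{\bf n}|^2 = v^2 + 2\sigma^2$), then smooths both series over
5 s. With the generator's 1 m correlated position noise the planted offset
is recovered exactly in ≈95% of runs and within ±1 s otherwise.

## Seat mat and centre of pressure

The 300 × 350 mm mat carries a 4 × 4 array of 50 × 65 mm cells on 20 mm
gaps, so the centroids sit at $x \in \{-105,-35,35,105\}$ mm and
$y \in \{-127.5,-42.5,42.5,127.5\}$ mm from the mat centre (+x right,
+y forward; the convention makes the rearward seated posture a negative
COPy, consistent with the course table). Each cell is read through a 70 Ω
reference resistor; the recorded drop $v$ across it gives the sensor
conductance $G = v/(R_\mathrm{ref}(V_\mathrm{supply}-v))$, with
$V_\mathrm{supply} = 3.3$ V an artifact choice (only the resistor value is
documented by the source system). Bench calibration loads each cell about
20 times between 200 Pa and 0.33 MPa; the per-cycle peak pressure and peak
conductance pairs are fitted with a 6th-order least-squares polynomial
(conductance scaled to [0, 1] first — the raw Vandermonde system at
$G \sim 10^{-3}$ S is numerically hopeless). Decoding clips the polynomial
to the calibrated pressure range, so an unloaded cell reports the lower
calibration bound, and force is pressure × nominal cell area.

The COP is the force-weighted average of the cell centroids. All-zero (and
low-load, < 50 N) frames yield flagged `NA` gaps rather than errors — the
rider stands during the trigger strikes. The COP inherits two exact
invariances used as property tests: translation covariance in the centroids
and scale invariance in the forces. `cop_agreement()` provides the
validation metrics against a reference system (slope/intercept of the
regression, Pearson and Spearman R²).

## Distance-domain alignment and section statistics

Comparisons are made by location, not by time: each signal is resampled
onto a uniform distance grid via the cumulative odometer distance
("synchorisation"). Two deliberate choices:

* **Bin-centre grid.** The grid is $d_k = (k-\tfrac12)\,\mathrm{step}$
  (default step 1 m), not $k\,\mathrm{step}$. Section boundaries of the
  course table are integers; sampling at bin centres keeps every grid point
  0.5 m away from a boundary, so a noise-free simulation reproduces every
  per-section mean exactly instead of mixing neighbouring sections at the
  boundary points.
* **COP smoothing.** COP channels may be smoothed with a 4 m moving average
  after resampling (the presentation convention of the source figures);
  speed is never smoothed. The exactness validation runs with smoothing off,
  because a 4 m window necessarily mixes section means across boundaries.

Standstill samples are collapsed before interpolation (distance must
advance); moving samples are never excluded. Sections are half-open
intervals $[D, D+\Delta D)$ with the final boundary closed.

Per participant and parameter, the 13 sections are compared with a one-way
ANOVA, Tukey's HSD over all 78 pairs, and Cohen's d with the pooled SD.
These single-trial comparisons are serially correlated (pseudoreplication)
and are used descriptively; no autocorrelation correction is applied,
matching the source procedure. The effect-size network connects two
sections when the participant-averaged d is at least 0.8 (a large effect),
with line weight mapping linearly to 1 at d ≥ 2 (huge). Whether the source
additionally required per-participant significance or significance on
average is not fully specified; this implementation requires Tukey
significance in a majority of participants in addition to the mean-d
threshold, which filters single-trip noise without demanding unanimity.

## Route compliance

For each parameter, the profiles of all participant pairs are correlated on
the common grid; the squared Pearson correlation measures route influence
(the course is the only shared variable). Per participant, the six R²
values are summarised by median and IQR. Conventions fixed here because the
source names none: quartiles by linear interpolation between order
statistics (R type 7), used consistently for the IQR and for the low-side
outlier rule (median < Q1 − 1.5 IQR across the cohort's medians). The rank
table ranks medians within each parameter (rank 1 = smallest, average ranks
on ties) and sums ranks across the three parameters. Kendall's W treats the
three parameters as judges and the participants as items:

$$W = \frac{12 S}{m^2(n^3-n) - m\sum(t^3-t)}, \qquad
\chi^2 = m(n-1)W \text{ on } n-1 \text{ df.}$$

Applying this standard formula to the published rank table gives
$S = 172$, $W = 2064/3024 = 0.6825$ and $\chi^2 = 12.29$ ($p = 0.056$),
whereas the source prints $W = 0.7857$ ($p = 0.0281$, consistent with
$\chi^2 = 18 \times 0.7857$). No variant derivable from the published text
reproduces the printed value; the package implements the standard formula,
verifies it against a hand computation and against the algebraically
equivalent $\sum R_i^2$ form (agreement to $10^{-12}$), and treats the
printed W as not reproducible.

## The synthetic-run generator

Raw recordings of the study are available only on request, so the
generator `simulate_run()` produces complete runs with known ground truth
that carry the statistical structure the analysis needs. Ground-truth speed
at distance $d$ is

$$v(d) = \mathrm{scale}\times\Big[\lambda\big(\mu_v(s(d)) + s_v(d)\big)
  + (1-\lambda)\big(\bar v + \xi(t)\big) + \eta(d)\Big],$$

floored at 0.1 m/s, and COPx/COPy follow the same structure around the
per-section COP means. The components:

* $\mu_v(s)$: the 13 per-section means of the course table.
* $s_v(d)$: a **course-shared micro-profile** — a smooth field over
  distance, identical for every participant of a cohort (one `course_seed`),
  scaled per section to 95% of the within-section variance. Shared terrain
  features (turns, surface defects, traffic pinch points) dominate
  within-section fluctuation in the real data; without a dominant shared
  component, compliant participant pairs could never reach the R² ≈ 0.5 the
  study reports. The 95/5 variance split was calibrated so a fully
  route-driven pair lands near that value; the simulated λ = 0.9 participant
  attains a median R² ≈ 0.48–0.52.
* $\eta(d)$: the unshared residual (5% of within-section variance), a
  fast-decorrelating AR(1) field over distance (0.25 m resolution,
  correlation ≈ 0.01 at 1 m) — push-cycle and rider-specific texture.
* $\xi(t)$: the individual, non-course process — AR(1) at 100 Hz with
  $\varphi = 0.98$ and stationary SD 0.31 m/s (the mean section SD), giving
  smooth, realistic speed wander for individualistic riders.
* $\lambda \in [0,1]$: the compliance weight. The default cohort uses
  λ = (0.2, 0.5, 0.5, 0.5, 0.9, 0.8, 0.5) with speed scales matching the
  spread of the published per-participant medians, spanning the
  individualistic-to-route-driven spectrum.

Wheel rates are obtained by inverting the odometry model, with half-sine
90° yaw pulses (2.5 s) at the turn boundaries; yaw does not perturb speed,
so turns do not bias section means. Mat cell forces allocate a 600 N seated
load (an artifact choice — the source states no seated load) as a 1 N
per-cell preload plus a bilinear two-cell-per-axis distribution whose
force-weighted centroid equals the planted COP exactly; the preload keeps
unloaded cells above the decoder's clip-to-range floor so the COP
round-trips exactly. One default profile sits 80 mm off-centre — the
largest lateral offset representable inside the centroid hull of a 4 × 4
array (the published off-centre shift of 150 mm lies outside any
force-weighted centroid of this geometry). Cell responses follow a
linear-plus-quadratic conductance law (inside the calibration polynomial's
model class) with a ±5% per-cell gain spread fixed by `mat_seed` — a
property of the physical mat, not of a run. Trigger strikes land on the
master sample grid with amplitude 10× the channel's 99th percentile
(floored for silent channels) in a fixed within-pentad amplitude pattern;
the mat records them at its nearest slave sample, plus optional Gaussian
timing jitter. GPS noise is AR(1)-correlated per axis
($\varphi = 0.99$ at 1 Hz, SD 2 m): phone receivers emit filtered, serially
correlated fixes, and white 2 m noise would produce a folded-noise
"speed" of ≈2.5 m/s at standstill, which no ramp alignment (including the
study's own) could survive. Multipath is an optional constant offset over a
distance window. The true path is the 13-leg polyline with 1.5 m corner
arcs, parameterised by arc length so its length equals the course length
exactly.

What the generator does **not** emulate: slopes and gravity (downhill
sections are faster only through their table means), surface vibration,
sensor hysteresis/viscoelastic phase shift, real multipath geometry, or
pedestrian/traffic agents. Passing tests therefore validate the processing
and statistics, not the physics of any particular street.

## Validation experiments and problem sizes

* **Noise-free round trip.** With λ = 1 and all noise off, the full sensing
  pipeline (gyro → sync → kinematics → voltages → COP → alignment)
  reproduces all 39 per-section means to better than $10^{-6}$ relative
  (measured: ~$10^{-13}$).
* **Planted effect.** Seven *independent* replicates (shared micro-profile
  disabled — with it on, the seven riders would be near-clones and
  averaging d across them would not reduce variance) at full Table-SD
  within-section noise; the section-1-vs-13 speed contrast (0.80 vs
  1.81 m/s, SDs 0.23/0.64) must appear as a network edge with mean d ≥ 2.
  Run over 50 seeds at the 1 m grid (n = 47 and 42 samples).
* **Compliance recovery.** The default cohort's rank sums must identify the
  λ = 0.9 participant as most route-driven and the λ = 0.2 participant as
  most individualistic; 50 seeds.
* **Null calibration.** ANOVA p-values across 13 identical sections are
  uniform (KS test over 400 seeds).

The problem sizes (50 seeds, 1 m grid, 100 Hz runs of ≈650 s) keep each
experiment in the minutes range while leaving the Monte-Carlo rates well
away from their thresholds.

## Known limitations

* Skew recovery through the detector is bounded by the 10 ms sampling
  quantisation of strike times (~$10^{-5}$ relative over a 670 s span).
* GPS/IMU alignment is exact only up to ±1 s under 1 m correlated noise.
* The printed concordance value (W = 0.7857) is not reproducible from the
  published ranks with the standard estimator; this package reports 0.6825.
* Correlated GPS noise still inflates `path_distance()` by a few percent at
  the default σ = 2 m; the printed path lengths imply effectively smoother
  tracks than any white- or AR-noise model at that σ.
* The N-of-1 section statistics are descriptive; serial correlation is not
  corrected.
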