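---
title: "Models and methods behind cervgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cervgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervgame)
```

This vignette explains the models implemented in cervgame, the choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not establish about real recordings.

## Frames and the YZX decomposition

The world frame has Z up (gravity along −Z) and X along magnetic north; the
head frame has X anterior, Y left, Z up. A head orientation is a rotation
`R` mapping head-frame vectors to world coordinates, carried redundantly as
a unit quaternion and a direction cosine matrix (validated to be orthonormal
with determinant +1 within 1e−6 on construction; all derived DCMs hold this
to 1e−9).

Cervical motion decomposes with the YZX Euler convention,
`R = R_Y(α) · R_Z(rot) · R_X(incl)`: flexion-extension α first (about the
lateral Y axis, positive = flexion, nose down), axial rotation second
(about Z, positive = looking left), lateral inclination last (about the
anterior X axis, positive = right tilt). Extracting flexion-extension as
the first factor is what makes the vertical cursor coordinate depend only
on α; that matches a controller in which the vertical coordinate is always
driven by flexion-extension. The decomposition is unique while the middle
angle stays off ±90°; we declare gimbal lock when the middle-angle cosine
falls below 1e−7 and raise a typed error naming the aligned axes rather
than returning an arbitrary branch. Axial rotation beyond ±85° is outside
the game's working envelope (targets need at most ~30°), so the lock region
is never reached in normal use.

## Sensor fusion

No specific fusion algorithm is mandated by the system being modeled, so
the package uses a deterministic complementary filter, the simplest
estimator adequate for slow, seated head motion:

* **Initialization**: TRIAD from the first accelerometer/magnetometer
  sample (gravity fixes tilt, the horizontal field component fixes yaw).
* **Prediction**: exact exponential-map integration of the gyroscope rate
  over each sample interval.
* **Correction**: at every sample the predicted gravity direction is
  rotated toward the measured one, and the predicted heading toward the
  measured magnetic heading, each by a fraction `gain` of the angular
  error.

The single gain (default 0.02 at 50 Hz, i.e. a ~1 s correction time
constant) trades gyro drift against acceleration disturbance; for
head-pointing at a screen the accelerations are small and the default is
deliberately conservative. Kalman-class filters were excluded by design:
they add covariance bookkeeping without changing any tested property at
these motion speeds. With the magnetometer disabled, yaw rests on the
gyroscope alone and drifts at the gyro bias rate.

Timestamps are carried explicitly, so any sample rate works; 50 Hz is the
default used throughout the tests.

## Neutral-pose calibration

`calibrate_neutral()` fuses the calibration stream and averages the
orientations in the trailing 2 s window (the hold asked of the subject)
with the **chordal mean**: the element-wise mean matrix projected back to
the nearest rotation by SVD. The chordal mean is deterministic and
invariant to sample order, which the suite tests as a property. If any
sample in the window deviates more than 5° from the mean the calibration is
rejected — a still head sits well under 1° of jitter, while a head that is
settling or wandering exceeds 5° quickly; the threshold is configurable.

## The absolute mapping

Only the symbol definitions of the pixel formulas are fixed by the system
description: `R_H`, `R_V` are pixel distances, `α_T`, `β_T` the range of
motion required to reach the targets. The package adopts the simplest law
consistent with those semantics — linear through the origin, hitting the
extent exactly at the required ROM:

```
x = R_H · β / β_T        y = −R_V · α / α_T
```

with β the inclination (or, sign-flipped, the axial rotation) angle. Three
open points were decided as follows:

* **Operand order** in forming the relative rotation: `R_T = R_cal⁻¹ R_S`,
  because the neutral posture must map to the identity and hence to the
  screen center; the other order does not anchor the center.
* **Half-extent vs inter-target distance**: `R_H`/`R_V` are treated as
  half-extents from the screen center; with extents at half the screen
  size, an angle of exactly `α_T` lands on the screen boundary.
* **Out-of-range angles clamp** to the screen edge rather than erroring:
  the airplane must stay visible, and a clamped cursor can still leave the
  edge when the head returns to range.

The sign convention (flexion down, right tilt right, looking right right)
keeps the control natural for a user facing the screen.

## Game rules

Targets spawn on a fixed cadence (default every 5 s), positions uniform
over the angular box `±required_rom` with consecutive targets at least
`min_separation` (5°) apart, placed by rejection sampling (capped, with a
typed error if the constraint is infeasible). A target is reached by the
first cursor sample strictly inside its radius during its
`[spawn, deadline)` window — no dwell requirement, the simplest reading of
"picking up" a target. A reached target disappears but the next spawns on
schedule, preserving the fixed 210 s session length of the default
protocol (2 × 21 targets × 5 s). The session score is
`100 · reached / total` pooled over series; per-series percentages are
logged too, and with equal series lengths their mean equals the pooled
score. The default target radius is 40 px on a 1280×720 screen — about
2.8° of flexion at the default mapping — chosen as a plausible
easy-difficulty size; it is fully configurable and no tested property
depends on its exact value.

## The synthetic user

`simulate_pursuit()` models a player per axis as

* an **intent** state that, after a reaction delay (default 0.4 s) from
  each spawn, approaches the target's required angles along a first-order
  exponential (time constant 0.3 s) with the angular speed capped (default
  60 deg/s, a comfortable cervical pace);
* an additive **Ornstein–Uhlenbeck motor-noise** state with stationary sd
  `motor_noise_sd` and a 2 s correlation time. The persistence matters:
  white aiming noise would almost surely wander into the target at some
  sample within a 5 s window, while errors that persist for seconds produce
  genuine misses, which is what makes scores informative.

Learning is one interpretable knob: the noise sd is multiplied by
`learning_rate` each session; delay, speed and time constant stay fixed.

The defaults are the package's reference study conditions: noise sd 9° and
correlation time 2 s put the first-session expected score near 69% under
the default protocol, and `learning_rate = 0.88` carries the mean to ~89%
by session 8 — a rising practice curve of the shape reported for older
adults learning such a game. These values were fixed once by simulating the
default protocol over a grid of noise parameters and are not tuned
elsewhere in the package or tests.

`synthesize_imu()` inverts the fusion step: gyroscope readings are the
axis-angle rates of the relative rotation between consecutive ground-truth
DCMs (head frame), the accelerometer is gravity rotated into the head
frame, the magnetometer the north reference, each plus Gaussian noise;
the gyro additionally carries a constant per-stream bias. Defaults
(0.3 deg/s noise, 0.2 deg/s bias, 0.01 g, 0.01 normalized) are typical
consumer-MEMS figures.

**What the simulator does not emulate**: linear acceleration of the head
(the accelerometer sees pure gravity), magnetic disturbance from the
environment, sensor-mounting slip, soft/hard-iron effects, fatigue, pain
avoidance, and any coupling between axes. Passing tests therefore establish
the correctness of the pipeline's algebra and logic and the filter's
behavior under nominal sensor noise — not robustness to the full mess of
real recordings.

## Questionnaire scorers

* **SEQ**: 13 Likert items, 1–5. Items Q7–Q10, Q12, Q13 are negatively
  keyed and reversed with the standard flip `6 − raw`; the total spans
  13–65. The reversal formula is the conventional one for 5-point Likert
  items; the instrument's published form states which items reverse but not
  the arithmetic. The 14th, open-ended item is never scored.
* **NDI**: 10 items, 0–5; raw total out of 50 and as a percentage (so
  percent is exactly twice the raw score).
* **MMSE** (adapted 35-point form): brackets 30–35 normal, 24–29
  borderline, 19–23 mild, 14–18 moderate, <14 severe; screening cutoff 24
  from age 65, 29 below. The education allowance (one extra error tolerated
  at elementary level, one fewer at university level) belongs to an
  error-count reading of the instrument; it is implemented as an optional
  ±1 shift of the cutoff comparison only, off by default, and never moves
  the severity bracket.
* **VAS** values are validated to [0, 10] and stored as-is, with a
  poor-pain-control flag above 3 points.

## Crossover analysis

All tests are two-sided at α = .05, and missing data are refused, never
imputed (a completers-only design). With assessments at weeks 0, 4, 8, 12,
16:

* **Within-treatment**: paired t on pre vs post of the period in which each
  subject received the treatment.
* **Residual (carryover)**: paired t of week 0 vs week 8; if significant,
  the comparison is repeated per sequence group with the Wilcoxon
  signed-rank test to attribute the carryover.
* **Period**: paired t of week 4 vs week 12.
* **Sequence**: per-subject within-treatment change compared between the
  A-B and B-A groups. The two groups are different subjects, so an
  *unpaired* two-sample Student t (equal variances, matching the
  Student-t style of the rest of the battery) is used; the original
  analysis does not name its test for this comparison, so this is a
  documented package choice, not a claim about the original.
* **Repeated-measures ANOVA** over the subjects × sessions score matrix
  (`aov` with a subject error stratum); if the session sum of squares is
  numerically zero the degenerate F is reported as 0 with p = 1 rather
  than as 0/0 noise.
* **Wilcoxon**: exact p for ≤ 25 nonzero differences without ties, normal
  approximation with continuity correction otherwise; all-zero differences
  are reported as a degenerate non-rejection.
* **Shapiro–Wilk** annotates normality; it never switches tests
  automatically.

## Numerical choices and test scale

Round-trip tolerances: 1e−6° for Euler angle recovery, 1e−9 for DCM
orthonormality and Frobenius reconstruction. The statistical calibration
tests use 1000 null replicates per test (binomial SE ≈ 0.7% at the nominal
5%), effect-recovery simulations 200 replicates at n = 100 subjects, and
the learning property 500 replicated 8-session protocols; simulator-based
unit tests run shorter sessions (3–7 targets) and lower rates (20–25 Hz)
where the property under test does not depend on scale. The per-sample
pursuit loop is implemented in C++ (via Rcpp) using R's RNG, so seeded runs
are reproducible across the R/C++ boundary.

## Known limitations

* The complementary filter is a stand-in for whatever estimator commercial
  sensors embed; agreement is only guaranteed on the synthetic signal
  model above.
* The linear mapping law and half-extent reading of `R_H`/`R_V` are the
  simplest forms consistent with the stated symbol semantics, not a
  reverse-engineered controller.
* The simulated learning curve matches a rising success trend
  qualitatively; no per-session clinical numbers are reproduced, since they
  depend on unpublished raw subject data.
* One active target at a time; whether a missed target lingers on screen
  has no observable effect in a headless engine.
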