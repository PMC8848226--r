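# cervgame

A headless R implementation of an inertial-sensor-controlled serious game
for task-oriented cervical exercise, together with the statistical tools of
a crossover (AB/BA) pilot trial of that intervention.

The target users are rehabilitation researchers and engineers who need the
full pipeline of such a system — head orientation from a head-mounted IMU,
neutral-pose calibration, angle-to-screen mapping, target scheduling and
scoring — reproducible and testable without any sensor hardware or game
client, plus the questionnaire scorers (SEQ, NDI, MMSE, VAS) and the
crossover analyses used to evaluate it.

## The model at the core

A head-mounted sensor with a 3D gyroscope, accelerometer and magnetometer
streams raw samples. A complementary filter fuses them into the per-sample
head-to-world direction cosine matrix *R*<sub>S</sub>. Before play, the
subject holds a neutral upright posture for 2 s and the calibration DCM
*R*<sub>cal</sub> is taken as the chordal mean of the fused orientations
over that hold. Play is driven by the relative rotation

&nbsp;&nbsp;&nbsp;&nbsp;*R*<sub>T</sub> = *R*<sub>cal</sub><sup>−1</sup> *R*<sub>S</sub>,

decomposed with the **YZX Euler convention** into flexion-extension *α*
(about the lateral Y axis), axial rotation (about the vertical Z axis) and
lateral inclination (about the anterior X axis). The cursor — a virtual
airplane — follows the **absolute mapping**

&nbsp;&nbsp;&nbsp;&nbsp;*x* = *R*<sub>H</sub> · *β* / *β*<sub>T</sub>,&nbsp;&nbsp;&nbsp;
*y* = −*R*<sub>V</sub> · *α* / *α*<sub>T</sub>,

where *R*<sub>H</sub>, *R*<sub>V</sub> are the screen half-extents in
pixels, *α*<sub>T</sub>, *β*<sub>T</sub> the range of motion (degrees)
required to reach them, and *β* the lateral-inclination or axial-rotation
angle depending on configuration. The same head orientation therefore
always lands the cursor on the same pixel, and flexion moves it down.
Targets spawn every 5 s at uniformly random positions inside the angular
box; a target is reached when the cursor enters its radius before the next
spawn, and the session score is the percentage of targets reached.

A synthetic user (reaction delay, rate-limited first-order pursuit,
persistent motor noise, session-to-session learning) plus an IMU
synthesizer close the loop, so the entire stack can be exercised and tested
end to end in software.

## Worked example

Simulate one subject's 4-week protocol (8 sessions, two series of 21
targets each, 5 s per target) and score the study instruments:

```r
library(cervgame)
set.seed(42)

cfg <- default_protocol_config()
cfg$game
#> <game_config> 2 series x 21 targets, one every 5 s (210 s session);
#>               radius 40 px, ROM 20 deg, difficulty 'easy'

round(simulate_protocol(user_model(), cfg$game, n_sessions = 8), 2)
#> [1] 76.19 69.05 69.05 76.19 80.95 80.95 88.10 85.71
```

The eight numbers are per-session success percentages: targets reached out
of 42, rising across sessions as the simulated user's motor noise decays
with practice. A single session in full detail:

```r
targets <- generate_targets(cfg$game, seed = 42)
traj <- simulate_pursuit(targets, user_model(), cfg$game$mapping)
cursor <- cbind(t = traj$t,
                cursor_from_angles(traj$alpha, traj$incl, cfg$game$mapping))
log <- run_session(cfg$game, cursor, targets = targets)
log
#> <session_log> 30/42 targets reached (71.43%); series: 57.14%, 85.71%
```

Questionnaire scoring:

```r
score_seq(c(5, 4, 4, 4, 5, 4, 1, 2, 2, 1, 5, 4, 5))  # suitability, 13-65
#> [1] 52
score_ndi(c(2, 1, 2, 3, 1, 2, 2, 1, 1, 0))           # disability, /50 and %
#> $raw [1] 15   $percent [1] 30
mmse_classify(31, age = 82)
#> $bracket "normal"  $cutoff 24  $below_cutoff FALSE
```

A SEQ of 52/65 indicates good suitability; an NDI of 30% is moderate neck
disability; an MMSE of 31 at age 82 is in the normal bracket, above the
geriatric cutoff of 24. `analyze_crossover()` runs the full trial battery
(within-treatment paired t tests, residual/period/sequence effects,
repeated-measures ANOVA over session scores) on a
`subject,sequence,week0,week4,week8,week12,week16` table.

A command-line wrapper over the same functions is installed at
`inst/cli/cervgame.R` with `simulate`, `replay`, `score` and `analyze`
commands.

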