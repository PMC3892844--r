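# flightcheck

Detection of illegal race-walking steps from a single sacrum-mounted
inertial sensor.

Race walking requires continuous ground contact: a step where both feet
leave the ground (a flight phase) is illegal. Judges detect flight by eye,
but the eye cannot resolve intervals much below 0.06 s, while real illegal
flight phases can be as short as one high-speed-camera frame — 0.008 s at
125 Hz. A tri-axial accelerometer worn at S1 on the sacrum can score every
step objectively. This package is for biomechanists, sports scientists and
engineers building or validating such a tool.

## What it computes

**Sensor method.** After zero-phase low-pass filtering at 20 Hz, each
vertical acceleration step cycle's bottom-most point is located, the heel
strike is detected as the dominant anteroposterior impact peak, and the
per-step offset

```
offset = t(heel strike) − t(vertical minimum)
```

is compared with a flight threshold τ (default 0.03 s, the ground-contact
force transmission offset): the step is illegal iff `offset > τ`.

**Camera reference.** Flight/double-support time from frame counts,
`t = n / Hz`, signed positive for double support and negative for flight;
a same-frame toe-off and heel strike is the 0.00 s threshold case,
counted legal.

**Validation statistics.** Limits-of-agreement validity (typical error of
the estimate `sqrt(RSS/(n−2))` from regressing sensor on camera, with
chi-square 95% confidence limits; mean bias ± SD of differences; Pearson
r), operator reliability (within-event typical error in frames and
ICC(3,1)), and the four-cell confusion summary with overall and
illegal-only accuracy.

**Synthetic generator.** `simulate_walk()` produces sacral-acceleration
traces with known event times, controllable signed ground-contact overlap
(including the judging-critical 0.008–0.05 s range), impact transients,
noise, and the paired camera annotation quantised to 125 Hz frames.

## Worked example

Simulate an 80-step session mixing legal and illegal steps — several of
them at or below the 0.008–0.03 s resolution limit of human judging —
with realistic sensor noise, then run the full comparison:

```r
library(flightcheck)
set.seed(1)
ov <- sample(c(-0.04, -0.02, -0.008, 0, 0.016, 0.03), 80, replace = TRUE)
sim <- simulate_walk(gait_params(n_steps = 80, overlap_time = ov,
                                 noise_sd = 0.05, seed = 1))
assessments <- detect_steps(sim$trace)
camera      <- label_camera_steps(sim$annotation)
pairs       <- compare_steps(camera, assessments)
confusion(pairs)
#> <confusion_summary>
#>   camera illegal: 32 agreed, 4 missed by sensor
#>   camera legal  : 39 agreed, 5 flagged by sensor
#>   accuracy      : 88.75% (89%); illegal-only 93.75%
agreement(pairs)
#> <agreement_report>
#>   n = 80 paired steps
#>   Pearson r    : 0.93
#>   TEE          : 0.008 s (95% CL 0.007 to 0.010)
#>   mean bias    : -0.002 (+/- 0.010) s
quadrant_report(pairs)
#> <quadrant_report>
#>   legal/legal 39  illegal/illegal 32  missed 4  flagged 5
```

The confusion summary counts per-step agreement between camera labels and
sensor verdicts (the misses concentrate on sub-frame flight times, as in
field use); the typical error of the estimate says the sensor's timing
disagrees with the camera by ~8 ms, and the quadrant counts reproduce the
four cells of the scatter report — top-right/bottom-left are agreements,
top-left camera-illegal steps the sensor missed, bottom-right legal steps
wrongly flagged.

A thin command-line interface over the same functions is installed at
`inst/cli/flightcheck.R` with subcommands `simulate`, `detect`,
`camera-label`, `compare`, `run` and `report`.

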