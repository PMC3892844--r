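---
title: "Detecting illegal race-walking steps from a sacral accelerometer: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting illegal race-walking steps from a sacral accelerometer: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightcheck)
```

## The problem

Race walking is defined by continuous ground contact: a step in which both
feet leave the ground (a flight phase) is illegal. Judges detect flight by
eye, but the human eye cannot resolve intervals much below 0.06 s, while
illegal flight phases are often far shorter — down to a single high-speed
camera frame, 0.008 s at 125 Hz. A single tri-axial accelerometer worn at
S1 on the sacrum, close to the body's centre of mass, offers an objective
alternative that can score every step an athlete takes.

`flightcheck` implements that sensor method end to end: the signal
processing and per-step classification, the high-speed-camera reference
computation it is validated against, the validation statistics, and a
synthetic gait-signal generator so that every stage can be exercised and
tested without any recorded data.

## The sensor method

The detection principle works entirely from event *timing* in two
acceleration channels:

1. All channels are low-pass filtered at 20 Hz with a 4th-order
   Butterworth filter applied forward and backward. The zero-phase
   contract matters: event timing must not be shifted by filtering, and a
   single-pass IIR filter would delay every event by its group delay.
2. The bottom-most point of each **vertical acceleration step cycle** is
   located: local minima of the vertical channel lying below the channel
   mean, separated by at least `min_peak_separation` (default 0.2 s,
   slightly below a race-walking step period of ~0.33 s at 3 steps/s).
3. **Heel strike** is detected in the anteroposterior channel as the
   dominant positive impact peak. Peak height is measured from the channel
   median, so a constant accelerometer offset cannot change which peaks
   clear the `peak_prominence` floor (default 0.5 g). A step window with
   no peak above the floor yields a gap, never a fabricated event time.
4. Each vertical minimum is paired with the nearest heel strike at or
   just after it, within half the median inter-minimum interval (plus a
   small pre-window of 20% of that tolerance, to absorb sample-grid
   jitter in which event is detected first). The per-step **offset** is
   `heel_strike_time − vert_min_time`; positive means the heel strike
   came later.
5. Flight is deemed to have occurred when the offset exceeds the
   **flight threshold** strictly. A heel strike coincident with the
   minimum, or exactly at the threshold, is legal.

The default threshold of 0.03 s is the ground-contact force transmission
offset: with continuous ground contact, the impact transient reaches the
sacrum about 0.03 s after the vertical minimum, and flight delays the heel
strike beyond that. It is a configurable parameter rather than a constant
because it was derived empirically from an agreement analysis against a
camera; `agreement()` exists precisely so it can be re-calibrated for a
different sensor or placement. Toe-off is deliberately not detected from
the sensor: toe-off kinematics coincide closely with heel strike at the
sacrum, so heel-strike timing alone carries the classification.

## The camera reference

The reference measurement counts camera frames between toe-off of one
foot and heel strike of the contralateral foot:
`t = n / Hz`. The difference is signed: positive time is double support
(legal), negative time is flight (illegal), and the same-frame case is a
distinct "threshold" label pooled with legal steps in accuracy
bookkeeping — a same-frame step cannot be shown to have left the ground.
Quantising continuous events to frames bounds the camera's own timing
error by one frame period (0.008 s at 125 Hz); `reliability()` and
`reliability_trial()` quantify the human operator's frame-picking error
on repeated identifications.

## Validation statistics

`agreement()` implements the limits-of-agreement validity statistics:

- **Typical error of the estimate (TEE)**: the standard error of the
  estimate from ordinary least-squares regression of the sensor measure
  on the camera measure, `sqrt(RSS / (n − 2))`, with 95% confidence
  limits from the chi-square distribution on `n − 2` degrees of freedom.
  The regression reading is the standard construction of this statistic;
  the package documents it explicitly because variants exist.
- **Mean bias**: `mean(sensor − camera)`. The spread attached to it is
  reported as the standard deviation of the differences; this
  interpretation of the published "±" convention is a documented choice.
- **Pearson correlation** of the paired measures.

`reliability()` reports the operator typical error as the within-event
standard deviation (root mean-square error of a one-way decomposition by
event, in frames) with chi-square confidence limits, and the intraclass
correlation in its two-way mixed, consistency, single-measure form,
ICC(3,1). The consistency form is a deliberate choice: a constant
repeat-to-repeat shift (e.g. a systematically later frame pick on day
two) is an offset, not inconsistency, and does not lower it. The source
method names no ICC form; this one matches its within-operator design.

`confusion()` tallies per-step agreement into four cells and reports two
rates: overall accuracy, and the variant
`100 × (total − legal_flagged) / total` that penalises only wrongly
flagged legal steps. The second is reported under that exact definition —
it is not the illegal-step sensitivity `illegal_agree / (illegal_agree +
illegal_missed)`, and the two disagree (96.25% vs ≈93% on the worked
80-step table); the package follows the published construction and flags
the distinction here rather than resolving it.

## The synthetic generator

`simulate_walk()` emulates the features the detector relies on, with
known ground truth:

- Heel strikes at the step period (default 3 steps/s, optionally
  jittered); toe-off of the contralateral foot at
  `heel_strike + overlap_time`. `overlap_time` (signed; positive =
  double support, negative = flight) is the controlled quantity, covering
  the 0.008–0.05 s range where judging by eye fails.
- The true sensor offset for each step is
  `max(transmission_delay − overlap_time, 0)`. The clamp encodes
  "coincided with, or just after": during long double support the heel
  strike coincides with the vertical minimum rather than preceding it.
  Without the clamp, steps with overlap above the transmission delay
  would place the heel strike *before* the minimum and the at-or-after
  pairing rule could not recover them.
- The vertical channel is `−base_amplitude · cos(φ(t))` with a
  piecewise-linear phase hitting `2πk` exactly at each true per-cycle
  minimum — exact minima even under per-step jitter — plus a damped
  12 Hz impact ring at each heel strike. The anteroposterior channel is a
  narrow half-sine pulse (50 ms, `impact_amplitude`, default 2 g) centred
  at the true heel strike over a 0.1 g baseline. The mediolateral channel
  carries only noise. Additive Gaussian noise (default 0.05 g) is applied
  to all channels.
- The camera annotation is the truth times quantised to the camera rate
  (default 125 Hz) with a floor convention: a frame records everything in
  its exposure window. Nearest-frame rounding is available as an option.

Defaults were chosen so that detection is comfortable at zero noise and
degrades under stress: 1 g vertical oscillation against a 2 g impact
leaves a large margin over the 0.5 g prominence floor, and 0.05 g noise
is mild relative to both.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: it is not a biofidelic musculoskeletal model.
Real sacral waveforms vary between athletes, steps are not independent,
impact shape changes with speed and fatigue, soft-tissue artefact and
sensor mounting add structured (non-Gaussian) noise, and the true
transmission delay is not exactly constant. Tests on simulated data
demonstrate that the algorithmic chain is correct and self-consistent;
they do not re-establish the field validity of the 0.03 s threshold,
which came from real sensor-vs-camera agreement data that are not
distributed.

## Numerical choices and degenerate inputs

- Threshold comparison is strict (`offset > threshold` ⇒ illegal);
  equality is legal. The boundary convention follows "after the
  threshold" meaning strictly after.
- Frame quantisation adds a 10⁻⁹ guard before flooring so that exact
  frame multiples (e.g. 0.008 s at 125 Hz) are not pushed down by
  floating-point representation.
- Constant or empty channels raise structured errors ("no step cycles");
  an anteroposterior channel with no peak above the prominence floor
  warns and returns an empty event set.
- Fully unpairable event sequences raise an error naming orphan events;
  isolated unpairable minima (typically the extra half-cycles at the
  trace edges) are excluded and counted, and the pipeline warns only when
  more than a handful of interior steps go undetected.
- With fewer than 3 paired steps, or constant camera values (a single
  repeated overlap), TEE is undefined and `agreement()` refuses rather
  than returning a degenerate fit; the pipeline then reports confusion
  only. A constant reliability table makes the ICC undefined and it is
  reported as `NA`.
- Re-running the pipeline from the same configuration and seed
  reproduces byte-identical CSV/JSON artefacts; the manifest records the
  threshold, cutoff and seed actually used and contains no timestamps.

## Problem sizes

The test suite and the reproduction script run the generator at 80 steps
(the size of the published validation set), 500 steps for the
parameter-recovery checks (verdict accuracy and bias recovery, where the
injected sensor-vs-camera offset must be recovered within one sensor
sample, 0.01 s) and a 1000-step sweep for the quantisation bound. These
sizes give stable statistics in seconds on a single CPU.

## Known limitations

- The anteroposterior heel-strike criterion of the antecedent sensor
  method is not published in detail; the largest-positive-peak operator
  with a prominence floor is a declared substitute.
- Whether the 0.03 s offset was measured on filtered or raw signals is
  unstated in the source; filtered is assumed, consistent with the
  zero-phase contract.
- Step pairing assumes the detector finds essentially every cycle; if
  whole interior steps are missed, downstream step indices shift and the
  camera/sensor join degrades. The pipeline warns in that case.
- The simulator's waveform is a stand-in (see above).

## A worked run

```{r, eval = FALSE}
library(flightcheck)
sim <- simulate_walk(gait_params(n_steps = 80, overlap_time = -0.02,
                                 noise_sd = 0.05, seed = 1))
assessments <- detect_steps(sim$trace)
camera <- label_camera_steps(sim$annotation)
pairs <- compare_steps(camera, assessments)
confusion(pairs)
agreement(pairs)
quadrant_report(pairs)
```
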