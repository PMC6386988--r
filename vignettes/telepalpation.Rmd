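---
title: "Simulated tele-palpation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated tele-palpation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telepalp)
```

This vignette is the package's account of the science it implements: the
simulated apparatus, the assumptions behind each component, the parameters
that matter, and the choices made where the physical system left the design
open.

## The apparatus in software

The simulated loop mirrors a two-site tele-palpation rig. On the "tactile"
side, a cartesian stage carries an indenter over a silicone phantom and a
load cell reads the normal contact force. On the "haptic" side, an optical
sensor tracks the operator's hand, and a fingertip actuator plays back the
force as a spike-triggered vibration. The package replaces each physical
element with an explicit model:

hand trajectory → gesture-to-velocity law → stage kinematics → contact
force → latency channel → spiking neuron → virtual subject → key presses →
psychophysical analysis.

All randomness derives from one session seed through named sub-streams
(`derive_seed()`), so each component is independently reproducible and a
full session serialises to byte-identical logs under the same seed.

## Phantom and contact mechanics

The phantom is a 100 × 100 × 15 mm block with twelve hemispherical
inclusions (radius 5 mm; three replicas each of four materials). Vertical
stiffness values are the measured per-material slopes ΔFz/Δz:

```{r}
default_materials()
```

Two deliberate simplifications:

* **Surface stiffness field, not layered mechanics.** Each inclusion's
  footprint disk carries its material's measured stiffness directly;
  everything else reads the matrix value. The measured per-site slope is
  the quantity the task discriminates, so the field reproduces it exactly
  rather than deriving it from burial depth and elastic moduli. There is no
  Hertzian or finite-element contact, no viscoelasticity and no shear.
* **Edge handling.** By default the field is hard-edged (`blend_width = 0`,
  boundary belonging to the inclusion); a linear blend band of configurable
  width is available because nothing in the physical system pins down how
  stiffness varies at the margins. The hard edge makes the force transient
  at a crossing a clean step, which is also the worst case for the encoder.

Contact is linear, `Fz = k·z`, valid over the small forces applied (at most
0.5 N, i.e. depths of ~0.14–0.23 mm). Inclusion placement is uniform
rejection sampling with a 5 mm edge margin, non-overlap enforced by centre
distance, and a 10 000-attempt cap that fails loudly naming the inclusion
it could not place.

The indentation characterization protocol advances at 0.125 mm/s until
0.5 N, estimates the slope by ordinary least squares per trial, and pools
five trials by median/IQR/range — the same summary a box plot of repeated
trials shows.

## Gesture control and the tracking metric

The stage velocity is zero while the hand sits inside a 50 mm neutral
sphere around the sensor, and grows linearly with the excess displacement
ρ − ρ₀ outside it, directed along the horizontal hand displacement. The
proportional gain between excess displacement and speed is not a published
quantity; the default is 1 (mm/s)/mm with a 20 mm/s ceiling for stability,
both configurable. Speed is continuous at the dead-zone boundary, and hand
samples leaving the sensor range are held at the last valid value.

Only X–Y motion is gesture-driven. The vertical axis runs a first-order
depth servo (time constant 50 ms by default) toward the depth at which the
local stiffness produces the force set-point. The physical platform
specifies only a protective 0.5 N threshold, not a vertical control law; a
servo was chosen because it produces exactly the force modulation over
stiffness boundaries that the feedback channel must convey: entering an
inclusion at servo equilibrium multiplies the force by k_in/k_matrix until
the servo re-settles. The default set-point of 0.25 N keeps that transient
(at most 0.25 × 3.69/2.14 ≈ 0.43 N) below the 0.5 N clamp and inside the
calibrated monotone range of the encoder.

Tracking fidelity is scored as the area between the boundaries of the
target and executed trajectories, as a percentage of the target area. The
boundary of a sampled path is extracted convexly (`chull`) at
`boundary_shrink = 0`, and tightened into a concave outline as the shrink
parameter grows: hull edges longer than a shrink-dependent threshold are
recursively split at the nearest interior point, accepting a split only if
both new edges are shorter than the edge they replace (which guarantees
termination). The area is the shoelace formula on the resulting polygon.
The default shrink of 0.5 mirrors the default compactness of the boundary
routine used on the physical data; for the convex characterization targets
(circles of 30/15 mm radius, squares of 60/30 mm side) any shrink value
yields the same area to sampling precision.

## Neuromorphic encoder

The force-to-spike converter is the two-variable Izhikevich model in its
canonical regular-spiking parameterization (a = 0.02, b = 0.2, c = −65,
d = 8, peak 30 mV), forward-Euler integrated at 5 kHz (0.2 ms steps) — the
rate the physical feedback chain used. The model's published parameter set
is used because the apparatus names the regime ("regular spiking") but not
the constants; all four are configurable. The integration core is compiled
(Rcpp); the test-suite checks it against an independent plain-R integration
at 0.01 ms steps, requiring spike counts over 1 s of constant input to
agree within 5 % across the calibrated input range.

The input current is affine in force, `I = offset + gain·F`, with zero
offset by default (no spontaneous firing — whether the deployed system ran
a background rate is unknown). The calibration chooses the gain so that
the force ceiling (0.5 N) lands at the top of a target rate range (100 Hz
by default) *within the monotone region* of the simulated f–I curve; this
is the sense in which saturation of the neural model is counterbalanced.
Concretely `calibrate_gain()` probes the f–I curve on a coarse grid up to
I = 100, restricts to its longest non-decreasing prefix, and bisects on
simulated steady-state rates. For the regular-spiking set at 0.2 ms steps
the f–I curve is monotone far beyond the currents used, so the default
range is comfortably inside it.

Spike detection is threshold-crossing at v ≥ 30 mV before reset, with the
spike stamped at the end of the step. Each spike maps to one biphasic
square pulse (±100 V about a 105 V offset, i.e. the driver's 200 V
peak-to-peak excursion); overlapping pulses sum and clip to the driver
rails. Pulse shape is a modelling choice — the driver's electrical settings
are known but its waveform is not.

## Virtual subject

The human participant is replaced by two models, used for different
purposes:

* `detect_rate_changes()` is a behavioural stand-in: windowed rate
  estimation (100 ms window, 25 ms stride), a running baseline equal to the
  median of the five preceding windows, a detection when the rate departs
  from baseline by more than 12 Hz, a 300 ms reaction latency, a 1 s
  refractory period, and 2 mm isotropic jitter on the recorded press
  position. The 12 Hz threshold was set from the transient analysis above:
  with a 0.25 N set-point and the default calibration, crossing into the
  stiff pair (3.68/3.69 N·mm⁻¹) raises the windowed rate by roughly
  15–20 Hz while the soft pair (2.74/2.88 N·mm⁻¹) produces about half
  that, so a threshold between the two yields the stiffness-dependent
  detectability the task studies. Every one of these numbers is a
  configurable model parameter, not a claim about human perception.
* `psychometric_response()` draws Bernoulli responses directly from the
  logistic psychometric law `P = γ + (1 − γ − λ)G(x)`. Parameter-recovery
  tests for the fitting code use this generator, so their verdicts do not
  depend on the detector heuristics.

## Psychophysical analysis

Presses are matched to the nearest inclusion centre; within the tolerance
radius (10 mm by default — the inclusion diameter — swept over 5/10/15/20)
the press is a true positive. Accuracy is TP/(TP + FP). The literal reading
of the alternative definition "TP over collected responses minus FP"
degenerates to TP/TP = 1 whenever any TP exists; it is available behind
`accuracy(..., definition = "positives")` but not used anywhere.

Identification is binary per inclusion (an inclusion is identified if at
least one TP press matches it in a session) with the material's inclusion
count as denominator, so repeated presses on one nodule inflate TP counts
but not identification rates — keeping the tolerance-curve and
identification-rate analyses independent. Rates are averaged across
sessions (not pooled across presses), with the interquartile range as
spread.

The psychometric fit minimises least squares of
`G(x) = [1 + e^{−(x−a)/b}]⁻¹` over (a, b) with Levenberg–Marquardt
(`minpack.lm::nls.lm`), started at a₀ = median stiffness, b₀ = half the
stiffness range, with b bounded below at 10⁻⁶. Non-convergence and
unidentifiable inputs (all rates equal, fewer than two distinct stimulus
levels) are flagged in the returned object rather than raised. With only
four stimulus levels and perfectly separated rates the scale estimate
collapses to its lower bound and the threshold lands between the separated
groups; this is the expected behaviour of the estimator, and the Monte
Carlo recovery test (Bernoulli noise, 200 trials per level) shows the
threshold estimate is unbiased to within 0.1 N·mm⁻¹.

## Latency and session modes

The two-site link is modelled, not transported: each force sample is read
at `t − d(t)` with `d(t)` bounded by the channel's 15 ms maximum. "In line
of sight" sessions default to a short fixed 2 ms delay, "not in line of
sight" to per-sample uniform jitter on [0, 15] ms with enforced order
preservation. With the bound set to zero the two modes produce identical
logs under the same seed — the modes differ only through the channel.

## What the generator emulates, and what it does not

The synthetic sessions emulate: the phantom geometry and measured
stiffness table, the neutral-sphere control law, the 0.5 N protective
clamp, 5 kHz spike encoding, bounded transport latency, six-minute
exploration, and press-based reporting with spatial scatter. They do not
emulate human motor noise (scripted trajectories are smooth pursuit),
attention lapses, learning across sessions, or perceptual memory — so
passing tests demonstrate that the pipeline and its analyses behave
correctly and that stiffer inclusions are more detectable than softer
ones, not that human identification percentages are reproduced. The
human-facing outcomes (tracking error rates of a few percent,
identification around 60–74 %, thresholds near 2.5–2.9 N·mm⁻¹) are targets
of qualitative, not numeric, reproduction; the simulated subject is
sharper-thresholded than people, and its soft-material rates are
correspondingly lower.

## Problem sizes and numerical choices

The test-suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute of simulated-neuron time:
trajectory targets sampled at 720 points; five indentation trials per
material with 0.01 N load-cell noise; f–I probing over 31 currents with
0.5 s settling and 1 s measurement; identification sessions of 60–360
simulated seconds at 100 Hz control rate; three sessions per latency
condition in the acceptance script; 100 Monte Carlo replicates for
threshold recovery. Euler divergence (non-finite state) raises an error
naming the step; indentation noise is floored at zero force; boundary
extraction falls back to the convex hull wherever digging would create
longer edges; stage positions clamp silently to the workspace; and every
file format (phantom JSON, path/force/response CSV, spike-train text with
JSON sidecar, session log directories, YAML configs) round-trips
losslessly, which the suite asserts byte-for-byte where determinism
matters.
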