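---
title: "Methods: a reflex-driven walking model and its disturbance experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reflex-driven walking model and its disturbance experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Competing models of the human spinal control of walking — central pattern
generators, reflex networks, and mixtures — all reproduce steady gait, so
steady-state resemblance cannot discriminate between them. A sharper probe is
the *immediate reaction* to unexpected disturbances: how muscle activations
change within tens of milliseconds of an electrical afferent volley, a tendon
tap, an imposed joint rotation, a trip, or a slip, and how those changes are
modulated across the gait cycle and with disturbance strength. `reflexgait`
implements a sagittal-plane neuromechanical walker whose muscle stimulations
are produced exclusively by phase-gated, delay-respecting spinal reflex
pathways, together with the five classic disturbance protocols and the
statistics used to compare model reactions with electromyographic (EMG)
reference data.

## The plant

**Skeleton.** Seven rigid segments (head-arms-trunk, thighs, shanks, feet)
form a planar kinematic tree with nine degrees of freedom: hip translation,
trunk pitch, and hip/knee/ankle rotation per leg. Equations of motion are
evaluated by a planar recursive Newton-Euler pass; the mass matrix is built
by the unit-acceleration trick and solved directly. Segment masses, lengths,
centres of mass and inertias scale to subject height and mass via standard
anthropometric regression fractions, so `scale_anthropometry(1.75, 64)`
reproduces a reported subject group and `scale_anthropometry(1.8, 80)` is
the default body used when studies do not report anthropometry. Joints carry
soft range-of-motion stops (1000 N m/rad beyond the limit, damped).

**Muscles.** Nine Hill-type muscle-tendon units per leg (HFL, GLU, HAM, RF,
VAS, BFSH, GAS, SOL, TA) follow the classic contractile-element /
series-elastic formulation: a bell-shaped force-length curve centred on
`l_opt` (width 0.56, floor 0.05), a hyperbolic force-velocity curve with
`f_v(0) = 1`, zero force at the maximal shortening velocity and an eccentric
plateau of 1.5, a quadratic-toe tendon (reference strain 0.04), and parallel
elastic and compressive buffer elements. The contractile velocity is obtained
each step by inverting the force-velocity relation against the tendon force,
which keeps the muscle state integration explicit and fast. Shortening
velocity is positive throughout the package. Moment arms are constant or
cosine-modulated in joint angle, and the signed arm is exactly the derivative
of MTU length with respect to the joint angle, so joint torque and fibre
work are energetically consistent (the tests verify this to 1e-6 by finite
differences). Excitation-activation coupling is first order with a 10 ms
time constant; stimulations live in [0.01, 1] — a baseline tone that never
switches fully off.

**Contact.** Heel and ball points per foot meet a compliant ground: linear
normal spring (80 kN/m per point) with penetration-rate damping (reference
0.03 m/s, multiplier bounded at 4 to keep heel-strike transients finite),
and anchor-based stick-slip friction (static 0.9, kinetic 0.8) whose anchors
convect with the belt, so a split-belt treadmill drives a sticking foot
naturally. Walking "overground" is the zero-belt special case; a belt speed
change under the stance foot is the Galilean equivalent of a treadmill belt
acceleration.

**Integration.** Semi-implicit Euler at a fixed 0.1 ms step. The step size
is a configuration value (0.1-0.5 ms is sensible); fixed-step integration
was chosen over adaptive schemes because it makes delay buffering exact,
trajectories bit-reproducible, and disturbance onsets step-aligned. On a
passive pendulum configuration the integrator conserves mechanical energy to
well under 0.1% per second at the default step (the drift scales linearly
with the step, as expected for a symplectic first-order scheme).

## The spinal controller

All stimulations are sums of a per-muscle baseline and reflex contributions
gated by leg phase (stance weight, swing weight, trailing-leg double
support), each reading *delayed* afferents: 20 ms transport delay for ankle
muscles, 10 ms for knee, 5 ms for hip and trunk signals. The pathways are:

* **SOL**: positive force feedback in stance — and nothing else. The soleus
  stance pathway carries structurally zero velocity-afferent weight, which
  grounds the correlation-confound analysis below.
* **GAS**: positive force feedback in stance.
* **VAS**: positive force feedback in stance, inhibited near knee
  overextension and by contralateral loading during double support.
* **TA**: tonic length feedback (ankle dorsiflexor, foot clearance) minus
  SOL force inhibition in stance.
* **GLU / HFL / HAM**: stance trunk-balance PD on forward lean (scaled by
  leg load); during the trailing double support a constant push-off
  rebalancing (HFL up, GLU down); in swing, HFL length feedback with HAM
  length inhibition plus a lean compensation, HAM and GLU force feedback to
  brake the swinging leg.
* **BFSH**: constant early-swing knee flexion drive.
* **RF**: baseline only — in this network the rectus femoris senses but does
  not actuate, which is why its response trends cannot modulate outside
  swing.

Heel strike and toe-off are detected online from the per-foot normal load
with hysteresis (30 N on, 15 N off) and a 20 ms debounce; events are
timestamped at the first step of the persistent contact change. Phase
weights cross-fade with a 10 ms first-order smoothing rather than switching
discontinuously.

The gains, offsets and baselines (26 + 9 numbers) are obtained by
optimization, not transcription; `default_reflex_params()` only seeds the
search.

## Gait optimization

`evaluate_cost()` scores a parameter set by `J = C_E + c_v * |v_avg −
v_tgt|` with `c_v = 100`, where `C_E` is the metabolic energy consumed over
the evaluation window (we use 12-15 s after a 5 s transient, about 15-20
strides) and `v_avg` the mean forward speed over that window. The metabolic
model is a compact muscle-level rate: activation/maintenance heat `0.5 a^2
F_max l_opt` [W], shortening heat (0.25 of contractile power), lengthening
heat (0.05), and positive contractile work — zero for a quiescent muscle and
additive over muscles and time. Falls (hip below 70% of standing height, or
a non-finite state) score a penalty `1e6 / (1 + distance)` that decreases
with distance walked, so partial progress is rewarded.

`optimize_gait()` wraps a hand-written (mu/mu_w, lambda) covariance-matrix
adaptation evolution strategy over log-scaled multiplicative offsets of the
parameters (bounds ±2 octaves), with a staged ranking: falling candidates
rank by distance, walking candidates outside ±0.05 m/s of the target rank by
speed error, and candidates at speed rank by `J` plus two realism
regularizers: a penalty on the time fraction any stimulation spends pinned
above 0.95 (bang-bang controllers walk cheaply but leave no headroom for
evoked responses), and a cadence prior holding the stride period near the
human preferred relationship (about 1.2 s at 1 m/s), without which the
optimizer favours atypically long, slow strides. The cost surface is highly
multimodal; the shipped parameter sets are the best of a few thousand
evaluations per speed, warm-started across speeds, and are versioned
fixtures under `inst/extdata/` (one flat name-value text file per
experiment speed: 0.83, 0.97, 1.11, 1.20 m/s, plus a 1.75 m / 64 kg body at
0.97 m/s). They are reference gaits for the disturbance experiments, not
claims of global optimality — their activation patterns are noticeably more
saturated than human EMG in some muscles, a known limitation noted below.

## Disturbance protocols

Every trial restarts from a stored limit-cycle snapshot (full state,
including muscle states, contact anchors, event history and afferent delay
buffers), captured at a heel strike of the target leg; conditions therefore
never interact, and stride-phase conditions map to onset times as `snapshot
time + fraction * stride period`. A zero-magnitude disturbance of any
protocol is bypassed entirely and reproduces the undisturbed continuation
bit-exactly — the tests assert this for all five protocols.

* **Afferent stimulation (MMR-style)**: for 10 ms, every muscle's force,
  length and velocity afferent is incremented by one normalized unit (one
  `F_max`, one `l_opt`, one `|v_max|`) at the recording point, so the pulse
  propagates through the physiological transport delays. Conditions: 16
  equal phases over the stride. The evoked spike width is measured as the
  contiguous time the evoked activation (disturbed minus undisturbed)
  exceeds 20% of its peak — a standard EMG burst onset/offset convention,
  chosen because the simulation is noise-free.
* **Tendon tap (TR)**: the hammer's kinetic energy (90 g at 1.5 m/s =
  0.10125 J) divided by the instantaneous tendon tension gives the imposed
  MTU stretch, capped at 5% of `l_opt` and applied as a 5 ms rise / 5 ms
  hold / 5 ms release length offset. An Achilles tap stretches SOL and GAS
  jointly (energy divided by their summed tension); a patellar option
  targets VAS and RF. The stretch therefore varies over the gait cycle
  inversely with muscle tension. Conditions: 16 equal stride phases.
* **Ankle stretch (SR)**: a stiff external servo (PD, 150 kN m/rad
  equivalent, torque-limited) rotates the ankle 8 degrees into dorsiflexion
  at 250 deg/s (32 ms), holds, and releases — the imposed rotation is
  verified to 8 ± 0.2 degrees at every phase condition. Conditions: 8 equal
  stride phases.
* **Trip (TRIP)**: a free 2.2 kg block (0.1 m square, friction 0.8) stands
  on the ground where the swing foot's ball will arrive at the requested
  swing fraction (5-75%), computed from the undisturbed trial's foot path;
  geometrically unreachable conditions are flagged unrealizable and
  excluded. Foot-block and block-ground contact use the standard
  spring-damper/friction model; the block translates without rotation (its
  rotational inertia is neglected).
* **Slip (SLIP)**: 150 ms after the detected heel strike, the stance-side
  surface velocity ramps by `dv` (0.1-0.5 m/s grid) within 50 ms. The sign
  convention (surface moving backward relative to progression, the
  equivalent of a treadmill belt speed-up) follows the source experiment's
  protocol and is configurable.

## Response analysis

The response of a muscle to one condition is the signed peak of the
disturbed-minus-undisturbed activation difference in a protocol-specific
window after onset (defaults: 0-40 ms for the stimulation and tap protocols,
10-60 ms for the ankle stretch, 20-100 ms for trips, 20-150 ms for slips;
window means are available as an alternative statistic). Collecting one
scalar per condition gives a response trend.

Trends are compared to a reference band (mean ± 1 s.d. per condition,
normalized so the peak |mean| is 1) by **optimal linear scaling**: the single
nonnegative factor `k` that maximizes the number of conditions whose scaled
model response lies within one s.d. of the reference mean. Because the
objective is piecewise constant in `k`, the exact optimum is found by
sweeping the interval breakpoints `(mean_i ± sd_i)/model_i`; ties are broken
by the smallest sum of squared residuals to the mean. The percentage of
conditions within the band is the similarity statistic. A multiplicative
scaling with no offset is used because responses are baseline-subtracted
changes — zero response must map to zero; an offset variant exists behind an
argument for sensitivity analysis. The implementation is verified against a
dense-grid brute-force maximizer on hundreds of random instances, and a
constructed fixture in which exactly 4 of 16 conditions are unreachable
yields 12/16 = 75%.

Response **amplitudes** (peak response relative to the muscle's own peak
background activation) are only compared for the mechanically replicated
protocols (SR, TRIP, SLIP); the stimulation and tap protocols evoke
artificially synchronized volleys whose absolute size the model does not
claim to capture.

Two further statistics probe *why* the model under-responds to whole-body
disturbances and what correlation analyses can(not) establish:

* `proprioceptive_change_ratio()` measures, per muscle and afferent type,
  the peak |disturbed − undisturbed| signal change, and reports the maximum
  ratio of the ankle-stretch changes to the trip and slip changes. The
  imposed joint rotation attacks the muscle directly; trips and slips act
  through the body's inertia, so their afferent perturbations are orders of
  magnitude smaller.
* `velocity_feedback_contribution()` reproduces the classic correlation
  argument: regress the soleus response amplitude on the imposed ankle
  angular-velocity change across stance perturbation trials of varying
  speed, project the fitted slope onto the undisturbed stance
  dorsiflexion-velocity profile (rectified at zero, since plantarflexion
  cannot excite a stretch response), and express the attributed activation
  as a percent of mean stance activation. In this model the attribution is
  substantially positive *even though the soleus stance pathway has exactly
  zero velocity gain* (asserted structurally and functionally in the
  tests) — velocity, length and force afferent changes are mutually
  correlated under an imposed rotation, so the regression cannot isolate a
  pathway.

## Synthetic reference data

Real digitized EMG bands are an optional input (delimited text: condition,
mean, sd). The test surface is synthetic: `generate_reference_band()` draws
a smooth bump-mixture trend over the condition axis (response trends across
gait phase are smooth in practice), normalizes it, attaches a band of
relative width `sd_rel` (default 0.25), and returns a matching model trend
with known ground-truth scale `k*`. Conditions forced "out of band" get the
*negated* mean, which no nonnegative scaling can place inside the band —
so the best achievable overlap is known exactly by construction, not by
simulation. `generate_emg_trials()` produces paired EMG-like traces
(smoothed stochastic background, Gaussian response bump of known height)
for testing the response extractor, exact in the noise-free limit. All
generation is reproducible from a seed and leaves the session RNG state
untouched.

What the synthetic data does *not* emulate: inter-subject variability
structure, rectification/smoothing artefacts of surface EMG, crosstalk
between neighbouring muscles, and non-Gaussian burst shapes. Passing the
synthetic suites therefore shows the statistics are computed correctly, not
that the model matches human data.

## Numerical and design choices worth knowing

* Step size 0.1 ms; delays are integer step counts; delayed reads before the
  buffer fills return the oldest sample (trials always start from snapshots
  whose buffers are full).
* Event debounce 20 ms; without it, load chatter at push-off fabricates
  millisecond-scale stance/swing segments.
* The TR stretch cap (5% `l_opt`) bounds the imposed stretch when tension is
  near zero (swing-phase taps); capped trials are flagged.
* The block placement gap (8 mm ahead of the predicted ball position) makes
  contact begin essentially at the requested swing fraction; the realized
  hit time is recorded in the trial manifest and used as the onset.
* Fall detection: hip height below 70% of standing, or any non-finite state;
  the simulator aborts and flags the trial.
* Problem sizes in the shipped tests: settling runs of 5-8 s per speed,
  trials of one to two strides at 0.5 ms recording resolution, 30-40 s
  walking endurance checks, 400 random instances for the band-scaling
  equivalence property. These choices keep the full suite in the minutes
  range on one core.

## Known limitations

* Sagittal plane only; no lateral balance, no 3-D joint moments.
* The optimized gaits are energetically plausible (about 3 J/kg/m) but
  drive some extensors closer to saturation than human EMG suggests, which
  compresses evoked-response headroom in those muscles.
* The tap and stimulation protocols abstract all electrophysiology (skin
  filtering, recruitment curves, synchronization); their response
  *amplitudes* are not meaningful, which is precisely why amplitude
  comparisons are restricted to SR/TRIP/SLIP.
* The obstacle is a translating block; no rotation, no compliant surface.
* Supraspinal modulation, cutaneous pathways and CPG dynamics are out of
  scope by design: the package tests what pure proprioceptive reflex
  control can and cannot explain.

## A minimal session

```{r example}
library(reflexgait)

params <- walking_params(0.97)
model  <- scale_anthropometry(1.8, 80)
snap   <- steady_snapshot(params, model = model, v0 = 0.97)

run  <- run_protocol("sr", params, snap, model = model)
tr   <- response_trend(run, muscles = c("SOL", "TA"))

band <- generate_reference_band(synth_spec(n_conditions = 8, seed = 1))$band
scale_to_band(tr[tr$muscle == "SOL", ], band)
```
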