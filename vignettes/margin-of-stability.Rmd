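---
title: "Methods: dual-system margin of stability at gait initiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-system margin of stability at gait initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmos)
```

## The model

Mediolateral (ML) balance at gait initiation is described by an inverted
pendulum of length $l = 0.575\,h$ (with $h$ the participant's own body
height) and eigenfrequency $\omega_0 = \sqrt{g/l}$, $g = 9.81$ m/s².
Stability at the swing-foot contact instant is summarised by the margin of
stability

$$\mathrm{MoS} = \mathrm{BoS}_{y,\max} - Y_{CoM,FC}, \qquad
  Y_{CoM,FC} = y_{CoM,FC} + \dot y_{CoM,FC} / \omega_0 ,$$

where $\mathrm{BoS}_{y,\max}$ is the ML extent of the base of support at
contact and $Y_{CoM,FC}$ the extrapolated centre of mass. A positive MoS
means the extrapolated CoM lies inside the base of support.

Two measurement routes produce the components independently:

* **Force plates.** $\ddot y = F_y/m$ (Newton's second law, forces summed
  over plates), then cumulative trapezoidal integration with null initial
  velocity and displacement — the participant starts from quiet standing.
  The integration yields displacement only; absolute position is anchored
  at the mean combined CoP of a 0.5 s quiet-standing window, because in
  static equilibrium the CoM lies vertically above the CoP. The base of
  support comes from the two quasi-plateaus of the ML CoP trace: the CoP
  sits under the stance foot during the swing phase and moves onto the
  landed foot just after contact, so the distance between the two plateau
  extrema measures the heel-to-heel extent.
* **Markerless capture.** The CoM channel is used directly; velocity is
  the backward first difference scaled by the sampling rate, exactly as
  the convention defines it (a central scheme would be slightly more
  accurate, but the printed definition is first-order backward, and we
  implement it as stated; its $O(\Delta t)$ bias at 85 Hz is a few
  10⁻⁴ m/s at contact, negligible against measurement noise). The base of
  support is the ML heel-to-heel distance at the contact sample.

### The frame behind the subtraction

$\mathrm{MoS} = \mathrm{BoS} - Y$ subtracts a coordinate from a size, so a
frame convention is required to make the two routes commensurable. Both
routes re-express their components with the origin at the **stance-limb
lateral base-of-support boundary at foot contact** and the axis positive
toward the swing side: the force route takes the stance-side CoP plateau
extremum as that boundary, the markerless route the stance-heel ML
position. In this frame $\mathrm{BoS}_{y,\max}$ *is* the swing-side
boundary coordinate and the MoS is invariant under translations of the
laboratory frame (a property the test suite checks by re-running the
analysis in a shifted frame).

### Events

One event set per trial is shared by both routes, so between-route MoS
differences cannot come from event timing. Detection runs on unfiltered
channels — the zero-lag filter is acausal and spreads the plate-2 loading
step symmetrically around the true contact, which would bias a threshold
crossing early by 1–2 samples:

* *onset*: combined ML CoP deviating more than 2.5 static SDs from its
  quiet-standing mean, sustained 50 ms;
* *foot-off*: the swing-heel vertical channel anchored at its apex — the
  last sample before the apex at which the heel was still below 20% of the
  lift. The apex anchor makes the rule robust to the smooth positional
  noise of markerless capture, which defeats naive small-threshold
  crossings;
* *foot-contact*: plate-2 vertical force above 10 N sustained 20 ms
  (force rule, the default), or the swing heel returning to its baseline
  after the apex (kinematic rule, for single-plate records).

## The synthetic generator

No public recordings of this protocol exist, so the package generates
trials whose ground truth is known *exactly*, and the whole pipeline is
validated against it. The design rule is: **position first, everything
else derived analytically.** The ML CoM trajectory is a closed-form C²
curve —

1. quiet standing ($y \equiv 0$, the frame origin) until onset;
2. an anticipatory quintic segment from rest to the foot-off state
   $(y_{fo}, v_{fo}, \omega_0^2 (y_{fo} - w/2))$, whose end-acceleration
   condition makes the CoP continuous into the next phase and forces the
   ML velocity to peak *before* foot-off;
3. an exact inverted-pendulum arc about the stance foot at $+w/2$ during
   swing (so the true CoP is constant there — the first plateau);
4. after contact, a driven-pendulum solution in which the CoP decays
   exponentially onto the landed foot at $-w/2$ (rate 40 s⁻¹, i.e. the
   second plateau is reached a few tens of milliseconds after heel
   contact); the forcing has a closed-form particular solution, so the
   segment stays analytic and C².

Forces and moments are then *derived*: $F_y = m \ddot y$,
$F_z$ split between plates by the exponential weight-transfer share (this
split keeps the plate-1 CoP exactly under the stance foot during the
transfer), and $M_x = -\mathrm{CoP}_y \cdot F_z$ per plate. By
construction the noiseless channels satisfy $F_y = m\ddot y$ and
$\mathrm{CoP} = y - \ddot y/\omega_0^2$ to machine precision, and the
true BoS, extrapolated CoM and MoS are available in closed form.

The swing-phase geometry is parameterised by the step width $w$, the peak
CoM excursion toward the stance side $A$, and the peak ML velocity; the
pendulum invariant $(y - w/2)^2 - (\dot y/\omega_0)^2$ then fixes the
foot-off state, and the extrapolated CoM at contact follows as
$w/2 + (X_{fo} - w/2) e^{\omega_0 T_{sw}}$. Group and condition defaults
were chosen once so that a default trial shows the magnitudes reported
for adult gait initiation — BoS ≈ 0.14 m, extrapolated CoM ≈ 0.05 m from
the stance boundary, MoS ≈ 0.09 m — with slower, narrower initiation for
the elderly and Parkinson cohorts and a faster, higher-MoS
maximum-velocity condition. Per-participant anthropometrics are drawn
from the cohort means and SDs; lognormal multipliers (8% between
participants, 4% between trials, 5% on phase durations) provide the
variability that spreads the Bland–Altman abscissa.

### The noise model

Force and moment channels receive white Gaussian noise (2 N and
0.2 N·m SD — instrument-grade figures; no per-trial noise magnitudes are
reported for either system, so these defaults are declared, not derived).
Kinematic channels receive 3 mm SD noise that is **band-limited at 3 Hz**
(white noise low-passed and rescaled): markerless CoM error is smooth
pose-model jitter, not frame-wise white noise. This matters because the
backward difference multiplies high-frequency position noise by the
sampling rate — white 3 mm noise at 85 Hz would produce ~0.1 m/s velocity
noise and MoS scatter an order of magnitude beyond what agreement studies
of such systems report, whereas the band-limited model yields
paired-difference SDs around 0.01 m, the scale actually observed. The
bandwidth is a visible, configurable profile parameter
(`kin_noise_band`).

A constant markerless CoM offset (`bias_mls`) can be injected to create a
known inter-system bias; the default is zero — the generator does not
presuppose the equivalence that the statistics are meant to test, it
just contains no mechanism for disagreement beyond noise unless one is
asked for.

### What the generator does not emulate

Anteroposterior dynamics (only a cosmetic progression channel is
generated), vertical CoM motion (plate vertical force is body weight plus
noise), multi-step walking after the first contact (the post-contact tail
is a stylised single-support continuation), soft-tissue artefacts,
Parkinsonian tremor or freezing, and pose-estimation failure modes.
Passing tests therefore demonstrate the *pipeline's* correctness and the
statistics' calibration under realistic signal structure — not the field
performance of any particular camera system.

## Numerical choices

* **Zero-lag filtering**: second-order Butterworth, 15 Hz, forward and
  backward. "No-lag" does not pin down end handling, so a concrete,
  bit-stable rule is fixed: odd-reflection padding of $3(\text{order}+1)$
  samples and steady-state initialisation of each pass at its first
  padded sample, which makes the filter exact on constants and confines
  end transients to the padding.
* **Rate conversion**: each block is filtered at its native rate and then
  brought to the common 85 Hz grid by linear interpolation (how the
  kHz-range force signals were brought to 85 Hz is not specified
  anywhere; interpolation after low-pass filtering is the convention
  chosen here, and at these rates its error is far below noise).
* **CoP plateaus from the unfiltered trace**: the zero-lag filter's
  symmetric impulse response undershoots on the fast stance-to-landed
  CoP transition, which would bias the second plateau extremum outward by
  several millimetres; the raw plateaus are constant by construction and
  raw CoP noise (~0.3 mm at 700 N) is negligible. Filtering is reserved
  for the kinematic differentiation/integration chain.
* **Support threshold**: a plate's CoP is defined only while its vertical
  force exceeds 10 N; the combined CoP is the Fz-weighted mean over
  loaded plates. Whether the original analysis combined plates into one
  global trace or concatenated per-plate plateaus is not stated; the
  weighted global trace is used because it degrades gracefully to the
  single-plate layout.
* **Second single-stance window**: when the recording ends after the
  first contact, the landed-foot plateau is searched in a fixed 0.2 s
  window after contact.
* **Bayes factor quadrature**: the JZS integral is evaluated on a log
  scale by adaptive quadrature (relative tolerance 10⁻⁸), split at the
  mixing density's unit scale; an independent fixed-grid oracle with 10⁵
  nodes agrees to better than 10⁻⁵ relative error across a
  $(t, n, r)$ grid, and frozen reference values from an independent
  implementation pin the absolute scale.

## Statistical design choices

* **Trial level, not subject level.** The residual degrees of freedom of
  the published analysis (~476 for 33 participants) indicate trial-level
  observations rather than a subject-mean repeated-measures model, so the
  trial-level factorial ANOVA is primary here; `mos_anova(aggregate =
  TRUE)` provides the subject-aggregated variant. Type II sums of squares
  handle the unequal group sizes and reduce to the classical balanced
  decomposition when cells are balanced (tested to 10⁻⁸).
* **Relative differences** are per-trial percentages of the pair mean,
  the standard Bland–Altman choice; pairs with a zero mean are flagged
  and excluded from relative summaries.
* **The Bayes factor** is computed on trial-level paired differences
  pooled across strata (matching the single published equivalence
  number), default prior scale $r = 1/\sqrt 2$, with per-stratum
  supplements and a robustness curve over prior widths.
* Shapiro–Wilk failure annotates a Bland–Altman panel rather than
  aborting it.

## Problem sizes and reproducibility

The validation suite simulates full study-sized cohorts — 33 participants
(10 young, 11 elderly, 12 Parkinson), five trials per velocity condition,
330 trials of roughly 1.9 s at 1000 Hz (forces) and 85 Hz (kinematics) —
which the pipeline processes in well under a minute; unit tests use
smaller cohorts. All randomness flows from explicit integer seeds:
identical seeds give bit-identical trials and cohorts.

```{r example}
trial <- simulate_trial(gait_profile(seed = 7, force_sd = 0,
                                     moment_sd = 0, kin_sd = 0))
ev <- detect_events(trial)
rbind(mos_for_trial(trial, "fps", ev),
      mos_for_trial(trial, "mls", ev))
trial$truth$mos
```

## Limitations

The package interfaces (`gait_profile()`, `TrialRecord` CSVs,
`read_trial()`) accept real recordings, but everything quantitative shown
here is established on synthetic data; conclusions about any physical
camera or plate system require that system's data. The CLI-style batch
interface is intentionally absent — the exported functions compose with
the pipe, and `scripts/acceptance.R` shows the full end-to-end run. C3D
ingestion is not provided; trials enter either from the generator or from
the documented CSV dialect.
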