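---
title: "Pain-aware stimulation control for robot-assisted rehabilitation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pain-aware stimulation control for robot-assisted rehabilitation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empain)
```

## The problem

A rehabilitation robot mobilizing an impaired elbow or forearm must
decide, iteration by iteration, whether the patient is in pain and what
to do about it. Neither of the two obvious signals suffices alone: a
spike in motor current (resistive torque) can come from benign
resistance, and muscle contraction seen in surface EMG can accompany
ordinary effort. The estimator implemented here therefore treats pain as
a fuzzy quantity inferred jointly from muscle contraction, resistive
torque and the session's own history — the range of motion (RoM) already
attained — so that pain encountered in territory the joint has already
conquered is discounted and the session can continue.

`empain` simulates this whole loop: synthetic signal generation, EMG
conditioning, feature extraction, the two-block fuzzy cascade, and the
closed-loop session controller that drives a three-mode electrical
stimulator (pain relief, massage, relax).

## Synthetic signals

Surface EMG is modelled as an amplitude-modulated Gaussian random
process: white Gaussian noise is shaped by a zero-phase Butterworth
band-pass to the 10–2000 Hz EMG band, normalized to unit RMS, and
multiplied by a contraction envelope in `[0, 1]`. Power-line
interference is a 50 Hz sinusoid of configurable relative amplitude;
baseline drift is a pair of sub-5 Hz sinusoids; a white noise floor can
be added. All components are driven by a single seed, and identical
configurations produce bit-identical traces.

The default sampling rate is 10 kHz. Acquisition hardware in this space
is described with rates from 10 kS/s up to 100 kHz; 10 kHz is the rate
consistent with a 2 kHz upper band edge and is what the generator,
filters and tests use throughout. Amplitudes are arbitrary normalized
units — an analog gain stage would only rescale them, and the feature
normalization removes scale anyway.

Motor current is generated by inverting the motor relation `T = K_t I`
from a torque profile, with optional Gaussian sensor noise. Achieved-RoM
sequences ramp by a configurable gain per iteration — the default
scenario regains one degree per 50 flexion/extension repetitions — and
saturate at a ceiling bounded by the joint workspace (130° elbow
flexion, 90° forearm supination).

What the generator does **not** emulate: motor-unit action-potential
trains and their firing statistics, electrode lift/motion artifacts,
inter-muscle crosstalk, fatigue-induced spectral compression, or any
physiological link from stimulation back to muscle state. Passing
end-to-end tests on these signals therefore demonstrates that the
pipeline's logic behaves as designed, not that the pain estimates are
clinically valid.

## Conditioning and features

The band-pass is implemented as a high-pass/low-pass Butterworth cascade
(order 4 per stage by default) applied forward–backward
(`signal::filtfilt`), giving zero phase so feature windows are not
shifted; offline analysis permits the non-causal filter. Cascading the
two half-filters keeps each stage well conditioned even though the low
edge (10 Hz) is 0.2% of Nyquist. The notch is an order-2 Butterworth
band-stop centred at 50 Hz with width `center/Q`, `Q = 30` (≈1.7 Hz),
chosen to take ≥20 dB off the line frequency while leaving tones two
octaves away essentially untouched. When a signal's rate makes the
2 kHz edge infeasible, the edge is clipped to `0.45 fs` with a warning
rather than an error, so low-rate recordings remain usable.

Windows default to 0.2 s with 50% overlap — standard surface-EMG
practice, and 2000 samples per window at 10 kHz. Four time-domain
features are computed per window: RMS, the simple square integral
(SSI), the v-order estimator and the log detector. Three printed-form
quirks in the source material are resolved in favour of the canonical
definitions:

- SSI is computed as the energy `Σx²` (the non-squared variant `Σx` is
  available via `definition = "first_power"` for comparison; it is not
  an energy and can be negative).
- The v-order estimator uses `(E|x|^v)^(1/v)` with default `v = 3`, so
  the feature carries amplitude units like the others; `v = 2`
  reproduces RMS exactly, which the tests assert.
- The log detector takes `log(|x| + ε)` with `ε = 1e-12`, since the raw
  logarithm is undefined at zero crossings; an all-zero window yields ε.

Features are normalized onto `[0, 10]` by an affine map fitted on a
calibration recording (observed per-feature min/max). Values outside the
calibration range are clipped, not extrapolated: the fuzzy variable
domains are hard bounds. Whether the bounds come from a dedicated
calibration recording or any other series is the caller's choice;
`run_session()` self-calibrates only when no map is supplied, and the
cross-condition comparisons in the tests always share one map fitted on
a contraction ramp — with per-condition self-calibration the normalized
features of a weak and a strong contraction would look identical.

## The fuzzy engine

The engine is classical Mamdani: AND = min over antecedent membership
degrees, implication = min (the consequent Gaussian is clipped at the
rule activation), aggregation = pointwise max, defuzzification = center
of area. Membership functions are Gaussian,
`exp(-(x-c)²/(2σ²))`. For a variable with *m* labels the default layout
spaces centers evenly across the range with `σ = spacing/2`,
giving ≈0.6 crossover between neighbours; everything is overridable,
and systems round-trip losslessly through YAML documents.

CoA is computed numerically — closed forms do not exist for clipped
Gaussian mixtures — with trapezoidal sums on a uniform grid of 1001
points over the output range. The tests check grid convergence
(doubling the grid moves the shipped systems' outputs by <1e-4) and
agreement within 1e-3 with an independent brute-force rectangle-rule
oracle on a 10⁶-point grid; measured agreement is ~3e-6. Crisp inputs
are clipped into their variable's range before fuzzification, mirroring
the normalization clipping. An identically zero aggregate returns the
midpoint of the output range with a warning; with the shipped complete
rule bases this is unreachable (Gaussians only underflow to zero tens
of σ away), but user-edited rule bases can get there.

One numerical property worth knowing: with an ordinally monotone rule
base, Mamdani/CoA output is monotone at the membership-function centers
but can wiggle by a few tenths (on a 0–10 scale) *between* centers,
where max-aggregation dilutes neighbouring rules unevenly. The
monotonicity tests therefore sweep the MF-center lattice; monotonicity
between centers holds for the contraction and torque directions of the
shipped systems but is not guaranteed in general.

## The two-block pain cascade

Block 1 maps the four normalized features (five MFs each: very_low …
very_high) to muscle contraction on `[0, 10]` (three MFs). Block 2 maps
contraction (3 MFs), resistive torque on `[0, 65]` Nm (5 MFs; the elbow
actuator's torque bound) and the previously-attained RoM margin on
`[0, 130]°` (4 MFs; the elbow flexion workspace) to a pain level on
`[0, 10]` with four labels (none, low, moderate, severe). `|T|` is used
because pain should not depend on rotation direction.

The original expert rule tables were never published, so the shipped
rule bases are generated from an ordinal recipe and are fully
overridable from the YAML documents in `inst/extdata/`. Each antecedent
label is mapped to its index; a weighted sum of normalized indices is
divided by the positive weight mass, clipped to `[0, 1]` and binned
uniformly (floor binning) onto the consequent labels. Block 1 weights
the four features equally. Block 2 weights contraction and torque +1
and the attained-RoM margin −0.5: the discount tempers mid-level pain
evidence but can never pull maximal contraction-plus-torque evidence
below the top pain band — deliberately, as a safety property. Floor
binning (rather than rounding) makes a zero-evidence antecedent land on
the lowest consequent, so a quiet muscle against zero torque reads as
pain in the lowest quartile.

The third input deserves a precise definition. "Previously attained
RoM" is passed to Block 2 as a *margin*: the number of degrees by which
the best RoM achieved so far exceeds the currently commanded angle,
floored at zero. Commanding an angle beyond anything previously reached
gives margin 0 (no discount); commanding well inside conquered
territory gives a large margin (strong discount). The per-window torque
input is the mean of `|T|` over the analysis window by default, with
the peak available via `torque_aggregation = "peak"`.

## The session controller

A session is `n_exercises × reps_per_exercise` iterations (default
6 × 5 = 30), one analysis window per iteration — the window spanning
that iteration's share of the trace. In automatic mode the stimulation
selector applies three bands: pain ≥ threshold → pain relief;
pain ≥ `massage_fraction ×` threshold (default 0.5) → massage;
otherwise off. The massage band edges are configurable — the three
stimulator modes are fixed, their automatic triggers are this package's
design. In manual mode the therapist's preset mode is applied
unconditionally. When the session completes, the stimulator switches to
relax automatically and a terminal relax record closes the log.

On a pain-relief activation the controller *holds* the commanded angle
for the next iteration instead of advancing it (stimulate-then-retry);
rehabilitation proceeding despite pain is the point of the RoM-margin
discount. The alternative policy — abort the exercising phase on pain —
is available as `on_pain = "abort"`. What the robot does mechanically
during stimulation (pause vs. slow) is outside the simulation; holding
the command is the modelled behaviour.

RoM-recovery accounting is `100 × (final − initial)/initial`; a joint
improving from 60° to 110° is an 83.3% recovery, and the analogous
passive-torque reduction (e.g. 10 Nm → 7 Nm) is 30%.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic
data built at run time: 3.5 s traces at 10 kHz (33 analysis windows at
0.2 s / 50% overlap) per session, one shared calibration ramp, 50
random engine/oracle comparisons, and 1000 random feature windows.
These sizes give stable statistics at desk scale. Every stochastic
component flows through an explicit integer seed, and seeded runs are
bit-reproducible; the acceptance script derives all of its seeds from
its `--seed` argument.

## Known limitations

- The pain scale is ordinal and uncalibrated: crisp outputs are
  comparable across conditions within this model, not across patients.
- The rule bases encode a generic ordinal recipe, not the judgment of a
  rehabilitation expert; they are shipped as editable documents
  precisely so that domain rules can replace them.
- Clinical outcome numbers (RoM trajectories, torque reduction) in this
  package are arithmetic on simulated sequences, not predictions; the
  generator's recovery dynamics (linear ramp with saturation) are a
  deliberately minimal stand-in.
- Real-time causal filtering, artifact rejection, electrode placement
  effects and stimulation physiology are out of scope.
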