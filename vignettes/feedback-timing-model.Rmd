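---
title: "Feedback-based temporal control of articulatory gestures: the model and its implementation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feedback-based temporal control of articulatory gestures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tirsim)
```

## The model

`tirsim` simulates articulatory timing as interactions among dynamical
systems. *Gestural systems* are abstract control units whose activation
(normalized to [0, 1]) drives vocal-tract goals; they are not movements.
What is controlled is *when* gestural activation begins and ends, and the
central claim implemented here is that those events are caused by
*time-representing systems* (TiRs) acting on binary *gating systems*: a
gesture's activation is 1 while its gate is open and 0 while it is closed,
with single-step transitions.

TiRs never encode time in units of time. Each TiR has an activation state
that grows by integrating force, and a set of threshold actions: when the
state crosses a threshold τ, the TiR emits a pulse that opens (χ = +1) or
closes (χ = −1) a gate. Five classes are provided:

* **Aperiodic clocks (ε)** — autonomous; once de-gated, the state grows at a
  context-set rate ω (activation/s). With ω = 1 the state numerically equals
  elapsed open time, which makes thresholds readable as seconds; only the
  ratio τ/ω matters for the action time.
* **Planning oscillators (θ)** — autonomous and periodic. Each oscillator
  carries a phase, a radial amplitude, and the amplitude derivative. Phases
  advance at angular frequency ω plus sine coupling,
  dθᵢ/dt = ωᵢ + Σⱼ Φᵢⱼ sin(θⱼ − θᵢ), with Φᵢⱼ > 0 attractive (in-phase) and
  Φᵢⱼ < 0 repulsive (anti-phase); only these two coupling polarities are
  allowed. An oscillator triggers its gesture when its phase crosses 0
  (mod 2π) — one phase per cycle, the conventional peak of the cosine —
  and only while its amplitude is at or above a threshold (default 0.5).
  Amplitude relaxes, critically damped, toward 1 while the oscillator's
  gate is open and toward 0 while closed (rise to ~95% in `amp_rise_s`,
  default 50 ms); this is what prevents premature triggering and
  re-triggering on later cycles, together with one-shot arming of every
  action per gate-open episode.
* **Internal feedback integrators (T̂)** — non-autonomous; they integrate a
  source gesture's activation at rate α (dx = α·g·dt). They model
  predictive feedback that never leaves the central nervous system.
* **External feedback integrators (T̄)** — as above, but the input is the
  *delayed sensory trace* of the source, g(t − d). The default delay d =
  120 ms is a calibration constant chosen to exceed the typical
  constriction-release timescale (50–100 ms), which is the reason external
  feedback cannot govern prevocalic timing.
* **Intra-gestural integrators (T~)** — internal integrators restricted to
  source from and act on their own gesture; with an activation-to-phase
  conversion they emulate a "virtual cycle" (deactivation at virtual phase
  3π/2 corresponds to a threshold of 0.75/f seconds of input; see
  `tau_from_phase()`).

## Rate control

Two context ("surroundings") variables modulate TiR parameters.

*Self-attention* λ ∈ [0, 1] scales feedback integration rates as
α = α′ / (1 + βλ), with the sensitivities ordered β_internal < β_external
(validated at model construction; defaults 1 and 4). Because the externally
routed interval carries the fixed sensory delay while its λ-slope is
shallower, the first-past-the-post competition between the internal and the
external TiR acting on the same gate hands control from internal (fast
rates) to external feedback (slow rates) at a crossover λ\*; with the
shipped calibration (internal base interval 142 ms; external base 30 ms
plus the 120 ms delay) λ\* ≈ 0.364, and the vocalic-to-coda interval is a
continuous, increasing, piecewise-affine function of λ with a single slope
change at λ\*. The calibration was fixed from this closed form before any
simulation: VC(λ) = min{142(1 + λ), 120 + 30(1 + 4λ)} ms, giving 210 ms at
λ = 0.5, inside the 150–400 ms range typical of vocalic-to-coda timing.

*Pace* maps onto oscillator frequency through a logistic
f(λ) = f_min + (f_max − f_min)·σ((λ − 0.5)/s), with f bounded in the theta
band (3–8 Hz; s = 0.15). The bounds encode the hypothesis that planning
oscillations are band-limited, so oscillator-governed intervals saturate at
extreme rates while feedback-governed intervals keep growing — the central
asymmetry the rate-control experiment (`rate_sweep()`) demonstrates. One λ
drives both maps by default, since the rate-control scenario treats
attention and pacing as correlated; the two λs remain separately settable
in `tir_model` parameters.

*Selectional anticipation*: `apply_final_position_boost()` multiplies the β
of feedback TiRs belonging to word-final selection units by
`gamma_word_final` (default 1.2) and additionally by
`gamma_utterance_final` (default 1.6) in the utterance-final word. This
produces boundary-related lengthening without any phrase-structure
machinery; the defaults were chosen to make the final-word lengthening
clearly visible (tens of ms at mid λ) while remaining within the range of
the other calibration constants.

## Competitive selection

Serial order is produced by two parallel domains of competitive selection.
μ-systems (syllable-sized motor plans) carry an initial activation gradient
(defaults: 0.9, 0.8, 0.7, … in intended order, threshold 1, growth rate
1/s); while their gates are open all grow at the common rate, the first to
reach threshold is *selected* (ties resolve to the lowest index with a
warning), selection closes all competitor gates and de-gates the unit's
children (its oscillator bank), and the selected unit is later *suppressed*
— reset to zero and retired — by the feedback TiR that deactivates its
final gesture (the coda release for CVC, the vowel for CV). Suppression
re-opens the gates of the not-yet-selected competitors and the cycle
repeats until the set is exhausted. Concept systems (word-sized) form the
second domain: selecting a concept de-gates exactly its member μ-systems,
and the concept is suppressed when its last member is. Suppressed units are
retired permanently; whether they could re-enter competition is left open
by the theory, and retiring them is the minimal reading consistent with
"iterates until all systems have been selected and suppressed".

## The hybrid syllable

`compile_utterance()` builds CV and CVC syllables under hybrid control:
prevocalic constriction (C), release (R) and vocalic (V) initiations are
triggered by three phase-coupled oscillators (C–R repulsive, each
attractive to V), while V deactivation and the postvocalic constriction (c)
and release (r) are governed by competing internal/external feedback
integrators chained V → c → r.

The oscillator calibration deserves a note. With sine coupling, a common
trigger phase, and equal frequencies, the *steady-state* symmetric
displacement of C and R about V is at most a quarter cycle (the coupling
equilibrium satisfies cos φ = A/2|R| ≤ 1, i.e. φ ≤ π/2), which at the
5.5 Hz mid-rate frequency caps the CV interval at ≈45 ms — short of the
50–100 ms empirically typical of prevocalic timing. Trigger times, however,
depend on the oscillators' initial phases, which are part of the learned
specification the model takes as input. The shipped calibration therefore
sets the initial relative phases to ±2.1 rad (±120°) about the vowel
oscillator and uses weak coupling (±0.5 rad/s), whose role is to stabilize
the pattern against noise rather than to create it; the slow symmetric
drift toward the coupling equilibrium before the first trigger preserves
the c-center pattern (asymmetry ≈5% at λ = 0.5, within the 10% the model is
tested to). At λ = 0.5 this yields CV ≈ 59 ms and CR ≈ 115 ms.

The noise-correlation zoo model with oscillator triggering
(`fig8_coupled_osc`) instead uses strong coupling (±60 rad/s): there the
point is that phase-coupling forces lock heterogeneous frequencies to a
common value, so local frequency noise perturbs the shared frequency (and
hence both intervals, positively correlated) much more than the locked
phase offsets. With weak coupling that model would degenerate into
independent triggers and produce negative correlations.

## Noise model and the Δ-correlation experiments

Stochasticity is interpreted as utterance-to-utterance variation in the
surroundings: per run, every TiR's rate is multiplied once by
(1 + σ_g·η)(1 + σ_l·ηᵢ), with η shared across TiRs (global noise) and ηᵢ
independent (local noise); multipliers are frozen within the run, not white
in time. `corr_experiment()` crosses five levels of each (0–10% in 2.5%
steps by default, excluding the deterministic zero/zero cell; 200 runs per
cell by default) and reports the Pearson correlation across runs between
the successive initiation intervals Δ12 and Δ23, with Fisher 95% intervals.
The qualitative signatures — shared trigger r ≡ 1; chains r → 1 as local
noise vanishes and r → 0 as global noise vanishes; coupled oscillators
positive throughout; independent and hybrid extra-gestural triggers
negative under local-dominant noise, the hybrid more strongly — are what
distinguish control topologies, and are asserted in the test suite at
100–500 runs per cell (correlation estimates at those sizes have standard
errors of about 0.05–0.10, which the test tolerances reflect).

## Numerical scheme

Integration is forward Euler on a fixed grid, default dt = 1 ms; all
between-event dynamics are first- or second-order smooth, and the discrete
zoo uses parameters comfortably away from stability limits (the strongest
coupling gives K·dt = 0.06). Events are logged at the first grid step where
their crossing condition holds (`time_s`, quantization ≤ dt), and each
event also carries `time_exact_s`, the crossing time interpolated linearly
within the step. Because TiR states are piecewise-linear between events,
this interpolation is exact, and the engine keeps cascades exact too: when
a gate flips mid-step, the fraction of the step the source was actually
active is carried into the next integration window (including the delayed
trace used by external TiRs), competition growth is corrected the same way
when gates re-open mid-step, competitors are frozen at their activation at
the exact selection time, and a re-gated clock or oscillator is initialized
compensated for the partial step. Interval analysis uses the exact times;
this is why, for example, the shared-trigger correlation is 1 to machine
precision rather than 1 minus a quantization artifact, and why halving dt
moves every logged event by at most one original dt across the whole model
zoo (asserted in the tests). Initial oscillator phases may be negative — a
lag before the first trigger-phase crossing — and rise through 0 without
registering a crossing; wrapping happens only at 2π.

Degenerate inputs are handled explicitly: missing initiations yield flagged
interval records rather than silent drops; correlations from fewer than 3
complete runs or with zero variance are flagged rather than NaN; non-finite
states abort with the offending system and time; unknown references,
out-of-range λ, and β_internal ≥ β_external are configuration errors.

## Problem sizes and reproducibility

The shipped experiment sizes are desk scale: 200 Monte-Carlo runs per noise
cell (500 for the zero-expectation local-only chain cell), 11-point λ
grids, and 1–9 s simulated utterances. One root seed drives everything;
per-run child streams are derived by counter, so batches are reproducible
run by run and identical seeds give bit-identical event logs. Run manifests
(`write_run_manifest()`) record the configuration hash and seed alongside
every output set.

## What the simulations do and do not show

All inputs here are parameter settings, not data: the generator reproduces
the *structure* of the timing patterns (symmetric displacement, the
internal-to-external handoff, rate plateaus vs. expandability, boundary
lengthening, noise-correlation signatures), under calibration constants
chosen once from the empirical ranges cited above. Passing tests show the
control logic produces those patterns; they do not estimate any speaker's
parameters, and the optional one-dimensional tract-variable plant
(`tract_variable()`, critically damped, target-blending) is a reporting
device for movement-like traces, not a vocal-tract model — it never feeds
back into timing, and the external sensory trace is the delayed gestural
activation rather than a transduced movement signal (the theory leaves this
open; the delayed-activation reading is the simpler one and is the one
implemented). Accentual/stress gestures, multi-articulator
weighting, and acoustics are out of scope.
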