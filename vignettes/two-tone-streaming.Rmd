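---
title: "Delayed inhibition and two-tone streaming: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed inhibition and two-tone streaming: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twotone)
```

## The model and its assumptions

`twotone` implements a periodically forced competition network of two
Wilson–Cowan units coupled by fast mutual excitation (strength `a`) and
slow, *delayed* inhibition (strength `b`, delay `D`, decay `tau_i`).  Each
unit represents the population at the best-frequency location of one of two
alternating pure tones; its input is `c` during its own tone and
`d = c (1 - df^(1/m))` during the other tone, a monotone image of the tone
frequency difference `df` motivated by how tonotopic responses fall off
with frequency separation.  The defining feature is the timescale
separation `tau << tau_i`: excitation acts within a tone, while inhibition
from a response outlasts it and masks the *next* tone (forward masking).

Two standing structural assumptions are enforced by `validate_params()`:

* `U1: a - b < theta` — without input the quiescent state is the only
  equilibrium, excluding trivially saturated dynamics;
* `U2: c >= theta` — a tone can always recruit its own unit once
  inhibition has decayed.

together with tonotopy (`c >= d`) and the stimulus-timing restrictions
`TR >= TD`, `TR >= D`.  Most analytic results additionally assume
`TD + D < TR` (tones and their delayed inhibition do not reach into the
next tone), and split into a long-delay regime `D > TD` and the
physiologically plausible short-delay regime `D <= TD`.

A converged `2TR`-periodic orbit is summarized by its number `n` of upward
threshold crossings per period and mapped to a percept:
`4 -> INT` (integration), `3 -> BIS` (bistability), `2 -> SEG`
(segregation), `0 -> SAT` (saturation); any other count is `OTHER`.

## Parameters that matter

| symbol | meaning | unit | typical value |
|---|---|---|---|
| `a` | mutual excitation | – | 1–2 |
| `b` | delayed inhibition strength | – | 2–3 |
| `c` | on-frequency input | – | 3–5.5 |
| `d` or `df` | cross-frequency input / frequency difference | – | `d = c(1-df^{1/m})`, `m = 6` |
| `tau` | unit time constant | s | 0.01–0.025 |
| `tau_i` | inhibitory decay | s | 0.2–0.4 |
| `D` | inhibitory delay | s | 0.01–0.03 |
| `theta` | activity threshold | – | 0.5 |
| `TD` | tone (onset-response) duration | s | 0.005–0.03 |
| `TR` (`PR = 1/TR`) | tone repetition time (rate) | s (Hz) | `PR` in 1–40 Hz |
| `slope` | sigmoid steepness `lambda` | – | 30 |

The shipped presets (`preset_params()`) are the named parameter sets used
throughout the examples and tests; `fig3`/`fig11B` drive the smooth model,
`fig9B`/`fig9C` the long-delay analytic tables, `fig10` the short-delay
tables and boundary curves.

## The smooth model and its integrator

With the sigmoid gain the system is a smooth DDE.  Two design choices were
genuinely open:

* **Gain placement.** The logistic gain is evaluated as `S(x - theta)` —
  centred on the Heaviside threshold — so the smooth and non-smooth models
  share their half-activation point and the crossing-count classification
  keeps its meaning as `lambda` grows.
* **Step geometry.** The integrator is a classical RK4 method of steps.
  The step `h` divides the forcing period exactly (`h = 2TR/N`, `N` even)
  and is capped at `min(tau/10, TD/20, D/4, TR/200)`.  Dividing the
  *period* rather than the delay means consecutive periods are
  grid-aligned, so the periodicity residual (sup-norm difference between
  the last two `2TR` windows) is an exact grid comparison with no
  interpolation error; delayed synaptic values are instead read from the
  stored dense solution by 4-point cubic Lagrange interpolation, which is
  `O(h^4)` and therefore does not degrade the integrator's order.  The cap
  `h <= D/4` guarantees every interpolation stencil lies in the already
  computed past.

`periodic_state()` integrates 40 periods from the constant history
`(1, 0, 1, 0)` and extends in 20-period blocks (up to 200) until the
periodicity residual falls below `1e-5`; non-convergent runs are returned
flagged, never discarded.  Crossing detection counts upward passages
through `theta` with a hysteresis band of `1e-3` to reject grazing
contacts, and locates crossing instants by interpolation on the dense grid.

Accuracy: successive step halvings contract the converged window at clean
fourth order (factors 16–21 in the tests), but the steep gain
(`lambda = 30`) amplifies the truncation-error prefactor, so at the default
step the orbit is resolved to about `1e-3`; from an eighth of the default
step downward successive halvings agree below `1e-5`.  Crossing counts and
percepts are step-independent in every check, which is what the scientific
conclusions rest on.  An independent adaptive solver (`deSolve::dede` at
tolerance `1e-8`) reproduces the trajectories to `~1e-2` sup-norm — the
residual disagreement reflects transient sensitivity at near-threshold
switches, and both solvers count identical crossings.

## The singular limit as an event system

For `tau -> 0` with Heaviside gain the units become binary and the model a
hybrid system: between events each synapse is either held at 1 (unit ON) or
decays as `s0 exp(-(t-t0)/tau_i)` (unit OFF).  `run_singular()` advances an
event queue containing tone onsets/offsets, *delayed landmarks* (`D` after
every unit switch, when the delayed trace seen by the other unit jumps),
and interior threshold crossings of decaying inhibition, whose times are
closed-form: `t = t0 + D + tau_i log(b s0 / (drive - theta))`.

At each event the binary configuration is resolved to a fixed point of the
instantaneous switching rules: turn-offs first, then turn-ons, iterated.  A
turn-on enabled by the *other* unit switching on within the same instant is
recorded with `cascade_rank = 1` — the infinitesimally delayed onset of the
singular limit, whose lag at finite `tau` is
`delta = tau log(1/(1-u*))` (`delta_lag()`).  When the quiescent and active
configurations coexist, the current one persists until its own
admissibility fails (hysteresis); this is the continuity convention under
which the analytic lemmas operate.  Ties at identical timestamps are
processed input-change first, then delayed jumps, then unit switches, with
A before B purely for bookkeeping — the cascade resolution fixes the
physical order.  Numerical conventions: events are grouped within `1e-9` s;
threshold comparisons carry a `1e-9` slack on the ON side so closed-form
crossing times (where the drive equals `theta` up to rounding) fire; a
segment lookup at exactly a landmark reads the post-jump segment.  A Zeno
guard aborts after `1e6` events; no physical trajectory of this system
comes near it.

The stabilized per-interval raster (codes: on at onset, on after the
cascade lag, interior turn-on, silent) is the object compared against the
analytic tables.

## Analytic state atlas

In one active tone interval the possible dynamics reduce to a binary
`2 x 2` matrix (turn-on at onset / on by offset per unit); exactly six of
the sixteen candidates are admissible (`admissible_main_matrices()`), and
the per-interval existence conditions (`interval_condition()`) partition
parameter space.  Gluing two intervals into a `2TR`-periodic orbit and
imposing the closure conditions leaves, in the long-delay regime, nine
states (`S, SB, SD, AP, AS, ASD, I, ID, IB`) whose conditions involve the
synaptic decay landmarks `N±`, `M±` plus extra gap-silence conditions
(`C9`, `C10`); the brute-force enumeration (`enumerate_2x4_forms()`)
recovers exactly these nine matrices plus the conjugates of the six
asymmetric ones.  One addition to the closure rules is needed: the all-zero
matrix passes them but is excluded by `U2` (a permanently silent periodic
state would let the synapses decay until the tone input alone fires a
unit).  Only the pairs `(I, SB)` and `(I, SD)` can coexist;
`coexistence_scan()` verifies this by random search.

In the short-delay regime (`D <= TD`, strong input `c - b >= theta`) each
unit is ON throughout its own tone and the classification hinges on what
the cross unit does in the lead window `[alpha, alpha + D]`: the nine
states `I, ID, IS, IDS, AS, ASD, AP, APcAS, AScI` with mutually exclusive
conditions (`bio_state()`).  One landmark deserves a note: in this regime
the decaying trace that can recruit the cross unit is cut off at the lead
window's end, where its value is `exp(-(2TR - TD)/tau_i)` — not the
long-delay landmark `exp(-(2TR - D)/tau_i)`.  The package exposes the
corrected quantity as `C2_plus_sd` in `condition_values()` and uses it for
the `AP`/`APcAS` split; the event-driven simulator, which knows nothing of
the tables, confirms the corrected split on random draws and sweeps
(`tests/testthat/test-oracle.R`).

`boundaries()` returns the fission and coherence curves in two variants:
`"printed"` evaluates the closed forms
`[(a - bN+ + c - theta)/c]^m` and `[(a - bM+ + c - theta)/c]^m`
(`N+ = exp(-(TR-D)/tau_i)`, `M+ = exp(-(2TR-TD)/tau_i)`), which track the
`AScI`↔`AS` and `APcAS`↔`AP` transitions respectively — the INT|BIS and
BIS|SEG percept boundaries; `"derived"` solves the state-table transition
conditions directly (`APcAS`↔`AP` from the corrected `C2+`, `AScI`↔`IDS`
from `R6-`).  The two variants use different transition pairs by
construction and bracket the bistable band differently; both are checked
against sweep-detected transitions.

## Sweeps and the van Noorden diagram

`run_sweep()` evaluates a uniform `(PR, df)` grid with any of the three
engines and returns a tidy per-cell table (counts, percept, state,
residual, validity).  `df` is sampled uniformly in `df` (not in semitones),
the default grid is 96 × 96, and each smooth-engine cell restarts from the
same history `(1, 0, 1, 0)` unless `warm_start` is requested, so results
are a pure function of the spec.  Per-cell failures (for instance analytic
classification outside `TD + D < TR`) are recorded as invalid cells, never
aborting the sweep.  The test suite and the acceptance script use reduced
48 × 48 grids for the smooth engine and 8–10 × 96 grids for the singular
engine; these sizes resolve every region and boundary of interest while a
single sweep stays under a minute of compute.

## What the checks do and do not show

The cross-validation triangle — analytic tables vs. event-driven singular
simulation vs. smooth DDE at steep gain — is strong evidence that the three
implementations encode the same dynamical system, including its boundary
structure.  It does not validate the model against auditory data: the
psychoacoustic boundary measurements the model was designed to match are an
external dataset and are not reproduced here.  Likewise the smooth model at
moderate `lambda` and `tau` is close to but not identical with the singular
limit; percept labels may differ in cells adjacent to analytic boundaries,
which is expected and quantified rather than suppressed.

## Known limitations

* Only two tonotopic channels and strict ABAB forcing; no triplet (ABA_)
  patterns, no stochastic inputs.
* Existence conditions cover the states reachable under `TD + D < TR`; for
  `TD + D >= TR` the simulators still run but rasters with multiple
  switches per interval are reported as `unclassified`.
* The analytic machinery addresses existence, not stability; stability is
  probed only empirically through convergence from the standard history.
* Percept *selection* and perceptual switching (the downstream competition
  that resolves bistability over seconds) are outside the model's scope.
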