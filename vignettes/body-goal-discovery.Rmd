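---
title: "Competence-driven discovery of touch goals on a simulated body"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competence-driven discovery of touch goals on a simulated body}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodygoals)
```

## The model

`bodygoals` simulates the hypothesis that early body knowledge is acquired
not by undirected motor babbling but by *self-generated goals* selected
through competence-based intrinsic motivation.  The agent is a planar
kinematic body (torso plus two 3-link arms, six joint angles, no
dynamics) covered by touch sensors on its one-dimensional surface.  Four
coupled components close the loop:

1. a **goal generator**: an online self-organizing map clustering the
   positive change of touch activation, encoded as a two-dimensional
   neural map;
2. a **goal selector**: softmax sampling over per-goal competence
   improvement at each trial start;
3. a **motor controller**: a leaky echo-state network reading the selected
   goal, blended with sinusoidal babbling by current competence, plus an
   associative memory of goal-accomplishing postures;
4. a **predictor** producing the two intrinsic-motivation signals — the
   competence ψ (a delta-rule estimate of the probability of matching the
   goal when selected) and the improvement ξ (a slow decaying average of
   the positive prediction error).

Every learning rate in the system is gated by ψ: prototypes, stored
postures and the goal map all freeze as competence saturates, so the
developmental trajectory is babble → focus on newly discovered goals →
uniform, disinterested mastery.

A trial ends at the first timestep where the thresholded map outcome
equals the selected goal, or after `max_steps`.  The predictor and
improvement updates happen once per trial; map and readout learning
happen at every timestep.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `som$eta_som` | 0.25 | – | base map learning rate |
| `reservoir$alpha` | 0.01 | – | readout delta-rule learning rate |
| `reservoir$tau_dr` | 100 | timesteps | reservoir leak time constant |
| `noise$beta` | 50 | timesteps | babbling timescale (period β/f) |
| `memory$tau_d_floor` | 1.2 | trials | floor of the posture-memory decay constant |
| `competence$eta_pred` | 0.35 | – | predictor learning rate |
| `competence$tau_xi` | 5 | trials | improvement smoothing constant |
| `selector$gamma` | 10 | – | softmax gain on ξ |
| `reservoir$epsilon` | 0.05 | – | spectral-radius margin |
| `som$theta_o` | 0 | activation | outcome threshold |
| `experiment$max_steps` | 200 | timesteps | trial time limit |

Architecture sizes: 30 sensors, a 20×20 encoded input map (400 inputs),
5×5 goal units, 150 reservoir units, 6 readouts, 8,000 trials by default.

Choices worth explaining:

* **γ = 10.**  The improvement signal ξ lives in [0, 0.2] per success
  (one success contributes `1/τ_ξ`); a gain of 10 makes a single fresh
  discovery roughly e² ≈ 7 times more likely to be selected than a
  stale goal, which produces the focussed practice bouts that the slow
  ξ decay is there to support.  The softmax uses the printed gain form
  `exp(ξγ)`, not the `exp(ξ/γ)` temperature form.
* **τ_ξ = 5 matters**: with `tau_xi = 1` (no smoothing) the focussing
  disappears and convergence degrades — the smoothing is load-bearing,
  not cosmetic.
* **θ_o = 0** together with prototypes initialized in U[0, 0.1]
  guarantees that a silent input (all-zero change map) yields strictly
  negative activations `−½‖w‖²`, so stillness can never generate an
  outcome or a spurious match.
* **τ_d floor.**  The posture memory's decay constant is
  `τ_d = max(1.2, 1/(1−ψ))`: pure competence gating at high ψ, but never
  faster than 1/1.2 per match, except that a goal's *first* match stores
  the experienced posture verbatim.
* **ε and the spectral bound.**  With `dt/τ_dr = 0.01` the update matrix
  `M = 0.01·W_rec + 0.99·I` has radius 0.99 even for `W_rec = 0`; the
  initializer rescales `W_rec` so that ρ(M) sits at the midpoint of
  `(max(1−ε, 0.99), 1)`, verified by eigendecomposition at construction.

## The body as data generator

All sensory data is produced by the simulated body itself; there is no
external data.  The defaults *are* the study conditions: unit links, a
torso of width 33/7 placing the shoulders at arclength 0.28 and 0.72 of
the body (so the "chest" spans the central region and is the area exposed
to both hands), touch σ = 2% of the body arclength, joint limits ±π, and
30 uniform sensors.  The sensor-density variant
(`density_variant = TRUE`) keeps everything else fixed and places 10
sensors on the first two thirds of the surface and 20 on the last third.

Two geometric decisions were genuinely open and are worth recording:

* **Torso width.**  The shoulder landmarks at 0.28/0.72 of the body
  length pin the torso/arm ratio; a narrow torso would make the chest a
  sliver and lose the chest-dominant touch profile of random movement.
* **Own-hand masking.**  Masking is specified as an arclength radius
  around each hand within which sensors ignore that hand.  The default
  radius equals the arm length, i.e. an arm's sensors respond only to the
  contralateral hand.  The babbling trajectories (cosines of uniform
  phase) spend most of their time near the fold limits ±π, which parks a
  hand on its own forearm; a small mask would let this dwell permanently
  activate own-arm sensors and swamp every touch statistic.  With the
  arm-length mask, arm touches are contralateral, the chest is touched
  most, and the shoulders (hidden in the arm/torso angle) least.

What the simulation does *not* emulate: collision or self-intersection
(links pass through each other), inertia or muscle dynamics, receptor
adaptation, proprioceptive or visual channels, and any noise in sensing.
Passing tests therefore show the *architecture's* competence dynamics on
an idealized body, not a claim about real tactile physiology.

## Numerical choices

* **Encoding.**  The change profile is linearly resampled in
  sensor-index space onto 20 columns; each active column gets a
  fixed-width (σ = 1.5 rows) Gaussian bump *place-coded* by amplitude:
  centre row `round(amp · 19) + 1` with amplitude clipped to [0, 1].
  Index-space (rather than arclength-space) resampling means a denser
  body region owns proportionally more of the goal map — which is
  exactly the mechanism probed by the density variant.  Place coding was
  chosen over rate coding because the vertical axis of the encoded map
  represents intensity as a *position*.
* **Winner ties** break to the lowest unit index; the activation winner
  is proven (and property-tested) identical to the brute-force nearest
  prototype.
* **Neighbourhood.**  Θ is binary on the Euclidean grid distance with
  threshold `(1−ψ̄) · max_grid_distance`: the full grid at zero
  competence, shrinking to the winner alone as ψ̄ → 1.  A raw threshold
  in [0, 1] would almost always include only the winner.
* **Integration.**  All leaky updates use explicit Euler steps: `dt = 1`
  timestep for the reservoir (`dt/τ_dr = 0.01`), `dt = 1` trial for ψ, ξ
  and the posture memory, since those signals are defined per trial.
* **Normalized postures.**  Stored target postures are joint angle / π so
  that they are commensurate with the readout's [0, 1) range; the π
  factor in the command blending restores radians.  The readout
  derivative is the tanh derivative masked to 0 where the positive-part
  clamp is active.
* **Trial boundaries.**  The reservoir state resets to zero each trial;
  the previous-touch reference for the first change computation is the
  touch pattern of the standing start posture, so trial onset itself
  cannot be encoded as a goal.  Babbling frequencies are drawn per joint,
  once per trial.
* **Degenerate inputs.**  Zero-trial runs yield empty logs; a 1×1 goal
  grid has zero grid diameter and thus never updates its single
  prototype; non-finite postures, mismatched vector lengths and
  non-positive ε are rejected with errors.
* **ξ of non-selected goals** is left untouched between selections (the
  per-trial update is vector-masked by the one-hot goal); letting it
  decay passively would bias selection toward recently selected goals
  beyond what the equations state.

## Problem sizes used in the tests

The stochastic acceptance tests run scaled-down conditions chosen to keep
a full suite run in a few minutes: a 3×3 goal grid with 15 sensors,
2,000 trials of ≤ 100 steps (convergence, coverage, duration-vs-age, and
the random baseline with 200 trials), and the density-variant body at
full 5×5 size for 3,000 trials of ≤ 200 steps, analysed in
10,000-timestep epochs.  Deterministic properties (winner equivalence,
spectral bounds, closed-form predictor convergence, freeze limits) are
tested at full size.

## Known limitations

* With the arm-length mask, hand-to-hand touches are rare under random
  movement in this geometry, so hand-end sensors do not show the peak
  frequencies a narrower mask would give them.
* The readout can only command non-negative joint angles
  (`z ∈ [0, 1)` scaled by π); postures discovered by babbling with
  negative angles are approximated at 0 by the learned skill and refined
  through the memory's decaying average under the mixed policy.
* Convergence at desk scale is partial (mean ψ ≈ 0.8 after 2,000 trials
  on the 3×3 body) — the trends, not the asymptotes, are the tested
  claims.
* Trials are capped at `max_steps`; the cap interacts with the slow
  reservoir transient (τ_dr = 100), so very short caps would prevent the
  learned skill from expressing itself.
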