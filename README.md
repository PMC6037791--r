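# bodygoals

Simulation of how an embodied agent can acquire knowledge of its own body
— which touch sensations it can cause, and how to cause them — purely from
**competence-based intrinsic motivation**, with no external task or reward.

The agent is a planar body: a torso with two kinematic 3-DoF arms (6 joint
angles in total) covered by 30 touch sensors living on the one-dimensional
body surface.  A sensor responds to each hand with a Gaussian of their 2-D
distance; sensors on an arm ignore that arm's own hand.  The controller is
built from four interacting components:

* **Goal generator** — an online self-organizing map (SOM).  The positive
  change of touch activation is encoded as a 20×20 map (horizontal: body
  position; vertical: place-coded change amplitude) and clustered by a 5×5
  SOM whose unit activation is `y_j = w_jᵀx − ½w_jᵀw_j` (equivalent to the
  nearest-prototype rule, but thresholdable).  Its learning step,
  `Δw_j = η_som (1−ψ̄)(1−ψ_j) Θ(win, j, (1−ψ̄)) (x − w_j)`,
  is gated by competence: mastered goals freeze their own prototypes and a
  globally competent agent freezes the whole map.
* **Goal selector** — at each trial start, one of the 25 goals is sampled
  from a softmax over the competence improvements,
  `p(g_j) ∝ exp(ξ_j γ)`, focusing practice on goals whose competence is
  currently rising.
* **Motor controller** — a leaky echo-state network (150 units, leak time
  constant τ_dr = 100, recurrent weights spectrally normalized into
  (1−ε, 1)) reads the selected goal and outputs 6 joint commands
  `z = [tanh(W a)]⁺`, blended with a per-joint sinusoidal babbling
  trajectory `n_j = cos(2πf_j t/β + π)`:
  `m = π(ψ_s z + (1−ψ_s) n)`.  An associative memory stores, per goal, the
  posture experienced at goal accomplishment (as a competence-gated
  decaying average) and the readout is trained toward it by a delta rule
  every timestep.
* **Predictor** — per-goal competence `ψ_j ∈ [0,1]` tracks the probability
  of accomplishing the goal (`Δψ = η_pred(match − pred) ⊙ g`), and the
  improvement signal `ξ` is a slow decaying average of the positive
  prediction error (`τ_ξ ξ̇ = −ξ + [match − pred]⁺`).

A *matching* event — the SOM outcome unit activated by the current touch
change coincides with the selected goal — ends the trial, rewards the
predictor and teaches the motor memory.  Every learning rate in the system
is modulated by ψ, so the architecture autonomously moves from motor
babbling to goal-directed skill, then freezes.

## Worked example

A scaled-down agent (3×3 goal grid, 15 sensors, 2,000 trials of at most
100 steps) runs in well under a minute:

```r
library(bodygoals)
cfg <- simulation_config(
  som = list(grid = c(3, 3)),
  body = list(n_sensors = 15),
  experiment = list(n_trials = 2000, max_steps = 100, seed = 1)
)
log <- run_simulation(cfg)
print(log)
#> <simulation_log> 2000 trials, 96425 timesteps
#>   matched: 1464 (73.2%), final mean psi = 0.776
```

73% of all trials end in a goal match, and the agent's mean self-estimated
competence over its 9 goals reaches 0.78 by trial 2,000.  Practice makes
skills faster:

```r
dv <- duration_vs_goal_age(log)
head(dv, 3)
#>   age mean_duration  mean_psi n
#> 1   1      13.44444 0.3500000 9
#> 2   2      27.11111 0.5775000 9
#> 3   3      25.88889 0.6961792 9
cor(dv$age, dv$mean_duration, method = "spearman")
#> [1] -0.25
```

The negative correlation says trials get shorter as a goal accumulates
successes.  The post-convergence touch histogram
(`touch_histogram(log, trials = 1501:2000)`) is positive at every sensor —
the self-formed goals cover the whole body space — and
`random_baseline(cfg)` shows the purely-random reference profile, maximal
in the central "chest" region that both hands can reach.

Other entry points: `density_variant_positions()` / 
`simulation_config(density_variant = TRUE)` for the body with a denser
right third of sensors, `epoch_touch_profile()` for early-versus-late
developmental comparisons, `goal_formation_history()` for the competence
trajectory of each goal, and `write_simulation_log()` for plain-text (CSV)
logs.  A thin command-line front end with `simulate`, `baseline` and
`analyze` subcommands is installed at `inst/cli/bodygoals.R`; default
configurations ship in `inst/extdata/`.

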