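body:
  link_lengths:
  - 1.0
  - 1.0
  - 1.0
  torso_width: 4.714285714285714
  n_sensors: 30.0
  joint_limits:
  - -3.141592653589793
  - 3.141592653589793
encoding:
  rows: 20.0
  cols: 20.0
  bump_sigma: 1.5
som:
  grid:
  - 5.0
  - 5.0
  eta_som: 0.25
  theta_o: 0.0
  init_range:
  - 0.0
  - 0.1
selector:
  gamma: 10.0
reservoir:
  n_units: 150.0
  tau_dr: 100.0
  dt: 1.0
  epsilon: 0.05
  alpha: 0.01
noise:
  beta: 50.0
memory:
  tau_d_floor: 1.2
competence:
  eta_pred: 0.35
  tau_xi: 5.0
experiment:
  n_trials: 8000.0
  max_steps: 200.0
  snapshot_every: 100.0
  seed: 1.0
density_variant: no
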