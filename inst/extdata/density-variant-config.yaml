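body:
  link_lengths:
  - 1.0
  - 1.0
  - 1.0
  torso_width: 4.714285714285714
  n_sensors: 30.0
  sensor_arc_positions:
  - 0.0
  - 0.074074074074074
  - 0.148148148148148
  - 0.222222222222222
  - 0.296296296296296
  - 0.37037037037037
  - 0.444444444444444
  - 0.518518518518518
  - 0.592592592592593
  - 0.666666666666667
  - 0.683333333333333
  - 0.7
  - 0.716666666666667
  - 0.733333333333333
  - 0.75
  - 0.766666666666667
  - 0.783333333333333
  - 0.8
  - 0.816666666666667
  - 0.833333333333333
  - 0.85
  - 0.866666666666667
  - 0.883333333333333
  - 0.9
  - 0.916666666666667
  - 0.933333333333333
  - 0.95
  - 0.966666666666667
  - 0.983333333333333
  - 1.0
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
density_variant: yes
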