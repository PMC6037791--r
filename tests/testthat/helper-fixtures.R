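# small configurations used across tests

tiny_cfg <- function(seed = 7, n_trials = 30, max_steps = 40) {
  simulation_config(
    som = list(grid = c(2, 2)),
    body = list(n_sensors = 12),
    reservoir = list(n_units = 40),
    experiment = list(n_trials = n_trials, max_steps = max_steps, seed = seed)
  )
}

# independent forward-kinematics oracle: accumulate 2x2 rotation matrices
# link by link instead of summing angles
rotmat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

fk_oracle_hand <- function(angles, anchor, base_angle, links) {
  D <- rotmat(base_angle)
  p <- anchor
  for (k in seq_along(links)) {
    D <- D %*% rotmat(angles[k])
    p <- p + drop(D %*% c(links[k], 0))
  }
  p
}
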