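test_that("recurrent weights are normalized into the spectral band", {
  set.seed(51)
  params <- init_reservoir(n_units = 60)
  # independent check: eigenvalues of the assembled update matrix
  k <- params$dt / params$tau_dr
  M <- k * params$W_rec + (1 - k) * diag(params$n_units)
  rho <- max(Mod(eigen(M, only.values = TRUE)$values))
  expect_equal(rho, params$spectral_radius, tolerance = 1e-9)
  expect_gt(rho, 1 - params$epsilon)
  expect_lt(rho, 1)
  expect_error(init_reservoir(epsilon = 0), "positive")
  expect_error(init_reservoir(epsilon = -0.1), "positive")
})

test_that("zero input is an exact fixed point and activity stays in [0, 1)", {
  set.seed(52)
  params <- init_reservoir(n_units = 50, n_inputs = 9)
  st <- reservoir_state(params)
  for (i in 1:50) st <- reservoir_step(st, params, numeric(9))
  expect_identical(st$r, numeric(50))
  expect_identical(st$z, numeric(6))

  g <- c(1, numeric(8))
  st <- reservoir_state(params)
  for (i in 1:200) {
    st <- reservoir_step(st, params, g)
    expect_true(all(st$a >= 0 & st$a < 1))
    expect_true(all(st$z >= 0 & st$z < 1))
  }
})

test_that("a constant goal input settles the reservoir onto an attractor", {
  set.seed(53)
  params <- init_reservoir(n_units = 50, n_inputs = 4)
  g <- c(0, 1, 0, 0)
  st <- reservoir_state(params)
  for (i in 1:5000) {
    prev <- st$r
    st <- reservoir_step(st, params, g)
  }
  expect_lt(sqrt(sum((st$r - prev)^2)), 1e-8)
})

test_that("different initial states washed by the same input converge (echo property)", {
  set.seed(54)
  params <- init_reservoir(n_units = 80, n_inputs = 4)
  g <- c(0, 0, 1, 0)
  s1 <- reservoir_state(params)
  s2 <- reservoir_state(params)
  s2$r <- rnorm(80)
  s2$a <- pmax(tanh(s2$r), 0)
  for (i in 1:10000) {
    s1 <- reservoir_step(s1, params, g)
    s2 <- reservoir_step(s2, params, g)
  }
  expect_lt(sqrt(sum((s1$r - s2$r)^2)), 1e-6)
})

test_that("readout clamps negatives and saturates below 1", {
  set.seed(55)
  params <- init_reservoir(n_units = 10, n_inputs = 2)
  a <- runif(10)
  expect_equal(readout(a, params), numeric(6))      # zero weights
  params$W_out[1, ] <- -5
  params$W_out[2, ] <- 1
  z <- readout(a, params)
  expect_equal(z[1], 0)
  expect_gt(z[2], 0.99)
  expect_lte(z[2], 1)
})

test_that("the delta rule is gated by error, learning flag and clamp derivative", {
  set.seed(56)
  params <- init_reservoir(n_units = 10, n_inputs = 2)
  a <- runif(10)
  st <- list(pre = drop(params$W_out %*% a))
  z <- pmax(tanh(st$pre), 0)
  same <- readout_update(params, d_s = z, z = z, pre = st$pre, a = a)
  expect_equal(same$W_out, params$W_out)
  off <- readout_update(params, d_s = z + 1, z = z, pre = st$pre, a = a,
                        learned = FALSE)
  expect_equal(off$W_out, params$W_out)
})

test_that("a scalar readout trained on constant activity converges to its target", {
  params <- list(W_out = matrix(0, 1, 1), alpha = 0.05)
  a <- 0.8
  d <- 0.6
  for (i in 1:500) {
    pre <- params$W_out[1, 1] * a
    z <- max(tanh(pre), 0)
    params <- readout_update(params, d, z, pre, a)
  }
  expect_equal(max(tanh(params$W_out[1, 1] * a), 0), d, tolerance = 1e-3)
})

test_that("readouts trained on two goals settle on distinct attractors", {
  set.seed(57)
  params <- init_reservoir(n_units = 60, n_inputs = 4)
  d1 <- c(0.8, 0.2, 0.5, 0.1, 0.9, 0.3)
  d2 <- c(0.1, 0.7, 0.2, 0.6, 0.2, 0.8)
  run_trial_steps <- function(params, g, d, steps = 150, train = TRUE) {
    st <- reservoir_state(params)
    for (t in seq_len(steps)) {
      st <- reservoir_step(st, params, g)
      if (train) params <- readout_update(params, d, st$z, st$pre, st$a)
    }
    list(params = params, z = st$z)
  }
  g1 <- c(1, 0, 0, 0)
  g2 <- c(0, 1, 0, 0)
  for (rep in 1:40) {
    params <- run_trial_steps(params, g1, d1)$params
    params <- run_trial_steps(params, g2, d2)$params
  }
  z1 <- run_trial_steps(params, g1, d1, train = FALSE)$z
  z2 <- run_trial_steps(params, g2, d2, train = FALSE)$z
  expect_gt(sqrt(sum((z1 - z2)^2)), 0.1)
  expect_lt(sqrt(sum((z1 - d1)^2)), sqrt(sum((z1 - d2)^2)))
})

test_that("the babbling trajectory follows its cosine definition", {
  f <- runif(6)
  expect_equal(random_trajectory(0, f), rep(-1, 6))
  expect_equal(random_trajectory(123, numeric(6)), rep(-1, 6))
  expect_equal(random_trajectory(50, rep(0.5, 6), beta = 50),
               rep(cos(2 * pi * 0.5 + pi), 6))
  set.seed(58)
  for (t in sample(0:500, 20)) {
    f <- runif(6)
    expect_equal(random_trajectory(t, f, beta = 50),
                 cos(2 * pi * f * t / 50 + pi))
    expect_true(all(abs(random_trajectory(t, f)) <= 1))
  }
  expect_error(random_trajectory(-1, f), "non-negative")
})

test_that("commands blend reservoir and babbling by competence and clip to limits", {
  z <- runif(6)
  n <- runif(6, -1, 1)
  expect_equal(mix_commands(z, n, 1), pi * z)
  expect_equal(mix_commands(z, n, 0), pi * n)
  expect_equal(mix_commands(z, z, 0.5), pi * z)
  lim <- matrix(c(-1, 1), 6, 2, byrow = TRUE)
  expect_true(all(abs(mix_commands(z, n, 0.3, joint_limits = lim)) <= 1))
  expect_error(mix_commands(z, n, 1.2), "\\[0, 1\\]")
})

test_that("the associative memory stores, tracks and freezes target postures", {
  mem <- motor_memory(4)
  p <- runif(6, -1, 1)
  mem <- memory_update(mem, 2, p, psi_j = 0.9)
  expect_true(mem$learned[2])
  expect_equal(mem$D[2, ], p)            # first match stores verbatim
  expect_false(any(mem$learned[-2]))

  # unfloored rule: zero competence copies the posture exactly
  p2 <- runif(6, -1, 1)
  m2 <- memory_update(mem, 2, p2, psi_j = 0, tau_floor = 1)
  expect_equal(m2$D[2, ], p2)

  # psi = 0.5, from 0 toward 1: halfway
  mem3 <- motor_memory(1)
  mem3$learned[1] <- TRUE
  mem3 <- memory_update(mem3, 1, rep(1, 6), psi_j = 0.5, tau_floor = 1)
  expect_equal(mem3$D[1, ], rep(0.5, 6))

  # floored rule caps the step at 1/tau_floor
  m4 <- motor_memory(1)
  m4$learned[1] <- TRUE
  m4 <- memory_update(m4, 1, rep(1, 6), psi_j = 0, tau_floor = 1.2)
  expect_equal(m4$D[1, ], rep(1 / 1.2, 6))

  # high competence freezes the stored posture
  frozen <- memory_update(mem, 2, p2, psi_j = 1)
  expect_equal(frozen$D[2, ], mem$D[2, ])
})
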