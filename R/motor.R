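#' Initialize the echo-state motor network
#'
#' Builds a leaky echo-state network ("dynamic reservoir"): `n_units`
#' recurrent units driven by the one-hot selected goal through Gaussian
#' input weights, with Gaussian recurrent weights rescaled so that the
#' discrete-time update matrix `M = (dt/tau_dr) W_rec + (1 - dt/tau_dr) I`
#' has spectral radius strictly inside `(1 - epsilon, 1)` (the reservoir
#' property: rich but non-chaotic transients that settle to input-specific
#' attractors, and to zero under zero input).  The rescaling solves for the
#' scalar that places the radius at the midpoint of the admissible
#' interval.  Readout weights start at zero so that a zero goal produces a
#' zero motor command.
#'
#' @param n_units reservoir size (default 150).
#' @param n_inputs number of goal units (default 25).
#' @param n_outputs number of readout units / joints (default 6).
#' @param tau_dr leak time constant in timesteps (default 100).
#' @param dt integration step (default 1 timestep).
#' @param epsilon spectral-radius margin, must be positive (default 0.05).
#' @param alpha readout learning rate (default 0.01).
#' @return an object of class `reservoir_params` including the verified
#'   `spectral_radius`.
#' @export
init_reservoir <- function(n_units = 150, n_inputs = 25, n_outputs = 6,
                           tau_dr = 100, dt = 1, epsilon = 0.05,
                           alpha = 0.01) {
  if (epsilon <= 0) stop("`epsilon` must be positive", call. = FALSE)
  k <- dt / tau_dr
  if (k <= 0 || k > 1) stop("`dt/tau_dr` must lie in (0, 1]", call. = FALSE)
  leak_rho <- abs(1 - k)            # radius of M when W_rec = 0
  if (leak_rho >= 1) stop("leak term alone violates the bound", call. = FALSE)
  target <- (1 + max(1 - epsilon, leak_rho)) / 2

  W_in <- matrix(stats::rnorm(n_units * n_inputs), n_units, n_inputs)
  W0 <- matrix(stats::rnorm(n_units * n_units), n_units, n_units) /
    sqrt(n_units)
  ev <- eigen(W0, only.values = TRUE)$values
  radius_at <- function(s) max(Mod(k * s * ev + (1 - k)))
  if (max(Mod(ev)) == 0) {
    if (leak_rho <= 1 - epsilon) {
      stop("zero recurrent matrix cannot satisfy the spectral bound",
           call. = FALSE)
    }
    s <- 1
  } else {
    upper <- 1
    while (radius_at(upper) < target) upper <- upper * 2
    s <- stats::uniroot(function(s) radius_at(s) - target,
                        lower = 0, upper = upper, tol = 1e-12)$root
  }
  params <- list(
    W_in = W_in,
    W_rec = s * W0,
    W_out = matrix(0, n_outputs, n_units),
    n_units = n_units, n_inputs = n_inputs, n_outputs = n_outputs,
    tau_dr = tau_dr, dt = dt, epsilon = epsilon, alpha = alpha,
    spectral_radius = radius_at(s)
  )
  if (params$spectral_radius <= 1 - epsilon || params$spectral_radius >= 1) {
    stop("spectral normalization failed to land in (1 - epsilon, 1)",
         call. = FALSE)
  }
  class(params) <- "reservoir_params"
  params
}

#' Fresh reservoir state
#'
#' Potentials, activations and readouts all start at zero; the state is
#' reset at each trial start so every goal pursuit traverses the same
#' transient from the same initial condition.
#'
#' @param params a [init_reservoir()] result.
#' @export
reservoir_state <- function(params) {
  list(r = numeric(params$n_units),
       a = numeric(params$n_units),
       pre = numeric(params$n_outputs),
       z = numeric(params$n_outputs))
}

#' One Euler step of the leaky reservoir
#'
#' `r <- r + (dt/tau_dr) (-r + W_in g + W_rec a)`, `a = [tanh r]^+`,
#' followed by the readout `z = [tanh(W_out a)]^+`.  All activations and
#' readouts therefore lie in `[0, 1)`.
#'
#' @param state a [reservoir_state()].
#' @param params a [init_reservoir()] result.
#' @param g one-hot goal input (length `n_inputs`).
#' @return the updated state (fields `r`, `a`, `pre`, `z`).
#' @export
reservoir_step <- function(state, params, g) {
  k <- params$dt / params$tau_dr
  r <- state$r + k * (-state$r + drop(params$W_in %*% g) +
                        drop(params$W_rec %*% state$a))
  a <- pmax(tanh(r), 0)
  pre <- drop(params$W_out %*% a)
  list(r = r, a = a, pre = pre, z = pmax(tanh(pre), 0))
}

#' Readout of joint-angle commands
#'
#' @param a reservoir activation vector.
#' @param params a [init_reservoir()] result.
#' @return `z = [tanh(W_out a)]^+`, 6 values in `[0, 1)`.
#' @export
readout <- function(a, params) {
  pmax(tanh(drop(params$W_out %*% a)), 0)
}

#' Delta-rule update of the readout weights
#'
#' Trains the readout toward the stored target posture of the selected
#' goal: `dW = alpha ((d_s - z) * z') a'`, where `z'` is the derivative of
#' the output nonlinearity -- `1 - tanh(pre)^2` where the positive-part
#' clamp is inactive and 0 where it clamps.  Applied at every timestep of a
#' trial, but only once the goal's target posture exists in the associative
#' memory (`learned`); otherwise the weights are untouched.
#'
#' @param params a [init_reservoir()] result.
#' @param d_s target posture for the selected goal, normalized to `[0, 1]`
#'   (joint angle / pi).
#' @param z,pre,a readout, its pre-activation and the reservoir activation
#'   at the current step.
#' @param learned whether `d_s` has ever been stored.
#' @return `params` with updated `W_out`.
#' @export
readout_update <- function(params, d_s, z, pre, a, learned = TRUE) {
  if (!learned) return(params)
  dz <- (1 - tanh(pre)^2) * (pre >= 0)
  params$W_out <- params$W_out +
    params$alpha * tcrossprod((d_s - z) * dz, a)
  params
}

#' Sinusoidal motor babbling
#'
#' The random trajectory generator outputs, for each joint, a cosine of a
#' frequency drawn once per trial: `n_j = cos(2 pi f_j t / beta + pi)`.
#' Every joint starts at -1 (`t = 0`) and sweeps its range smoothly,
#' producing the exploratory movements that seed skill discovery.
#'
#' @param t timestep (non-negative scalar).
#' @param freqs per-joint frequencies in `[0, 1]`, fixed over a trial.
#' @param beta timescale factor (default 50).
#' @return 6 values in `[-1, 1]`.
#' @export
random_trajectory <- function(t, freqs, beta = 50) {
  if (t < 0) stop("`t` must be non-negative", call. = FALSE)
  cos(2 * pi * freqs * t / beta + pi)
}

#' Blend reservoir output with motor babbling
#'
#' The motor command is the competence-weighted convex combination
#' `m = pi (psi_s z + (1 - psi_s) n)`, clipped to the joint limits: an
#' incompetent agent moves by pure babbling, a fully competent one by the
#' learned reservoir attractor alone.
#'
#' @param z readout vector in `[0, 1)`.
#' @param n babbling vector in `[-1, 1]`.
#' @param psi_s competence of the selected goal, in `[0, 1]`.
#' @param joint_limits 6 x 2 matrix of `[lo, hi]` limits (default
#'   `[-pi, pi]` everywhere).
#' @return 6 joint-angle targets in radians.
#' @export
mix_commands <- function(z, n, psi_s,
                         joint_limits = matrix(c(-pi, pi), 6, 2,
                                               byrow = TRUE)) {
  if (psi_s < 0 || psi_s > 1) stop("`psi_s` must be in [0, 1]", call. = FALSE)
  m <- pi * (psi_s * z + (1 - psi_s) * n)
  pmin(pmax(m, joint_limits[, 1]), joint_limits[, 2])
}

#' Create the associative motor memory
#'
#' Stores one target posture per goal (normalized to joint angle / pi) plus
#' a flag recording whether the goal has ever been matched; a target is
#' only meaningful once its flag is set.
#'
#' @param n_goals number of goals.
#' @param n_joints number of joints (default 6).
#' @export
motor_memory <- function(n_goals, n_joints = 6) {
  structure(list(D = matrix(0, n_goals, n_joints),
                 learned = logical(n_goals)),
            class = "motor_memory")
}

#' Competence-gated update of a goal's target posture
#'
#' On a matching event for goal `j`, the stored target moves toward the
#' experienced posture as a decaying average with time constant
#' `tau_d = max(tau_floor, 1 / (1 - psi_j))`: low competence updates the
#' target strongly, high competence freezes it (the update vanishes as
#' `psi_j -> 1`).  The very first match stores the experienced posture
#' verbatim and marks the goal as learned.
#'
#' @param mem a [motor_memory()].
#' @param j matched goal index.
#' @param p_norm experienced posture normalized to joint angle / pi.
#' @param psi_j competence of goal `j`.
#' @param tau_floor lower bound on the decay constant (default 1.2; set to
#'   1 for the unfloored competence-only rule).
#' @return the updated memory.
#' @export
memory_update <- function(mem, j, p_norm, psi_j, tau_floor = 1.2) {
  if (!mem$learned[j]) {
    mem$D[j, ] <- p_norm
    mem$learned[j] <- TRUE
  } else {
    tau_d <- max(tau_floor, if (psi_j >= 1) Inf else 1 / (1 - psi_j))
    mem$D[j, ] <- mem$D[j, ] + (1 / tau_d) * (p_norm - mem$D[j, ])
  }
  mem
}
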