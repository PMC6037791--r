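#' Initialize all agent components
#'
#' Builds the body, the goal-generator map, the reservoir, the associative
#' motor memory and the competence state from one configuration.  All
#' random initializations (SOM prototypes, reservoir weights) draw from the
#' current RNG stream, so `set.seed()` (or [run_simulation()], which seeds
#' for you) makes the agent fully reproducible.  The agent starts at the
#' zero posture (arms stretched out along the torso axis).
#'
#' @param cfg a [simulation_config()].
#' @return an object of class `bodygoals_agent`.
#' @export
init_agent <- function(cfg) {
  body <- do.call(body_config, cfg$body)
  n_goals <- prod(cfg$som$grid)
  som <- som_state(input_dim = cfg$encoding$rows * cfg$encoding$cols,
                   grid = cfg$som$grid, eta_som = cfg$som$eta_som,
                   theta_o = cfg$som$theta_o,
                   init_range = cfg$som$init_range)
  res <- init_reservoir(n_units = cfg$reservoir$n_units, n_inputs = n_goals,
                        n_outputs = 6, tau_dr = cfg$reservoir$tau_dr,
                        dt = cfg$reservoir$dt,
                        epsilon = cfg$reservoir$epsilon,
                        alpha = cfg$reservoir$alpha)
  agent <- list(
    body = body,
    som = som,
    reservoir = res,
    memory = motor_memory(n_goals),
    competence = competence_state(n_goals,
                                  eta_pred = cfg$competence$eta_pred,
                                  tau_xi = cfg$competence$tau_xi),
    posture = numeric(6),
    n_goals = n_goals
  )
  class(agent) <- "bodygoals_agent"
  agent
}

#' Run one goal-pursuit trial
#'
#' Executes the full perception-action-learning loop for one trial of the
#' selected goal.  Per timestep: the reservoir is stepped with the one-hot
#' goal, the readout is blended with the sinusoidal babbling trajectory
#' (weights `psi_s` and `1 - psi_s`), the resulting joint command moves the
#' arms kinematically, touch is sensed, its positive change is encoded into
#' the 2-D map, the SOM is read out and updated, and the thresholded
#' outcome is compared with the goal.  The readout weights are trained each
#' step toward the goal's stored target posture (once one exists).  The
#' trial ends at the first matching timestep -- recording the experienced
#' posture in the associative memory -- or after `max_steps`.  At trial
#' end the predictor and improvement signals are updated once with the
#' trial's match (1 if any timestep matched, else 0).
#'
#' @param agent a [init_agent()] result (carries the end posture of the
#'   previous trial; the pre-movement touch pattern is the reference for
#'   the first step's change, so a standing posture triggers no outcome).
#' @param goal_index index of the selected goal.
#' @param cfg the [simulation_config()] used to build the agent.
#' @return a list with the updated `agent` and a `record` list (goal,
#'   duration, matched flag, per-sensor mean touch activation, end posture,
#'   psi/xi snapshots).
#' @export
run_trial <- function(agent, goal_index, cfg) {
  body <- agent$body
  som <- agent$som
  res <- agent$reservoir
  max_steps <- cfg$experiment$max_steps
  beta <- cfg$noise$beta
  rows <- cfg$encoding$rows
  cols <- cfg$encoding$cols
  bump_sigma <- cfg$encoding$bump_sigma
  tau_floor <- cfg$memory$tau_d_floor
  theta_o <- som$theta_o
  lim_lo <- body$joint_limits[, 1]
  lim_hi <- body$joint_limits[, 2]

  s <- goal_index
  g <- numeric(agent$n_goals)
  g[s] <- 1
  psi <- agent$competence$psi
  psi_s <- psi[s]
  psi_bar <- mean(psi)
  pred <- psi_s

  # trial-constant pieces
  freqs <- stats::runif(6)
  drive <- res$W_in[, s]
  k_res <- res$dt / res$tau_dr
  W_rec <- res$W_rec
  W_out <- res$W_out
  alpha <- res$alpha
  learned_s <- agent$memory$learned[s]
  d_s <- agent$memory$D[s, ]
  W_som <- som$W
  gc_ <- som$grid_coords
  coef_base <- som$eta_som * (1 - psi_bar) * (1 - psi)
  theta_n <- (1 - psi_bar) * som$max_grid_dist

  posture <- agent$posture
  prev_touch <- touch_activation(forward_kinematics(posture, body), body)
  touch_sum <- numeric(body$n_sensors)

  r <- numeric(res$n_units)
  a <- numeric(res$n_units)
  matched <- FALSE
  duration <- max_steps

  for (t in seq_len(max_steps)) {
    # motor command
    r <- r + k_res * (-r + drive + drop(W_rec %*% a))
    a <- pmax(tanh(r), 0)
    pre <- drop(W_out %*% a)
    z <- pmax(tanh(pre), 0)
    n_traj <- cos(2 * pi * freqs * t / beta + pi)
    m <- pi * (psi_s * z + (1 - psi_s) * n_traj)
    posture <- pmin(pmax(m, lim_lo), lim_hi)

    # sensing
    geom <- forward_kinematics(posture, body)
    touch <- touch_activation(geom, body)
    touch_sum <- touch_sum + touch
    delta <- pmax(touch - prev_touch, 0)
    prev_touch <- touch

    # goal generation
    x <- as.vector(encode_map(delta, rows = rows, cols = cols,
                              bump_sigma = bump_sigma))
    y <- drop(W_som %*% x) - 0.5 * rowSums(W_som^2)
    win <- which.max(y)

    # competence-modulated map learning (every timestep)
    d_grid <- sqrt((gc_[, 1] - gc_[win, 1])^2 + (gc_[, 2] - gc_[win, 2])^2)
    coef <- coef_base * (d_grid < theta_n)
    idx <- which(coef > 0)
    if (length(idx)) {
      W_som[idx, ] <- W_som[idx, ] +
        coef[idx] * (matrix(x, length(idx), ncol(W_som), byrow = TRUE) -
                       W_som[idx, , drop = FALSE])
    }

    # readout training toward the stored target posture
    if (learned_s) {
      dz <- (1 - tanh(pre)^2) * (pre >= 0)
      W_out <- W_out + alpha * tcrossprod((d_s - z) * dz, a)
    }

    # outcome and matching
    if (y[win] > theta_o && win == s) {
      matched <- TRUE
      duration <- t
      agent$memory <- memory_update(agent$memory, s, posture / pi, psi_s,
                                    tau_floor = tau_floor)
      break
    }
  }

  som$W <- W_som
  res$W_out <- W_out
  agent$som <- som
  agent$reservoir <- res
  agent$posture <- posture

  match <- as.numeric(matched)
  agent$competence <- predictor_update(agent$competence, match, pred, g)
  agent$competence <- improvement_update(agent$competence, match, pred, g)

  record <- list(goal = s, duration = duration, matched = matched,
                 touch_mean = touch_sum / duration, end_posture = posture,
                 psi = agent$competence$psi, xi = agent$competence$xi)
  list(agent = agent, record = record)
}

#' Run a full simulation
#'
#' Seeds the RNG, initializes the agent and loops over trials: at each
#' trial start a goal is sampled from the softmax over competence
#' improvements, then [run_trial()] executes and learns.  Identical
#' `(config, seed)` pairs produce identical logs.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed; defaults to `cfg$experiment$seed`.
#' @param progress print a line every 500 trials.
#' @return an object of class `simulation_log`: a `trials` data frame (one
#'   row per trial: goal, duration, matched, cumulative timesteps, the
#'   selected goal's competence after the trial and the mean competence),
#'   per-trial matrices `touch` (mean sensor activation), `postures`,
#'   `psi` and `xi`, periodic SOM-weight and motor-memory `snapshots`, the
#'   final agent, the config and the seed.
#' @export
run_simulation <- function(cfg, seed = cfg$experiment$seed, progress = FALSE) {
  set.seed(seed)
  agent <- init_agent(cfg)
  n_trials <- cfg$experiment$n_trials
  n_goals <- agent$n_goals
  n_sensors <- agent$body$n_sensors
  snap_every <- cfg$experiment$snapshot_every

  goal <- integer(n_trials)
  duration <- integer(n_trials)
  matched <- logical(n_trials)
  touch <- matrix(0, n_trials, n_sensors)
  postures <- matrix(0, n_trials, 6)
  psi <- matrix(0, n_trials, n_goals)
  xi <- matrix(0, n_trials, n_goals)
  snap_trials <- integer(0)
  snap_som <- list()
  snap_mem <- list()

  for (i in seq_len(n_trials)) {
    p <- goal_probabilities(agent$competence$xi, cfg$selector$gamma)
    g <- select_goal(p)
    s <- which(g == 1)
    out <- run_trial(agent, s, cfg)
    agent <- out$agent
    rec <- out$record
    goal[i] <- s
    duration[i] <- rec$duration
    matched[i] <- rec$matched
    touch[i, ] <- rec$touch_mean
    postures[i, ] <- rec$end_posture
    psi[i, ] <- rec$psi
    xi[i, ] <- rec$xi
    if (i %% snap_every == 0 || i == n_trials) {
      snap_trials <- c(snap_trials, i)
      snap_som[[length(snap_som) + 1L]] <- agent$som$W
      snap_mem[[length(snap_mem) + 1L]] <- agent$memory$D
    }
    if (progress && i %% 500 == 0) {
      message(sprintf("trial %d/%d  mean psi = %.3f", i, n_trials,
                      mean(rec$psi)))
    }
  }

  trials <- data.frame(
    trial = seq_len(n_trials), goal = goal, duration = duration,
    matched = matched, cum_steps = cumsum(as.numeric(duration)),
    psi_goal = if (n_trials) psi[cbind(seq_len(n_trials), goal)] else numeric(0),
    psi_mean = if (n_trials) rowMeans(psi) else numeric(0)
  )
  structure(list(trials = trials, touch = touch, postures = postures,
                 psi = psi, xi = xi,
                 snapshots = list(trials = snap_trials, som = snap_som,
                                  memory = snap_mem),
                 agent = agent, config = cfg, seed = seed),
            class = "simulation_log")
}

#' Random-movement touch baseline
#'
#' Measures where the body gets touched when movements are purely random:
#' trials of sinusoidal babbling (competence forced to zero, all learning
#' off), accumulating the mean activation of every sensor over all
#' timesteps.  This is the reference profile against which goal-directed
#' touch distributions are compared; body topology makes the "chest"
#' (central body region, reachable by both hands) the most frequently
#' touched area.
#'
#' @param cfg a [simulation_config()].
#' @param n_trials number of babbling trials (default 500).
#' @param seed RNG seed (default `cfg$experiment$seed`).
#' @return numeric vector of per-sensor mean activation.
#' @export
random_baseline <- function(cfg, n_trials = 500, seed = cfg$experiment$seed) {
  set.seed(seed)
  body <- do.call(body_config, cfg$body)
  max_steps <- cfg$experiment$max_steps
  beta <- cfg$noise$beta
  lim_lo <- body$joint_limits[, 1]
  lim_hi <- body$joint_limits[, 2]
  total <- numeric(body$n_sensors)
  steps <- 0
  for (i in seq_len(n_trials)) {
    freqs <- stats::runif(6)
    for (t in seq_len(max_steps)) {
      m <- pi * cos(2 * pi * freqs * t / beta + pi)
      posture <- pmin(pmax(m, lim_lo), lim_hi)
      total <- total + touch_activation(forward_kinematics(posture, body),
                                        body)
      steps <- steps + 1
    }
  }
  total / steps
}

#' Per-sensor mean touch activation
#'
#' Averages the per-trial mean sensor activations over all trials, or over
#' the trials in which one given goal was pursued (the rows of the
#' goal-wise touch histogram).
#'
#' @param log a [run_simulation()] log.
#' @param goal optional goal index to condition on.
#' @param trials optional trial-index subset (applied before `goal`).
#' @return numeric vector of per-sensor means.
#' @export
touch_histogram <- function(log, goal = NULL, trials = NULL) {
  if (nrow(log$trials) == 0) stop("empty simulation log", call. = FALSE)
  keep <- if (is.null(trials)) seq_len(nrow(log$trials)) else trials
  if (!is.null(goal)) keep <- keep[log$trials$goal[keep] == goal]
  colMeans(log$touch[keep, , drop = FALSE])
}

#' Trial duration as a function of goal age
#'
#' For every matched trial, the "age" of its goal is the cumulated number
#' of that goal's successful trials so far.  Averaging duration (and
#' competence) over all goals at each age exposes the developmental trend:
#' as motor accuracy improves with practice, the time needed to accomplish
#' a goal decreases.
#'
#' @param log a [run_simulation()] log.
#' @return data frame with one row per age: `age`, `mean_duration`,
#'   `mean_psi`, `n` (number of goal/trial pairs at that age).
#' @export
duration_vs_goal_age <- function(log) {
  tr <- log$trials
  if (nrow(tr) == 0) stop("empty simulation log", call. = FALSE)
  m <- tr[tr$matched, , drop = FALSE]
  if (nrow(m) == 0) {
    return(data.frame(age = integer(0), mean_duration = numeric(0),
                      mean_psi = numeric(0), n = integer(0)))
  }
  m$age <- stats::ave(rep(1, nrow(m)), m$goal, FUN = cumsum)
  agg <- stats::aggregate(cbind(duration, psi_goal) ~ age, data = m, FUN = mean)
  n <- as.integer(table(factor(m$age, levels = sort(unique(m$age)))))
  data.frame(age = as.integer(agg$age), mean_duration = agg$duration,
             mean_psi = agg$psi_goal, n = n)
}

#' History of goal formation
#'
#' The system's self-estimated probability of succeeding at each goal
#' (psi), sampled at the snapshot cadence, prepended with the all-zero
#' initial state.  Rows are goals, columns snapshot times.
#'
#' @param log a [run_simulation()] log.
#' @return matrix `n_goals` x `n_snapshots + 1` with the snapshot trial
#'   indices (0 = before learning) as column names.
#' @export
goal_formation_history <- function(log) {
  idx <- log$snapshots$trials
  h <- cbind(0, if (length(idx)) t(log$psi[idx, , drop = FALSE]) else NULL)
  colnames(h) <- c(0, idx)
  h
}

#' Touch profiles per developmental epoch
#'
#' Splits the simulation into consecutive epochs of `epoch_length`
#' timesteps (trials are assigned to the epoch containing their start) and
#' returns the duration-weighted mean sensor activation per epoch.  Used
#' to compare early and late developmental stages of the touch
#' distribution.
#'
#' @param log a [run_simulation()] log.
#' @param epoch_length epoch size in timesteps (default 10000).
#' @param complete_only drop the trailing partial epoch (default TRUE).
#' @return matrix epochs x sensors; row names give the epoch start step.
#' @export
epoch_touch_profile <- function(log, epoch_length = 10000,
                                complete_only = TRUE) {
  tr <- log$trials
  if (nrow(tr) == 0) stop("empty simulation log", call. = FALSE)
  start <- tr$cum_steps - tr$duration
  epoch <- floor(start / epoch_length)
  n_complete <- floor(max(tr$cum_steps) / epoch_length)
  keep_epochs <- sort(unique(epoch))
  if (complete_only) keep_epochs <- keep_epochs[keep_epochs < n_complete]
  prof <- t(vapply(keep_epochs, function(e) {
    i <- which(epoch == e)
    w <- tr$duration[i]
    colSums(log$touch[i, , drop = FALSE] * w) / sum(w)
  }, numeric(ncol(log$touch))))
  rownames(prof) <- keep_epochs * epoch_length
  prof
}

#' Write / read a simulation log as plain-text files
#'
#' Serializes the trial table, the per-trial touch/posture/psi/xi
#' matrices and the configuration into CSV/YAML files inside `dir`
#' (`trials.csv`, `touch.csv`, `postures.csv`, `psi.csv`, `xi.csv`,
#' `som_weights.csv` for the final prototypes, `memory.csv`,
#' `config.yaml`).  `read_simulation_log()` reconstructs a log sufficient
#' for all analysis functions.
#'
#' @param log a [run_simulation()] log.
#' @param dir output directory (created if missing).
#' @return the directory (write) or a `simulation_log` (read), invisibly.
#' @export
write_simulation_log <- function(log, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(log$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  for (nm in c("touch", "postures", "psi", "xi")) {
    utils::write.csv(log[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(log$agent$som$W, file.path(dir, "som_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(learned = log$agent$memory$learned,
                         log$agent$memory$D),
                   file.path(dir, "memory.csv"), row.names = FALSE)
  write_config(log$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_simulation_log
#' @export
read_simulation_log <- function(dir) {
  log <- list(
    trials = utils::read.csv(file.path(dir, "trials.csv")),
    touch = as.matrix(utils::read.csv(file.path(dir, "touch.csv"))),
    postures = as.matrix(utils::read.csv(file.path(dir, "postures.csv"))),
    psi = as.matrix(utils::read.csv(file.path(dir, "psi.csv"))),
    xi = as.matrix(utils::read.csv(file.path(dir, "xi.csv"))),
    snapshots = list(trials = integer(0), som = list(), memory = list()),
    config = read_config(file.path(dir, "config.yaml"))
  )
  dimnames(log$touch) <- dimnames(log$postures) <- NULL
  dimnames(log$psi) <- dimnames(log$xi) <- NULL
  class(log) <- "simulation_log"
  invisible(log)
}

#' @export
print.simulation_log <- function(x, ...) {
  tr <- x$trials
  cat("<simulation_log> ", nrow(tr), " trials, ",
      if (nrow(tr)) max(tr$cum_steps) else 0, " timesteps\n", sep = "")
  if (nrow(tr)) {
    cat("  matched: ", sum(tr$matched), " (",
        round(100 * mean(tr$matched), 1), "%), final mean psi = ",
        round(tr$psi_mean[nrow(tr)], 3), "\n", sep = "")
  }
  invisible(x)
}
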