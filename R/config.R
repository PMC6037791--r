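#' Default simulation configuration
#'
#' Assembles the full run configuration with the model's standard
#' parameters and sizes: 30 touch sensors, a 20 x 20 encoded input map, a
#' 5 x 5 goal grid (25 goals), a 150-unit reservoir with 6 readouts,
#' eta_som 0.25, alpha 0.01, tau_dr 100, beta 50, tau_d floor 1.2,
#' eta_pred 0.35, tau_xi 5, and 8,000 trials.  Any section can be
#' overridden with a partial list; unspecified entries keep their
#' defaults.  `density_variant = TRUE` replaces the uniform sensor layout
#' with [density_variant_positions()] (a third of the sensors on the first
#' two thirds of the body, the rest on the last third).
#'
#' @param body,encoding,som,selector,reservoir,noise,memory,competence,experiment
#'   named lists of overrides for the corresponding section.
#' @param density_variant logical flag selecting the non-uniform sensor
#'   layout.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(body = list(), encoding = list(), som = list(),
                              selector = list(), reservoir = list(),
                              noise = list(), memory = list(),
                              competence = list(), experiment = list(),
                              density_variant = FALSE) {
  cfg <- list(
    body = list(link_lengths = c(1, 1, 1), torso_width = 33 / 7, n_sensors = 30,
                sensor_arc_positions = NULL, touch_sigma = NULL,
                mask_radius = NULL, joint_limits = c(-pi, pi)),
    encoding = list(rows = 20, cols = 20, bump_sigma = 1.5),
    som = list(grid = c(5, 5), eta_som = 0.25, theta_o = 0,
               init_range = c(0, 0.1)),
    selector = list(gamma = 10),
    reservoir = list(n_units = 150, tau_dr = 100, dt = 1, epsilon = 0.05,
                     alpha = 0.01),
    noise = list(beta = 50),
    memory = list(tau_d_floor = 1.2),
    competence = list(eta_pred = 0.35, tau_xi = 5),
    experiment = list(n_trials = 8000, max_steps = 200, snapshot_every = 100,
                      seed = 1),
    density_variant = isTRUE(density_variant)
  )
  override <- list(body = body, encoding = encoding, som = som,
                   selector = selector, reservoir = reservoir, noise = noise,
                   memory = memory, competence = competence,
                   experiment = experiment)
  for (sec in names(override)) {
    extra <- setdiff(names(override[[sec]]), names(cfg[[sec]]))
    if (length(extra)) {
      stop("unknown ", sec, " option(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], override[[sec]])
  }
  if (cfg$density_variant && is.null(cfg$body$sensor_arc_positions)) {
    n <- cfg$body$n_sensors
    cfg$body$sensor_arc_positions <-
      density_variant_positions(round(n / 3), n - round(n / 3))
  }
  validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(encoding$rows >= 2, encoding$cols >= 2, encoding$bump_sigma > 0,
              length(som$grid) == 2, all(som$grid >= 1), som$eta_som > 0,
              selector$gamma >= 0,
              reservoir$n_units >= 1, reservoir$epsilon > 0,
              reservoir$tau_dr > 0, reservoir$dt > 0, reservoir$alpha >= 0,
              noise$beta > 0, memory$tau_d_floor >= 1,
              competence$eta_pred > 0, competence$eta_pred <= 1,
              competence$tau_xi >= 1,
              experiment$n_trials >= 0, experiment$max_steps >= 1,
              experiment$snapshot_every >= 1)
  })
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' The YAML document mirrors the [simulation_config()] sections, so a file
#' round-trips to an identical configuration; missing keys fall back to
#' the defaults.
#'
#' @param cfg a `simulation_config`.
#' @param path file path.
#' @return `read_config()` returns a `simulation_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x[c("body", "encoding", "som", "selector", "reservoir", "noise", "memory",
      "competence", "experiment")] <-
    lapply(x[c("body", "encoding", "som", "selector", "reservoir", "noise",
               "memory", "competence", "experiment")],
           function(s) Filter(Negate(is.null), s))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(simulation_config, c(
    x[intersect(names(x), c("body", "encoding", "som", "selector",
                            "reservoir", "noise", "memory", "competence",
                            "experiment"))],
    list(density_variant = isTRUE(x$density_variant))
  ))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n",
      "  goals: ", prod(x$som$grid), " (", x$som$grid[1], " x ", x$som$grid[2],
      "), sensors: ", x$body$n_sensors,
      ", reservoir: ", x$reservoir$n_units, " units\n",
      "  trials: ", x$experiment$n_trials,
      ", max steps/trial: ", x$experiment$max_steps,
      ", seed: ", x$experiment$seed,
      if (x$density_variant) ", density variant" else "", "\n", sep = "")
  invisible(x)
}
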