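#' Create the goal-generator self-organizing map
#'
#' The goal generator is an online self-organizing map (SOM): each of the
#' `prod(grid)` output units stores a prototype of an encoded touch-change
#' pattern in its afferent weights, and the unit grid preserves the
#' topology of the input space.  Unlike the classic algorithm, which
#' anneals its learning rate and neighbourhood over time, learning here is
#' modulated by the agent's competence (see [som_update()]): a goal that
#' the agent can reliably accomplish freezes its own prototype, and a
#' globally competent agent freezes the whole map.
#'
#' @param input_dim dimensionality of the flattened input map (default 400).
#' @param grid output grid size, default `c(5, 5)` (25 goals).
#' @param eta_som base learning rate (default 0.25).
#' @param theta_o output threshold of [outcome_filter()]; with the default
#'   0 and small positive initial weights, a silent input (all-zero map)
#'   yields activations `-||w||^2/2 < 0` and can never produce an outcome.
#' @param init_range range of the uniform weight initialization (draws from
#'   the current RNG stream).
#' @return an object of class `som_state` with fields `W`
#'   (`n_units` x `input_dim` prototypes), `grid_coords`, `max_grid_dist`,
#'   `eta_som` and `theta_o`.
#' @export
som_state <- function(input_dim = 400, grid = c(5, 5), eta_som = 0.25,
                      theta_o = 0, init_range = c(0, 0.1)) {
  stopifnot(length(grid) == 2L, all(grid >= 1), input_dim >= 1)
  n_units <- prod(grid)
  coords <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                  col = seq_len(grid[2])))
  som <- list(
    W = matrix(stats::runif(n_units * input_dim, init_range[1], init_range[2]),
               n_units, input_dim),
    grid = grid,
    grid_coords = coords,
    max_grid_dist = sqrt(sum((grid - 1)^2)),
    eta_som = eta_som,
    theta_o = theta_o
  )
  class(som) <- "som_state"
  som
}

#' SOM output activation
#'
#' Computes the biologically plausible form of the nearest-prototype rule:
#' `y_j = w_j' x - w_j' w_j / 2`, a weighted sum of the input minus a
#' weight-dependent bias.  Maximizing `y_j` is equivalent to minimizing the
#' squared Euclidean distance `||x - w_j||^2` (the input norm is constant
#' across units), but the activation can additionally be compared against
#' an absolute threshold, which [outcome_filter()] exploits.
#'
#' @param x flattened sensory map (length `input_dim`).
#' @param som a [som_state()].
#' @return numeric vector of unit activations.
#' @export
som_activation <- function(x, som) {
  if (length(x) != ncol(som$W)) {
    stop("input dimension does not match SOM weights", call. = FALSE)
  }
  drop(som$W %*% x) - 0.5 * rowSums(som$W^2)
}

#' Winning SOM unit
#'
#' Index of the unit maximizing [som_activation()]; identical to the
#' brute-force nearest-prototype index. Ties break to the lowest index.
#'
#' @inheritParams som_activation
#' @param y optional precomputed activation vector.
#' @export
som_winner <- function(x, som, y = NULL) {
  if (is.null(y)) y <- som_activation(x, som)
  which.max(y)
}

#' Competence-modulated SOM weight update
#'
#' Moves prototypes toward the input with a step gated three ways by
#' competence: globally by `(1 - psi_bar)` (mean competence over goals),
#' per unit by `(1 - psi_j)`, and through the winner neighbourhood, whose
#' radius `(1 - psi_bar) * max_grid_dist` shrinks from the whole grid at
#' zero competence to the winner alone as the agent masters its goals.
#' At `psi_bar = 1` the map is frozen entirely.
#'
#' @param som a [som_state()].
#' @param x flattened sensory map.
#' @param win winner index (see [som_winner()]).
#' @param psi per-goal competences in `[0, 1]`.
#' @param psi_bar mean competence; defaults to `mean(psi)`.
#' @return the updated `som_state`.
#' @export
som_update <- function(som, x, win, psi, psi_bar = mean(psi)) {
  if (any(psi < 0) || any(psi > 1)) {
    stop("`psi` entries must lie in [0, 1]", call. = FALSE)
  }
  g <- som$grid_coords
  d <- sqrt((g[, 1] - g[win, 1])^2 + (g[, 2] - g[win, 2])^2)
  theta_n <- (1 - psi_bar) * som$max_grid_dist
  coef <- som$eta_som * (1 - psi_bar) * (1 - psi) * (d < theta_n)
  idx <- which(coef > 0)
  if (length(idx)) {
    W <- som$W
    k <- length(idx)
    W[idx, ] <- W[idx, ] +
      coef[idx] * (matrix(x, k, ncol(W), byrow = TRUE) - W[idx, , drop = FALSE])
    som$W <- W
  }
  som
}

#' Thresholded one-hot outcome vector
#'
#' The binary outcome pattern is all zeros except possibly the winner unit,
#' which is set to 1 only when its activation strictly exceeds `theta_o`.
#' This filters out spurious outcomes: during stillness the input map is
#' all-zero and every activation is negative, so no goal outcome is
#' generated.
#'
#' @param y SOM activation vector.
#' @param win winner index.
#' @param theta_o outcome threshold.
#' @return binary vector with at most one 1.
#' @export
outcome_filter <- function(y, win, theta_o = 0) {
  o <- numeric(length(y))
  o[win] <- as.numeric(y[win] > theta_o)
  o
}
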