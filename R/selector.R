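#' Goal-selection probabilities
#'
#' Softmax over the per-goal competence improvement xi with gain `gamma`:
#' `p(g_j) = exp(xi_j * gamma) / sum_i exp(xi_i * gamma)`.  Goals whose
#' competence is currently improving fastest are favoured; at `gamma = 0`
#' (or equal improvements) selection is uniform.  Computed with
#' max-subtraction so large gains cannot overflow.
#'
#' @param xi per-goal competence improvements (finite).
#' @param gamma non-negative softmax gain; higher values concentrate
#'   selection on the currently most improving goals (default 10).
#' @return probability vector summing to 1.
#' @export
goal_probabilities <- function(xi, gamma = 10) {
  if (any(!is.finite(xi))) stop("`xi` must be finite", call. = FALSE)
  if (gamma < 0) stop("`gamma` must be non-negative", call. = FALSE)
  e <- exp(xi * gamma - max(xi * gamma))
  e / sum(e)
}

#' Sample a one-hot goal
#'
#' Draws one goal from the selection probabilities (from the current RNG
#' stream) and returns it as a one-hot vector over the goal grid.
#'
#' @param probabilities a valid probability vector, e.g. from
#'   [goal_probabilities()].
#' @return binary vector with exactly one 1.
#' @export
select_goal <- function(probabilities) {
  g <- numeric(length(probabilities))
  g[sample.int(length(probabilities), 1L, prob = probabilities)] <- 1
  g
}
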