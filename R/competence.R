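#' Create a competence state
#'
#' Holds the two competence-based intrinsic-motivation signals: `psi`, the
#' per-goal estimate of the probability of accomplishing the goal when
#' selected (a delta-rule tracker of match outcomes, starting at 0), and
#' `xi`, a slowly decaying average of the positive prediction error that
#' measures competence *improvement* and drives goal selection.
#'
#' @param n_goals number of goals.
#' @param eta_pred predictor learning rate (default 0.35).
#' @param tau_xi decay constant of the improvement average in trials
#'   (default 5); values near 1 remove the smoothing and with it the
#'   focussing on newly discovered goals.
#' @return an object of class `competence_state`.
#' @export
competence_state <- function(n_goals, eta_pred = 0.35, tau_xi = 5) {
  structure(list(psi = numeric(n_goals),
                 xi = numeric(n_goals),
                 eta_pred = eta_pred,
                 tau_xi = tau_xi),
            class = "competence_state")
}

#' Goal-outcome matching signal
#'
#' `match = o' g`: 1 exactly when the thresholded outcome winner coincides
#' with the selected goal, 0 otherwise (including when no outcome fired).
#'
#' @param o binary outcome vector (at most one 1).
#' @param g one-hot selected-goal vector of the same length.
#' @export
matching <- function(o, g) {
  if (length(o) != length(g)) {
    stop("outcome and goal vectors must have the same length", call. = FALSE)
  }
  sum(o * g)
}

#' Predicted probability of accomplishing the selected goal
#'
#' `pred = psi' g`, i.e. the competence of the selected goal; 0 for a
#' fresh state.
#'
#' @param state a [competence_state()].
#' @param g one-hot goal vector.
#' @export
predict_competence <- function(state, g) {
  sum(state$psi * g)
}

#' Delta-rule update of the competence predictor
#'
#' Applied once per trial, at trial end:
#' `psi <- psi + eta_pred (match - pred) g`, clipped to `[0, 1]`.  Only the
#' selected goal's competence changes.  Under i.i.d. Bernoulli matches the
#' estimate tracks the goal's success probability.
#'
#' @param state a [competence_state()].
#' @param match trial matching signal, 0 or 1.
#' @param pred the prediction made at trial start ([predict_competence()]).
#' @param g one-hot goal vector.
#' @return the updated state.
#' @export
predictor_update <- function(state, match, pred, g) {
  state$psi <- pmin(1, pmax(0, state$psi + state$eta_pred * (match - pred) * g))
  state
}

#' Decaying-average update of the competence improvement
#'
#' Applied once per trial to the selected goal's component:
#' `xi_j <- xi_j + (1/tau_xi) (-xi_j + [match - pred]^+)`.  Only the
#' positive part of the prediction error counts -- failing at a mastered
#' goal drives motivation toward zero, not below it -- and the slow decay
#' keeps the agent focussed for several trials on goals whose competence
#' just jumped.  Non-selected goals keep their current value.
#'
#' @inheritParams predictor_update
#' @return the updated state.
#' @export
improvement_update <- function(state, match, pred, g) {
  err <- max(match - pred, 0)
  state$xi <- pmax(0, state$xi + (1 / state$tau_xi) * (-state$xi + err) * g)
  state
}
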