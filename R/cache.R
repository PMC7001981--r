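#' Policy-probability cache
#'
#' The cache stores P(pi | s): the probability of each policy conditioned on
#' each hidden state, initialised uniform (1/17 everywhere) so that no habit
#' can fire before anything has been learned. It is trained by the delta rule
#' of [cache_update()] and consulted through [expected_policy_prob()] and
#' [habit_check()].
#'
#' @param model A `tmaze_model`.
#' @param p_th Habitisation threshold: a habit fires when the expected cached
#'   probability of some policy strictly exceeds it. Default 0.90.
#' @param eta Learning rate in (0, 1] multiplying the occupancy-weighted
#'   prediction error. Default 1: the update weight is the occupancy belief
#'   alone.
#' @return An object of class `policy_cache` with fields `table`
#'   (n_policies x n_states, each state's column over policies sums to 1),
#'   `p_th` and `eta`.
#' @export
policy_cache <- function(model, p_th = 0.90, eta = 1) {
  stopifnot(eta > 0, eta <= 1)
  structure(list(
    table = matrix(1 / model$n_policies, nrow = model$n_policies,
                   ncol = model$n_states),
    p_th = p_th,
    eta = eta
  ), class = "policy_cache")
}

#' Expected cached policy probability (Eq. over the belief)
#'
#' E_s[P(pi | s)] = sum_i s_i P(pi | s_i) for every policy: the cached policy
#' probabilities averaged under a belief over hidden states.
#'
#' @param cache A `policy_cache`.
#' @param belief Probability vector over hidden states.
#' @return Numeric vector with one expectation per policy.
#' @export
expected_policy_prob <- function(cache, belief) {
  as.vector(cache$table %*% belief)
}

#' Delta-rule cache update
#'
#' For every state s and policy pi:
#' P'(pi|s) = P(pi|s) + eta * w_s * (pi_hat_pi - P(pi|s)),
#' where w is a state-occupancy weight vector and pi_hat the current policy
#' posterior. The trial engine weights each state by the agent's expected
#' occupancy of it over the remainder of the trial under the policy
#' posterior, so the update reaches all the states the agent entertains;
#' states with zero weight are untouched. The update preserves each state's
#' normalisation over policies exactly.
#'
#' @param cache A `policy_cache`.
#' @param belief State-occupancy weight vector w (length n_states; an
#'   occupancy belief or predictive occupancy distribution).
#' @param posterior A `policy_posterior`, or a bare probability vector over
#'   policies.
#' @return The updated `policy_cache`.
#' @export
cache_update <- function(cache, belief, posterior) {
  pi_hat <- if (inherits(posterior, "policy_posterior")) posterior$probs else posterior
  # (pi_hat - table) recycles pi_hat down each state column; sweep scales
  # column s by the occupancy belief of s.
  cache$table <- cache$table +
    cache$eta * sweep(pi_hat - cache$table, 2L, belief, `*`)
  cache
}

#' Threshold test for habit selection
#'
#' @param expected Per-policy expectations from [expected_policy_prob()].
#' @param p_th Habitisation threshold (strict inequality).
#' @return List of class `habit_decision`: `habitual` (logical), `policy_id`
#'   (argmax policy, ties to the lowest id; `NA` when not habitual) and
#'   `expected_prob` (the maximum expectation).
#' @export
habit_check <- function(expected, p_th) {
  m <- max(expected)
  if (m > p_th) {
    list(habitual = TRUE, policy_id = which.max(expected), expected_prob = m)
  } else {
    list(habitual = FALSE, policy_id = NA_integer_, expected_prob = m)
  }
}
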