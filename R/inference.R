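#' Exact Bayesian belief update
#'
#' One filtering step: the belief is pushed through the transition matrix of
#' the executed action (skipped when `action` is `NULL`, i.e. for the pure
#' observation update at trial start) and conditioned on the received
#' observation through the likelihood, then renormalised.
#'
#' @param belief Probability vector over hidden states.
#' @param action Executed action name, or `NULL` for an observation-only
#'   update.
#' @param observation List with `location` and `cue` (as produced by
#'   [world_step()]).
#' @param model A `tmaze_model`.
#' @return Updated probability vector.
#' @export
belief_update <- function(belief, action, observation, model) {
  pred <- if (is.null(action)) belief else as.vector(model$B[[action]] %*% belief)
  post <- model$A[obs_index(observation$location, observation$cue), ] * pred
  z <- sum(post)
  if (z <= 0) {
    stop("impossible observation: zero posterior mass under the predicted states")
  }
  post / z
}

#' Policy-conditioned state prediction
#'
#' Rolls the current belief forward to step `tau` under the policy's actions,
#' i.e. applies B(a_{t+1}) ... B(a_tau).
#'
#' @param belief Probability vector over hidden states at step `t`.
#' @param policy A policy record from [enumerate_policies()].
#' @param model A `tmaze_model`.
#' @param t Current within-trial step (0-based; 0 = before the first action).
#' @param tau Target step, `t <= tau <= horizon`.
#' @return Predicted probability vector at step `tau`.
#' @export
predict_states <- function(belief, policy, model, t = 0L, tau = model$horizon) {
  if (tau > model$horizon) stop("tau exceeds the policy horizon")
  if (tau < t) stop("tau must be >= t")
  s <- belief
  if (tau > t) {
    for (k in (t + 1L):tau) {
      s <- as.vector(model$B[[policy$actions[k]]] %*% s)
    }
  }
  s
}

# One step of the expected-free-energy path integral: ambiguity plus risk of
# the predicted state distribution s. Shared by expected_free_energy() and the
# scheme-3 incremental scan so that both accumulate bitwise-identical sums.
.efe_term <- function(s, model) {
  o <- as.vector(model$A %*% s)
  nz <- o > 0
  ambiguity <- -sum(model$H * s)
  risk <- -sum(o[nz] * (log(o[nz]) - model$lnC[nz]))
  ambiguity + risk
}

#' Expected free energy of a policy
#'
#' The path integral G_pi = sum over future steps tau = t+1..T of
#' G(pi, tau) = -H[P(o|s)] . s_pi(tau) - (ln o_pi(tau) - lnC) . o_pi(tau),
#' where s_pi(tau) is the policy-conditioned state prediction and
#' o_pi(tau) = A s_pi(tau). The first term is the expected observation
#' ambiguity, the second the KL divergence of predicted from preferred
#' outcomes; both are non-positive, hence G_pi <= 0 and larger (less
#' negative) values mark better policies.
#'
#' @inheritParams predict_states
#' @return Scalar G_pi (<= 0).
#' @export
expected_free_energy <- function(policy, belief, model, t = 0L) {
  G <- 0
  s <- belief
  if (t < model$horizon) {
    for (tau in (t + 1L):model$horizon) {
      s <- as.vector(model$B[[policy$actions[tau]]] %*% s)
      G <- G + .efe_term(s, model)
    }
  }
  G
}

#' Precision-weighted softmax policy posterior
#'
#' @param G Numeric vector of per-policy expected free energies.
#' @param gamma Softmax precision (> 0).
#' @return List of class `policy_posterior` with elements `probs` (sums to 1)
#'   and `G`. Computed with max-subtraction for numerical safety.
#' @export
policy_posterior <- function(G, gamma) {
  if (gamma <= 0) stop("gamma must be > 0")
  if (any(!is.finite(G))) stop("non-finite expected free energy")
  w <- gamma * G
  w <- w - max(w)
  p <- exp(w)
  structure(list(probs = p / sum(p), G = G), class = "policy_posterior")
}

#' Sample the next action from a policy posterior
#'
#' The probability of each action is the posterior mass of the policies whose
#' action at the current step equals it; the action is sampled from that
#' marginal using the global RNG stream.
#'
#' @param posterior A `policy_posterior`.
#' @param model A `tmaze_model` (supplies the action matrix).
#' @param t Current within-trial step (0-based).
#' @return Action name.
#' @export
select_action <- function(posterior, model, t) {
  if (t >= model$horizon) stop("no action to select at the end of a trial")
  step_actions <- model$actions_matrix[, t + 1L]
  marg <- vapply(TMAZE_ACTIONS,
                 function(a) sum(posterior$probs[step_actions == a]),
                 numeric(1))
  TMAZE_ACTIONS[sample.int(4L, 1L, prob = marg)]
}

#' Run one fully deliberative trial
#'
#' Executes the stage A-E loop four times: observe, update beliefs, evaluate
#' the expected free energy of every policy, form the precision-weighted
#' softmax posterior, sample an action and act. When a [policy_cache()] is
#' supplied, the delta-rule update is applied after each policy-posterior
#' computation and once more at trial end with the final belief and the
#' executed policy (see the vignette); the habit machinery itself is not
#' engaged.
#'
#' @param model A `tmaze_model`.
#' @param D Initial-state prior for the trial (see [build_D()]).
#' @param context True context label for the trial.
#' @param p_reward World reward-delivery probability.
#' @param cache Optional `policy_cache` to train alongside.
#' @param trial Trial index (bookkeeping only).
#' @param prev_final_belief Final belief of the previous trial, used only for
#'   the pre-trial cached-probability monitor; `NULL` on trial 1.
#' @return List with `record` (a `trial_record`), the updated `cache` and
#'   `final_belief`.
#' @export
run_trial_full <- function(model, D, context, p_reward = 0.95, cache = NULL,
                           trial = 1L, prev_final_belief = NULL) {
  .run_trial(model, D, context, scheme = "full", cache = cache,
             prev_final_belief = prev_final_belief, p_reward = p_reward,
             trial = trial)
}
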