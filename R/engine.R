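# Unified within-trial engine for the full deliberative scheme and the three
# caching schemes. A single engine guarantees that, whenever the habit
# machinery is inert (p_th > 1, or a uniform cache), every scheme consumes the
# RNG stream identically and reproduces the full-inference trajectory bit for
# bit.

# Evaluate all policies from the current belief: accumulate each policy's
# expected-free-energy path integral and its predicted state occupancies over
# the remaining steps. When `probe_cache` is given (scheme 3), the cache is
# probed after every accumulation step and the first threshold crossing
# terminates evaluation. Returns either the completed evaluation (G, the
# per-policy occupancy accumulators, step counts) or the crossing policy.
.evaluate_policies <- function(belief, model, t, probe_cache = NULL) {
  horizon <- model$horizon
  n_pol <- model$n_policies
  remaining <- horizon - t
  G <- rep(NA_real_, n_pol)
  occ <- vector("list", n_pol)
  n_steps <- 0L
  n_efe <- 0
  for (p in seq_len(n_pol)) {
    g <- 0
    s <- belief
    acc <- belief  # occupancy accumulator, tau = t .. horizon
    done <- 0L
    for (tau in (t + 1L):horizon) {
      s <- as.vector(model$B[[model$actions_matrix[p, tau]]] %*% s)
      g <- g + .efe_term(s, model)
      acc <- acc + s
      done <- done + 1L
      n_steps <- n_steps + 1L
      if (!is.null(probe_cache) &&
          sum(probe_cache$table[p, ] * s) > probe_cache$p_th) {
        return(list(crossed = TRUE, policy_id = p,
                    n_efe = n_efe + done / remaining, n_steps = n_steps))
      }
    }
    n_efe <- n_efe + 1
    G[p] <- g
    occ[[p]] <- acc
  }
  list(crossed = FALSE, G = G, occ = occ, n_efe = n_efe, n_steps = n_steps)
}

.run_trial <- function(model, D, context, scheme, cache, prev_final_belief,
                       p_reward, trial = 1L) {
  horizon <- model$horizon
  n_pol <- model$n_policies
  world <- world_state(context, trial)

  # Trial-start observation: the (uninformative) white cue at the start
  # location; pure observation update with s_hat = D.
  obs0 <- list(location = model$topology$start, cue = "white")
  belief <- belief_update(D, NULL, obs0, model)

  # Panel-C monitor: the pre-trial expected cached policy probabilities under
  # the previous trial's final belief (the initial prior on trial 1).
  pre_E <- if (!is.null(cache)) {
    expected_policy_prob(cache,
                         if (is.null(prev_final_belief)) D else prev_final_belief)
  } else NULL

  habit_policy <- NULL
  habitised <- logical(horizon)
  if (scheme == "scheme1" && !is.null(prev_final_belief)) {
    hd <- habit_check(expected_policy_prob(cache, prev_final_belief), cache$p_th)
    if (hd$habitual) habit_policy <- model$policies[[hd$policy_id]]
  }

  actions_taken <- character(horizon)
  cues <- character(horizon)
  locations <- integer(horizon)
  posteriors <- vector("list", horizon)
  rewarded <- FALSE
  n_efe <- 0         # policy evaluations (fractional for scheme 3)
  n_eval_steps <- 0L # raw per-(policy, tau) accumulation steps

  # Policies still consistent with the actions executed so far this trial.
  # The cache stores the probability that a policy is being pursued given a
  # state, so the posterior written into it must exclude policies the agent
  # can no longer be pursuing; by trial end exactly the executed policy
  # remains. Action selection itself keeps the full softmax posterior.
  live <- rep(TRUE, n_pol)

  for (t in 0:(horizon - 1L)) {
    i <- t + 1L

    if (is.null(habit_policy) && scheme == "scheme2") {
      # Planning-stage check: each policy is probed on its own one-step
      # prediction.
      e <- vapply(seq_len(n_pol), function(p) {
        sp <- as.vector(model$B[[model$actions_matrix[p, i]]] %*% belief)
        sum(cache$table[p, ] * sp)
      }, numeric(1))
      hd <- habit_check(e, cache$p_th)
      if (hd$habitual) habit_policy <- model$policies[[hd$policy_id]]
    }

    if (is.null(habit_policy)) {
      # Evaluation stage. Under scheme 3 the cache is probed after every
      # accumulation step of every path integral (canonical id order) and the
      # first crossing terminates all evaluation.
      ev <- .evaluate_policies(belief, model, t,
                               probe_cache = if (scheme == "scheme3") cache)
      n_efe <- n_efe + ev$n_efe
      n_eval_steps <- n_eval_steps + ev$n_steps
      if (ev$crossed) {
        habit_policy <- model$policies[[ev$policy_id]]
      } else {
        post <- policy_posterior(ev$G, model$gamma)
        posteriors[[i]] <- post
        if (!is.null(cache)) {
          # Delta-rule training. The update posterior is the softmax masked
          # to history-consistent policies; each state's update weight is the
          # agent's expected occupancy of it over the remainder of the trial
          # (current step included) under that posterior.
          pi_hat <- post$probs * live
          pi_hat <- pi_hat / sum(pi_hat)
          w <- Reduce(`+`, Map(`*`, ev$occ, pi_hat)) / (horizon - t + 1L)
          cache <- cache_update(cache, w, pi_hat)
        }
        action <- select_action(post, model, t)
      }
    }

    if (!is.null(habit_policy)) {
      action <- habit_policy$actions[i]
      habitised[i] <- TRUE
    }

    # The agent's transition model gives undefined moves `stay` semantics, so
    # an action sampled from the policy marginal that is undefined at the
    # (observed) current location means "stay" there; resolve it before
    # acting. Every resolved sequence is again a member of the exhaustive
    # policy set.
    if (is.na(model$topology$moves[world$location, action])) action <- "stay"

    prev_loc <- world$location
    step <- world_step(world, action, p_reward, model$topology)
    world <- step$state
    actions_taken[i] <- action
    locations[i] <- step$observation$location
    cues[i] <- step$observation$cue
    if (step$observation$cue == "red") rewarded <- TRUE
    belief <- belief_update(belief, action, step$observation, model)

    # Prune policies whose step-i action (resolved through the stay fallback)
    # would not have produced the observed transition.
    acols <- match(model$actions_matrix[, i], colnames(model$topology$moves))
    dests <- model$topology$moves[cbind(prev_loc, acols)]
    dests[is.na(dests)] <- prev_loc
    live <- live & dests == world$location
  }

  executed_id <- policy_id(model$policies, actions_taken)

  # End-of-trial consolidation: in a trial with no habitised choice the
  # history-consistent set has collapsed onto the executed policy; writing it
  # into the cache at the final belief gives the terminal states their cached
  # values.
  if (!is.null(cache) && !any(habitised)) {
    pi_hat <- as.numeric(live) / sum(live)
    cache <- cache_update(cache, belief, pi_hat)
  }

  record <- structure(list(
    trial = trial,
    scheme = scheme,
    actions = actions_taken,
    locations = locations,
    cues = cues,
    rewarded = rewarded,
    habitised = habitised,
    habitised_at = if (any(habitised)) which(habitised)[1L] else NA_integer_,
    executed_policy = executed_id,
    pre_trial_expected = pre_E,
    posteriors = posteriors,
    n_efe_evals = n_efe,
    n_eval_steps = n_eval_steps,
    final_belief = belief,
    context_posterior = context_marginal(belief)
  ), class = "trial_record")

  list(record = record, cache = cache, final_belief = belief)
}

#' Run one trial under caching scheme 1 (cache at action selection)
#'
#' Before anything else the agent probes the cache with the previous trial's
#' final belief; if some policy's expected cached probability exceeds the
#' threshold, that policy's four actions are executed open-loop -- no
#' planning, no policy evaluation, no cache update -- while belief filtering
#' still runs on the incoming observations, so the context posterior stays
#' current. Otherwise the trial is fully deliberative and the cache is
#' trained. Trial 1 (no previous belief) is always deliberative.
#'
#' @param model A `tmaze_model`.
#' @param cache A `policy_cache`.
#' @param prev_final_belief Final belief of the previous trial, or `NULL` on
#'   trial 1.
#' @param D Initial-state prior for the trial.
#' @param context True context label.
#' @param p_reward World reward-delivery probability.
#' @param trial Trial index.
#' @return List with `record`, updated `cache`, and `final_belief`.
#' @export
run_trial_scheme1 <- function(model, cache, prev_final_belief, D, context,
                              p_reward = 0.95, trial = 1L) {
  .run_trial(model, D, context, scheme = "scheme1", cache = cache,
             prev_final_belief = prev_final_belief, p_reward = p_reward,
             trial = trial)
}

#' Run one trial under caching scheme 2 (cache at planning)
#'
#' At every decision point each policy's one-step state prediction is probed
#' against the cache; the first policy whose expected cached probability
#' exceeds the threshold is adopted habitually for the remainder of the
#' trial. Deliberative decision points run the full evaluation and train the
#' cache.
#'
#' @inheritParams run_trial_scheme1
#' @param prev_final_belief Final belief of the previous trial, used only for
#'   the pre-trial cached-probability monitor (not for any habit decision);
#'   `NULL` on trial 1.
#' @export
run_trial_scheme2 <- function(model, cache, D, context, p_reward = 0.95,
                              trial = 1L, prev_final_belief = NULL) {
  .run_trial(model, D, context, scheme = "scheme2", cache = cache,
             prev_final_belief = prev_final_belief, p_reward = p_reward,
             trial = trial)
}

#' Run one trial under caching scheme 3 (cache at policy evaluation)
#'
#' Policies are evaluated in canonical order; the expected-free-energy path
#' integral of each is accumulated step by step and the cache is probed on
#' every predicted state. The first threshold crossing terminates all
#' evaluation and the crossing policy is adopted habitually for the rest of
#' the trial; if no crossing occurs the decision point completes normally.
#'
#' @inheritParams run_trial_scheme2
#' @export
run_trial_scheme3 <- function(model, cache, D, context, p_reward = 0.95,
                              trial = 1L, prev_final_belief = NULL) {
  .run_trial(model, D, context, scheme = "scheme3", cache = cache,
             prev_final_belief = prev_final_belief, p_reward = p_reward,
             trial = trial)
}
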