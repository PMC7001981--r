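#' Experiment configuration
#'
#' Bundles and validates the parameters of a batch simulation. Defaults are
#' the study conditions: 40 trials, 100 repetitions, context A switching to D
#' at trial 21, reward delivered at the correct location 95% of the time,
#' context-stability prior 0.99, habitisation threshold 0.90.
#'
#' @param scheme One of `"full"`, `"scheme1"`, `"scheme2"`, `"scheme3"`.
#' @param n_trials Trials per repetition.
#' @param n_reps Number of independently seeded repetitions.
#' @param switch_trial Trial at which the context switches from the first to
#'   the second entry of `contexts`; `NA` for a single fixed context.
#' @param contexts Context labels before/after the switch.
#' @param schedule Optional explicit schedule data.frame (columns
#'   `first_trial`, `context`); overrides `switch_trial`/`contexts`.
#' @param p_reward World reward-delivery probability.
#' @param p_reward_model Agent's assumed reward probability (defaults to
#'   `p_reward`).
#' @param stability Context-stability prior across trials.
#' @param p_th Habitisation threshold.
#' @param gamma Softmax precision.
#' @param utility Preference strength for reward observations.
#' @param eta Cache learning rate.
#' @param seed Base RNG seed; per-repetition streams are derived from it.
#' @return Validated list of class `experiment_config`.
#' @export
experiment_config <- function(scheme = c("scheme1", "scheme2", "scheme3", "full"),
                              n_trials = 40L, n_reps = 100L,
                              switch_trial = 21L, contexts = c("A", "D"),
                              schedule = NULL,
                              p_reward = 0.95, p_reward_model = p_reward,
                              stability = 0.99, p_th = 0.90,
                              gamma = 4, utility = 3, eta = 1, seed = 1L) {
  scheme <- match.arg(scheme)
  bad <- character(0)
  chk_prob <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      bad <<- c(bad, name)
    }
  }
  chk_prob(p_reward, "p_reward")
  chk_prob(p_reward_model, "p_reward_model")
  chk_prob(stability, "stability")
  if (!is.numeric(p_th) || length(p_th) != 1L || is.na(p_th)) bad <- c(bad, "p_th")
  if (!is.numeric(n_trials) || n_trials < 1) bad <- c(bad, "n_trials")
  if (!is.numeric(n_reps) || n_reps < 1) bad <- c(bad, "n_reps")
  if (!is.numeric(gamma) || gamma <= 0) bad <- c(bad, "gamma")
  if (!is.numeric(utility) || utility < 0) bad <- c(bad, "utility")
  if (!is.numeric(eta) || eta <= 0 || eta > 1) bad <- c(bad, "eta")
  if (length(bad) > 0) {
    stop("invalid experiment configuration field(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(schedule)) {
    schedule <- if (is.na(switch_trial) || switch_trial > n_trials) {
      data.frame(first_trial = 1L, context = contexts[1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(first_trial = c(1L, as.integer(switch_trial)),
                 context = contexts[1:2], stringsAsFactors = FALSE)
    }
  }
  if (!all(schedule$context %in% TMAZE_CONTEXTS)) {
    stop("invalid experiment configuration field(s): schedule (unknown context)")
  }
  structure(list(
    scheme = scheme, n_trials = as.integer(n_trials),
    n_reps = as.integer(n_reps), schedule = schedule,
    p_reward = p_reward, p_reward_model = p_reward_model,
    stability = stability, p_th = p_th, gamma = gamma, utility = utility,
    eta = eta, seed = as.integer(seed)
  ), class = "experiment_config")
}

# Derived per-repetition seed: repetitions keep their streams when n_reps
# changes, and the value always fits a 32-bit integer.
rep_seed <- function(seed, rep) {
  as.integer(((as.numeric(seed) %% 20011) * 100003 + rep * 7919) %% 2147483647)
}

#' Run a batch simulation
#'
#' Runs `n_reps` independently seeded repetitions of `n_trials` trials under
#' the configured scheme, with a fresh uniform cache and uniform context
#' prior per repetition. Between trials only the context marginal of the
#' final belief survives (through the stability kernel of [build_D()]); the
#' location resets to the start.
#'
#' @param config An [experiment_config()].
#' @return Object of class `tmaze_metrics`: a data.frame with one row per
#'   (rep, trial) and columns `rep`, `trial`, `context`, `rewarded`,
#'   `context_entropy`, `habitised_at`, `habitised_1..4`, `n_habitised`,
#'   `max_expected_prob`, `executed_policy`, `n_efe_evals`, `n_eval_steps`,
#'   `ctx_A..ctx_D`. The configuration is attached as attribute `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  model <- tmaze_model(p_reward_model = config$p_reward_model,
                       utility = config$utility, gamma = config$gamma)
  n <- config$n_reps * config$n_trials
  out <- data.frame(
    rep = integer(n), trial = integer(n), context = character(n),
    rewarded = logical(n), context_entropy = numeric(n),
    habitised_at = integer(n),
    habitised_1 = logical(n), habitised_2 = logical(n),
    habitised_3 = logical(n), habitised_4 = logical(n),
    n_habitised = integer(n),
    max_expected_prob = numeric(n), executed_policy = integer(n),
    n_efe_evals = numeric(n), n_eval_steps = integer(n),
    ctx_A = numeric(n), ctx_B = numeric(n), ctx_C = numeric(n),
    ctx_D = numeric(n), stringsAsFactors = FALSE
  )
  row <- 0L
  for (rep in seq_len(config$n_reps)) {
    set.seed(rep_seed(config$seed, rep))
    cache <- policy_cache(model, p_th = config$p_th, eta = config$eta)
    prev_belief <- NULL
    ctx_post <- rep(0.25, 4)
    for (trial in seq_len(config$n_trials)) {
      ctx <- context_at_trial(trial, config$schedule)
      D <- build_D(ctx_post, config$stability, model$topology)
      res <- switch(config$scheme,
        full = run_trial_full(model, D, ctx, config$p_reward, cache, trial,
                              prev_final_belief = prev_belief),
        scheme1 = run_trial_scheme1(model, cache, prev_belief, D, ctx,
                                    config$p_reward, trial),
        scheme2 = run_trial_scheme2(model, cache, D, ctx, config$p_reward,
                                    trial, prev_final_belief = prev_belief),
        scheme3 = run_trial_scheme3(model, cache, D, ctx, config$p_reward,
                                    trial, prev_final_belief = prev_belief)
      )
      cache <- res$cache
      prev_belief <- res$final_belief
      ctx_post <- res$record$context_posterior
      r <- res$record
      row <- row + 1L
      out$rep[row] <- rep
      out$trial[row] <- trial
      out$context[row] <- ctx
      out$rewarded[row] <- r$rewarded
      out$context_entropy[row] <- context_entropy(r$context_posterior)
      out$habitised_at[row] <- r$habitised_at
      out$habitised_1[row] <- r$habitised[1]
      out$habitised_2[row] <- r$habitised[2]
      out$habitised_3[row] <- r$habitised[3]
      out$habitised_4[row] <- r$habitised[4]
      out$n_habitised[row] <- sum(r$habitised)
      out$max_expected_prob[row] <- max(r$pre_trial_expected)
      out$executed_policy[row] <- r$executed_policy
      out$n_efe_evals[row] <- r$n_efe_evals
      out$n_eval_steps[row] <- r$n_eval_steps
      out$ctx_A[row] <- r$context_posterior[1]
      out$ctx_B[row] <- r$context_posterior[2]
      out$ctx_C[row] <- r$context_posterior[3]
      out$ctx_D[row] <- r$context_posterior[4]
    }
  }
  attr(out, "config") <- config
  class(out) <- c("tmaze_metrics", "data.frame")
  out
}

#' Per-trial aggregate table
#'
#' Averages the per-repetition records over repetitions for each trial:
#' reward rate ("performance"), normalised context entropy ("uncertainty"),
#' habitised fraction overall and per choice point, mean of the maximum
#' expected cached policy probability, mean deliberation cost, and the mean
#' context posterior.
#'
#' @param metrics A `tmaze_metrics` data.frame from [run_experiment()].
#' @return Data.frame of class `tmaze_summary` with one row per trial.
#' @export
summarize_metrics <- function(metrics) {
  stopifnot(inherits(metrics, "tmaze_metrics") || is.data.frame(metrics))
  trials <- sort(unique(metrics$trial))
  agg <- function(col, f = mean) {
    as.numeric(tapply(metrics[[col]], metrics$trial, f))
  }
  out <- data.frame(
    trial = trials,
    reward_rate = agg("rewarded"),
    context_entropy = agg("context_entropy"),
    habit_fraction = as.numeric(tapply(!is.na(metrics$habitised_at),
                                       metrics$trial, mean)),
    habit_fraction_1 = agg("habitised_1"),
    habit_fraction_2 = agg("habitised_2"),
    habit_fraction_3 = agg("habitised_3"),
    habit_fraction_4 = agg("habitised_4"),
    max_expected_prob = agg("max_expected_prob"),
    n_efe_evals = agg("n_efe_evals"),
    n_eval_steps = agg("n_eval_steps"),
    ctx_A = agg("ctx_A"), ctx_B = agg("ctx_B"),
    ctx_C = agg("ctx_C"), ctx_D = agg("ctx_D")
  )
  attr(out, "config") <- attr(metrics, "config")
  class(out) <- c("tmaze_summary", "data.frame")
  out
}

#' First trial at which an aggregate series exceeds a threshold
#'
#' @param summary_table A `tmaze_summary` (or any data.frame with a `trial`
#'   column).
#' @param threshold Threshold to exceed (strict).
#' @param from_trial Search from this trial onwards.
#' @param column Name of the series to inspect.
#' @return The smallest qualifying trial index, or `NA` if none.
#' @examples
#' d <- data.frame(trial = 1:3, max_expected_prob = c(0.2, 0.5, 0.95))
#' first_threshold_crossing(d, 0.9) # 3
#' @export
first_threshold_crossing <- function(summary_table, threshold,
                                     from_trial = 1L,
                                     column = "max_expected_prob") {
  sub <- summary_table[summary_table$trial >= from_trial, , drop = FALSE]
  hit <- which(sub[[column]] > threshold)
  if (length(hit) == 0L) return(NA_integer_)
  sub$trial[hit[1L]]
}

#' Fraction of repetitions executing a given policy, per trial
#'
#' @param metrics A `tmaze_metrics` data.frame.
#' @param policy Policy id whose execution frequency is wanted.
#' @return Data.frame with columns `trial` and `fraction`.
#' @export
policy_execution_fraction <- function(metrics, policy) {
  frac <- tapply(metrics$executed_policy == policy, metrics$trial, mean)
  data.frame(trial = as.integer(names(frac)), fraction = as.numeric(frac),
             row.names = NULL)
}
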