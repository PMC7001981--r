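#' Likelihood matrix A
#'
#' P(observation | hidden state): at the reward location of a state's context
#' the red cue appears with probability `p_reward_model` (white with the
#' complement); every other location emits the white cue deterministically.
#'
#' @param p_reward_model Reward-delivery probability assumed by the agent.
#' @param topology A `tmaze_topology`.
#' @return A 20 x 40 column-stochastic matrix.
#' @export
build_A <- function(p_reward_model, topology = tmaze_topology()) {
  stopifnot(p_reward_model >= 0, p_reward_model <= 1)
  A <- matrix(0, nrow = 20L, ncol = 40L)
  for (loc in 1:10) {
    for (ctx in 1:4) {
      s <- state_index(loc, ctx)
      if (loc == topology$reward_location[[ctx]]) {
        A[obs_index(loc, "red"), s] <- p_reward_model
        A[obs_index(loc, "white"), s] <- 1 - p_reward_model
      } else {
        A[obs_index(loc, "white"), s] <- 1
      }
    }
  }
  A
}

#' Per-action transition matrices B
#'
#' Deterministic location moves tensored with the identity on context: the
#' context never changes within a trial. Actions undefined at a location fall
#' back to `stay` semantics so that every B is a valid (0/1 column-stochastic)
#' transition map; the policy set never exercises the fallback.
#'
#' @param topology A `tmaze_topology`.
#' @return Named list of four 40 x 40 matrices, one per action.
#' @export
build_B <- function(topology = tmaze_topology()) {
  out <- lapply(TMAZE_ACTIONS, function(a) {
    B <- matrix(0, nrow = 40L, ncol = 40L)
    for (loc in 1:10) {
      dest <- topology$moves[loc, a]
      if (is.na(dest)) dest <- loc
      for (ctx in 1:4) {
        B[state_index(dest, ctx), state_index(loc, ctx)] <- 1
      }
    }
    B
  })
  names(out) <- TMAZE_ACTIONS
  out
}

#' Log prior preferences over observations, lnC
#'
#' Unnormalised log-preference equal to `utility` for every red (reward)
#' observation and 0 for every white one, softmax-normalised over the 20
#' observations and returned in log space. `utility = 0` is indifference.
#'
#' @param utility Non-negative scalar preference strength (log-preference
#'   units).
#' @return Numeric vector of length 20; `exp()` of it sums to 1.
#' @export
build_lnC <- function(utility) {
  stopifnot(utility >= 0)
  u <- rep(0, 20L)
  u[obs_index(1:10, "red")] <- utility
  u - log(sum(exp(u)))
}

#' Initial-state prior D for a trial
#'
#' Location is reset to the start with certainty; the context prior is the
#' previous trial's context posterior passed through the stability kernel
#' that keeps the context with probability `stability` and spreads the
#' remainder equally over the other three contexts. On trial 1 the previous
#' posterior is uniform.
#'
#' @param prev_context_posterior Probability vector of length 4 over contexts.
#' @param stability Prior probability that the context is unchanged across
#'   trials.
#' @param topology A `tmaze_topology`.
#' @return Probability vector of length 40.
#' @export
build_D <- function(prev_context_posterior = rep(0.25, 4), stability = 0.99,
                    topology = tmaze_topology()) {
  p <- prev_context_posterior
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("prev_context_posterior must be a probability vector of length 4")
  }
  if (stability < 0 || stability > 1) stop("stability must lie in [0, 1]")
  K <- matrix((1 - stability) / 3, 4L, 4L)
  diag(K) <- stability
  ctx_prior <- as.vector(K %*% p)
  D <- numeric(40L)
  D[state_index(topology$start, 1:4)] <- ctx_prior
  D
}

#' Assemble the T-maze generative model
#'
#' Bundles the likelihood, transitions, preferences, enumerated policy set
#' and softmax precision into one model object. The policy count is validated
#' against the exhaustive enumeration (17 for the double T-maze). The
#' per-state observation entropy H (the ambiguity penalty of the expected
#' free energy) is precomputed.
#'
#' Default `gamma` and `utility` were calibrated once so that the fully
#' deliberative agent's reward rate ramps within the first ~5 trials of a
#' stable context (see the package vignette); they are exposed for study.
#'
#' @param p_reward_model Reward-delivery probability assumed by the agent
#'   (mirrors the world's by default).
#' @param utility Preference strength for reward observations.
#' @param gamma Softmax precision (> 0) applied to expected free energy.
#' @param topology A `tmaze_topology`.
#' @return An object of class `tmaze_model`.
#' @examples
#' m <- tmaze_model()
#' dim(m$A)             # 20 40
#' length(m$policies)   # 17
#' @export
tmaze_model <- function(p_reward_model = 0.95, utility = 3, gamma = 4,
                        topology = tmaze_topology()) {
  stopifnot(gamma > 0)
  policies <- enumerate_policies(topology)
  if (length(policies) != 17L) {
    stop("policy enumeration did not produce the expected 17 policies")
  }
  A <- build_A(p_reward_model, topology)
  # ambiguity vector: entropy of each likelihood column
  H <- apply(A, 2L, function(col) {
    nz <- col > 0
    -sum(col[nz] * log(col[nz]))
  })
  structure(list(
    A = A,
    B = build_B(topology),
    lnC = build_lnC(utility),
    policies = policies,
    actions_matrix = attr(policies, "actions_matrix"),
    gamma = gamma,
    utility = utility,
    p_reward_model = p_reward_model,
    H = H,
    horizon = 4L,
    n_states = 40L,
    n_obs = 20L,
    n_policies = length(policies),
    topology = topology
  ), class = "tmaze_model")
}

#' @export
print.tmaze_model <- function(x, ...) {
  cat("T-maze generative model\n")
  cat(sprintf("  states: %d (10 locations x 4 contexts)\n", x$n_states))
  cat(sprintf("  observations: %d (10 locations x 2 cues)\n", x$n_obs))
  cat(sprintf("  policies: %d (horizon %d)\n", x$n_policies, x$horizon))
  cat(sprintf("  p_reward_model = %.3f, utility = %.2f, gamma = %.2f\n",
              x$p_reward_model, x$utility, x$gamma))
  invisible(x)
}

# Context marginal of a 40-state belief.
#' Marginal posterior over contexts
#'
#' @param belief Probability vector over the 40 hidden states.
#' @return Probability vector of length 4 (contexts A..D).
#' @export
context_marginal <- function(belief) {
  vapply(1:4, function(ctx) sum(belief[state_index(1:10, ctx)]), numeric(1))
}

#' Normalised entropy of a context distribution
#'
#' Shannon entropy divided by log(4), giving a value in [0, 1]; used as the
#' per-trial "uncertainty" metric.
#'
#' @param p Probability vector of length 4.
#' @return Scalar in [0, 1].
#' @export
context_entropy <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(4)
}
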