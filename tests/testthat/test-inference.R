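test_that("belief filtering matches hand Bayes computations", {
  m <- default_model()
  # deterministic transition, single consistent state
  b <- belief_update(delta_belief(21), "left",
                     list(location = 5, cue = "red"), m)
  expect_equal(b, delta_belief(17))
  # white at the start location is uninformative
  b0 <- delta_belief(1) * 0.5 + delta_belief(4) * 0.5
  expect_equal(belief_update(b0, NULL, list(location = 1, cue = "white"), m), b0)
  # hand Bayes: 0.5 on (loc 6, A) and (loc 6, D); move left; white at 5.
  # P(white|5,A) = 0.05, P(white|5,D) = 1, so P(A) = 0.05 / 1.05.
  b <- belief_update(delta_belief(21) * 0.5 + delta_belief(24) * 0.5,
                     "left", list(location = 5, cue = "white"), m)
  expect_equal(context_marginal(b)[1], 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(sum(b), 1, tolerance = 1e-10)
  # impossible observations raise
  expect_error(belief_update(delta_belief(1), NULL,
                             list(location = 5, cue = "red"), m),
               "impossible observation")
})

test_that("policy-conditioned predictions roll the belief along the policy path", {
  m <- default_model()
  # policy 1 from state 1 lands on state 17 at the horizon
  expect_equal(predict_states(delta_belief(1), m$policies[[1]], m, 0, 4),
               delta_belief(17))
  # tau = t is the identity
  b <- uniform_prior()
  expect_identical(predict_states(b, m$policies[[3]], m, 2, 2), b)
  # context is carried along unchanged
  p7 <- m$policies[[policy_id(m$policies, c("up", "right", "up", "right"))]]
  pred <- predict_states(build_D(rep(0.25, 4), 1), p7, m, 0, 4)
  expect_equal(pred[state_index(10, 1:4)], rep(0.25, 4))
  expect_error(predict_states(b, m$policies[[1]], m, 0, 5), "horizon")
})

test_that("expected free energy equals a brute-force evaluation on a toy model", {
  m <- toy_model()
  # independent oracle: explicit loops over states and outcomes
  efe_oracle <- function(actions, belief) {
    G <- 0
    s <- belief
    for (tau in seq_along(actions)) {
      s <- as.vector(m$B[[actions[tau]]] %*% s)
      ambiguity <- 0
      for (i in seq_along(s)) {
        for (o in seq_len(nrow(m$A))) {
          if (m$A[o, i] > 0) {
            ambiguity <- ambiguity + s[i] * m$A[o, i] * log(m$A[o, i])
          }
        }
      }
      opred <- numeric(nrow(m$A))
      for (o in seq_len(nrow(m$A))) {
        for (i in seq_along(s)) opred[o] <- opred[o] + m$A[o, i] * s[i]
      }
      risk <- 0
      for (o in seq_len(nrow(m$A))) {
        if (opred[o] > 0) risk <- risk - opred[o] * (log(opred[o]) - m$lnC[o])
      }
      G <- G + ambiguity + risk
    }
    G
  }
  set.seed(99)
  for (acts in list(c("a", "a"), c("a", "b"), c("b", "a"), c("b", "b"))) {
    for (k in 1:5) {
      p <- stats::runif(1)
      belief <- c(p, 1 - p)
      pol <- list(actions = acts)
      expect_equal(expected_free_energy(pol, belief, m, 0),
                   efe_oracle(acts, belief), tolerance = 1e-12)
    }
  }
})

test_that("expected free energy is non-positive and zero only at matched preferences", {
  m <- default_model()
  set.seed(11)
  for (k in 1:10) {
    w <- stats::runif(40)
    belief <- w / sum(w)
    G <- vapply(m$policies, expected_free_energy, numeric(1),
                belief = belief, model = m, t = 0)
    expect_true(all(G <= 1e-12))
  }
  # with deterministic A and predictions equal to preferences, G = 0:
  # a one-state model whose sole outcome is fully preferred
  m1 <- list(A = matrix(1, 1, 1), B = list(stay = matrix(1, 1, 1)),
             lnC = 0, H = 0, horizon = 2L)
  expect_equal(expected_free_energy(list(actions = c("stay", "stay")), 1, m1, 0), 0)
})

test_that("the policy posterior is a precision-weighted softmax", {
  p <- policy_posterior(c(0, -1), gamma = 1)
  expect_equal(p$probs, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(p$probs[1], 0.7311, tolerance = 1e-4)
  # equal G gives the uniform distribution
  expect_equal(policy_posterior(rep(-3, 17), 4)$probs, rep(1 / 17, 17))
  # large precision concentrates on the argmax
  expect_equal(policy_posterior(c(-1, -2), 1e4)$probs[1], 1, tolerance = 1e-12)
  expect_error(policy_posterior(c(0, NaN), 1), "non-finite")
  expect_error(policy_posterior(c(0, -1), 0))
})

test_that("actions are sampled from the posterior's step-action marginal", {
  m <- default_model()
  # point mass on policy 1 at the trial start forces `up`
  pp <- structure(list(probs = c(1, rep(0, 16)), G = rep(0, 17)),
                  class = "policy_posterior")
  expect_identical(select_action(pp, m, 0), "up")
  # shared prefix: mass split over policies that agree at step 2
  probs <- rep(0, 17)
  probs[policy_id(m$policies, c("up", "left", "up", "left"))] <- 0.5
  probs[policy_id(m$policies, c("up", "left", "up", "right"))] <- 0.5
  pp <- structure(list(probs = probs, G = rep(0, 17)), class = "policy_posterior")
  expect_identical(select_action(pp, m, 1), "left")
  # Monte-Carlo frequency tracks the marginal
  probs <- rep(0, 17)
  probs[policy_id(m$policies, c("up", "left", "up", "left"))] <- 0.6
  probs[policy_id(m$policies, c("up", "right", "up", "right"))] <- 0.4
  pp <- structure(list(probs = probs, G = rep(0, 17)), class = "policy_posterior")
  set.seed(5)
  draws <- vapply(1:10000, function(i) select_action(pp, m, 1), character(1))
  expect_equal(mean(draws == "left"), 0.6, tolerance = 0.02)
})

test_that("a deliberative trial costs 68 policy evaluations and lands where the policy points", {
  m <- tmaze_model(p_reward_model = 1, gamma = 32)
  set.seed(2)
  res <- run_trial_full(m, build_D(c(1, 0, 0, 0), 1), "A", p_reward = 1)
  expect_equal(res$record$n_efe_evals, 68)
  expect_equal(res$record$n_eval_steps, 17L * (4L + 3L + 2L + 1L))
  expect_identical(res$record$actions, c("up", "left", "up", "left"))
  expect_true(res$record$rewarded)
  # the final belief concentrates on state 17 (location 5, context A)
  expect_equal(res$final_belief, delta_belief(17), tolerance = 1e-10)
  expect_equal(sum(res$final_belief), 1, tolerance = 1e-10)
})
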