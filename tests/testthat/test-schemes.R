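test_that("with an unreachable threshold all schemes reproduce full inference bit for bit", {
  strip <- function(x) {
    attr(x, "config") <- NULL
    class(x) <- "data.frame"
    x
  }
  base <- NULL
  for (scheme in c("full", "scheme1", "scheme2", "scheme3")) {
    cfg <- experiment_config(scheme = scheme, n_trials = 8, n_reps = 3,
                             p_th = 1.01, seed = 7)
    mt <- strip(run_experiment(cfg))
    expect_true(all(is.na(mt$habitised_at)))
    if (is.null(base)) base <- mt else expect_identical(mt, base)
  }
  # and every trial is fully deliberative at 68 policy evaluations
  expect_true(all(base$n_efe_evals == 68))
})

test_that("scheme 1 is deliberative on trial 1 and habitual from trial 2 when p_th = 0", {
  cfg <- experiment_config(scheme = "scheme1", n_trials = 5, n_reps = 3,
                           p_th = 0, seed = 2)
  mt <- run_experiment(cfg)
  expect_true(all(is.na(mt$habitised_at[mt$trial == 1])))
  expect_true(all(mt$habitised_at[mt$trial > 1] == 1))
  # habitual trials skip policy evaluation entirely
  expect_true(all(mt$n_efe_evals[mt$trial > 1] == 0))
  expect_true(all(mt$n_efe_evals[mt$trial == 1] == 68))
})

test_that("habitual scheme-1 trials execute open loop but keep monitoring the context", {
  m <- default_model()
  set.seed(4)
  cache <- policy_cache(m, p_th = 0.9)
  cache$table[, 17] <- c(1, rep(0, 16))  # a perfect habit for policy 1 at state 17
  res <- run_trial_scheme1(m, cache, prev_final_belief = delta_belief(17),
                           D = build_D(c(1, 0, 0, 0), 0.99), context = "D",
                           p_reward = 0.95)
  r <- res$record
  expect_true(all(r$habitised))
  expect_identical(r$actions, c("up", "left", "up", "left"))
  expect_identical(r$n_efe_evals, 0)
  expect_false(r$rewarded)  # context D pays at location 10, not 5
  # belief filtering ran: the white cue at location 5 downweights context A
  expect_lt(r$context_posterior[1], 0.99)
  expect_equal(sum(res$final_belief), 1, tolerance = 1e-10)
  # habitual trials never touch the cache
  expect_identical(res$cache$table, cache$table)
})

test_that("scheme 2 adopts a policy at the choice point whose prediction is cached", {
  m <- default_model()
  cache <- policy_cache(m, p_th = 0.9)
  # all states reachable one step ahead carry probability 1 for policy 1
  cache$table[, state_index(3, 1:4)] <- 0
  cache$table[1, state_index(3, 1:4)] <- 1
  set.seed(9)
  res <- run_trial_scheme2(m, cache, build_D(rep(0.25, 4), 0.99), "A")
  expect_identical(res$record$habitised_at, 1L)
  expect_identical(res$record$actions, m$policies[[1]]$actions)
  expect_identical(res$record$n_efe_evals, 0)
  # a uniform cache leaves every choice point deliberative
  set.seed(9)
  res2 <- run_trial_scheme2(m, policy_cache(m, p_th = 0.9),
                            build_D(rep(0.25, 4), 0.99), "A")
  expect_true(all(!res2$record$habitised))
})

test_that("scheme 3 terminates the path integral at the first cached crossing", {
  m <- default_model()
  cache <- policy_cache(m, p_th = 0.9)
  cache$table[, 17] <- c(1, rep(0, 16))
  set.seed(10)
  res <- run_trial_scheme3(m, cache, build_D(c(1, 0, 0, 0), 1), "A")
  r <- res$record
  # policy 1's integral reaches state 17 at tau = 4 of the first choice point
  expect_identical(r$habitised_at, 1L)
  expect_identical(r$actions, m$policies[[1]]$actions)
  # cost: policy 1 only, all 4 accumulation steps of a 4-step integral
  expect_identical(r$n_eval_steps, 4L)
  expect_equal(r$n_efe_evals, 1)
})

test_that("cache values stay in the unit interval over full scheme runs", {
  for (scheme in c("scheme1", "scheme2", "scheme3")) {
    m <- default_model()
    set.seed(6)
    cache <- policy_cache(m)
    prev <- NULL
    ctx_post <- rep(0.25, 4)
    for (tr in 1:10) {
      D <- build_D(ctx_post, 0.99)
      res <- switch(scheme,
        scheme1 = run_trial_scheme1(m, cache, prev, D, "A", trial = tr),
        scheme2 = run_trial_scheme2(m, cache, D, "A", trial = tr),
        scheme3 = run_trial_scheme3(m, cache, D, "A", trial = tr))
      cache <- res$cache
      prev <- res$final_belief
      ctx_post <- res$record$context_posterior
      expect_true(all(cache$table >= 0 & cache$table <= 1))
      expect_equal(colSums(cache$table), rep(1, 40), tolerance = 1e-10)
    }
  }
})
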