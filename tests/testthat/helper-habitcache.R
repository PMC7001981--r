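# Shared fixtures, built in code.

# Default model, constructed once per test run.
.default_model_env <- new.env()
default_model <- function() {
  if (is.null(.default_model_env$m)) .default_model_env$m <- tmaze_model()
  .default_model_env$m
}

# A small two-state / two-observation / two-action model with a non-trivial
# likelihood, used to cross-check the expected-free-energy implementation
# against a brute-force oracle. Shapes follow the tmaze_model contract.
toy_model <- function(utility = 2) {
  A <- matrix(c(0.8, 0.2,
                0.3, 0.7), nrow = 2)    # columns are states
  Ba <- matrix(c(0, 1,
                 1, 0), nrow = 2)       # swap states
  Bb <- diag(2)                          # stay
  u <- c(utility, 0)
  lnC <- u - log(sum(exp(u)))
  H <- apply(A, 2, function(col) -sum(col[col > 0] * log(col[col > 0])))
  list(A = A, B = list(a = Ba, b = Bb), lnC = lnC, H = H, horizon = 2L)
}

# Uniform-context prior over the 40 states with the location at start.
uniform_prior <- function() build_D(rep(0.25, 4), stability = 1)

# Point-mass belief on one hidden state.
delta_belief <- function(state, n = 40L) {
  b <- numeric(n)
  b[state] <- 1
  b
}
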