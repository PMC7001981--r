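---
title: "Habit formation by policy caching: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habit formation by policy caching: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitcache)
```

## The task and the generative model

An agent forages in a double T-maze with 10 locations. It always starts at
location 1; locations 5, 7, 8 and 10 are absorbing terminals and exactly one
of them is baited on each trial, determined by a hidden context: A baits 5,
B baits 7, C baits 8, D baits 10. At the baited location a red cue (the
reward) is delivered with probability `p_reward`; everywhere else, and on
the complementary non-delivery event, the cue is white. A trial consists of
four successive choices among the moves `up`, `left`, `right`, `stay`.

The agent's generative model is a discrete partially observed Markov
decision process:

* **Hidden states.** 40 = 10 locations × 4 contexts, indexed
  `(location − 1) × 4 + context`. Location 5 in context A is state 17;
  the start in context D is state 4.
* **Observations.** 20 = 10 locations × 2 cues (white, red). Locations are
  observed without noise; only the cue at a baited location is informative
  about the context.
* **Likelihood `A`.** White with certainty everywhere except the context's
  baited location, where red has probability `p_reward_model` (the agent's
  model mirrors the world's reward stochasticity by default, and the two are
  separately configurable to study model–world mismatch).
* **Transitions `B`.** One deterministic 0/1 matrix per action: location
  moves tensored with the identity on context (the context cannot change
  within a trial). Actions undefined at a location are given `stay`
  semantics so every `B` is a valid transition map.
* **Preferences `lnC`.** Unnormalised log-preference `utility` for every red
  observation, 0 for white, softmax-normalised over the 20 observations.
* **Prior `D`.** Location resets to the start with certainty; the context
  prior is the previous trial's context posterior passed through a
  stability kernel that keeps the context with probability `stability` and
  spreads the remainder equally over the other three. This is the only
  quantity carried between trials, and it is what lets evidence accumulate
  across trials.
* **Policies.** All length-4 action sequences under the rule: the first
  action is the unique move available at the start (the agent must enter
  the maze); at every later non-terminal location the defined moves plus
  `stay` are available; terminals absorb. Exhaustive enumeration yields
  exactly 17 policies, of which 4 reach a terminal; enumeration order is
  lexicographic over `up < left < right < stay`, which puts
  `up,left,up,left` (the best policy for context A) at id 1. The
  constructor validates the count of 17 at build time.

## Deliberative control

Each trial runs the perception–action loop four times. After each
observation the belief is updated by exact Bayesian filtering (the state
space is small enough that variational approximations would add error for
no gain). Every policy is then scored by its expected free energy, the path
integral over the remaining steps of an ambiguity term (expected
observation entropy given states) and a risk term (KL divergence of
predicted from preferred outcomes). Both terms are non-positive, so G_π ≤ 0
and less negative is better. A precision-weighted softmax of G_π (precision
`gamma`, computed with max-subtraction) gives the policy posterior; the
next action is sampled from the posterior's step-action marginal.

Two consequences of scoring *all* 17 policies at every choice point deserve
note. First, policies incompatible with the actions already executed are
still scored on their remaining actions applied to the current belief; the
cost counter is therefore exactly 4 × 17 = 68 policy evaluations per fully
deliberative trial. Second, the sampled action marginal can name an action
undefined at the (observed) current location; since the agent's own
transition model gives undefined moves `stay` semantics, the engine resolves
such an action to `stay` before acting. Every resolved sequence is again a
member of the exhaustive policy set.

## The policy cache and the delta rule

The cache stores `P(π|s)`: for each of the 40 hidden states, the
probability that each of the 17 policies is being pursued. It is
initialised uniform (1/17), so no habit can fire before anything has been
learned, and is consulted through its expectation under a belief,
`E_ŝ[P(π|s)] = Σ_i ŝ_i P(π|s_i)`. Training is a delta rule,

`P(π|s) ← P(π|s) + η · w_s · (π̂_π − P(π|s))`,

which preserves each state's normalisation over policies exactly. Two
design choices here were genuinely open and are resolved as follows:

* **The update posterior π̂** is the softmax posterior masked to policies
  consistent with the actions executed so far in the trial, renormalised.
  Without the mask, policies that share a *suffix* (e.g. the three policies
  whose last action is `left` from location 6) tie in G mid-trial and their
  diluted posterior overwrites the terminal-state columns, so cached values
  at the states that matter most never stabilise. The mask reflects what
  the cache means: the probability that a policy is being pursued. At trial
  end the consistent set has collapsed onto the executed policy, and a
  final consolidation update writes it into the cache under the final
  belief — this is the same rule at t = T, and it is how terminal states
  (e.g. state 17) acquire their cached values.
* **The weight `w`** is the agent's expected occupancy of each state over
  the remainder of the trial (current step included) under the masked
  posterior — the states the agent entertains, not merely the state it
  occupies. Occupancy-only weighting would leave every future-path column
  untouched at the time decisions about it are made, and mid-trial
  habitisation (schemes 2 and 3) could then never spread across choice
  points. The learning rate `η` scales the whole weight; at its default of
  1 the occupancy term alone governs update speed.

Habitual trials and habitual trial-remainders never update the cache: the
delta rule only learns from deliberative evaluations.

## The three habitisation schemes

All three schemes share the threshold rule: a habit fires when some
policy's expected cached probability strictly exceeds `p_th`; ties go to
the lowest policy id.

* **Scheme 1 (action selection).** Before stage A of each trial the cache
  is probed with the *previous* trial's final belief. A crossing policy is
  executed open-loop for the whole trial — no planning, no evaluation, no
  cache update, cost 0 — while belief filtering continues, so the context
  posterior stays current even under habitual control. Trial 1 is always
  deliberative. Estimation happens; deliberation does not.
* **Scheme 2 (planning).** At each choice point every policy is probed on
  its own one-step prediction; a crossing policy is adopted for the
  remainder of the trial. Deliberation and habit can coexist within a
  trial, and habitisation characteristically appears first at the fourth
  choice (whose predictions reach the terminal states, cached with the
  highest values) and spreads to earlier choices as the mid-path columns
  are learned.
* **Scheme 3 (policy evaluation).** Policies are evaluated in canonical id
  order; after every accumulation step of a policy's path integral the
  cache is probed on the predicted state, and the first crossing terminates
  all evaluation. Because the probe is prospective — it reaches the
  terminal states from the first choice point — habitisation mostly fires
  at the first choice and thereby covers all four choices of the trial;
  its cost counter records completed fractions of path integrals, so a
  fully deliberative trial again scores 68.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `p_reward` | 0.95 | reward delivery probability at the baited location |
| `stability` | 0.99 | prior probability the context persists across trials |
| `p_th` | 0.90 | habitisation threshold (strict) |
| `gamma` | 4 | softmax precision on expected free energy |
| `utility` | 3 | log-preference for reward observations |
| `eta` | 1 | cache learning rate |
| `n_trials`, `n_reps` | 40, 100 | trials per run, repetitions per experiment |
| `switch_trial` | 21 | first trial of the second context (A → D) |

`p_reward`, `p_th`, the trial counts and the switch point are the task's
stated conditions. The stability prior is stated in two places with two
values (99% and 90%); 0.99 is adopted — it belongs to the task description,
and the weaker prior makes post-switch perseveration too short-lived to
match the reported three-to-four-trial window — and the parameter is
exposed for study. `gamma` and `utility` are not stated anywhere and were
calibrated once, jointly, so that the fully deliberative agent's reward
rate ramps within the first ~5 trials of a stable context; they were not
revisited afterwards. `eta` defaults to 1 so that the printed delta-rule
weight (the occupancy term) alone governs learning speed.

## Numerical choices and degenerate inputs

* Softmax uses max-subtraction; non-finite G values are an error.
* Belief updates renormalise after conditioning; an observation with zero
  mass under the predicted states raises an impossible-observation error
  rather than returning NaNs.
* `0 log 0` terms in entropies and KL divergences are treated as 0.
* Argmax ties (habit check) resolve to the lowest policy id; scheme 3 scans
  policies in canonical id order, so its first crossing is deterministic
  given the cache.
* All randomness flows through R's global RNG; experiments seed each
  repetition with a stream derived from the base seed and the repetition
  index, so earlier repetitions are unchanged when `n_reps` grows.

## What the simulations do and do not show

The experiment harness *is* the data-generating process: the world model
(deterministic moves, per-trial contexts, Bernoulli cue delivery) is the
same one the agent assumes, apart from optional `p_reward` /
`p_reward_model` mismatch. Passing tests therefore demonstrate the internal
dynamics of habitisation — threshold crossings, perseveration,
deliberation-cost savings — under matched model and world. They do not
speak to robustness under structural mismatch (volatile contexts within a
trial, reward relocation, transition noise), which the model deliberately
excludes, nor to biological parameter ranges.

Test and acceptance runs use the study sizes directly (100 repetitions of
40 trials; a few seconds per scheme), with smaller runs (2–20 repetitions,
4–15 trials) for exact-equality and determinism checks.

## Known limitations

* With `eta = 1` and the end-of-trial consolidation, a cached column can
  move to the executed policy in a single confident trial, so habits
  re-form within a few trials of the new context being identified after a
  switch; slower, multi-trial consolidation requires `eta < 1`.
* Habit *learning* of policies outside the 17-policy repertoire is out of
  scope, as are merged scheme variants and model-averaging arbitration
  between controllers.
* Precision `gamma` is fixed; the qualitative sharpening of policy
  selection over trials emerges from belief sharpening alone.
* Wall-clock time is not a supported cost measure; the cost proxy is the
  count of expected-free-energy evaluations (fractional for scheme 3's
  truncated integrals).
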