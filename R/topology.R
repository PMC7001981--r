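# Canonical action order: used everywhere a deterministic ordering is needed
# (policy enumeration, action marginals).
TMAZE_ACTIONS <- c("up", "left", "right", "stay")

# Context labels in index order 1..4.
TMAZE_CONTEXTS <- c("A", "B", "C", "D")

#' Double T-maze topology
#'
#' Builds the fixed double T-maze used throughout the package: 10 locations,
#' start at location 1, four absorbing terminal (reward) locations
#' \{5, 7, 8, 10\}, and deterministic moves
#' 1-up-3; 3-left-2, 3-right-4; 2-up-6; 4-up-9; 6-left-5, 6-right-7;
#' 9-left-8, 9-right-10. `stay` is defined at every location and maps it to
#' itself; terminals admit only `stay`. Each context A--D baits exactly one
#' terminal: A-5, B-7, C-8, D-10.
#'
#' @return An object of class `tmaze_topology`: a list with elements
#'   `locations`, `start`, `terminals`, `moves` (a 10 x 4 matrix of
#'   destination locations, `NA` where a move is undefined), `reward_location`
#'   (named by context) and `contexts`.
#' @examples
#' topo <- tmaze_topology()
#' topo$moves[1, "up"]      # 3
#' topo$reward_location["A"] # 5
#' @export
tmaze_topology <- function() {
  moves <- matrix(NA_integer_, nrow = 10L, ncol = 4L,
                  dimnames = list(NULL, TMAZE_ACTIONS))
  moves[1L, "up"] <- 3L
  moves[3L, "left"] <- 2L
  moves[3L, "right"] <- 4L
  moves[2L, "up"] <- 6L
  moves[4L, "up"] <- 9L
  moves[6L, "left"] <- 5L
  moves[6L, "right"] <- 7L
  moves[9L, "left"] <- 8L
  moves[9L, "right"] <- 10L
  moves[, "stay"] <- 1:10
  structure(list(
    locations = 1:10,
    start = 1L,
    terminals = c(5L, 7L, 8L, 10L),
    moves = moves,
    reward_location = c(A = 5L, B = 7L, C = 8L, D = 10L),
    contexts = TMAZE_CONTEXTS
  ), class = "tmaze_topology")
}

#' Hidden-state and observation index conventions
#'
#' The agent's generative model has 40 hidden states (10 locations x 4
#' contexts) indexed `(location - 1) * 4 + context`, and 20 observations
#' (10 locations x 2 cues) indexed `(location - 1) * 2 + cue`, with cue 1 =
#' white and cue 2 = red. Under this convention, e.g., location 5 in context A
#' is state 17 and location 1 in context D is state 4.
#'
#' @param location Integer location id(s) in 1..10.
#' @param context Context label(s) `"A".."D"` or index 1..4.
#' @param cue Cue label(s), `"white"` or `"red"`.
#' @return Integer index vector.
#' @examples
#' state_index(5, "A") # 17
#' state_index(1, "D") # 4
#' obs_index(5, "red") # 10
#' @export
state_index <- function(location, context) {
  (as.integer(location) - 1L) * 4L + context_index(context)
}

#' @rdname state_index
#' @export
obs_index <- function(location, cue) {
  (as.integer(location) - 1L) * 2L + ifelse(cue == "red", 2L, 1L)
}

#' @rdname state_index
#' @export
context_index <- function(context) {
  if (is.numeric(context)) return(as.integer(context))
  idx <- match(context, TMAZE_CONTEXTS)
  if (anyNA(idx)) stop("unknown context label: ", paste(context, collapse = ", "))
  idx
}

#' Initial world state for a trial
#'
#' @param context True context label for the trial (`"A".."D"`).
#' @param trial Trial index (>= 1).
#' @return A `tmaze_world` list with fields `location`, `context`, `trial`,
#'   `step`.
#' @export
world_state <- function(context, trial = 1L) {
  stopifnot(context %in% TMAZE_CONTEXTS, trial >= 1)
  structure(list(location = 1L, context = context,
                 trial = as.integer(trial), step = 0L),
            class = "tmaze_world")
}

#' Advance the world by one action
#'
#' Moves the agent along the maze and samples the cue at the destination.
#' The cue is red with probability `p_reward` if and only if the destination
#' is the reward location of the true context; everywhere else (and on the
#' complementary 5% non-delivery event) the cue is white.
#' Undefined (location, action) pairs are an error: the enumerated policy set
#' never emits them.
#'
#' @param state A `tmaze_world` state.
#' @param action One of `"up"`, `"left"`, `"right"`, `"stay"`.
#' @param p_reward Probability of reward delivery at the correct location.
#' @param topology A `tmaze_topology`.
#' @return List with the new `state` and an `observation` (list with
#'   `location` and `cue`). Uses the global RNG stream for the cue draw.
#' @export
world_step <- function(state, action, p_reward, topology = tmaze_topology()) {
  stopifnot(p_reward >= 0, p_reward <= 1)
  dest <- unname(topology$moves[state$location, action])
  if (is.na(dest)) {
    stop(sprintf("invalid move: action '%s' undefined at location %d",
                 action, state$location))
  }
  reward_loc <- topology$reward_location[[state$context]]
  cue <- "white"
  if (dest == reward_loc && stats::runif(1L) < p_reward) cue <- "red"
  state$location <- dest
  state$step <- state$step + 1L
  list(state = state, observation = list(location = dest, cue = cue))
}

#' Context in force at a trial
#'
#' @param trial Trial index (>= 1).
#' @param schedule A data.frame with columns `first_trial` (sorted, starting
#'   at 1) and `context`; each row gives the context in force from
#'   `first_trial` onwards.
#' @return The context label at `trial`.
#' @examples
#' sched <- data.frame(first_trial = c(1, 21), context = c("A", "D"))
#' context_at_trial(20, sched) # "A"
#' context_at_trial(21, sched) # "D"
#' @export
context_at_trial <- function(trial, schedule) {
  if (trial < 1) stop("trial must be >= 1")
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1,
            all(c("first_trial", "context") %in% names(schedule)))
  ft <- schedule$first_trial
  if (ft[1] != 1 || is.unsorted(ft, strictly = TRUE)) {
    stop("schedule must be sorted and start at trial 1")
  }
  as.character(schedule$context[findInterval(trial, ft)])
}
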