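#' Enumerate the allowable policies of a maze
#'
#' Depth-first enumeration of all length-`horizon` action sequences under the
#' rule: the first action is the unique (non-stay) move available at the start
#' location -- the agent must commit to entering the maze; at every subsequent
#' non-terminal location the available actions are the defined moves plus
#' `stay`; terminal locations absorb (only `stay`). Policies are returned in
#' the canonical lexicographic order over actions (up < left < right < stay)
#' and ids are assigned in that order. For the double T-maze this yields
#' exactly 17 policies, of which 4 reach a reward location.
#'
#' @param topology A `tmaze_topology`.
#' @param horizon Policy length (number of actions per trial); 4 for the
#'   double T-maze.
#' @return An object of class `tmaze_policies`: a list of policy records,
#'   each with `id`, `actions` (character vector of length `horizon`),
#'   `trajectory` (locations visited, length `horizon + 1`, start included)
#'   and `reaches_reward` (logical). Attribute `actions_matrix` holds the
#'   n_policies x horizon action matrix used by the inference engine.
#' @examples
#' pols <- enumerate_policies(tmaze_topology())
#' length(pols)             # 17
#' pols[[1]]$actions        # up, left, up, left
#' pols[[1]]$trajectory     # 1 3 2 6 5
#' @export
enumerate_policies <- function(topology, horizon = 4L) {
  available <- function(loc, first) {
    if (first) {
      acts <- TMAZE_ACTIONS[TMAZE_ACTIONS != "stay"]
      acts <- acts[!is.na(topology$moves[loc, acts])]
      if (length(acts) != 1L) {
        stop("start location must have exactly one non-stay move")
      }
      return(acts)
    }
    if (loc %in% topology$terminals) return("stay")
    TMAZE_ACTIONS[!is.na(topology$moves[loc, ])]
  }
  out <- list()
  recurse <- function(loc, actions, trajectory) {
    if (length(actions) == horizon) {
      out[[length(out) + 1L]] <<- list(
        actions = actions,
        trajectory = trajectory,
        reaches_reward = any(trajectory %in% topology$terminals))
      return(invisible(NULL))
    }
    for (a in available(loc, first = length(actions) == 0L)) {
      dest <- unname(topology$moves[loc, a])
      recurse(dest, c(actions, a), c(trajectory, dest))
    }
  }
  recurse(topology$start, character(0), topology$start)
  for (i in seq_along(out)) out[[i]]$id <- i
  out <- lapply(out, function(p) p[c("id", "actions", "trajectory", "reaches_reward")])
  amat <- do.call(rbind, lapply(out, `[[`, "actions"))
  structure(out, class = "tmaze_policies", actions_matrix = amat)
}

#' Look up a policy by its action sequence
#'
#' Policies are named in the literature by their actions (e.g. the best
#' policy for context A is up, left, up, left); this resolves such a name to
#' the canonical id.
#'
#' @param policies A `tmaze_policies` object.
#' @param actions Character vector of actions, one per step.
#' @return The matching policy id, or `NA` if the sequence is not in the set.
#' @examples
#' pols <- enumerate_policies(tmaze_topology())
#' policy_id(pols, c("up", "left", "up", "left"))
#' policy_id(pols, c("up", "right", "up", "right"))
#' @export
policy_id <- function(policies, actions) {
  amat <- attr(policies, "actions_matrix")
  hit <- which(apply(amat, 1L, function(r) all(r == actions)))
  if (length(hit) == 0L) return(NA_integer_)
  hit[1L]
}

#' @export
as.data.frame.tmaze_policies <- function(x, ...) {
  data.frame(
    id = vapply(x, `[[`, integer(1), "id"),
    actions = vapply(x, function(p) paste(p$actions, collapse = ","), character(1)),
    trajectory = vapply(x, function(p) paste(p$trajectory, collapse = ","), character(1)),
    reaches_reward = vapply(x, `[[`, logical(1), "reaches_reward"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.tmaze_policies <- function(x, ...) {
  cat(sprintf("Policy set: %d policies (%d reach a reward location)\n",
              length(x), sum(vapply(x, `[[`, logical(1), "reaches_reward"))))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
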