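#' Export the policy table to CSV
#'
#' @param policies A `tmaze_policies` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_policy_table <- function(policies, path) {
  utils::write.csv(as.data.frame(policies), path, row.names = FALSE)
  invisible(path)
}

#' Export the generative-model matrices to JSON
#'
#' Dumps A, the per-action B matrices, lnC, the policy table and the scalar
#' parameters in a structured JSON document for inspection.
#'
#' @param model A `tmaze_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_model_json <- function(model, path) {
  payload <- list(
    n_states = model$n_states,
    n_obs = model$n_obs,
    n_policies = model$n_policies,
    p_reward_model = model$p_reward_model,
    utility = model$utility,
    gamma = model$gamma,
    A = model$A,
    B = model$B,
    lnC = model$lnC,
    policies = as.data.frame(model$policies)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Export a cache snapshot to long-format CSV
#'
#' One row per (state, policy) pair with the cached probability P(pi | s);
#' the data behind the per-state value panels.
#'
#' @param cache A `policy_cache`.
#' @param path Output file path.
#' @param trial Optional trial index recorded in a `trial` column.
#' @return The path, invisibly.
#' @export
export_cache_csv <- function(cache, path, trial = NA_integer_) {
  n_pol <- nrow(cache$table)
  n_states <- ncol(cache$table)
  d <- data.frame(
    trial = trial,
    state = rep(seq_len(n_states), each = n_pol),
    policy = rep(seq_len(n_pol), times = n_states),
    probability = as.vector(cache$table)
  )
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the full experiment configuration, seed and package version as
#' JSON; a run can be reproduced exactly from its manifest.
#'
#' @param config An `experiment_config`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, path) {
  payload <- unclass(config)
  payload$package_version <- as.character(utils::packageVersion("habitcache"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}
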