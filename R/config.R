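#' Default run configuration
#'
#' All tunables of the simulator with their defaults: a 10x10 grid, five
#' actions, utilities `c(3, 0)` on the reward/null outcomes, policy depth
#' 4, 16 gradient-descent iterations per time step, 10 navigation moves, 30
#' foraging moves, likelihood Dirichlet prior 1/100, prior inverse
#' precision 1, learning rate 1, gradient step 1/4, proximity weight 1/4
#' and 250 ms per movement. The default entrance is the bottom-left corner;
#' target and hidden-object locations are configuration, not constants.
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    grid_rows = 10L, grid_cols = 10L,
    utilities = c(3, 0),
    policy_depth = 4L,
    iterations_per_step = 16L,
    navigation_moves = 10L,
    foraging_moves = 30L,
    likelihood_prior_scale = 0.01,
    transition_prior_scale = 2,
    beta_prior = 1,
    eta = 1,
    step_size = 0.25,
    proximity_weight = 0.25,
    step_duration = 0.25,
    seed = 1L,
    start = 91L,           # bottom-left of the 10x10 grid
    target = 55L,          # Manhattan distance 8 from the default start
    hidden_object = 28L,
    ablate_novelty = FALSE,
    action_mode = "argmax",
    record_trace = TRUE,
    online_learning = TRUE,
    session_targets = c(55L, 23L),
    session_hidden_objects = c(28L, 87L)
  ), class = "run_config")
}

# type/positivity checks for a completed configuration
validate_run_config <- function(cfg) {
  pos <- c("grid_rows", "grid_cols", "policy_depth", "iterations_per_step",
           "likelihood_prior_scale", "transition_prior_scale", "beta_prior",
           "eta", "step_size", "step_duration")
  for (k in pos) if (any(cfg[[k]] <= 0)) stop("config: ", k, " must be > 0")
  if (cfg$navigation_moves < 0 || cfg$foraging_moves < 0)
    stop("config: move counts must be >= 0")
  if (cfg$proximity_weight < 0) stop("config: proximity_weight must be >= 0")
  if (!cfg$action_mode %in% c("argmax", "sample"))
    stop("config: action_mode must be 'argmax' or 'sample'")
  n <- cfg$grid_rows * cfg$grid_cols
  for (k in c("start", "target", "hidden_object"))
    if (cfg[[k]] < 1 || cfg[[k]] > n) stop("config: ", k, " out of grid range")
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys take their defaults (an empty file yields the default run);
#' unknown keys are rejected by name.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) {
    v <- user[[k]]
    if (is.numeric(cfg[[k]]) && !is.numeric(v))
      stop("config: ", k, " must be numeric")
    cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(v) else v
  }
  validate_run_config(cfg)
}

#' Run a configured scenario
#'
#' Builds the generative model and grid world from a configuration and runs
#' a navigation trial, a foraging trial, or an alternating session.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [load_config()]).
#' @param scenario one of "navigation", "foraging", "session".
#' @return a `sim_record` (navigation/foraging) or list of records
#'   (session).
#' @export
run_scenario <- function(config = default_run_config(),
                         scenario = c("navigation", "foraging", "session")) {
  scenario <- match.arg(scenario)
  cfg <- validate_run_config(config)
  geom <- grid_geometry(cfg$grid_rows, cfg$grid_cols)
  common <- list(beta_prior = cfg$beta_prior, step_size = cfg$step_size,
                 action_mode = cfg$action_mode,
                 record_trace = cfg$record_trace)
  if (scenario == "navigation") {
    model <- build_geocache_model(
      geom, cfg$target, utilities = cfg$utilities,
      proximity_weight = cfg$proximity_weight,
      policy_depth = cfg$policy_depth,
      iterations_per_step = cfg$iterations_per_step)
    world <- grid_world(geom, cfg$start, cfg$target, seed = cfg$seed)
    do.call(run_navigation_trial,
            c(list(model, world, n_moves = cfg$navigation_moves), common))
  } else if (scenario == "foraging") {
    model <- build_geocache_model(
      geom, cfg$hidden_object, utilities = cfg$utilities,
      dirichlet_prior_scale = cfg$likelihood_prior_scale,
      transition_prior_scale = cfg$transition_prior_scale,
      proximity_weight = 0,
      policy_depth = cfg$policy_depth,
      iterations_per_step = cfg$iterations_per_step)
    world <- grid_world(geom, cfg$start, cfg$hidden_object, seed = cfg$seed)
    do.call(run_foraging_trial,
            c(list(model, world, n_moves = cfg$foraging_moves,
                   learning = learning_config(cfg$eta,
                                              online = cfg$online_learning),
                   ablate_novelty = cfg$ablate_novelty), common))
  } else {
    script <- lapply(seq_along(cfg$session_targets), function(i) list(
      target = cfg$session_targets[i],
      hidden_object = cfg$session_hidden_objects[i],
      navigation_moves = cfg$navigation_moves,
      foraging_moves = cfg$foraging_moves))
    do.call(run_geocaching_session,
            c(list(geom, script, start = cfg$start,
                   utilities = cfg$utilities,
                   proximity_weight = cfg$proximity_weight,
                   dirichlet_prior_scale = cfg$likelihood_prior_scale,
                   transition_prior_scale = cfg$transition_prior_scale,
                   seed = cfg$seed), common))
  }
}
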