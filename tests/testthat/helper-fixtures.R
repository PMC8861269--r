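# Shared fixtures and memoised heavy simulations. Expensive runs (full
# navigation / foraging batteries) are computed once per test session and
# reused by the property and acceptance tests.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

grid10 <- function() grid_geometry(10, 10)

# known-map model with saturated Dirichlet counts on likelihood and
# transitions (the exploitation limit)
saturated_geocache_model <- function(target, geometry = grid10(), ...) {
  m <- build_geocache_model(geometry, target, ...)
  m$a <- list(what = 1e6 * m$A$what + 1e-4)
  m$b <- lapply(m$B, function(x) 1e6 * x + 1e-4)
  m
}

# foraging model: flat 1/100 likelihood prior, uncertain transitions,
# no proximity preference (the object's location is unknown to the agent)
foraging_model <- function(hidden_object, geometry = grid10()) {
  build_geocache_model(geometry, hidden_object,
                       dirichlet_prior_scale = 0.01,
                       transition_prior_scale = 2,
                       proximity_weight = 0)
}

# seeded start/target pair at Manhattan distance 1..10
nav_pair <- function(seed, geometry = grid10()) {
  set.seed(seed)
  repeat {
    start <- sample.int(geometry$n_states, 1)
    target <- sample.int(geometry$n_states, 1)
    d <- manhattan_distance(geometry, start, target)
    if (d >= 1 && d <= 10) return(list(start = start, target = target, d = d))
  }
}

run_foraging_seed <- function(seed, ablate = FALSE, geometry = grid10(),
                              n_moves = 30) {
  set.seed(seed)
  hidden <- sample.int(geometry$n_states, 1)
  start <- sample.int(geometry$n_states, 1)
  m <- foraging_model(hidden, geometry)
  w <- grid_world(geometry, start, hidden, seed = seed)
  run_foraging_trial(m, w, n_moves, ablate_novelty = ablate,
                     record_trace = FALSE)
}

# ---- memoised batteries ----------------------------------------------------

default_nav_record <- function() cached("default_nav_record", {
  run_scenario(default_run_config(), "navigation")
})

navigation_battery <- function() cached("navigation_battery", {
  lapply(1:20, function(i) {
    p <- nav_pair(i)
    m <- saturated_geocache_model(p$target)
    w <- grid_world(grid10(), p$start, p$target, seed = i)
    rec <- run_navigation_trial(m, w, 10, record_trace = FALSE)
    list(pair = p, record = rec)
  })
})

foraging_battery_full <- function() cached("foraging_battery_full", {
  lapply(1:50, run_foraging_seed)
})

foraging_battery_ablated <- function() cached("foraging_battery_ablated", {
  lapply(1:20, function(s) run_foraging_seed(s, ablate = TRUE))
})

random_walk_battery <- function() cached("random_walk_battery", {
  lapply(1:50, function(seed) {
    set.seed(seed)
    g <- grid10()
    hidden <- sample.int(g$n_states, 1)
    start <- sample.int(g$n_states, 1)
    run_random_walk(grid_world(g, start, hidden), 30, seed = seed)
  })
})
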