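#' Grid-world generative process
#'
#' The true environment, kept strictly separate from the agent's model: a
#' location on a grid, moved deterministically by actions (edge-stay), that
#' emits a one-hot `where` outcome and a `what` outcome that is "reward"
#' exactly at `reward_location`.
#'
#' @param geometry a [grid_geometry()].
#' @param start starting location index.
#' @param reward_location location generating the "reward" outcome (the
#'   navigation target or the hidden object of a foraging patch).
#' @param seed optional integer seed consumed by sampling-mode trials.
#' @return object of class `grid_world`.
#' @export
grid_world <- function(geometry, start, reward_location, seed = NULL) {
  stopifnot(start >= 1, start <= geometry$n_states,
            reward_location >= 1, reward_location <= geometry$n_states)
  structure(list(geometry = geometry, location = as.integer(start),
                 start = as.integer(start),
                 reward_location = as.integer(reward_location),
                 seed = seed),
            class = "grid_world")
}

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf("<grid_world> %dx%d, at %d, reward at %d\n",
              x$geometry$n_rows, x$geometry$n_cols, x$location,
              x$reward_location))
  invisible(x)
}

#' Advance the generative process by one action
#'
#' @param world a [grid_world()].
#' @param action action index or name.
#' @return list with `world` (updated) and `outcomes`, an integer vector
#'   with elements `what` (1 = reward, 2 = null) and `where` (location
#'   index).
#' @export
env_step <- function(world, action) {
  if (is.character(action)) action <- match(action, grid_actions())
  if (is.na(action) || action < 1 || action > 5) stop("invalid action")
  world$location <- move_location(world$geometry, world$location, action)
  list(world = world, outcomes = observe_world(world))
}

# outcomes emitted at the current true location
observe_world <- function(world) {
  c(what = if (world$location == world$reward_location) 1L else 2L,
    where = world$location)
}

# ---------------------------------------------------------------------------
# trial engine

# one Gauss-Seidel sweep block over the observed part of the shared chain
chain_inference <- function(v, s, lnD, lnBf, lnBb, likmat, acts, t_now,
                            n_iter, step, record_trace) {
  n <- nrow(s)
  trace <- if (record_trace) array(NA_real_, c(n, t_now, n_iter))
  F_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (tau in seq_len(t_now)) {
      fwd <- if (tau == 1) lnD else as.vector(lnBf[, , acts[tau - 1]] %*% s[, tau - 1])
      eps <- fwd + likmat[, tau] - log_stable(s[, tau])
      if (tau < t_now)
        eps <- eps + as.vector(lnBb[, , acts[tau]] %*% s[, tau + 1])
      v[, tau] <- v[, tau] + step * (eps - mean(eps))
      s[, tau] <- softmax(v[, tau])
    }
    Fv <- 0
    for (tau in seq_len(t_now)) {
      fwd <- if (tau == 1) lnD else as.vector(lnBf[, , acts[tau - 1]] %*% s[, tau - 1])
      Fv <- Fv + sum(s[, tau] * (log_stable(s[, tau]) - fwd - likmat[, tau]))
    }
    F_trace[it] <- Fv
    if (record_trace) trace[, , it] <- s[, seq_len(t_now)]
  }
  list(v = v, s = s, trace = trace, F_trace = F_trace)
}

# log message tables as n x n x n_actions arrays for the kernel
log_B_cubes <- function(model) {
  lb <- model_log_B(model)
  n <- model$geometry$n_states
  k <- length(model$B)
  fw <- array(0, c(n, n, k)); bw <- array(0, c(n, n, k))
  for (u in seq_len(k)) { fw[, , u] <- lb$forward[[u]]; bw[, , u] <- lb$backward[[u]] }
  list(forward = fw, backward = bw)
}

#' Run one plan-act-observe trial
#'
#' The receding-horizon loop shared by navigation and foraging: at every
#' move the agent (i) refines policy-independent beliefs about the observed
#' past by gradient descent on free energy, (ii) infers policy-conditioned
#' beliefs over the planning window for every enumerated policy, (iii)
#' scores policies by expected free energy, (iv) updates precision against
#' the newly observed outcome (the previous step's policy set is re-scored:
#' policies whose first action cannot explain the new location acquire a
#' large free energy and drop out, which is what moves precision), and (v)
#' executes the first action of the winning posterior. With a learning
#' configuration, Dirichlet counts are accumulated (online per move by
#' default).
#'
#' @param model a `gen_model`; its `D` is replaced by a unit vector at the
#'   world's start location.
#' @param world a [grid_world()].
#' @param n_moves number of executed actions.
#' @param learning NULL (no learning) or a [learning_config()].
#' @param ablate_novelty drop the novelty term from policy scores.
#' @param record_trace record the per-iteration belief trace (needed for
#'   the simulated electrophysiology).
#' @param beta_prior prior inverse precision.
#' @param step_size gradient-descent step.
#' @param action_mode "argmax" or "sample" (seeded by `world$seed`).
#' @param occam_window optional positive scalar; policies whose log
#'   posterior falls more than this below the maximum are dropped from
#'   averaging and action selection (a performance knob, off by default).
#' @return object of class `sim_record`.
#' @export
run_trial <- function(model, world, n_moves, learning = NULL,
                      ablate_novelty = FALSE, record_trace = TRUE,
                      beta_prior = 1, step_size = 0.25,
                      action_mode = c("argmax", "sample"),
                      occam_window = NULL) {
  action_mode <- match.arg(action_mode)
  if (!is.null(world$seed)) set.seed(world$seed)
  n <- model$geometry$n_states
  T1 <- n_moves + 1L
  n_iter <- model$iterations_per_step
  depth <- model$policy_depth
  model$D <- as.numeric(seq_len(n) == world$start)
  lnD <- log_stable(model$D)
  pol <- enumerate_policies(model$actions, depth)
  npol <- nrow(pol)
  E <- if (is.null(model$E)) rep(1 / npol, npol) else model$E

  obs <- empty_observations(model, T1)
  obs[, 1] <- observe_world(world)
  locations <- integer(T1); locations[1] <- world$location
  acts_exec <- integer(0)

  # message tables (rebuilt when counts change)
  lnA <- model_log_A(model)
  Bc <- log_B_cubes(model)
  likmat <- matrix(0, n, T1)
  refresh_lik <- function(upto) {
    for (tau in seq_len(upto)) likmat[, tau] <<- likelihood_message(lnA, obs[, tau])
  }
  refresh_lik(1)

  v_chain <- matrix(0, n, T1)
  s_chain <- matrix(1 / n, n, T1)
  # model-average snapshot from the previous planning cycle: beliefs persist
  # across cycles (warm start), so rasters carry smooth settling transients
  # rather than re-initialization artefacts
  prev_snap <- matrix(1 / n, n, T1)

  gamma_trace <- numeric(n_iter * n_moves)
  gamma_steps <- numeric(n_moves)
  F_trace <- numeric(n_iter * n_moves)
  belief_trace <- if (record_trace) array(NA_real_, c(n, T1, n_iter * n_moves))
  Gmat <- matrix(NA_real_, npol, n_moves)
  risk_m <- ambig_m <- novel_m <- matrix(NA_real_, npol, n_moves)
  Qmat <- matrix(NA_real_, npol, n_moves)
  # per-policy postdictive free energy against the newest observation
  # (drives the precision update; undefined at the first step)
  Fmat <- matrix(NA_real_, npol, n_moves)
  entropy_before <- entropy_after <- rep(NA_real_, n_moves)
  selected <- data.frame(step = seq_len(n_moves), action = NA_integer_,
                         action_name = NA_character_,
                         novelty_selected = NA_real_, G_selected = NA_real_)
  a_prior <- model$a
  b_prior <- model$b
  gamma_prev <- 1 / beta_prior
  G_prev <- NULL
  prev_S <- NULL
  pol_first <- pol[, 1]

  for (k in seq_len(n_moves)) {
    it_idx <- (k - 1L) * n_iter + seq_len(n_iter)
    depth_t <- min(depth, T1 - k)

    if (k > 1) {  # warm-start the newly appended time point
      s0 <- pmax(prev_snap[, k], .log_floor)
      s_chain[, k] <- s0 / sum(s0)
      v_chain[, k] <- log(s_chain[, k])
    }

    # per-policy warm start of the planning window: policy (a1..ad) at this
    # step continues the beliefs of its predecessor (executed action, a1,
    # .., a(d-1)) from the previous step, which predicted exactly these time
    # points from the same past; the freshly uncovered horizon point is the
    # predecessor's rollout one step further
    init_s <- array(1 / n, c(n, npol, depth_t))
    if (k > 1 && !is.null(prev_S)) {
      n_act <- length(model$actions)
      pred <- rep((acts_exec[k - 1L] - 1L) * n_act^(depth - 1L) + 1L, npol)
      if (depth > 1) for (j in seq_len(depth - 1L))
        pred <- pred + (pol[, j] - 1L) * n_act^(depth - 1L - j)
      avail <- dim(prev_S)[3]
      Bbar <- model_expected_B(model)
      for (d in seq_len(depth_t)) {
        if (d + 1L <= avail) {
          init_s[, , d] <- prev_S[, pred, d + 1L]
        } else {
          prev_slice <- if (d == 1L) matrix(s_chain[, k], n, npol)
                        else matrix(init_s[, , d - 1L], n, npol)
          for (u in seq_len(n_act)) {
            idx <- which(pol[, d] == u)
            if (length(idx))
              init_s[, idx, d] <- Bbar[[u]] %*% prev_slice[, idx]
          }
        }
      }
    }

    # (i) policy-independent beliefs about the observed past
    ch <- chain_inference(v_chain, s_chain, lnD, Bc$forward, Bc$backward,
                          likmat, acts_exec, k, n_iter, step_size,
                          record_trace)
    v_chain <- ch$v; s_chain <- ch$s
    F_trace[it_idx] <- ch$F_trace

    # (iv) precision against the newly observed outcome, on the previous
    # step's policy set (skipped at the first step: nothing to re-score)
    if (k > 1) {
      F_by_action <- vapply(seq_along(model$actions), function(u) {
        fwd <- as.vector(Bc$forward[, , u] %*% s_prev_anchor)
        post <- softmax(fwd + likmat[, k])
        sum(post * (log_stable(post) - fwd - likmat[, k]))
      }, numeric(1))
      F_old <- F_by_action[pol_first]
      Fmat[, k] <- F_old
      prec <- update_precision(beta_prior, E, F_old, G_prev, n_iter)
      gamma_k <- prec$gamma
      q_pre  <- policy_posterior(E, F_old, G_prev, gamma_prev)
      q_post <- policy_posterior(E, F_old, G_prev, gamma_k)
      entropy_before[k] <- -sum(q_pre * log_stable(q_pre))
      entropy_after[k]  <- -sum(q_post * log_stable(q_post))
    } else {
      gamma_k <- 1 / beta_prior
    }
    gamma_trace[it_idx] <- c(rep(gamma_prev, n_iter - 1L), gamma_k)
    gamma_steps[k] <- gamma_k

    # (ii) policy-conditioned window beliefs
    kern <- window_inference_cpp(Bc$forward, Bc$backward, s_chain[, k],
                                 t(pol[, seq_len(depth_t), drop = FALSE]),
                                 init_s, n_iter, step_size, record_trace)
    S_fut <- kern$S  # n x npol x depth_t

    # (iii) expected free energy and the policy posterior
    efe <- expected_free_energy(model, S_fut, pol,
                                include_novelty = !ablate_novelty)
    Gmat[, k] <- efe$G
    risk_m[, k] <- efe$risk; ambig_m[, k] <- efe$ambiguity
    novel_m[, k] <- efe$novelty
    Q <- policy_posterior(E, 0, efe$G, gamma_k)
    if (!is.null(occam_window)) {
      keep <- log(pmax(Q, .log_floor)) >= max(log(Q)) - occam_window
      Q[!keep] <- 0
      Q <- Q / sum(Q)
    }
    Qmat[, k] <- Q

    # (v) act
    sel <- select_action(Q, pol, 1, mode = action_mode)
    u <- sel$action
    best <- which.max(Q)
    selected$action[k] <- u
    selected$action_name[k] <- model$actions[u]
    selected$novelty_selected[k] <- efe$novelty[best]
    selected$G_selected[k] <- efe$G[best]

    s_prev_anchor <- s_chain[, k]
    stepped <- env_step(world, u)
    world <- stepped$world
    obs[, k + 1L] <- stepped$outcomes
    locations[k + 1L] <- world$location
    acts_exec <- c(acts_exec, u)
    refresh_lik(k + 1L)

    # learning (online)
    if (!is.null(learning) && isTRUE(learning$online)) {
      fwd <- as.vector(Bc$forward[, , u] %*% s_chain[, k])
      s_post <- softmax(fwd + likmat[, k + 1L])
      if (learning$learn_what && !is.null(model$a)) {
        model$a$what <- update_likelihood_counts(
          model$a$what, s_post, obs["what", k + 1L], learning$eta)
      }
      if (learning$learn_transitions && !is.null(model$b)) {
        model$b[[u]] <- model$b[[u]] +
          learning$eta * tcrossprod(s_post, s_chain[, k])
      }
      lnA <- model_log_A(model)
      Bc <- log_B_cubes(model)
      refresh_lik(k + 1L)
    }

    # raster assembly: observed past from the chain, planning window as the
    # posterior-weighted policy average, horizon tail held at the window end
    if (record_trace) {
      wtr <- kern$trace  # n x (npol*depth_t) x n_iter
      for (it in seq_len(n_iter)) {
        snap <- matrix(NA_real_, n, T1)
        snap[, seq_len(k)] <- ch$trace[, , it]
        for (d in seq_len(depth_t)) {
          cols <- (d - 1L) * npol + seq_len(npol)
          snap[, k + d] <- as.vector(wtr[, cols, it] %*% Q)
        }
        if (k + depth_t < T1)
          snap[, (k + depth_t + 1L):T1] <- snap[, k + depth_t]
        belief_trace[, , it_idx[it]] <- snap
      }
    }
    snap <- matrix(NA_real_, n, T1)
    snap[, seq_len(k)] <- s_chain[, seq_len(k), drop = FALSE]
    for (d in seq_len(depth_t))
      snap[, k + d] <- as.vector(matrix(S_fut[, , d], n, npol) %*% Q)
    if (k + depth_t < T1)
      snap[, (k + depth_t + 1L):T1] <- snap[, k + depth_t]
    prev_snap <- snap

    gamma_prev <- gamma_k
    G_prev <- efe$G
    prev_S <- S_fut
  }

  # final pass over the complete observation sequence (feeds batch learning
  # and the reported posterior beliefs)
  ch <- chain_inference(v_chain, s_chain, lnD, Bc$forward, Bc$backward,
                        likmat, acts_exec, T1, n_iter, step_size, FALSE)
  final_beliefs <- ch$s

  if (!is.null(learning) && !isTRUE(learning$online)) {
    if (learning$learn_what && !is.null(model$a))
      model$a$what <- update_likelihood_counts(
        model$a$what, final_beliefs[, 2:T1], obs["what", 2:T1], learning$eta)
    if (learning$learn_transitions && !is.null(model$b))
      model$b <- update_transition_counts(model$b, final_beliefs, acts_exec,
                                          learning$eta)
  }

  structure(list(
    kind = "trial", n_moves = n_moves, n_timepoints = T1,
    geometry = model$geometry, iterations_per_step = n_iter,
    policy_depth = depth, actions = model$actions,
    start = world$start, reward_location = world$reward_location,
    locations = locations, actions_executed = acts_exec,
    outcomes = obs, visited = sort(unique(locations)),
    discovered = any(obs["what", ] == 1L, na.rm = TRUE),
    first_reward_step = {
      hit <- which(obs["what", ] == 1L)
      if (length(hit)) hit[1] - 1L else NA_integer_
    },
    policy_posterior = Qmat, G = Gmat, risk = risk_m, ambiguity = ambig_m,
    novelty = novel_m, F_policies = Fmat, policies = pol,
    selected = selected,
    gamma_trace = gamma_trace, gamma_steps = gamma_steps,
    beta_prior = beta_prior, entropy_before = entropy_before,
    entropy_after = entropy_after, F_trace = F_trace,
    belief_trace = belief_trace, final_beliefs = final_beliefs,
    a_prior = a_prior, b_prior = b_prior,
    a_posterior = model$a, b_posterior = model$b,
    learning = learning, ablate_novelty = ablate_novelty,
    seed = world$seed
  ), class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf(
    "<sim_record> %d moves on %dx%d grid; start %d, reward %d; %s\n",
    x$n_moves, x$geometry$n_rows, x$geometry$n_cols, x$start,
    x$reward_location,
    if (x$discovered) sprintf("first reward at step %d", x$first_reward_step)
    else "reward not found"))
  invisible(x)
}

#' Goal-directed navigation trial
#'
#' Ten moves (by default) on a known map: the agent plans depth-4 policies
#' under its preference for the rewarding outcome and for proximity to the
#' target, and follows a shortest available path.
#'
#' @param model a `gen_model` with known (or count-saturated) likelihood and
#'   transitions.
#' @param world a [grid_world()] whose reward location is the target.
#' @param n_moves number of moves (default 10).
#' @param ... passed to [run_trial()].
#' @return a `sim_record`.
#' @export
run_navigation_trial <- function(model, world, n_moves = 10, ...) {
  rec <- run_trial(model, world, n_moves, learning = NULL, ...)
  rec$kind <- "navigation"
  rec
}

#' Epistemic foraging trial
#'
#' Thirty moves (by default) in a novel patch: the `what` likelihood starts
#' at a small uniform Dirichlet prior, so expected free energy acquires a
#' novelty term that draws the agent to unvisited locations; counts
#' accumulate as locations are visited (online by default) and visited
#' locations lose their novelty.
#'
#' @param model a `gen_model` carrying Dirichlet likelihood (and optionally
#'   transition) concentration parameters.
#' @param world a [grid_world()] whose reward location is the hidden
#'   object.
#' @param n_moves number of moves (default 30).
#' @param learning a [learning_config()].
#' @param ... passed to [run_trial()].
#' @return a `sim_record`.
#' @export
run_foraging_trial <- function(model, world, n_moves = 30,
                               learning = learning_config(), ...) {
  if (is.null(model$a))
    stop("foraging expects Dirichlet counts on the what likelihood")
  rec <- run_trial(model, world, n_moves, learning = learning, ...)
  rec$kind <- "foraging"
  rec
}

#' Uniform random-walk baseline
#'
#' A policy-free reference agent taking uniformly random actions through
#' the same generative process; used to benchmark discovery frequency.
#'
#' @param world a [grid_world()].
#' @param n_moves number of moves.
#' @param seed integer seed.
#' @return list with `locations`, `visited`, `discovered`.
#' @export
run_random_walk <- function(world, n_moves, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  locations <- integer(n_moves + 1L)
  locations[1] <- world$location
  discovered <- world$location == world$reward_location
  for (k in seq_len(n_moves)) {
    st <- env_step(world, sample.int(5L, 1L))
    world <- st$world
    locations[k + 1L] <- world$location
    discovered <- discovered || st$outcomes["what"] == 1L
  }
  list(locations = locations, visited = sort(unique(locations)),
       discovered = discovered)
}

#' Alternating navigation / foraging session
#'
#' Plays out the full task: navigate to a target, then forage the local
#' patch for a hidden object that marks the next starting point, repeating
#' for each round of the script. Each foraging patch gets fresh likelihood
#' priors (novelty recurs in every new local area); within a patch learned
#' counts carry forward move to move.
#'
#' @param geometry a [grid_geometry()].
#' @param session_script list of rounds, each a list with elements `target`
#'   and `hidden_object` (location indices) and optional `navigation_moves`
#'   (default 10) and `foraging_moves` (default 30; 0 skips foraging).
#' @param start entrance location of the first navigation trial (default:
#'   bottom-left corner).
#' @param utilities,proximity_weight,dirichlet_prior_scale,
#'   transition_prior_scale model settings (see
#'   [build_geocache_model()]); the Dirichlet scales apply to foraging
#'   patches only.
#' @param seed integer seed.
#' @param ... passed to [run_trial()].
#' @return list of `sim_record`s in execution order, alternating
#'   navigation and foraging.
#' @export
run_geocaching_session <- function(geometry, session_script,
                                   start = loc_index(geometry, geometry$n_rows, 1),
                                   utilities = c(3, 0),
                                   proximity_weight = 0.25,
                                   dirichlet_prior_scale = 0.01,
                                   transition_prior_scale = 2,
                                   seed = NULL, ...) {
  records <- list()
  current <- start
  for (i in seq_along(session_script)) {
    round <- session_script[[i]]
    nav_moves <- if (is.null(round$navigation_moves)) 10L else round$navigation_moves
    forage_moves <- if (is.null(round$foraging_moves)) 30L else round$foraging_moves
    rseed <- if (is.null(seed)) NULL else seed + i

    nav_model <- build_geocache_model(geometry, round$target,
                                      utilities = utilities,
                                      proximity_weight = proximity_weight)
    nav_world <- grid_world(geometry, current, round$target, seed = rseed)
    nav <- run_navigation_trial(nav_model, nav_world, n_moves = nav_moves, ...)
    records[[length(records) + 1L]] <- nav
    current <- nav$locations[nav$n_timepoints]

    if (forage_moves > 0) {
      forage_model <- build_geocache_model(
        geometry, round$hidden_object, utilities = utilities,
        proximity_weight = 0,
        dirichlet_prior_scale = dirichlet_prior_scale,
        transition_prior_scale = transition_prior_scale)
      forage_world <- grid_world(geometry, current, round$hidden_object,
                                 seed = rseed)
      for_rec <- run_foraging_trial(forage_model, forage_world,
                                    n_moves = forage_moves, ...)
      records[[length(records) + 1L]] <- for_rec
      current <- if (for_rec$discovered) for_rec$reward_location
                 else for_rec$locations[for_rec$n_timepoints]
    }
  }
  records
}
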