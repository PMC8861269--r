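#' Exact posterior by exhaustive enumeration
#'
#' Brute-force smoothing on a tiny model: enumerates every hidden state
#' sequence, scores it against the observations up to `t_now`, and returns
#' exact marginals and the log evidence. Tractable only for a handful of
#' states and time points; serves as the independent oracle for the
#' variational scheme.
#'
#' @param model a `gen_model` (plain `A`/`B` tables are used).
#' @param actions integer vector of executed action indices
#'   (`n_timepoints - 1`).
#' @param observations observation matrix (see [empty_observations()]).
#' @param t_now latest observed time point (default: all).
#' @return list with `marginals` (`n_states x n_timepoints`) and
#'   `log_evidence`.
#' @export
enumerate_posterior <- function(model, actions, observations,
                                t_now = ncol(observations)) {
  n <- model$geometry$n_states
  T1 <- ncol(observations)
  if (n^T1 > 2e6) stop("model too large for exhaustive enumeration")
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), T1)))
  loglik_col <- function(tau, s) {
    if (tau > t_now) return(0)
    total <- 0
    for (m in seq_len(nrow(observations))) {
      o <- observations[m, tau]
      if (!is.na(o)) total <- total + log(model$A[[m]][o, s])
    }
    total
  }
  logp <- apply(seqs, 1, function(sq) {
    lp <- log(model$D[sq[1]]) + loglik_col(1, sq[1])
    if (T1 > 1) for (tau in 2:T1) {
      lp <- lp + log(model$B[[actions[tau - 1]]][sq[tau], sq[tau - 1]]) +
        loglik_col(tau, sq[tau])
    }
    lp
  })
  mx <- max(logp)
  w <- exp(logp - mx)
  logZ <- mx + log(sum(w))
  w <- w / sum(w)
  marg <- vapply(seq_len(T1), function(tau)
    vapply(seq_len(n), function(s) sum(w[seqs[, tau] == s]), numeric(1)),
    numeric(n))
  list(marginals = matrix(marg, nrow = n), log_evidence = logZ)
}

# random column-stochastic matrix (flat Dirichlet columns)
random_stochastic <- function(n_rows, n_cols) {
  m <- matrix(rgamma(n_rows * n_cols, 1, 1), n_rows, n_cols)
  sweep(m, 2, colSums(m), "/")
}

#' Oracle test fixtures
#'
#' Deterministically generates a tiny POMDP of the simulator's model class
#' (an unambiguous location modality plus a noisy two-level "what"
#' modality), a sampled trajectory, and its exactly enumerated posterior
#' marginals and evidence.
#'
#' Kinds: `tiny_hmm` (2-3 states, 2 random stochastic actions),
#' `two_state_bandit` (2 states, deterministic stay/switch actions),
#' `mini_grid` (known-map 2x2 grid world with its five actions).
#'
#' @param kind fixture family.
#' @param seed integer seed; the same seed always returns the same fixture.
#' @return list with `model`, `actions` (executed sequence), `observations`,
#'   `t_now`, `truth` (sampled state sequence) and `exact`
#'   (see [enumerate_posterior()]).
#' @export
make_fixture <- function(kind = c("tiny_hmm", "two_state_bandit",
                                  "mini_grid"), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "tiny_hmm") {
    n <- sample(2:3, 1)
    T1 <- sample(2:4, 1)
    A <- list(what = random_stochastic(2, n), where = diag(n))
    B <- list(random_stochastic(n, n), random_stochastic(n, n))
    acts_avail <- c("a1", "a2")
  } else if (kind == "two_state_bandit") {
    n <- 2L; T1 <- 4L
    A <- list(what = random_stochastic(2, n), where = diag(n))
    B <- list(stay = diag(2), switch = matrix(c(0, 1, 1, 0), 2))
    acts_avail <- c("stay", "switch")
  } else {
    geom <- grid_geometry(2, 2)
    n <- 4L; T1 <- 4L
    target <- sample.int(4L, 1)
    model <- build_geocache_model(geom, target, policy_depth = 1L)
    A <- model$A; B <- model$B
    acts_avail <- grid_actions()
  }
  geom <- if (kind == "mini_grid") grid_geometry(2, 2) else
    structure(list(n_rows = 1L, n_cols = n, n_states = as.integer(n)),
              class = "grid_geometry")
  C <- list(what = c(0, 0), where = rep(0, n))
  D <- if (kind == "mini_grid") as.numeric(random_stochastic(n, 1)) else
    as.numeric(random_stochastic(n, 1))
  model <- generative_model(geom, A, B, C, D, policy_depth = 1L,
                            actions = acts_avail)
  acts <- sample(seq_along(acts_avail), T1 - 1, replace = TRUE)
  s <- sample.int(n, 1, prob = D)
  obs <- empty_observations(model, T1)
  truth <- integer(T1)
  for (tau in seq_len(T1)) {
    if (tau > 1) s <- sample.int(n, 1, prob = model$B[[acts[tau - 1]]][, s])
    truth[tau] <- s
    obs["what", tau] <- sample.int(2L, 1, prob = model$A$what[, s])
    obs["where", tau] <- s
  }
  list(model = model, actions = acts, observations = obs, t_now = T1,
       truth = truth,
       exact = enumerate_posterior(model, acts, obs, T1))
}
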