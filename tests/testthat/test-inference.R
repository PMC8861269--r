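# small deterministic chain used by several cases: identity what-mapping is
# replaced by a noisy one so smoothing is nontrivial
noisy_fixture <- function(seed = 3) make_fixture("tiny_hmm", seed = seed)

test_that("an unambiguous observation pins beliefs to a delta", {
  g <- grid_geometry(2, 2)
  m <- build_geocache_model(g, 3)
  obs <- empty_observations(m, 1)
  obs[, 1] <- c(2L, 2L)  # null outcome, location 2
  fit <- infer_states(m, matrix(integer(0), 1, 0), obs, t_now = 1,
                      iterations = 128, record_trace = FALSE)
  expect_lt(max(abs(fit$s[, 1, 1] - c(0, 1, 0, 0))), 1e-6)
})

test_that("mean-centred prediction error vanishes in the symmetric case", {
  n <- 3
  geom <- structure(list(n_rows = 1L, n_cols = n, n_states = n),
                    class = "grid_geometry")
  m <- generative_model(
    geom,
    A = list(what = matrix(1 / 2, 2, n)),
    B = list(matrix(1 / n, n, n)),
    C = list(what = c(0, 0)), D = rep(1 / n, n),
    policy_depth = 1L, actions = "a")
  beliefs <- matrix(1 / n, n, 3)
  obs <- empty_observations(m, 3)
  eps <- state_prediction_error(m, c(1L, 1L), beliefs, obs, tau = 2, t_now = 0)
  expect_equal(eps - mean(eps), rep(0, n))
  expect_error(state_prediction_error(m, c(1L, 1L), beliefs, obs, 4, 0),
               "tau out of range")
})

test_that("belief iteration is stationary under zero or constant error", {
  b <- list(v = matrix(c(0.3, -0.1, 0.4, 0.2), 2, 2))
  b$s <- apply(b$v, 2, softmax)
  expect_equal(belief_iteration(b, matrix(0, 2, 2)), b)
  expect_equal(belief_iteration(b, matrix(5, 2, 2)), b)
  expect_error(belief_iteration(b, matrix(0, 2, 2), step_size = 0), "step_size")
})

test_that("free energy is non-increasing over iterations on random models", {
  for (seed in 1:100) {
    fx <- make_fixture("tiny_hmm", seed = seed)
    Fs <- numeric(16)
    fit <- infer_states(fx$model, fx$actions, fx$observations, fx$t_now,
                        iterations = 16)
    for (it in 1:16) {
      S <- matrix(fit$trace_s[, 1, , it], nrow = dim(fit$trace_s)[1])
      Fs[it] <- policy_free_energy(fx$model, fx$actions, S, fx$observations,
                                   fx$t_now)
    }
    expect_true(all(diff(Fs) <= 1e-8),
                info = paste("free energy rose at seed", seed))
  }
})

test_that("variational marginals match exhaustive enumeration on tiny models", {
  for (seed in 1:10) {
    fx <- make_fixture("tiny_hmm", seed = seed)
    fit <- infer_states(fx$model, fx$actions, fx$observations, fx$t_now,
                        iterations = 512, record_trace = FALSE)
    S <- matrix(fit$s[, 1, ], nrow = dim(fit$s)[1])
    expect_lt(max(abs(S - fx$exact$marginals)), 5e-3)
  }
})

test_that("the trace records every iteration for every time point", {
  fx <- noisy_fixture()
  fit <- infer_states(fx$model, fx$actions, fx$observations, fx$t_now,
                      iterations = 16)
  T1 <- ncol(fx$observations)
  expect_equal(dim(fit$trace_s), c(fx$model$geometry$n_states, 1, T1, 16))
  df <- belief_trace_df(fit)
  expect_equal(nrow(df), fx$model$geometry$n_states * T1 * 16)
  expect_true(all(diff(unique(df$iteration)) > 0))
  # normalization at every recorded iteration
  sums <- apply(fit$trace_s, c(2, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("a one-state model believes the only state at every iteration", {
  geom <- structure(list(n_rows = 1L, n_cols = 1L, n_states = 1L),
                    class = "grid_geometry")
  m <- generative_model(geom, A = list(what = matrix(c(0.4, 0.6), 2, 1)),
                        B = list(matrix(1, 1, 1)), C = list(what = c(0, 0)),
                        D = 1, policy_depth = 1L, actions = "a")
  obs <- empty_observations(m, 3); obs["what", ] <- c(1L, 2L, 2L)
  fit <- infer_states(m, matrix(1L, 1, 2), obs, t_now = 3)
  expect_true(all(fit$trace_s == 1))
})

test_that("free energy vanishes under perfect deterministic prediction", {
  g <- grid_geometry(2, 2)
  m <- build_geocache_model(g, 3, proximity_weight = 0)
  m$D <- c(1, 0, 0, 0)
  obs <- empty_observations(m, 2)
  obs[, 1] <- c(2L, 1L)                 # at location 1, null
  obs[, 2] <- c(2L, 2L)                 # moved right to location 2
  beliefs <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  Fv <- policy_free_energy(m, 4L, beliefs, obs, t_now = 2)
  expect_equal(Fv, 0, tolerance = 1e-12)
})

test_that("with a flat model the free energy is the outcome entropy", {
  n <- 4; k <- 3
  geom <- structure(list(n_rows = 1L, n_cols = n, n_states = n),
                    class = "grid_geometry")
  m <- generative_model(geom, A = list(what = matrix(1 / k, k, n)),
                        B = list(matrix(1 / n, n, n)),
                        C = list(what = rep(0, k)), D = rep(1 / n, n),
                        policy_depth = 1L, actions = "a")
  obs <- empty_observations(m, 1); obs["what", 1] <- 2L
  beliefs <- matrix(1 / n, n, 1)
  expect_equal(policy_free_energy(m, integer(0), beliefs, obs, 1), log(k))
})

test_that("variational free energy upper-bounds the exact log evidence", {
  for (seed in 1:10) {
    fx <- make_fixture("tiny_hmm", seed = seed)
    fit <- infer_states(fx$model, fx$actions, fx$observations, fx$t_now,
                        iterations = 512, record_trace = FALSE)
    S <- matrix(fit$s[, 1, ], nrow = dim(fit$s)[1])
    Fv <- policy_free_energy(fx$model, fx$actions, S, fx$observations,
                             fx$t_now)
    expect_gte(Fv, -fx$exact$log_evidence - 1e-9)
    expect_lt(Fv - (-fx$exact$log_evidence), 1e-3)
  }
})

test_that("Bayesian model averaging mixes policy-conditioned beliefs", {
  s <- array(0, c(2, 2, 1))
  s[, 1, 1] <- c(1, 0); s[, 2, 1] <- c(0, 1)
  expect_equal(as.vector(bayesian_model_average(s, c(0.7, 0.3))), c(0.7, 0.3))
  # identical beliefs are invariant to the mixture weights
  s[, 2, 1] <- c(1, 0)
  expect_equal(as.vector(bayesian_model_average(s, c(0.2, 0.8))), c(1, 0))
  # single policy passes through
  m <- matrix(c(0.4, 0.6), 2, 1)
  expect_equal(bayesian_model_average(m, 1), m)
})
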