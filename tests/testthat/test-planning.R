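test_that("policy enumeration is exhaustive and lexicographic", {
  pol <- enumerate_policies(grid_actions(), 4)
  expect_equal(nrow(pol), 625)
  expect_equal(ncol(pol), 4)
  expect_equal(nrow(unique(pol)), 625)
  pol2 <- enumerate_policies(grid_actions(), 2)
  expect_equal(nrow(pol2), 25)
  expect_equal(pol2[1, ], c(1L, 1L))     # (up, up)
  expect_equal(pol2[25, ], c(5L, 5L))    # (stay, stay)
  expect_equal(pol2[2, ], c(1L, 2L))     # last position varies fastest
  expect_equal(nrow(enumerate_policies(c("a", "b"), 1)), 2)
  expect_error(enumerate_policies(grid_actions(), 0), "depth")
})

test_that("predicted outcomes mix the expected likelihood over beliefs", {
  g <- grid_geometry(10, 10)
  m <- build_geocache_model(g, 42)
  o <- predicted_outcomes(m, as.numeric(seq_len(100) == 42))
  expect_equal(o$what, c(1, 0))
  o <- predicted_outcomes(m, rep(1 / 100, 100))
  expect_equal(o$what, c(0.01, 0.99))
  expect_equal(sum(o$where), 1)
  # a symmetric Dirichlet prior predicts 50/50 regardless of beliefs
  mu <- build_geocache_model(g, 42, dirichlet_prior_scale = 0.01)
  expect_equal(predicted_outcomes(mu, as.numeric(seq_len(100) == 7))$what,
               c(0.5, 0.5))
})

test_that("risk equals the divergence of predicted outcomes from preferences", {
  # single-modality model so the reward-risk is isolated
  n <- 4
  geom <- structure(list(n_rows = 1L, n_cols = n, n_states = n),
                    class = "grid_geometry")
  A <- matrix(0, 2, n); A[1, 2] <- 1; A[2, -2] <- 1
  m <- generative_model(geom, A = list(what = A),
                        B = list(diag(n)), C = list(what = c(3, 0)),
                        D = rep(1 / n, n), policy_depth = 1L, actions = "stay")
  beliefs <- array(as.numeric(seq_len(n) == 2), c(n, 1, 1))  # at the target
  efe <- expected_free_energy(m, beliefs, matrix(1L, 1, 1))
  expect_equal(efe$risk, log(1 / softmax(c(3, 0))[1]), tolerance = 1e-12)
  expect_equal(efe$ambiguity, 0)
  expect_equal(efe$novelty, 0)
  expect_equal(efe$G, efe$risk + efe$ambiguity - efe$novelty)
})

test_that("a known identity mapping contributes no ambiguity", {
  g <- grid_geometry(3, 3)
  m <- build_geocache_model(g, 5, proximity_weight = 0)
  beliefs <- array(1 / 9, c(9, 1, 2))
  efe <- expected_free_energy(m, beliefs, matrix(c(5L, 5L), 1, 2))
  # what-ambiguity is 0 too: the true mapping is deterministic
  expect_equal(efe$ambiguity, 0)
})

test_that("novelty is the Dirichlet information-gain bound", {
  a <- cbind(c(0.01, 0.01))
  expect_equal(novelty_term(a, c(0.5, 0.5), 1), 25)
  expect_lt(novelty_term(matrix(1e6, 2, 3), c(0.5, 0.5), c(1, 0, 0)), 1e-6)
  # one observation strictly reduces the term
  a2 <- a; a2[1, 1] <- a2[1, 1] + 1
  expect_lt(novelty_term(a2, c(0.5, 0.5), 1), novelty_term(a, c(0.5, 0.5), 1))
  expect_error(novelty_term(cbind(c(0, 1)), c(0.5, 0.5), 1), "> 0")
})

test_that("novelty is equal across unvisited locations and dies with counts", {
  g <- grid_geometry(3, 3)
  m <- build_geocache_model(g, 5, dirichlet_prior_scale = 0.01,
                            proximity_weight = 0)
  nov <- vapply(1:9, function(j)
    novelty_term(m$a$what, c(0.5, 0.5), as.numeric(seq_len(9) == j)),
    numeric(1))
  expect_true(all(nov > 0))
  expect_equal(diff(range(nov)), 0)
  m$a$what <- matrix(1e6, 2, 9)
  expect_lt(novelty_term(m$a$what, c(0.5, 0.5), rep(1 / 9, 9)), 1e-6)
})

test_that("the policy posterior is a precision-weighted softmax", {
  expect_equal(policy_posterior(rep(1 / 3, 3), 0, c(1, 1, 1), 2), rep(1 / 3, 3))
  # habit limit: gamma -> 0 and F = 0 recovers E
  E <- c(0.9, 0.1)
  expect_equal(policy_posterior(E, 0, c(5, -3), 1e-12), E, tolerance = 1e-9)
  q <- policy_posterior(c(0.5, 0.5), 0, c(0, 1), 1)
  expect_equal(q, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_error(policy_posterior(c(0.5, 0.5), c(0, 0, 0), c(0, 1), 1), "length")
  expect_error(policy_posterior(c(0.5, 0.5), 0, c(0, 1), 0), "gamma")
})

test_that("the policy posterior is gauge-invariant in F, G and ln E", {
  E <- c(0.2, 0.3, 0.5); Fv <- c(0, 2, 1); G <- c(3, 1, 2)
  q0 <- policy_posterior(E, Fv, G, 1.3)
  expect_equal(policy_posterior(E, Fv + 10, G, 1.3), q0)
  expect_equal(policy_posterior(E, Fv, G - 5, 1.3), q0)
  expect_equal(policy_posterior(E * 4, Fv, G, 1.3), q0, tolerance = 1e-12)
})

test_that("precision only moves when observations re-rank policies", {
  # no evidence: F = 0 keeps beta at its prior, gamma trace flat
  p <- update_precision(1, rep(1 / 2, 2), 0, c(0, 3))
  expect_equal(p$beta, 1)
  expect_equal(p$gamma_trace, rep(1, 16))
  # constant G: (Q - Q0) . G is gauge-zero whatever F does
  p <- update_precision(1, rep(1 / 3, 3), c(0, 10, 5), c(2, 2, 2))
  expect_equal(p$beta, 1)
  expect_error(update_precision(0, rep(1 / 2, 2), 0, c(0, 1)), "beta_prior")
})

test_that("precision converges to the self-consistent fixed point", {
  E <- rep(1 / 2, 2); Fv <- c(0, 10); G <- c(0, 3)
  p <- update_precision(1, E, Fv, G, n_iter = 64)
  # independent fixed-point iteration, run to 1e-10
  beta <- 1
  repeat {
    gamma <- 1 / beta
    Q <- softmax(log(E) - Fv - gamma * G)
    Q0 <- softmax(log(E) - gamma * G)
    beta_new <- 1 + sum((Q - Q0) * G)
    if (abs(beta_new - beta) < 1e-10) break
    beta <- beta_new
  }
  expect_lt(p$beta, 1)          # confidence rose, gamma > 1
  expect_gt(p$gamma, 1)
  expect_equal(p$beta, beta, tolerance = 1e-8)
})

test_that("actions are selected by marginalizing the policy posterior", {
  pol <- enumerate_policies(grid_actions(), 2)
  q <- rep(1 / 25, 25)
  sel <- select_action(q, pol, 1)
  expect_equal(sel$marginal, rep(0.2, 5))
  expect_equal(sel$action_name, "up")          # tie-break by action order
  q2 <- numeric(25); q2[pol[, 1] == 1] <- 0.6 / 5; q2[pol[, 1] == 2] <- 0.4 / 5
  expect_equal(select_action(q2, pol, 1)$action_name, "up")
  # single policy returns its step action
  one <- matrix(c(3L, 2L), 1, 2, byrow = TRUE)
  attr(one, "actions") <- grid_actions()
  expect_equal(select_action(1, one, 2)$action_name, "down")
  expect_error(select_action(numeric(0), pol[0, , drop = FALSE], 1), "empty")
  expect_error(select_action(q, pol, 3), "step_index")
  # seeded sampling is reproducible
  set.seed(5); s1 <- select_action(q, pol, 1, mode = "sample")$action
  set.seed(5); s2 <- select_action(q, pol, 1, mode = "sample")$action
  expect_identical(s1, s2)
})
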