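test_that("the grid-world model has the documented structure", {
  g <- grid_geometry(10, 10)
  m <- build_geocache_model(g, 34)
  expect_equal(m$A$where, diag(100))               # location observed exactly
  expect_equal(which(m$A$what[1, ] == 1), 34)      # reward only at the target
  expect_equal(colSums(m$A$what), rep(1, 100))
  expect_equal(m$C$what, c(3, 0))
  # graded proximity preference, zero at the target
  d <- manhattan_distance(g, seq_len(100), rep(34, 100))
  expect_equal(m$C$where, -0.25 * d)
  expect_equal(max(m$C$where), 0)
  expect_null(m$a)
  expect_null(m$b)
})

test_that("Dirichlet priors are attached at the configured scales", {
  g <- grid_geometry(10, 10)
  m <- build_geocache_model(g, 7, dirichlet_prior_scale = 1 / 100,
                            transition_prior_scale = 2)
  expect_true(all(m$a$what == 0.01))
  expect_equal(dim(m$a$what), c(2L, 100L))
  expect_equal(m$b[[4]], 2 * m$B[[4]] + 1e-4)
  expect_error(build_geocache_model(g, 7, dirichlet_prior_scale = 0),
               "dirichlet_prior_scale")
  expect_error(build_geocache_model(g, 7, transition_prior_scale = -1),
               "transition_prior_scale")
  expect_error(build_geocache_model(g, 101), "target_location")
})

test_that("a single-cell grid degenerates cleanly", {
  g <- grid_geometry(1, 1)
  m <- build_geocache_model(g, 1)
  for (u in seq_along(m$B)) expect_equal(m$B[[u]], matrix(1, 1, 1))
  expect_equal(m$D, 1)
})

test_that("model validation rejects broken tables", {
  g <- grid_geometry(2, 2)
  m <- build_geocache_model(g, 1)
  bad <- m; bad$A$what[1, 2] <- 0.5
  expect_error(validate_generative_model(bad), "sum to 1")
  bad <- m; bad$D <- rep(0.3, 4)
  expect_error(validate_generative_model(bad), "D must sum to 1")
  bad <- m; bad$a <- list(what = matrix(0, 2, 4))
  expect_error(validate_generative_model(bad), "> 0")
  bad <- m; bad$policy_depth <- 0L
  expect_error(validate_generative_model(bad), "policy_depth")
})

test_that("expected likelihood is the Dirichlet column mean", {
  expect_equal(expected_likelihood(cbind(c(1, 1))), cbind(c(0.5, 0.5)))
  expect_equal(expected_likelihood(cbind(c(0.01, 0.01))), cbind(c(0.5, 0.5)))
  expect_equal(expected_likelihood(cbind(c(3, 1))), cbind(c(0.75, 0.25)))
  expect_error(expected_likelihood(cbind(c(0, 0))), "zero column")
})

test_that("expected log likelihood matches digamma identities and Monte Carlo", {
  # psi(2) = psi(1) + 1, so a column of ones gives -1 for both entries
  expect_equal(expected_log_likelihood(cbind(c(1, 1))),
               cbind(c(-1, -1)))
  # large-count limit approaches the log of the mean
  expect_lt(max(abs(expected_log_likelihood(cbind(c(1000, 1000))) - log(0.5))),
            1e-3)
  expect_error(expected_log_likelihood(cbind(c(-1, 1))), "> 0")

  # Monte-Carlo oracle for a sparse column: E[ln p1], p ~ Dir(0.01, 0.01).
  # Gamma(0.01) draws underflow in linear space, so sample their logs with
  # the boosted-shape identity ln G_a = ln G_{a+1} + ln(U) / a and combine
  # with log-sum-exp.
  set.seed(42)
  nmc <- 1e6
  lg1 <- log(rgamma(nmc, 1.01)) + log(runif(nmc)) / 0.01
  lg2 <- log(rgamma(nmc, 1.01)) + log(runif(nmc)) / 0.01
  mx <- pmax(lg1, lg2)
  lp <- lg1 - (mx + log(exp(lg1 - mx) + exp(lg2 - mx)))
  se <- sd(lp) / sqrt(nmc)
  expect_lt(abs(mean(lp) - expected_log_likelihood(cbind(c(0.01, 0.01)))[1, 1]),
            3 * se)
})

test_that("expected log likelihood obeys Jensen and the saturation limit", {
  set.seed(7)
  a <- matrix(rgamma(20, 2, 1), 4, 5)
  expect_true(all(expected_log_likelihood(a) <= log(expected_likelihood(a))))
  a_big <- 1e3 + 1e3 * expected_likelihood(a)  # every cell >= 1e3
  expect_lt(max(abs(expected_log_likelihood(a_big) -
                    log(expected_likelihood(a_big)))), 1e-3)
})

test_that("ambiguity measures outcome entropy per state", {
  expect_equal(ambiguity_vector(diag(5)), rep(0, 5))
  expect_equal(ambiguity_vector(cbind(c(0.5, 0.5))), log(2))
  expect_equal(ambiguity_vector(cbind(c(0.75, 0.25))),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  # list input sums modalities; zero columns of a deterministic modality add 0
  A <- list(what = cbind(c(0.5, 0.5), c(1, 0)), where = diag(2))
  expect_equal(ambiguity_vector(A), c(log(2), 0))
})

test_that("shifting a preference column by a constant changes no behavior", {
  g <- grid_geometry(4, 4)
  m1 <- build_geocache_model(g, 6, policy_depth = 3)
  m2 <- m1
  m2$C$what <- m2$C$what + 7.3
  m2$C$where <- m2$C$where - 2.1
  r1 <- run_navigation_trial(m1, grid_world(g, 16, 6), 4, record_trace = FALSE)
  r2 <- run_navigation_trial(m2, grid_world(g, 16, 6), 4, record_trace = FALSE)
  expect_equal(r1$policy_posterior, r2$policy_posterior)
  expect_identical(r1$locations, r2$locations)
})

test_that("model JSON serialization round-trips byte-stably", {
  g <- grid_geometry(3, 4)
  m <- build_geocache_model(g, 5, dirichlet_prior_scale = 0.01,
                            transition_prior_scale = 2)
  js1 <- model_to_json(m)
  m2 <- model_from_json(js1)
  expect_equal(m2$A, m$A)
  expect_equal(m2$a, m$a)
  expect_equal(m2$b, m$b)
  expect_equal(m2$C, m$C)
  expect_identical(as.character(model_to_json(m2)), as.character(js1))
})
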