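#' Enumerate fixed-depth policies
#'
#' All `n_actions^depth` ordered action sequences in lexicographic order
#' under the documented action order (the first policy repeats the first
#' action, the last repeats the last).
#'
#' @param actions character vector of action names (or an integer count).
#' @param depth policy depth (planning horizon), >= 1.
#' @return integer matrix `n_policies x depth` of action indices, with the
#'   action names attached as attribute `actions`.
#' @examples
#' nrow(enumerate_policies(grid_actions(), 4))  # 625
#' @export
enumerate_policies <- function(actions, depth) {
  if (depth < 1) stop("depth must be >= 1")
  if (is.numeric(actions) && length(actions) == 1)
    actions <- as.character(seq_len(actions))
  k <- length(actions)
  grid <- expand.grid(rep(list(seq_len(k)), depth))[, depth:1, drop = FALSE]
  pol <- as.matrix(grid[do.call(order, as.data.frame(grid)), , drop = FALSE])
  dimnames(pol) <- NULL
  storage.mode(pol) <- "integer"
  structure(pol, actions = actions)
}

#' Predicted outcome distributions under a policy
#'
#' `o[m] = A_bar[m] %*% s`, using the expected likelihood (Dirichlet mean)
#' where concentration parameters are present.
#'
#' @param model a `gen_model`.
#' @param beliefs state expectation vector at the future time point (or the
#'   `n_states x n_policies x n_timepoints` array of [infer_states()]).
#' @param policy policy index into the beliefs array (ignored when
#'   `beliefs` is a vector).
#' @param tau time point index into the beliefs array (ignored when
#'   `beliefs` is a vector).
#' @return named list of outcome probability vectors, one per modality.
#' @export
predicted_outcomes <- function(model, beliefs, policy = 1, tau = 1) {
  s <- if (is.array(beliefs) && length(dim(beliefs)) == 3)
    beliefs[, policy, tau] else as.vector(beliefs)
  Abar <- model_expected_A(model)
  lapply(Abar, function(Am) as.vector(Am %*% s))
}

#' Dirichlet novelty (information-gain) term
#'
#' The expected reduction of uncertainty about a Dirichlet-parameterized
#' likelihood column if the predicted outcome were observed from the
#' believed state: `o . W . s` with
#' `W_ij = (1 / a_ij - 1 / a_bar_j) / 2`, `a_bar_j = sum_k a_kj`.
#' Nonnegative, strictly decreasing in every count increment, and
#' vanishing as counts saturate.
#'
#' @param a strictly positive concentration table.
#' @param predicted_outcome outcome probability vector (rows of `a`).
#' @param belief state probability vector (columns of `a`).
#' @return scalar >= 0.
#' @export
novelty_term <- function(a, predicted_outcome, belief) {
  if (any(a <= 0)) stop("concentration parameters must be > 0")
  W <- 0.5 * sweep(1 / a, 2, 1 / colSums(a))
  as.numeric(predicted_outcome %*% W %*% belief)
}

# log-softmax preferences per modality (the gauge-invariant form of C)
log_softmax_C <- function(model) {
  lapply(model$C, function(cm) {
    cm <- cm - max(cm)
    cm - log(sum(exp(cm)))
  })
}

#' Expected free energy of policies
#'
#' Scores each policy over its future window by
#' `G = risk + ambiguity - novelty`, summed over future time points and
#' outcome modalities:
#' risk is the divergence of predicted outcomes from preferences,
#' `o . (ln o - Ctilde)` with `Ctilde` the log-softmax of `C`;
#' ambiguity is the expected outcome entropy given states, `s . H`;
#' novelty is the Dirichlet information gain of [novelty_term()] (zero when
#' no concentration parameters are attached).
#'
#' @param model a `gen_model`.
#' @param beliefs array `n_states x n_policies x horizon` of future state
#'   expectations (time points after the current one), e.g. the window
#'   beliefs of the planner, or the `s` array of [infer_states()] restricted
#'   to future time points.
#' @param policies integer policy matrix (rows aligned with the second
#'   dimension of `beliefs`); only used for its row count.
#' @param include_novelty set FALSE to ablate the novelty drive.
#' @return data.frame with one row per policy: `risk`, `ambiguity`,
#'   `novelty`, `G`.
#' @export
expected_free_energy <- function(model, beliefs, policies = NULL,
                                 include_novelty = TRUE) {
  if (is.matrix(beliefs)) beliefs <- array(beliefs, c(nrow(beliefs), 1, ncol(beliefs)))
  npol <- dim(beliefs)[2]
  horizon <- dim(beliefs)[3]
  if (!is.null(policies) && nrow(policies) != npol)
    stop("policies and beliefs disagree on the number of policies")
  Abar <- model_expected_A(model)
  Ct <- log_softmax_C(model)
  H <- lapply(Abar, ambiguity_vector)
  W <- if (include_novelty && !is.null(model$a))
    lapply(model$a, function(am) 0.5 * sweep(1 / am, 2, 1 / colSums(am)))

  risk <- ambiguity <- novelty <- numeric(npol)
  for (tau in seq_len(horizon)) {
    S <- matrix(beliefs[, , tau], ncol = npol)
    for (m in names(Abar)) {
      O <- Abar[[m]] %*% S
      risk <- risk + colSums(O * (log_stable(O) - Ct[[m]]))
      ambiguity <- ambiguity + as.vector(H[[m]] %*% S)
      if (!is.null(W[[m]]))
        novelty <- novelty + colSums(O * (W[[m]] %*% S))
    }
  }
  data.frame(risk = risk, ambiguity = ambiguity, novelty = novelty,
             G = risk + ambiguity - novelty)
}

#' Posterior over policies
#'
#' `Q(pi) = softmax(ln E - F - gamma * G)`: habits, evidence and
#' precision-weighted expected free energy. Invariant to adding a constant
#' to `F`, `G` or `ln E`.
#'
#' @param E prior probability vector over policies (habit).
#' @param F_vector per-policy variational free energies.
#' @param G_vector per-policy expected free energies.
#' @param gamma precision (inverse temperature), > 0.
#' @return probability vector over policies.
#' @export
policy_posterior <- function(E, F_vector, G_vector, gamma) {
  k <- length(G_vector)
  if (length(F_vector) == 1) F_vector <- rep(F_vector, k)
  if (length(E) == 1) E <- rep(E, k)
  if (length(E) != k || length(F_vector) != k)
    stop("E, F_vector and G_vector must share length")
  if (gamma <= 0) stop("gamma must be > 0")
  softmax(log_stable(E / sum(E)) - F_vector - gamma * G_vector)
}

#' Precision (inverse temperature) update over policies
#'
#' Iterates the self-consistent precision equations to a fixed point,
#' recording gamma at every iteration:
#' `Q = softmax(ln E - F - gamma G)`, `Q0 = softmax(ln E - gamma G)`,
#' `beta <- beta_prior + (Q - Q0) . G`, `gamma = 1 / beta` (beta floored at
#' 1e-6). When observations (through `F`) concentrate `Q` on low-G policies
#' relative to `Q0`, beta falls below its prior and gamma rises -- the
#' substrate of phasic dopamine.
#'
#' @param beta_prior prior inverse precision (> 0), or a previous
#'   `precision_state` whose `beta_prior` is reused.
#' @param E habit prior over policies.
#' @param F_vector,G_vector per-policy free energies.
#' @param n_iter fixed-point iterations (default 16).
#' @return object of class `precision_state`: `beta_prior`, `beta`,
#'   `gamma`, and `gamma_trace` (length `n_iter`).
#' @export
update_precision <- function(beta_prior, E, F_vector, G_vector,
                             n_iter = 16L) {
  if (inherits(beta_prior, "precision_state")) beta_prior <- beta_prior$beta_prior
  if (beta_prior <= 0) stop("beta_prior must be > 0")
  k <- length(G_vector)
  if (length(F_vector) == 1) F_vector <- rep(F_vector, k)
  if (length(E) == 1) E <- rep(E, k)
  lnE <- log_stable(E / sum(E))
  beta <- beta_prior
  gamma_trace <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    gamma <- 1 / beta
    Q  <- softmax(lnE - F_vector - gamma * G_vector)
    Q0 <- softmax(lnE - gamma * G_vector)
    beta <- max(beta_prior + sum((Q - Q0) * G_vector), 1e-6)
    gamma_trace[i] <- 1 / beta
  }
  structure(list(beta_prior = beta_prior, beta = beta, gamma = 1 / beta,
                 gamma_trace = gamma_trace),
            class = "precision_state")
}

#' @export
print.precision_state <- function(x, ...) {
  cat(sprintf("<precision_state> beta_prior %.4g, beta %.4g, gamma %.4g\n",
              x$beta_prior, x$beta, x$gamma))
  invisible(x)
}

#' Select an action from the policy posterior
#'
#' Marginalizes the policy posterior over the action at `step_index`
#' (`P(u) = sum over policies whose step action is u`) and returns the
#' argmax, breaking ties by the documented action order; optionally samples
#' from the marginal instead.
#'
#' @param policy_posterior probability vector over policies.
#' @param policies integer policy matrix from [enumerate_policies()].
#' @param step_index which step of the policies to marginalize (default 1).
#' @param mode "argmax" (default, deterministic) or "sample" (uses the
#'   session RNG; seed it for reproducibility).
#' @return list with `action` (index), `action_name` (if names are
#'   attached) and `marginal` (probability vector over actions).
#' @export
select_action <- function(policy_posterior, policies, step_index = 1,
                          mode = c("argmax", "sample")) {
  mode <- match.arg(mode)
  if (nrow(policies) == 0) stop("empty policy set")
  if (step_index < 1 || step_index > ncol(policies))
    stop("step_index exceeds policy depth")
  acts <- attr(policies, "actions")
  n_act <- if (!is.null(acts)) length(acts) else max(policies)
  marginal <- vapply(seq_len(n_act), function(u)
    sum(policy_posterior[policies[, step_index] == u]), numeric(1))
  u <- if (mode == "argmax") which.max(marginal)  # first max = action order
       else sample.int(n_act, 1, prob = marginal)
  list(action = u,
       action_name = if (!is.null(acts)) acts[u] else as.character(u),
       marginal = marginal)
}
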