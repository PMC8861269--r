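#' Observation matrix helper
#'
#' Observations are stored as an integer matrix with one row per outcome
#' modality (matching `names(model$A)`) and one column per time point;
#' entries are 1-based outcome level indices, `NA` for not-yet-observed
#' time points.
#'
#' @param model a `gen_model`.
#' @param n_timepoints number of time points (moves + 1).
#' @return all-`NA` integer matrix with modality rownames.
#' @export
empty_observations <- function(model, n_timepoints) {
  matrix(NA_integer_, length(model$A), n_timepoints,
         dimnames = list(names(model$A), NULL))
}

# Combined log-likelihood message for the outcomes observed at one time
# point: sum over modalities of the observed row of ln A (digamma
# expectations where Dirichlet counts are attached).
likelihood_message <- function(lnA, obs_col) {
  msg <- 0
  for (m in seq_along(lnA)) {
    if (!is.na(obs_col[m])) msg <- msg + lnA[[m]][obs_col[m], ]
  }
  msg
}

#' State prediction error
#'
#' The gradient of variational free energy with respect to the
#' log-beliefs about the location at time point `tau` under one policy:
#' the sum of the available messages minus `ln s`. Messages are the
#' forward message from `tau - 1` through the policy's action (the
#' log initial prior at `tau = 1`), the backward message from `tau + 1`
#' through the transposed, column-renormalized transition table (omitted at
#' the last time point), and the log-likelihood message of the outcomes
#' observed at `tau` (omitted for `tau > t_now`). Dirichlet-uncertain
#' tables enter through their digamma expectations.
#'
#' @param model a `gen_model`.
#' @param policy integer vector of action indices; `policy[k]` is the action
#'   between time points `k` and `k + 1`.
#' @param beliefs `n_states x n_timepoints` matrix of current state
#'   expectations for this policy.
#' @param observations observation matrix (see [empty_observations()]).
#' @param tau time point in `1..n_timepoints`.
#' @param t_now latest observed time point.
#' @return numeric vector over locations.
#' @export
state_prediction_error <- function(model, policy, beliefs, observations,
                                   tau, t_now) {
  T1 <- ncol(beliefs)
  if (tau < 1 || tau > T1) stop("tau out of range")
  lnA <- model_log_A(model)
  lnB <- model_log_B(model)
  fwd <- if (tau == 1) log_stable(model$D)
         else as.vector(lnB$forward[[policy[tau - 1]]] %*% beliefs[, tau - 1])
  bck <- if (tau < T1)
           as.vector(lnB$backward[[policy[tau]]] %*% beliefs[, tau + 1])
         else 0
  lik <- if (tau <= t_now) likelihood_message(lnA, observations[, tau]) else 0
  as.vector(fwd + bck + lik - log_stable(beliefs[, tau]))
}

#' One gradient-descent update of beliefs
#'
#' Depolarizations move along the mean-centred prediction error,
#' `v <- v + step_size * (eps - mean(eps))`, and firing rates are the
#' softmax of `v` (normalization is restored exactly). Mean-centring
#' exploits the softmax gauge freedom: a constant error moves nothing.
#'
#' @param beliefs list with elements `v` and `s` (matrices
#'   `n_states x n_timepoints`).
#' @param errors matrix of prediction errors, same shape.
#' @param step_size scalar in (0, 1].
#' @return updated `beliefs` list.
#' @export
belief_iteration <- function(beliefs, errors, step_size = 0.25) {
  if (step_size <= 0 || step_size > 1) stop("step_size must be in (0, 1]")
  centred <- sweep(errors, 2, colMeans(errors))
  beliefs$v <- beliefs$v + step_size * centred
  beliefs$s <- softmax_cols(beliefs$v)
  beliefs
}

#' Policy-conditioned state estimation
#'
#' Runs `iterations` Gauss-Seidel sweeps of gradient descent on variational
#' free energy over all time points for every policy, recording every
#' iteration. This is the reference (small-model) path; trial simulations
#' use a compiled kernel with the same update rule.
#'
#' @param model a `gen_model`.
#' @param policies integer matrix, one row per policy, `n_timepoints - 1`
#'   action indices per row (a single policy may be given as a vector).
#' @param observations observation matrix.
#' @param t_now latest observed time point.
#' @param iterations number of sweeps; default
#'   `model$iterations_per_step`.
#' @param step_size gradient step, default 1/4.
#' @param record_trace keep the per-iteration trace (arrays
#'   `n_states x n_policies x n_timepoints x iterations`)?
#' @return list with `s`, `v` (arrays `n_states x n_policies x
#'   n_timepoints`), `trace_s`, `trace_v` (or NULL) and `iterations`.
#' @export
infer_states <- function(model, policies, observations, t_now,
                         iterations = NULL, step_size = 0.25,
                         record_trace = TRUE) {
  if (is.vector(policies)) policies <- matrix(policies, nrow = 1)
  n <- model$geometry$n_states
  npol <- nrow(policies)
  T1 <- ncol(observations)
  n_iter <- if (is.null(iterations)) model$iterations_per_step else iterations
  lnA <- model_log_A(model)
  lnB <- model_log_B(model)
  lnD <- log_stable(model$D)
  lik <- matrix(0, n, T1)
  for (tau in seq_len(min(t_now, T1)))
    lik[, tau] <- likelihood_message(lnA, observations[, tau])

  v <- array(0, c(n, npol, T1))
  s <- array(1 / n, c(n, npol, T1))
  trace_s <- if (record_trace) array(NA_real_, c(n, npol, T1, n_iter))
  trace_v <- if (record_trace) array(NA_real_, c(n, npol, T1, n_iter))

  for (it in seq_len(n_iter)) {
    for (p in seq_len(npol)) {
      for (tau in seq_len(T1)) {
        fwd <- if (tau == 1) lnD
               else as.vector(lnB$forward[[policies[p, tau - 1]]] %*% s[, p, tau - 1])
        bck <- if (tau < T1)
                 as.vector(lnB$backward[[policies[p, tau]]] %*% s[, p, tau + 1])
               else 0
        li <- if (tau <= t_now) lik[, tau] else 0
        eps <- fwd + bck + li - log_stable(s[, p, tau])
        v[, p, tau] <- v[, p, tau] + step_size * (eps - mean(eps))
        s[, p, tau] <- softmax(v[, p, tau])
      }
    }
    if (record_trace) {
      trace_s[, , , it] <- s
      trace_v[, , , it] <- v
    }
  }
  list(s = s, v = v, trace_s = trace_s, trace_v = trace_v,
       iterations = n_iter)
}

#' Per-policy variational free energy
#'
#' Complexity-minus-accuracy over the observed time points:
#' `F = sum_{tau <= t_now} s_tau . (ln s_tau - forward message - likelihood
#' message)`. For fixed observations this is non-increasing over belief
#' iterations and upper-bounds the negative log evidence of the observed
#' outcome sequence under the policy.
#'
#' @inheritParams state_prediction_error
#' @return scalar free energy (nats).
#' @export
policy_free_energy <- function(model, policy, beliefs, observations, t_now) {
  lnA <- model_log_A(model)
  lnB <- model_log_B(model)
  total <- 0
  for (tau in seq_len(min(t_now, ncol(beliefs)))) {
    fwd <- if (tau == 1) log_stable(model$D)
           else as.vector(lnB$forward[[policy[tau - 1]]] %*% beliefs[, tau - 1])
    li <- likelihood_message(lnA, observations[, tau])
    st <- beliefs[, tau]
    total <- total + sum(st * (log_stable(st) - fwd - li))
  }
  total
}

#' Bayesian model average of policy-conditioned beliefs
#'
#' `s_bar_tau = sum_pi Q(pi) s[, pi, tau]`; each averaged vector sums to 1.
#'
#' @param beliefs array `n_states x n_policies x n_timepoints` (the `s`
#'   element of [infer_states()]), or a matrix for a single policy.
#' @param policy_posterior probability vector over policies.
#' @return matrix `n_states x n_timepoints`.
#' @export
bayesian_model_average <- function(beliefs, policy_posterior) {
  if (is.matrix(beliefs)) beliefs <- array(beliefs, c(nrow(beliefs), 1, ncol(beliefs)))
  stopifnot(abs(sum(policy_posterior) - 1) < 1e-8,
            dim(beliefs)[2] == length(policy_posterior))
  apply(beliefs, 3, function(S) as.vector(S %*% policy_posterior))
}

#' Long-format belief trace
#'
#' Flattens an [infer_states()] trace into a data frame with columns
#' `iteration`, `policy`, `tau`, `state`, `s`, `v`, suitable for CSV export.
#'
#' @param fit result of [infer_states()] with `record_trace = TRUE`.
#' @return data.frame.
#' @export
belief_trace_df <- function(fit) {
  if (is.null(fit$trace_s)) stop("no trace recorded")
  d <- dim(fit$trace_s)  # n, npol, T1, iter
  grid <- expand.grid(state = seq_len(d[1]), policy = seq_len(d[2]),
                      tau = seq_len(d[3]), iteration = seq_len(d[4]))
  data.frame(iteration = grid$iteration, policy = grid$policy,
             tau = grid$tau, state = grid$state,
             s = as.vector(fit$trace_s), v = as.vector(fit$trace_v))
}
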