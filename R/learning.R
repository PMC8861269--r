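#' Learning configuration
#'
#' @param eta learning rate (count mass added per observed time point),
#'   > 0, default 1.
#' @param learn_what update the `what`-likelihood concentration parameters?
#' @param learn_transitions update transition concentration parameters?
#' @param online when TRUE (the default used by foraging trials) counts are
#'   accumulated after every executed move, so visited locations lose their
#'   novelty within the trial; when FALSE the whole trial is accumulated in
#'   one batch at the end.
#' @return object of class `learning_config`.
#' @export
learning_config <- function(eta = 1, learn_what = TRUE,
                            learn_transitions = TRUE, online = TRUE) {
  if (eta <= 0) stop("eta must be > 0")
  structure(list(eta = eta, learn_what = learn_what,
                 learn_transitions = learn_transitions, online = online),
            class = "learning_config")
}

#' Accumulate likelihood concentration parameters
#'
#' Associative (Hebbian) accumulation: for every included time point the
#' outer product of the observed outcome and the (model-averaged) state
#' expectation is added, `a_ij <- a_ij + eta * o_tau[i] * s_tau[j]`. Each
#' time point adds exactly `eta` total count mass.
#'
#' @param a strictly positive concentration table for one modality.
#' @param belief_per_tau `n_states x n_timepoints` matrix of
#'   Bayesian-model-average state expectations (a single vector for one
#'   time point).
#' @param outcome_per_tau integer vector of observed outcome indices (rows
#'   of `a`), one per included time point; or a one-hot matrix
#'   `n_outcomes x n_timepoints`.
#' @param eta learning rate.
#' @return updated concentration table.
#' @export
update_likelihood_counts <- function(a, belief_per_tau, outcome_per_tau,
                                     eta = 1) {
  if (is.vector(belief_per_tau))
    belief_per_tau <- matrix(belief_per_tau, ncol = 1)
  if (nrow(belief_per_tau) != ncol(a))
    stop("belief dimension does not match concentration table")
  if (is.matrix(outcome_per_tau)) {
    O <- outcome_per_tau
    if (nrow(O) != nrow(a) || ncol(O) != ncol(belief_per_tau))
      stop("outcome matrix shape mismatch")
  } else {
    if (length(outcome_per_tau) != ncol(belief_per_tau))
      stop("need one outcome per time point")
    O <- matrix(0, nrow(a), length(outcome_per_tau))
    O[cbind(outcome_per_tau, seq_along(outcome_per_tau))] <- 1
  }
  a + eta * O %*% t(belief_per_tau)
}

#' Accumulate transition concentration parameters
#'
#' For each executed action `u` at step `tau`,
#' `b[[u]]_ij <- b[[u]]_ij + eta * s_{tau+1}[i] * s_tau[j]`. Tables of
#' actions that were not executed are unchanged.
#'
#' @param b list of strictly positive concentration tables, one per action.
#' @param belief_per_tau `n_states x n_timepoints` matrix of state
#'   expectations.
#' @param actions integer vector of executed action indices
#'   (`n_timepoints - 1` of them).
#' @param eta learning rate.
#' @return updated list of tables.
#' @export
update_transition_counts <- function(b, belief_per_tau, actions, eta = 1) {
  if (length(actions) != ncol(belief_per_tau) - 1)
    stop("need one action per transition")
  for (k in seq_along(actions)) {
    u <- actions[k]
    b[[u]] <- b[[u]] +
      eta * tcrossprod(belief_per_tau[, k + 1], belief_per_tau[, k])
  }
  b
}
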