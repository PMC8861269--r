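#' Construct a generative model
#'
#' Low-level constructor for the POMDP generative model: likelihood tables
#' `A` per outcome modality (optionally with Dirichlet concentration tables
#' `a`), transition tables `B` per action (optionally with concentrations
#' `b`), log preferences `C` per modality, initial-state prior `D`, habit
#' prior `E` over policies (NULL means uniform), a planning depth and the
#' number of gradient-descent iterations per time step.
#'
#' @param geometry a [grid_geometry()] (or any list with `n_states`).
#' @param A named list of column-stochastic likelihood matrices
#'   (`n_outcomes x n_states`), one per modality.
#' @param B list of column-stochastic transition matrices
#'   (`n_states x n_states`), one per action.
#' @param C named list of numeric utility vectors (natural-log relative
#'   probabilities over outcome levels), one per modality.
#' @param D probability vector over initial locations.
#' @param a optional named list of strictly positive Dirichlet concentration
#'   tables, same shapes as the matching entries of `A`. Modalities absent
#'   from `a` are treated as known exactly.
#' @param b optional list of concentration tables matching `B`.
#' @param E optional probability vector over policies (habit prior); NULL
#'   means uniform.
#' @param policy_depth planning horizon (number of future actions per
#'   policy).
#' @param iterations_per_step gradient-descent iterations per time step.
#' @param actions character vector of action names.
#' @param outcome_labels optional named list of outcome level labels.
#' @return a validated object of class `gen_model`.
#' @seealso [build_geocache_model()] for the grid-world instantiation.
#' @export
generative_model <- function(geometry, A, B, C, D, a = NULL, b = NULL,
                             E = NULL, policy_depth = 4L,
                             iterations_per_step = 16L,
                             actions = grid_actions(),
                             outcome_labels = NULL) {
  model <- structure(list(
    geometry = geometry, A = A, B = B, C = C, D = D, a = a, b = b, E = E,
    policy_depth = as.integer(policy_depth),
    iterations_per_step = as.integer(iterations_per_step),
    actions = actions, outcome_labels = outcome_labels
  ), class = "gen_model")
  validate_generative_model(model)
  model
}

#' Validate a generative model
#'
#' Checks shape consistency, column-stochasticity of `A`, `B`, `D` and `E`
#' to 1e-10, strict positivity of concentration tables, finiteness of
#' preferences, and `policy_depth >= 1`.
#'
#' @param model a `gen_model`.
#' @param tol stochasticity tolerance.
#' @return the model, invisibly; stops on violation.
#' @export
validate_generative_model <- function(model, tol = 1e-10) {
  n <- model$geometry$n_states
  if (model$policy_depth < 1L) stop("policy_depth must be >= 1")
  if (model$iterations_per_step < 1L) stop("iterations_per_step must be >= 1")
  for (m in names(model$A)) {
    Am <- model$A[[m]]
    if (ncol(Am) != n) stop("A[", m, "]: column count must equal n_states")
    if (any(Am < -tol)) stop("A[", m, "]: negative probabilities")
    if (max(abs(colSums(Am) - 1)) > tol)
      stop("A[", m, "]: columns must sum to 1")
  }
  if (length(model$B) != length(model$actions))
    stop("need one transition table per action")
  for (u in seq_along(model$B)) {
    Bu <- model$B[[u]]
    if (!all(dim(Bu) == c(n, n))) stop("B[", u, "]: must be n_states square")
    if (max(abs(colSums(Bu) - 1)) > tol)
      stop("B[", u, "]: columns must sum to 1")
  }
  if (!is.null(model$a)) {
    for (m in names(model$a)) {
      if (is.null(model$A[[m]])) stop("a[", m, "]: no matching modality in A")
      if (!all(dim(model$a[[m]]) == dim(model$A[[m]])))
        stop("a[", m, "]: shape must match A[", m, "]")
      if (any(model$a[[m]] <= 0)) stop("a[", m, "]: entries must be > 0")
    }
  }
  if (!is.null(model$b)) {
    if (length(model$b) != length(model$B)) stop("b: need one table per action")
    for (u in seq_along(model$b)) {
      if (!all(dim(model$b[[u]]) == c(n, n))) stop("b[", u, "]: bad shape")
      if (any(model$b[[u]] <= 0)) stop("b[", u, "]: entries must be > 0")
    }
  }
  for (m in names(model$C)) {
    if (length(model$C[[m]]) != nrow(model$A[[m]]))
      stop("C[", m, "]: length must match outcome levels of A[", m, "]")
    if (any(!is.finite(model$C[[m]]))) stop("C[", m, "]: must be finite")
  }
  if (length(model$D) != n) stop("D: length must equal n_states")
  if (abs(sum(model$D) - 1) > tol) stop("D must sum to 1")
  if (!is.null(model$E) && abs(sum(model$E) - 1) > tol)
    stop("E must sum to 1")
  invisible(model)
}

#' @export
print.gen_model <- function(x, ...) {
  n <- x$geometry$n_states
  cat(sprintf("<gen_model> %d states, modalities: %s; %d actions, depth %d\n",
              n, paste(names(x$A), collapse = ", "),
              length(x$actions), x$policy_depth))
  if (!is.null(x$a))
    cat("  Dirichlet likelihood counts on:", paste(names(x$a), collapse = ", "), "\n")
  if (!is.null(x$b)) cat("  Dirichlet transition counts present\n")
  invisible(x)
}

#' Build the grid-world ("geocaching") generative model
#'
#' Two outcome modalities over a single location factor: `what` registers a
#' rewarding outcome (levels "reward", "null"), generated only at the target
#' location; `where` reports the current location unambiguously (identity
#' likelihood). Preferences assign the configured utilities to the `what`
#' levels and a graded proximity preference over locations,
#' `C[where](loc) = -proximity_weight * ManhattanDistance(loc, target)`.
#' When `dirichlet_prior_scale` is given, the `what` likelihood carries a
#' uniform Dirichlet prior at that scale (the agent must learn where the
#' reward is); when `transition_prior_scale` is given, transition tables
#' carry concentration parameters `scale * B_true + 1e-4`.
#'
#' @param geometry a [grid_geometry()].
#' @param target_location location index generating the "reward" outcome.
#' @param utilities length-2 utilities (log relative probabilities) for the
#'   "reward" and "null" outcomes; the default `c(3, 0)` makes the reward
#'   outcome about 20 times more expected than null.
#' @param dirichlet_prior_scale positive scalar, or NULL for an exactly
#'   known `what` mapping.
#' @param transition_prior_scale positive scalar, or NULL for exactly known
#'   transitions.
#' @param proximity_weight nonnegative weight of the proximity preference
#'   (0 disables it).
#' @param policy_depth,iterations_per_step see [generative_model()].
#' @param initial_location optional location index; when given, `D` is the
#'   matching unit vector, otherwise uniform.
#' @return a `gen_model`.
#' @examples
#' g <- grid_geometry(10, 10)
#' m <- build_geocache_model(g, target_location = 34)
#' softmax(m$C$what)[1] / softmax(m$C$what)[2]  # ~ exp(3) ~ 20.1
#' @export
build_geocache_model <- function(geometry, target_location,
                                 utilities = c(3, 0),
                                 dirichlet_prior_scale = NULL,
                                 transition_prior_scale = NULL,
                                 proximity_weight = 0.25,
                                 policy_depth = 4L,
                                 iterations_per_step = 16L,
                                 initial_location = NULL) {
  n <- geometry$n_states
  if (target_location < 1 || target_location > n)
    stop("target_location out of range for geometry")
  if (!is.null(dirichlet_prior_scale) && dirichlet_prior_scale <= 0)
    stop("dirichlet_prior_scale must be > 0")
  if (!is.null(transition_prior_scale) && transition_prior_scale <= 0)
    stop("transition_prior_scale must be > 0")
  if (length(utilities) != 2) stop("utilities must have length 2")
  if (proximity_weight < 0) stop("proximity_weight must be >= 0")

  A_what <- rbind(as.numeric(seq_len(n) == target_location),   # reward
                  as.numeric(seq_len(n) != target_location))   # null
  A_where <- diag(n)
  A <- list(what = A_what, where = A_where)

  B <- build_transition_tables(geometry)

  C <- list(
    what = utilities,
    # + 0 normalizes IEEE negative zero so serialization is byte-stable
    where = -proximity_weight *
      manhattan_distance(geometry, seq_len(n), rep(target_location, n)) + 0
  )

  D <- if (is.null(initial_location)) rep(1 / n, n) else
    as.numeric(seq_len(n) == initial_location)

  a <- if (!is.null(dirichlet_prior_scale))
    list(what = matrix(dirichlet_prior_scale, 2, n))
  b <- if (!is.null(transition_prior_scale))
    lapply(B, function(Bu) transition_prior_scale * Bu + 1e-4)

  generative_model(geometry, A, B, C, D, a = a, b = b,
                   policy_depth = policy_depth,
                   iterations_per_step = iterations_per_step,
                   outcome_labels = list(what = c("reward", "null")))
}

#' Expected likelihood under a Dirichlet posterior
#'
#' Column-wise mean of the Dirichlet distribution: column `j` equals
#' `a[, j] / sum(a[, j])`.
#'
#' @param a strictly positive concentration table.
#' @return column-stochastic matrix of the same shape.
#' @export
expected_likelihood <- function(a) {
  if (any(a < 0)) stop("concentration parameters must be nonnegative")
  cs <- colSums(a)
  if (any(cs == 0)) stop("zero column sum in concentration table")
  sweep(a, 2, cs, "/")
}

#' Expected log likelihood under a Dirichlet posterior
#'
#' `E[ln A_ij] = digamma(a_ij) - digamma(sum_k a_kj)`. By Jensen's
#' inequality every entry lies below the log of [expected_likelihood()];
#' the two agree in the large-count limit.
#'
#' @param a strictly positive concentration table.
#' @return real-valued matrix of the same shape.
#' @export
expected_log_likelihood <- function(a) {
  if (any(a <= 0)) stop("concentration parameters must be > 0")
  sweep(digamma(a), 2, digamma(colSums(a)))
}

#' Outcome ambiguity per hidden state
#'
#' Aleatoric uncertainty about outcomes under each state:
#' `H_j = -sum_i A_ij ln A_ij`, summed over modalities when `A` is a list.
#' `0 * ln 0` is treated as 0, so a deterministic mapping has zero
#' ambiguity.
#'
#' @param A column-stochastic likelihood matrix, or list of such matrices
#'   (one per modality).
#' @return nonnegative vector over states.
#' @export
ambiguity_vector <- function(A) {
  one <- function(M) {
    L <- ifelse(M > 0, log(M), 0)
    -colSums(M * L)
  }
  if (is.list(A)) Reduce(`+`, lapply(A, one)) else one(A)
}

# Per-modality expected likelihoods: Dirichlet mean where counts exist,
# the true table otherwise.
model_expected_A <- function(model) {
  out <- model$A
  if (!is.null(model$a))
    for (m in names(model$a)) out[[m]] <- expected_likelihood(model$a[[m]])
  out
}

# Per-action expected transitions (Dirichlet mean where counts exist).
model_expected_B <- function(model) {
  if (is.null(model$b)) model$B else lapply(model$b, expected_likelihood)
}

# Log-likelihood tables used in messages: digamma expectation when counts
# are present, floored plain log otherwise. Floored at -32 either way.
model_log_A <- function(model) {
  lapply(names(model$A), function(m) {
    if (!is.null(model$a[[m]])) pmax(expected_log_likelihood(model$a[[m]]), -32)
    else log_stable(model$A[[m]])
  }) |> stats::setNames(names(model$A))
}

# Log transition tables (forward) and transposed-renormalized (backward).
model_log_B <- function(model) {
  fw <- lapply(seq_along(model$B), function(u) {
    if (!is.null(model$b)) pmax(expected_log_likelihood(model$b[[u]]), -32)
    else log_stable(model$B[[u]])
  })
  Bbar <- model_expected_B(model)
  bw <- lapply(Bbar, function(Bu) {
    M <- t(Bu)
    cs <- colSums(M)
    M <- sweep(M, 2, pmax(cs, .Machine$double.eps), "/")
    # states unreachable under the action carry no backward information
    M[, cs == 0] <- 1 / nrow(M)
    log_stable(M)
  })
  list(forward = fw, backward = bw)
}
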