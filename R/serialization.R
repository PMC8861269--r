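# JSON round-trip helpers. Arrays are rendered as row-major nested lists
# (jsonlite's convention) at full precision; save -> load -> save is
# byte-stable.

model_to_list <- function(model) {
  list(
    geometry = list(n_rows = model$geometry$n_rows,
                    n_cols = model$geometry$n_cols),
    A = model$A, B = model$B, C = model$C, D = model$D,
    a = model$a, b = model$b, E = model$E,
    policy_depth = model$policy_depth,
    iterations_per_step = model$iterations_per_step,
    actions = model$actions,
    outcome_labels = model$outcome_labels
  )
}

#' Serialize a generative model to JSON
#'
#' @param model a `gen_model`.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
model_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(model_to_list(model), digits = NA, auto_unbox = TRUE,
                         null = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Load a generative model from JSON
#'
#' @param path file path or JSON string produced by [model_to_json()].
#' @return a validated `gen_model`.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  geom <- grid_geometry(x$geometry$n_rows, x$geometry$n_cols)
  as_mat_list <- function(l) if (is.null(l)) NULL else
    lapply(l, function(m) matrix(unlist(m), nrow = nrow(m)))
  generative_model(
    geom,
    A = as_mat_list(x$A), B = as_mat_list(x$B),
    C = lapply(x$C, as.numeric), D = as.numeric(x$D),
    a = as_mat_list(x$a), b = as_mat_list(x$b),
    E = if (is.null(x$E)) NULL else as.numeric(x$E),
    policy_depth = x$policy_depth,
    iterations_per_step = x$iterations_per_step,
    actions = x$actions,
    outcome_labels = x$outcome_labels
  )
}

#' Save a trial record to JSON
#'
#' The complete `sim_record` (including the belief trace when recorded) as
#' one JSON document; [load_record()] restores it without loss of
#' structure.
#'
#' @param record a `sim_record`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
save_record <- function(record, path) {
  rec <- unclass(record)
  rec$geometry <- unclass(rec$geometry)
  if (!is.null(rec$learning)) rec$learning <- unclass(rec$learning)
  js <- jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE,
                         null = "null")
  writeLines(js, path)
  invisible(path)
}

#' Load a trial record saved by [save_record()]
#'
#' @param path file path.
#' @return a `sim_record`.
#' @export
load_record <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$geometry <- grid_geometry(x$geometry$n_rows, x$geometry$n_cols)
  x$outcomes <- matrix(as.integer(unlist(x$outcomes)), nrow = 2,
                       dimnames = list(c("what", "where"), NULL),
                       byrow = FALSE)
  if (!is.null(x$belief_trace))
    x$belief_trace <- array(unlist(x$belief_trace),
                            dim = dim(x$belief_trace))
  structure(x, class = "sim_record")
}

#' Write the tabular exports of a trial
#'
#' Writes `beliefs.csv` (long-format final posterior beliefs),
#' `planning.csv` (per step and policy: expected-free-energy components and
#' posterior, the selected action and precision) and, when a belief trace
#' was recorded, `ephys.csv` (see [ephys_long()]); plus `model.json` if a
#' model is supplied and `record.json`.
#'
#' @param record a `sim_record`.
#' @param dir output directory (created if needed).
#' @param model optional `gen_model` to store alongside.
#' @return the directory, invisibly.
#' @export
write_record_csvs <- function(record, dir, model = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fb <- record$final_beliefs
  beliefs <- data.frame(
    tau = rep(seq_len(ncol(fb)), each = nrow(fb)),
    state = rep(seq_len(nrow(fb)), ncol(fb)),
    s = as.vector(fb))
  write.csv(beliefs, file.path(dir, "beliefs.csv"), row.names = FALSE)

  npol <- nrow(record$G)
  steps <- record$n_moves
  pol_str <- if (!is.null(record$policies))
    apply(matrix(record$actions[record$policies], nrow(record$policies)), 1,
          paste, collapse = ">")
  else rep(NA_character_, npol)
  planning <- data.frame(
    step = rep(seq_len(steps), each = npol),
    policy = rep(seq_len(npol), steps),
    actions = rep(pol_str, steps),
    F = as.vector(record$F_policies),
    risk = as.vector(record$risk),
    ambiguity = as.vector(record$ambiguity),
    novelty = as.vector(record$novelty),
    G = as.vector(record$G),
    Q = as.vector(record$policy_posterior),
    selected_action = rep(record$selected$action_name, each = npol),
    gamma = rep(record$gamma_steps, each = npol))
  write.csv(planning, file.path(dir, "planning.csv"), row.names = FALSE)

  if (!is.null(record$belief_trace))
    ephys_long(ephys_traces(record), file.path(dir, "ephys.csv"))
  if (!is.null(model)) model_to_json(model, file.path(dir, "model.json"))
  save_record(record, file.path(dir, "record.json"))
  invisible(dir)
}
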