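#' Grid geometry
#'
#' Defines the rectangular grid housing the single hidden state factor
#' (location). Locations are 1-based row-major indices: location
#' `(row - 1) * n_cols + col`, with row 1 at the top and column 1 at the
#' left; the action "up" decreases the row.
#'
#' @param n_rows,n_cols positive integer grid dimensions.
#' @return an object of class `grid_geometry` with fields `n_rows`, `n_cols`
#'   and `n_states = n_rows * n_cols`.
#' @examples
#' g <- grid_geometry(10, 10)
#' loc_index(g, 1, 1)   # 1, top-left
#' loc_rowcol(g, 100)   # c(10, 10), bottom-right
#' @export
grid_geometry <- function(n_rows, n_cols) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols))
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_states = as.integer(n_rows) * as.integer(n_cols)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d (%d locations)\n",
              x$n_rows, x$n_cols, x$n_states))
  invisible(x)
}

#' Location index from (row, col)
#'
#' @param geometry a [grid_geometry()].
#' @param row,col 1-based coordinates.
#' @return integer location index in `1..n_states` (row-major).
#' @export
loc_index <- function(geometry, row, col) {
  stopifnot(all(row >= 1), all(row <= geometry$n_rows),
            all(col >= 1), all(col <= geometry$n_cols))
  as.integer((row - 1L) * geometry$n_cols + col)
}

#' (row, col) from location index
#'
#' @param geometry a [grid_geometry()].
#' @param loc location index in `1..n_states`.
#' @return integer vector `c(row, col)` (or a 2-column matrix for vector
#'   input).
#' @export
loc_rowcol <- function(geometry, loc) {
  stopifnot(all(loc >= 1), all(loc <= geometry$n_states))
  row <- (as.integer(loc) - 1L) %/% geometry$n_cols + 1L
  col <- (as.integer(loc) - 1L) %% geometry$n_cols + 1L
  if (length(loc) == 1L) c(row, col) else cbind(row = row, col = col)
}

#' Manhattan (city-block) distance between two locations
#'
#' @param geometry a [grid_geometry()].
#' @param loc_a,loc_b location indices.
#' @return integer distance.
#' @export
manhattan_distance <- function(geometry, loc_a, loc_b) {
  a <- loc_rowcol(geometry, loc_a)
  b <- loc_rowcol(geometry, loc_b)
  if (is.matrix(a) || is.matrix(b)) {
    a <- matrix(a, ncol = 2); b <- matrix(b, ncol = 2)
    abs(a[, 1] - b[, 1]) + abs(a[, 2] - b[, 2])
  } else {
    abs(a[1] - b[1]) + abs(a[2] - b[2])
  }
}

#' The five allowed actions, in their documented order
#'
#' The order `up < down < left < right < stay` fixes lexicographic policy
#' enumeration and deterministic tie-breaking in action selection.
#'
#' @return character vector of action names.
#' @export
grid_actions <- function() c("up", "down", "left", "right", "stay")

#' Apply an action to a location (edge-stay rule)
#'
#' An action that would leave the grid maps to "stay", so transition tables
#' remain column-stochastic without an absorbing boundary state.
#'
#' @param geometry a [grid_geometry()].
#' @param loc current location index.
#' @param action action name or index into [grid_actions()].
#' @return new location index.
#' @export
move_location <- function(geometry, loc, action) {
  if (is.character(action)) action <- match(action, grid_actions())
  stopifnot(!is.na(action), action >= 1, action <= 5)
  rc <- loc_rowcol(geometry, loc)
  row <- rc[1]; col <- rc[2]
  if (action == 1L) row <- row - 1L
  if (action == 2L) row <- row + 1L
  if (action == 3L) col <- col - 1L
  if (action == 4L) col <- col + 1L
  if (row < 1L || row > geometry$n_rows || col < 1L || col > geometry$n_cols)
    return(as.integer(loc))  # edge-stay
  loc_index(geometry, row, col)
}

#' Deterministic grid transition tables
#'
#' One column-stochastic table per action; each column is a unit vector
#' placing all mass on the destination of [move_location()].
#'
#' @param geometry a [grid_geometry()].
#' @return named list of `n_states x n_states` matrices, one per action;
#'   entry `[i, j]` is the probability of moving to location `i` from `j`.
#' @export
build_transition_tables <- function(geometry) {
  n <- geometry$n_states
  out <- lapply(seq_along(grid_actions()), function(u) {
    B <- matrix(0, n, n)
    for (j in seq_len(n)) B[move_location(geometry, j, u), j] <- 1
    B
  })
  names(out) <- grid_actions()
  out
}
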