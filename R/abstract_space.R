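#' Discrete multidimensional abstract spaces
#'
#' The task environment is a set of five discrete feature spaces, each a grid
#' with six values per dimension: two one-dimensional spaces (S1P, S1C), two
#' two-dimensional spaces (S2C, S2P) and one three-dimensional space (S3P).
#' The first space of each dimensionality belongs to Set 1 (S1P, S2C, S3P) and
#' the second to Set 2 (S1C, S2P); comparing the two sets measures transfer of
#' structural knowledge. Locations are 0-based integer coordinate vectors.
#'
#' @param label One of `"S1P"`, `"S2C"`, `"S2P"`, `"S1C"`, `"S3P"`.
#' @param n_values Number of discrete values per dimension (default 6).
#' @return An object of class `abstract_space` with fields `label`, `n_dims`,
#'   `n_values`, `set_index` and `symbol_tag`.
#' @examples
#' sp <- abstract_space("S2C")
#' sp$n_dims     # 2
#' sp$set_index  # 1
#' @export
abstract_space <- function(label, n_values = 6L) {
  label <- match.arg(label, names(.space_table))
  if (n_values < 2L) stop("n_values must be >= 2")
  info <- .space_table[[label]]
  structure(
    list(label = label, n_dims = info$n_dims, n_values = as.integer(n_values),
         set_index = info$set_index, symbol_tag = info$symbol_tag),
    class = "abstract_space")
}

# fixed session order; Set 1 = first space of each dimensionality encountered
.space_table <- list(
  S1P = list(n_dims = 1L, set_index = 1L, symbol_tag = "primary"),
  S2C = list(n_dims = 2L, set_index = 1L, symbol_tag = "control"),
  S2P = list(n_dims = 2L, set_index = 2L, symbol_tag = "primary"),
  S1C = list(n_dims = 1L, set_index = 2L, symbol_tag = "control"),
  S3P = list(n_dims = 3L, set_index = 1L, symbol_tag = "primary"))

#' @export
print.abstract_space <- function(x, ...) {
  cat(sprintf("<abstract_space %s: %dD, %d values/dim, Set %d (%s)>\n",
              x$label, x$n_dims, x$n_values, x$set_index, x$symbol_tag))
  invisible(x)
}

#' Session order of the five abstract spaces
#'
#' @return Character vector `c("S1P","S2C","S2P","S1C","S3P")`, the fixed
#'   order in which the spaces are encountered within a session.
#' @export
space_order <- function() c("S1P", "S2C", "S2P", "S1C", "S3P")

#' All locations of a space
#'
#' @param space An `abstract_space`.
#' @return Integer matrix, one row per location (0-based coordinates),
#'   ordered with the first dimension varying fastest.
#' @export
all_locations <- function(space) {
  stopifnot(inherits(space, "abstract_space"))
  g <- do.call(expand.grid, rep(list(0:(space$n_values - 1L)), space$n_dims))
  m <- as.matrix(g)
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

.check_location <- function(space, x) {
  if (length(x) != space$n_dims)
    stop("location has ", length(x), " coordinates; space is ", space$n_dims, "D")
  if (any(x < 0L) || any(x > space$n_values - 1L))
    stop("location out of bounds: ", paste(x, collapse = ","))
  invisible(as.integer(x))
}

#' Chebyshev distance between two locations
#'
#' The number of steps a perfect navigator needs between two locations when a
#' move may change every coordinate by at most one (Moore moves, diagonals
#' allowed): the maximum absolute coordinate difference.
#'
#' @param a,b Integer coordinate vectors of equal length.
#' @return Non-negative integer.
#' @examples
#' chebyshev_distance(c(2, 2), c(5, 2))  # 3
#' @export
chebyshev_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  as.integer(max(abs(as.integer(a) - as.integer(b))))
}

#' Candidate options around a current location
#'
#' The pool from which step options are drawn: every in-bounds location with
#' Chebyshev distance to the current location between 1 and `r_pool`, where
#' `r_pool` is 2 in one-dimensional spaces (otherwise only two candidates
#' would ever exist) and 1 in two- and three-dimensional spaces. The current
#' location is never in its own pool.
#'
#' @param space An `abstract_space`.
#' @param current Integer coordinate vector.
#' @return Integer matrix of pool locations, one per row.
#' @export
option_pool <- function(space, current) {
  current <- .check_location(space, current)
  r_pool <- if (space$n_dims == 1L) 2L else 1L
  locs <- all_locations(space)
  d <- apply(locs, 1L, function(l) max(abs(l - current)))
  locs[d >= 1L & d <= r_pool, , drop = FALSE]
}

#' Flag the distance-minimising options
#'
#' An option is optimal when it attains the minimum Chebyshev distance to the
#' goal among the offered options; ties are all flagged.
#'
#' @param options Integer matrix of options (one per row).
#' @param goal Integer coordinate vector.
#' @return Logical vector, one flag per option.
#' @examples
#' opts <- rbind(c(3, 3), c(1, 1), c(3, 2), c(2, 3))
#' optimal_options(opts, c(5, 5))  # TRUE FALSE FALSE FALSE
#' @export
optimal_options <- function(options, goal) {
  if (is.null(dim(options))) options <- matrix(options, nrow = 1L)
  if (nrow(options) == 0L) stop("no options given")
  d <- apply(options, 1L, chebyshev_distance, b = goal)
  d == min(d)
}

#' Generate the option set for one step
#'
#' Samples `min(4, pool size)` distinct options from the pool around the
#' current location. The set is guaranteed to contain at least one pool
#' member attaining the pool-wide minimum distance to the goal (so a perfect
#' navigator can always make progress), and the goal itself whenever it lies
#' in the pool. Options attaining the within-set minimum distance to the goal
#' are flagged optimal.
#'
#' @param space An `abstract_space`.
#' @param current,goal Integer coordinate vectors, `current != goal`.
#' @param n_options Maximum number of options offered (default 4).
#' @return A list of class `option_set`: `current`, `goal`, `options`
#'   (integer matrix) and `optimal_flags` (logical).
#' @export
generate_options <- function(space, current, goal, n_options = 4L) {
  current <- .check_location(space, current)
  goal <- .check_location(space, goal)
  if (identical(current, goal)) stop("current equals goal; path already complete")
  pool <- option_pool(space, current)
  if (nrow(pool) == 0L) stop("empty option pool")
  n_take <- min(n_options, nrow(pool))
  d_goal <- apply(pool, 1L, chebyshev_distance, b = goal)
  forced <- integer(0)
  goal_row <- which(d_goal == 0L)
  if (length(goal_row)) {
    forced <- goal_row
  } else {
    # one pool-wide best option is always offered
    best <- which(d_goal == min(d_goal))
    forced <- if (length(best) == 1L) best else sample(best, 1L)
  }
  rest <- setdiff(seq_len(nrow(pool)), forced)
  extra <- if (n_take - length(forced) > 0L)
    rest[sample.int(length(rest), n_take - length(forced))] else integer(0)
  idx <- sample(c(forced, extra))  # shuffle display order
  opts <- pool[idx, , drop = FALSE]
  structure(list(current = current, goal = goal, options = opts,
                 optimal_flags = optimal_options(opts, goal)),
            class = "option_set")
}

#' Sample start and destination for a path
#'
#' Draws an ordered pair of distinct locations uniformly at random.
#'
#' @param space An `abstract_space`.
#' @return List with integer vectors `start` and `goal`.
#' @export
sample_endpoints <- function(space) {
  locs <- all_locations(space)
  idx <- sample.int(nrow(locs), 2L)
  list(start = locs[idx[1L], ], goal = locs[idx[2L], ])
}

# "x;y;z" serialization used in the behavioral CSV
format_location <- function(x) paste(as.integer(x), collapse = ";")

parse_location <- function(s) as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
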