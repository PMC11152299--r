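# The 5x5 Taxi grid world (Taxi-v3 dynamics), precomputed as full
# transition tables so both the routing agent and the Q-learning baseline
# run against identical dynamics.
#
# State encoding (0-based internally, returned 1-based):
#   s = ((row * 5 + col) * 5 + passenger) * 4 + destination
# passenger in 0..4 (0=R, 1=G, 2=Y, 3=B, 4=in taxi), destination in 0..3.
# A state is terminal when the passenger sits at the destination landmark.

.env_cache <- new.env(parent = emptyenv())

.taxi_landmarks <- matrix(c(0, 0, 0, 4, 4, 0, 4, 3), ncol = 2, byrow = TRUE,
                          dimnames = list(c("R", "G", "Y", "B"), c("row", "col")))

# walls east of these (row, col) cells
.taxi_walls <- matrix(c(0, 1, 1, 1, 3, 0, 3, 2, 4, 0, 4, 2),
                      ncol = 2, byrow = TRUE)

.taxi_wall_east <- function(row, col) {
  any(.taxi_walls[, 1] == row & .taxi_walls[, 2] == col)
}

#' Encode / decode Taxi states
#'
#' The integer encoding of the 500 Taxi states:
#' `s = ((row * 5 + col) * 5 + passenger) * 4 + destination + 1`, with
#' `row`, `col` in 0..4, `passenger` in 0..4 (4 = in the taxi) and
#' `destination` in 0..3 (landmarks R, G, Y, B). States are 1-based.
#'
#' @param row,col Taxi cell (0-based).
#' @param passenger Passenger location code, 0..4.
#' @param destination Destination landmark code, 0..3.
#' @return `taxi_encode` returns the 1-based state index; `taxi_decode`
#'   returns a tibble with columns `row`, `col`, `passenger`,
#'   `destination`.
#' @export
taxi_encode <- function(row, col, passenger, destination) {
  as.integer(((row * 5 + col) * 5 + passenger) * 4 + destination + 1L)
}

#' @param state 1-based state index (vectorised).
#' @rdname taxi_encode
#' @export
taxi_decode <- function(state) {
  s <- as.integer(state) - 1L
  destination <- s %% 4L
  s <- s %/% 4L
  passenger <- s %% 5L
  s <- s %/% 5L
  tibble::tibble(row = s %/% 5L, col = s %% 5L,
                 passenger = passenger, destination = destination)
}

#' The Taxi environment
#'
#' Builds the complete transition tables of the 5x5 Taxi grid world: 500
#' encodable states (25 taxi cells x 5 passenger locations x 4
#' destinations), of which 400 are non-terminal, six actions (south,
#' north, east, west, pickup, dropoff), the standard wall layout, and the
#' two reward channels: the sparse training signal (+20 on a successful
#' dropoff at the destination, 0 otherwise) and the dense evaluation
#' accounting (-1 per step, -10 for an illegal pickup/dropoff, +20 on
#' success) which is never fed to the learning agent.
#'
#' @return A list of class `taxi_env` with `n_states`, `n_actions`,
#'   transition matrix `nxt` (1-based), `reward_sparse`, `reward_dense`,
#'   `done`, `illegal` (all 500 x 6), `is_terminal`, and `start_states`
#'   (the 400 non-terminal states). The tables are deterministic and
#'   cached after the first build.
#' @export
taxi_env <- function() {
  if (!is.null(.env_cache$taxi)) return(.env_cache$taxi)
  n <- 500L
  nxt <- matrix(0L, n, 6L)
  r_sparse <- matrix(0, n, 6L)
  r_dense <- matrix(-1, n, 6L)
  done <- matrix(FALSE, n, 6L)
  illegal <- matrix(FALSE, n, 6L)
  lm <- .taxi_landmarks
  at_landmark <- function(row, col) {
    hit <- which(lm[, 1] == row & lm[, 2] == col)
    if (length(hit)) hit[1] - 1L else -1L
  }
  for (s in 1:n) {
    s0 <- s - 1L
    d_dest <- s0 %% 4L; s0 <- s0 %/% 4L
    d_pass <- s0 %% 5L; s0 <- s0 %/% 5L
    d_col <- s0 %% 5L; d_row <- s0 %/% 5L
    for (a in 1:6) {
      row <- d_row; col <- d_col; pass <- d_pass; dest <- d_dest
      if (a == 1L && row < 4L) row <- row + 1L
      if (a == 2L && row > 0L) row <- row - 1L
      if (a == 3L && col < 4L && !.taxi_wall_east(row, col)) col <- col + 1L
      if (a == 4L && col > 0L && !.taxi_wall_east(row, col - 1L)) col <- col - 1L
      if (a == 5L) {  # pickup
        if (pass < 4L && at_landmark(row, col) == pass) {
          pass <- 4L
        } else {
          illegal[s, a] <- TRUE
          r_dense[s, a] <- -10
        }
      }
      if (a == 6L) {  # dropoff
        here <- at_landmark(row, col)
        if (pass == 4L && here == dest) {
          pass <- dest
          r_sparse[s, a] <- 20
          r_dense[s, a] <- 20
        } else if (pass == 4L && here >= 0L) {
          pass <- here
        } else {
          illegal[s, a] <- TRUE
          r_dense[s, a] <- -10
        }
      }
      nxt[s, a] <- taxi_encode(row, col, pass, dest)
      done[s, a] <- pass == dest
    }
  }
  dd <- taxi_decode(1:n)
  terminal <- dd$passenger == dd$destination
  env <- structure(list(n_states = n, n_actions = 6L, nxt = nxt,
                        reward_sparse = r_sparse, reward_dense = r_dense,
                        done = done, illegal = illegal, is_terminal = terminal,
                        start_states = which(!terminal)),
                   class = "taxi_env")
  .env_cache$taxi <- env
  env
}

#' Reset the Taxi environment
#'
#' Draws a uniformly random non-terminal state (random taxi cell, random
#' destination, random passenger location excluding
#' passenger-at-destination starts). Uses R's RNG, so runs are reproducible
#' under `set.seed()`.
#'
#' @param env A [taxi_env()].
#' @return A 1-based state index.
#' @export
taxi_reset <- function(env) {
  env$start_states[sample.int(length(env$start_states), 1L)]
}

#' Step the Taxi environment
#'
#' @param env A [taxi_env()].
#' @param state Current 1-based state.
#' @param action Action 1..6 (south, north, east, west, pickup, dropoff).
#' @return List with `state` (next state), `reward` (sparse training
#'   signal: +20 on success, else 0), `done`, `illegal` (whether the step
#'   was an illegal pickup/dropoff attempt) and `dense` (the evaluation
#'   reward of the step).
#' @export
taxi_step <- function(env, state, action) {
  state <- as.integer(state); action <- as.integer(action)
  if (state < 1L || state > env$n_states) stop("malformed state")
  if (action < 1L || action > 6L) stop("action must be in 1..6")
  list(state = env$nxt[state, action],
       reward = env$reward_sparse[state, action],
       done = env$done[state, action],
       illegal = env$illegal[state, action],
       dense = env$reward_dense[state, action])
}

#' The 25-cell location-only grid of the Taxi world
#'
#' The taxi's location graph alone (cells numbered row-major 0..24,
#' returned 1-based), with the four movement actions and the same wall
#' layout. Used for latent-learning demonstrations: a random walk on this
#' graph suffices to recover the grid adjacency in the first-order
#' weights.
#'
#' @return A list of class `taxi_locations_env` with `n_states = 25`,
#'   `n_actions = 4`, transition matrix `nxt`, and the true directed
#'   `adjacency` matrix of the grid.
#' @export
taxi_locations_env <- function() {
  n <- 25L
  nxt <- matrix(0L, n, 4L)
  for (s in 1:n) {
    row <- (s - 1L) %/% 5L; col <- (s - 1L) %% 5L
    for (a in 1:4) {
      r2 <- row; c2 <- col
      if (a == 1L && row < 4L) r2 <- row + 1L
      if (a == 2L && row > 0L) r2 <- row - 1L
      if (a == 3L && col < 4L && !.taxi_wall_east(row, col)) c2 <- col + 1L
      if (a == 4L && col > 0L && !.taxi_wall_east(row, col - 1L)) c2 <- col - 1L
      nxt[s, a] <- r2 * 5L + c2 + 1L
    }
  }
  adj <- matrix(0L, n, n)
  for (s in 1:n) for (a in 1:4) if (nxt[s, a] != s) adj[s, nxt[s, a]] <- 1L
  structure(list(n_states = n, n_actions = 4L, nxt = nxt, adjacency = adj),
            class = "taxi_locations_env")
}
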