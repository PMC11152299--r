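# Independent oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Brute-force rectified-network solver: enumerate every subset of edges as
# the candidate conducting set, solve the resulting linear resistor network
# with sources pinned, and keep a subset consistent with the diode sign
# conditions (conducting edges need a nonnegative drop, blocked edges a
# nonpositive one). Returns the node potentials.
oracle_rectified <- function(W, ground, sources, vsrc = 1, tol = 1e-9) {
  n <- nrow(W)
  edges <- which(W > 0, arr.ind = TRUE)
  E <- nrow(edges)
  stopifnot(E <= 8)
  solve_subset <- function(act) {
    # resistor graph over the active edges only
    A <- matrix(0, n, n)
    for (e in which(act)) {
      i <- edges[e, 1]; j <- edges[e, 2]
      A[i, j] <- A[i, j] + W[i, j]
      A[j, i] <- A[j, i] + W[i, j]
    }
    # nodes connected to a source through active edges
    reach <- rep(FALSE, n)
    reach[sources] <- TRUE
    repeat {
      grow <- reach | (colSums(A[reach, , drop = FALSE] > 0) > 0)
      if (all(grow == reach)) break
      reach <- grow
    }
    V <- numeric(n)
    V[sources] <- vsrc
    unk <- setdiff(which(reach), sources)
    if (length(unk)) {
      L <- diag(rowSums(A)[unk] + ground[unk], nrow = length(unk)) -
        A[unk, unk, drop = FALSE]
      b <- A[unk, sources, drop = FALSE] %*% rep(vsrc, length(sources))
      sol <- tryCatch(solve(L, b), error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      V[unk] <- sol
    }
    V
  }
  for (mask in 0:(2^E - 1)) {
    act <- bitwAnd(mask, 2^(seq_len(E) - 1)) > 0
    V <- solve_subset(act)
    if (is.null(V)) next
    dv <- V[edges[, 1]] - V[edges[, 2]]
    if (all(dv[act] >= -tol) && all(dv[!act] <= tol)) return(V)
  }
  stop("no consistent active set found")
}

# Classical nodal analysis for a bidirectional (symmetric) resistor
# network with pinned sources; no rectification.
oracle_bidirectional <- function(Wsym, ground, sources, vsrc = 1) {
  n <- nrow(Wsym)
  reach <- rep(FALSE, n)
  reach[sources] <- TRUE
  repeat {
    grow <- reach | (colSums(Wsym[reach, , drop = FALSE] > 0) > 0)
    if (all(grow == reach)) break
    reach <- grow
  }
  V <- numeric(n)
  V[sources] <- vsrc
  unk <- setdiff(which(reach), sources)
  if (length(unk)) {
    L <- diag(rowSums(Wsym)[unk] + ground[unk], nrow = length(unk)) -
      Wsym[unk, unk, drop = FALSE]
    b <- Wsym[unk, sources, drop = FALSE] %*% rep(vsrc, length(sources))
    V[unk] <- solve(L, b)
  }
  V
}

# random rectified test network: n nodes, E directed edges, some grounds
random_network <- function(n, E, n_ground = 1L) {
  pairs <- which(diag(n) == 0, arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), E), , drop = FALSE]
  W <- matrix(0, n, n)
  W[pick] <- runif(E, 0.2, 2)
  g <- numeric(n)
  g[sample.int(n, n_ground)] <- runif(n_ground, 0.5, 2)
  list(W = W, ground = g)
}

# Independent Taxi dynamics, derived from the printed map rather than a
# wall table, with its own decode/encode arithmetic.
.oracle_taxi_map <- c(
  "+---------+",
  "|R: | : :G|",
  "| : | : : |",
  "| : : : : |",
  "| | : | : |",
  "|Y| : |B: |",
  "+---------+")

oracle_taxi_step <- function(state, action) {
  s <- state - 1L
  dest <- s %% 4L; s <- s %/% 4L
  pass <- s %% 5L; s <- s %/% 5L
  col <- s %% 5L; row <- s %/% 5L
  landmarks <- list(c(0L, 0L), c(0L, 4L), c(4L, 0L), c(4L, 3L))
  can_east <- function(r, c) {
    substr(.oracle_taxi_map[r + 2L], 2L * c + 3L, 2L * c + 3L) == ":"
  }
  reward <- -1; illegal <- FALSE
  if (action == 1L) row <- min(row + 1L, 4L)
  else if (action == 2L) row <- max(row - 1L, 0L)
  else if (action == 3L) { if (col < 4L && can_east(row, col)) col <- col + 1L }
  else if (action == 4L) { if (col > 0L && can_east(row, col - 1L)) col <- col - 1L }
  else if (action == 5L) {
    if (pass < 4L && all(landmarks[[pass + 1L]] == c(row, col))) pass <- 4L
    else { reward <- -10; illegal <- TRUE }
  } else if (action == 6L) {
    here <- which(vapply(landmarks, function(l) all(l == c(row, col)), TRUE))
    if (pass == 4L && length(here) && here - 1L == dest) {
      pass <- dest; reward <- 20
    } else if (pass == 4L && length(here)) {
      pass <- here - 1L
    } else { reward <- -10; illegal <- TRUE }
  }
  list(state = ((row * 5L + col) * 5L + pass) * 4L + dest + 1L,
       reward = reward, illegal = illegal, done = pass == dest)
}

# BFS shortest-path distances on an undirected adjacency matrix
oracle_bfs_dist <- function(A, from) {
  n <- nrow(A)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- setdiff(which(colSums(A[frontier, , drop = FALSE] > 0) > 0),
                   which(!is.na(dist)))
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# random-tree generator and subgoal-chain walker shared by the
# shortest-path property and acceptance tests
.random_tree <- function(n) {
  A <- matrix(0, n, n)
  perm <- sample.int(n)
  for (i in 2:n) {
    j <- perm[sample.int(i - 1, 1)]
    A[perm[i], j] <- A[j, perm[i]] <- 1
  }
  A
}

.subgoal_chain_length <- function(a, start, goal) {
  s <- start
  hops <- 0L
  repeat {
    a$state <- s
    dynroute:::.agent_solve(a)
    s <- select_subgoal(a, s)
    hops <- hops + 1L
    if (s == goal || hops > a$n) break
  }
  if (s == goal) hops else NA_integer_
}

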