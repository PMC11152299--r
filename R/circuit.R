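# Rectified resistive state network and its nodal-analysis solver.
#
# A state node is a Kenyon-cell-like unit; the directed conductance w[i,j]
# plays the role of a rectifying gap junction from axon i to axon j. The
# implicit ground node sits at potential 0 and is never a state.

#' Construct a rectified resistive state network
#'
#' The agent's world model: a directed graph of nonnegative conductances
#' between state nodes, plus a per-node conductance to an implicit ground
#' node held at potential 0. Edge `(i, j)` behaves like a resistor in series
#' with an ideal diode: it carries current `w[i,j] * (V_i - V_j)` only while
#' `V_i > V_j`, and nothing otherwise, so `w[i,j]` and `w[j,i]` are
#' independent quantities.
#'
#' @param conductance An `n x n` numeric matrix of nonnegative directed
#'   conductances; the diagonal must be zero (no self-loops).
#' @param ground Length-`n` numeric vector of nonnegative conductances to
#'   ground. Defaults to all zero.
#' @return An object of class `resistive_network` with elements
#'   `conductance`, `ground` and `n_nodes`.
#' @examples
#' W <- matrix(0, 2, 2); W[1, 2] <- 2
#' net <- resistive_network(W, ground = c(0, 2))
#' solve_circuit(net, sources = 1)$potentials
#' @export
resistive_network <- function(conductance, ground = NULL) {
  conductance <- as.matrix(conductance)
  n <- nrow(conductance)
  stopifnot(ncol(conductance) == n, n >= 1)
  if (any(conductance < 0)) stop("conductances must be nonnegative")
  if (any(diag(conductance) != 0)) stop("self-loop conductances are not allowed")
  if (is.null(ground)) ground <- numeric(n)
  ground <- as.numeric(ground)
  stopifnot(length(ground) == n)
  if (any(ground < 0)) stop("ground conductances must be nonnegative")
  structure(list(conductance = conductance, ground = ground, n_nodes = n),
            class = "resistive_network")
}

#' @export
print.resistive_network <- function(x, ...) {
  cat("<resistive_network> ", x$n_nodes, " nodes, ",
      sum(x$conductance > 0), " directed edges, ",
      sum(x$ground > 0), " grounded nodes\n", sep = "")
  invisible(x)
}

#' Solve node potentials and rectified currents by nodal analysis
#'
#' Pins each source node at `source_potential` (the one-hot active state, or
#' a set of simultaneously active state nodes), holds the implicit ground
#' node at 0, and solves Kirchhoff's current law for the remaining
#' potentials. Because each edge conducts in one direction only, the set of
#' conducting edges depends on the potentials it produces; the solver
#' iterates an active set (solve the linear system for the currently
#' conducting edges, then reclassify every edge by the sign of its potential
#' drop) to a self-consistent fixed point. Numerical potential ties are
#' classified as non-conducting.
#'
#' Nodes not connected to any source carry no current and are reported at
#' potential 0. If no grounded node is reachable from the sources, no
#' current can flow: every reachable node floats at `source_potential`.
#'
#' @param network A [resistive_network].
#' @param sources Integer vector (1-based) of nodes pinned to
#'   `source_potential`; must be non-empty.
#' @param source_potential Source potential, default 1. Only relative
#'   magnitudes of currents and potentials matter to the agent.
#' @param tol Convergence tolerance on the potential change between
#'   active-set iterations.
#' @param max_iter Active-set iteration cap; past 40 iterations the edge
#'   classification uses damped potentials to break cycling.
#' @return A `circuit_solution`: list with `potentials` (length n, in
#'   `[0, source_potential]`), `edge_current` and `edge_power` (n x n,
#'   nonnegative), `ground_current` (length n), `converged`, `iterations`,
#'   and the `sources` used.
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- 1; W[2, 3] <- 1
#' sol <- solve_circuit(resistive_network(W, c(0, 0, 1)), sources = 1)
#' sol$potentials  # 1, 2/3, 1/3
#' @export
solve_circuit <- function(network, sources, source_potential = 1,
                          tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(network, "resistive_network"))
  sources <- as.integer(sources)
  if (length(sources) == 0) stop("at least one source node is required")
  if (any(sources < 1 | sources > network$n_nodes)) stop("source index out of range")
  stopifnot(source_potential > 0)
  raw <- .solve_rectified_cpp(network$conductance, network$ground, sources,
                              source_potential, tol, as.integer(max_iter))
  V <- raw$potentials
  drop <- outer(V, V, "-")
  drop[drop < 0] <- 0
  I <- network$conductance * drop
  structure(list(
    potentials = V,
    edge_current = I,
    edge_power = I * drop,
    ground_current = network$ground * V,
    converged = raw$converged,
    iterations = raw$iterations,
    sources = sources,
    source_potential = source_potential
  ), class = "circuit_solution")
}

#' @export
print.circuit_solution <- function(x, ...) {
  cat("<circuit_solution> ", length(x$potentials), " nodes; sources {",
      paste(x$sources, collapse = ", "), "}; total ground current ",
      format(sum(x$ground_current), digits = 4),
      if (!x$converged) "; NOT converged" else "", "\n", sep = "")
  invisible(x)
}

#' Power dissipated on one directed edge
#'
#' `P[i,j] = I[i,j] * (V_i - V_j)`, zero whenever the edge is blocked
#' (`V_i <= V_j`). The edge with maximal power out of the active state node
#' is the agent's subgoal edge.
#'
#' @param solution A `circuit_solution`.
#' @param i,j Node indices (1-based).
#' @export
edge_power <- function(solution, i, j) {
  stopifnot(inherits(solution, "circuit_solution"))
  n <- length(solution$potentials)
  i <- as.integer(i); j <- as.integer(j)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) stop("node index out of range")
  solution$edge_power[i, j]
}

#' Tidy a circuit solution into an edge table
#'
#' @param x A `circuit_solution`.
#' @param ... Unused.
#' @return A tibble with one row per edge carrying current: `from`, `to`,
#'   `current`, `power`, `drop`.
#' @method tidy circuit_solution
#' @export
tidy.circuit_solution <- function(x, ...) {
  idx <- which(x$edge_current > 0, arr.ind = TRUE)
  tibble::tibble(
    from = as.integer(idx[, 1]),
    to = as.integer(idx[, 2]),
    current = x$edge_current[idx],
    power = x$edge_power[idx],
    drop = x$potentials[idx[, 1]] - x$potentials[idx[, 2]]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' Export / import a network as a plain-text edge list
#'
#' Tab-separated, one line per edge: `from  to  conductance`, with ground
#' conductances written as lines whose target token is `GND`. Rows are
#' ordered by ascending source then target index, so exports are
#' deterministic.
#'
#' @param network A [resistive_network].
#' @param path File path.
#' @return `write_edgelist` returns `path` invisibly; `read_edgelist`
#'   returns a [resistive_network].
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "resistive_network"))
  idx <- which(network$conductance > 0, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  lines <- c(
    sprintf("%d\t%d\t%.17g", idx[, 1], idx[, 2], network$conductance[idx]),
    sprintf("%d\tGND\t%.17g", which(network$ground > 0),
            network$ground[network$ground > 0])
  )
  writeLines(c(sprintf("# nodes\t%d", network$n_nodes), lines), path)
  invisible(path)
}

#' @rdname write_edgelist
#' @param n_nodes Node count override; by default read from the file header.
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  header <- grepl("^#", lines)
  if (is.null(n_nodes)) {
    h <- lines[header][1]
    n_nodes <- as.integer(strsplit(h, "\t")[[1]][2])
  }
  lines <- lines[!header & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  W <- matrix(0, n_nodes, n_nodes)
  g <- numeric(n_nodes)
  for (p in parts) {
    i <- as.integer(p[[1]])
    w <- as.numeric(p[[3]])
    if (p[[2]] == "GND") g[i] <- w else W[i, as.integer(p[[2]])] <- w
  }
  resistive_network(W, g)
}
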