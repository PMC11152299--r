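# Procedurally generated Voronoi navigation world.
#
# Locations come from Poisson-disk (Bridson) sampling of the unit square;
# neighbouring locations are joined by the Delaunay triangulation
# (Bowyer-Watson); passable edges are the duals of removed Voronoi walls —
# a uniform random spanning tree of the Delaunay graph guarantees
# connectivity, and each remaining wall is then removed independently.

# Bridson's Poisson-disk sampling in [0,1]^2: no two points closer than r.
.poisson_disk <- function(r, k = 30L) {
  cell <- r / sqrt(2)
  gdim <- as.integer(ceiling(1 / cell))
  grid <- matrix(0L, gdim, gdim)
  pts <- matrix(NA_real_, 4096L, 2L)
  n_pts <- 0L
  gidx <- function(p) pmin(pmax(as.integer(p %/% cell) + 1L, 1L), gdim)
  add_pt <- function(p) {
    n_pts <<- n_pts + 1L
    if (n_pts > nrow(pts)) pts <<- rbind(pts, matrix(NA_real_, nrow(pts), 2L))
    pts[n_pts, ] <<- p
    g <- gidx(p)
    grid[g[1], g[2]] <<- n_pts
    n_pts
  }
  ok <- function(p) {
    g <- gidx(p)
    for (i in max(1L, g[1] - 2L):min(gdim, g[1] + 2L)) {
      for (j in max(1L, g[2] - 2L):min(gdim, g[2] + 2L)) {
        q <- grid[i, j]
        if (q > 0L && sum((pts[q, ] - p)^2) < r * r) return(FALSE)
      }
    }
    TRUE
  }
  active <- add_pt(runif(2))
  while (length(active)) {
    pick <- sample.int(length(active), 1L)
    base <- pts[active[pick], ]
    placed <- FALSE
    for (t in seq_len(k)) {
      rad <- r * sqrt(runif(1, 1, 4))
      ang <- runif(1, 0, 2 * pi)
      p <- base + rad * c(cos(ang), sin(ang))
      if (all(p >= 0) && all(p <= 1) && ok(p)) {
        active <- c(active, add_pt(p))
        placed <- TRUE
        break
      }
    }
    if (!placed) active <- active[-pick]
  }
  pts[seq_len(n_pts), , drop = FALSE]
}

# squared circumcircle test: is p strictly inside the circumcircle of
# triangle (a, b, c)? (a, b, c counter-clockwise)
.in_circumcircle <- function(ax, ay, bx, by, cx, cy, px, py) {
  ax <- ax - px; ay <- ay - py
  bx <- bx - px; by <- by - py
  cx <- cx - px; cy <- cy - py
  det <- (ax * ax + ay * ay) * (bx * cy - cx * by) -
         (bx * bx + by * by) * (ax * cy - cx * ay) +
         (cx * cx + cy * cy) * (ax * by - bx * ay)
  det > 0
}

# Bowyer-Watson incremental Delaunay triangulation. Returns the unique
# undirected edges as a 2-column matrix of point indices.
.delaunay_edges <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  # super-triangle enclosing the unit square by a wide margin
  P <- rbind(pts, c(-50, -50), c(50, -50), c(0.5, 100))
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tri <- list(c(s1, s2, s3))
  ccw <- function(t) {
    a <- P[t[1], ]; b <- P[t[2], ]; c_ <- P[t[3], ]
    if ((b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]) < 0)
      t[c(1, 3, 2)] else t
  }
  tri[[1]] <- ccw(tri[[1]])
  for (ip in seq_len(n)) {
    px <- P[ip, 1]; py <- P[ip, 2]
    bad <- vapply(tri, function(t) {
      .in_circumcircle(P[t[1], 1], P[t[1], 2], P[t[2], 1], P[t[2], 2],
                       P[t[3], 1], P[t[3], 2], px, py)
    }, logical(1))
    hole <- tri[bad]
    tri <- tri[!bad]
    # boundary = edges of the hole appearing exactly once
    edges <- do.call(rbind, lapply(hole, function(t) {
      rbind(t[c(1, 2)], t[c(2, 3)], t[c(3, 1)])
    }))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- key %in% names(which(table(key) == 1L))
    for (e in which(once)) {
      tri[[length(tri) + 1L]] <- ccw(c(edges[e, 1], edges[e, 2], ip))
    }
  }
  keep <- vapply(tri, function(t) all(t <= n), logical(1))
  tri <- tri[keep]
  ed <- do.call(rbind, lapply(tri, function(t) {
    rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(3, 1)]))
  }))
  unique(ed)
}

# Wilson's algorithm: uniform spanning tree of an undirected graph given as
# an adjacency list. Returns a 2-column edge matrix.
.uniform_spanning_tree <- function(nbrs) {
  n <- length(nbrs)
  in_tree <- logical(n)
  root <- sample.int(n, 1L)
  in_tree[root] <- TRUE
  nxt <- integer(n)
  edges <- matrix(0L, n - 1L, 2L)
  n_e <- 0L
  for (v in sample.int(n)) {
    if (in_tree[v]) next
    u <- v
    while (!in_tree[u]) {         # loop-erased random walk
      nb <- nbrs[[u]]
      nxt[u] <- nb[sample.int(length(nb), 1L)]
      u <- nxt[u]
    }
    u <- v
    while (!in_tree[u]) {
      in_tree[u] <- TRUE
      n_e <- n_e + 1L
      edges[n_e, ] <- c(u, nxt[u])
      u <- nxt[u]
    }
  }
  edges[seq_len(n_e), , drop = FALSE]
}

#' Generate a Voronoi navigation world
#'
#' Samples `n_locations` points in the unit square by Poisson-disk
#' sampling (which keeps locations from being too close together),
#' triangulates them (Delaunay), and opens a passable subset of the dual
#' Voronoi walls: the walls dual to a uniform random spanning tree of the
#' Delaunay graph are always removed (guaranteeing a connected world), and
#' every other wall is removed independently with probability
#' `extra_open_prob`. The agent moves between locations along passable
#' edges; action `k` at a location leads to the `k`-th entry of its
#' neighbour list (stored in ascending index order).
#'
#' Randomness comes from R's RNG: call `set.seed()` first for a
#' reproducible world.
#'
#' @param n_locations Number of locations (states), default 150.
#' @param extra_open_prob Probability of removing each wall not already
#'   opened by the spanning tree, default 0.3.
#' @param max_retries Poisson-disk radius is auto-tuned; number of radius
#'   shrinkages allowed before giving up.
#' @return A list of class `voronoi_world`: `points` (tibble `index, x,
#'   y`), `delaunay` and `passable` (2-column undirected edge matrices),
#'   `neighbors` (list of sorted neighbour vectors), `n_states`,
#'   `n_actions` (maximum degree), `degree`.
#' @export
voronoi_world <- function(n_locations = 150L, extra_open_prob = 0.3,
                          max_retries = 20L) {
  stopifnot(n_locations >= 2L)
  r <- sqrt(0.55 / n_locations)
  pts <- NULL
  for (try in seq_len(max_retries)) {
    cand <- .poisson_disk(r)
    if (nrow(cand) >= n_locations) {
      pts <- cand[seq_len(n_locations), , drop = FALSE]
      break
    }
    r <- r * 0.92
  }
  if (is.null(pts)) stop("Poisson-disk sampling failed to reach n_locations")
  del <- .delaunay_edges(pts)
  nbrs <- lapply(seq_len(n_locations), function(i) {
    sort(unique(c(del[del[, 1] == i, 2], del[del[, 2] == i, 1])))
  })
  tree <- .uniform_spanning_tree(nbrs)
  tree <- cbind(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
  key_del <- paste(del[, 1], del[, 2])
  key_tree <- paste(tree[, 1], tree[, 2])
  rest <- del[!(key_del %in% key_tree), , drop = FALSE]
  open_extra <- rest[runif(nrow(rest)) < extra_open_prob, , drop = FALSE]
  passable <- rbind(tree, open_extra)
  passable <- passable[order(passable[, 1], passable[, 2]), , drop = FALSE]
  nb_pass <- lapply(seq_len(n_locations), function(i) {
    sort(unique(c(passable[passable[, 1] == i, 2],
                  passable[passable[, 2] == i, 1])))
  })
  deg <- lengths(nb_pass)
  structure(list(
    points = tibble::tibble(index = seq_len(n_locations),
                            x = pts[, 1], y = pts[, 2]),
    delaunay = del, passable = passable, neighbors = nb_pass,
    n_states = as.integer(n_locations), n_actions = as.integer(max(deg)),
    degree = deg
  ), class = "voronoi_world")
}

#' @export
print.voronoi_world <- function(x, ...) {
  cat("<voronoi_world> ", x$n_states, " locations, ",
      nrow(x$passable), " passable edges (of ", nrow(x$delaunay),
      " Delaunay), max degree ", x$n_actions, "\n", sep = "")
  invisible(x)
}

#' Reset the Voronoi navigation task
#'
#' The first episode starts at a random location; later episodes start
#' where the previous one ended (the agent navigates continuously across
#' episodes). The target(s) are drawn uniformly among the other locations;
#' with `n_goals = 2` two distinct targets are drawn and the episode ends
#' at whichever is reached first.
#'
#' @param world A [voronoi_world()].
#' @param prev_state End location of the previous episode, or `NULL` for
#'   the first episode.
#' @param n_goals Number of simultaneous reward sources (1 or 2).
#' @return List with `state` and integer vector `targets`.
#' @export
voronoi_reset <- function(world, prev_state = NULL, n_goals = 1L) {
  state <- if (is.null(prev_state)) {
    sample.int(world$n_states, 1L)
  } else {
    as.integer(prev_state)
  }
  cand <- seq_len(world$n_states)[-state]
  targets <- cand[sample.int(length(cand), n_goals)]
  list(state = state, targets = targets)
}

#' Step the Voronoi navigation task
#'
#' @param world A [voronoi_world()].
#' @param state Current location.
#' @param action Action index, 1..degree(state); moves to the `action`-th
#'   stored neighbour.
#' @param targets Target location(s) of the episode.
#' @return List with `state`, sparse `reward` (+20 on reaching a target,
#'   else 0) and `done`.
#' @export
voronoi_step <- function(world, state, action, targets) {
  nb <- world$neighbors[[state]]
  if (action < 1L || action > length(nb)) {
    stop("action ", action, " not available at location ", state)
  }
  s2 <- nb[action]
  done <- s2 %in% targets
  list(state = s2, reward = if (done) 20 else 0, done = done)
}

#' Serialize a Voronoi world
#'
#' Writes `<prefix>_locations.csv` (`index,x,y`) and
#' `<prefix>_passable.tsv` (edge-list format, unit conductances standing
#' for passability, both directions).
#'
#' @param world A [voronoi_world()].
#' @param prefix File path prefix.
#' @export
write_voronoi_world <- function(world, prefix) {
  utils::write.csv(world$points, paste0(prefix, "_locations.csv"),
                   row.names = FALSE)
  W <- matrix(0, world$n_states, world$n_states)
  W[world$passable] <- 1
  W[world$passable[, c(2, 1)]] <- 1
  write_edgelist(resistive_network(W), paste0(prefix, "_passable.tsv"))
  invisible(prefix)
}
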