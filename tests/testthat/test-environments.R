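# The three benchmark environments.

test_that("taxi state space has 500 states and 400 non-terminal states", {
  env <- taxi_env()
  expect_equal(env$n_states, 500L)
  expect_equal(sum(env$is_terminal), 100L)
  expect_equal(length(env$start_states), 400L)
  # encode/decode are inverse bijections over the full space
  d <- taxi_decode(1:500)
  expect_equal(taxi_encode(d$row, d$col, d$passenger, d$destination), 1:500)
})

test_that("taxi transitions agree with the independent map-derived oracle", {
  env <- taxi_env()
  nxt_o <- matrix(0L, 500, 6)
  rew_o <- matrix(0, 500, 6)
  ill_o <- matrix(FALSE, 500, 6)
  done_o <- matrix(FALSE, 500, 6)
  for (s in 1:500) {
    for (a in 1:6) {
      o <- oracle_taxi_step(s, a)
      nxt_o[s, a] <- o$state
      rew_o[s, a] <- o$reward
      ill_o[s, a] <- o$illegal
      done_o[s, a] <- o$done
    }
  }
  expect_identical(env$nxt, nxt_o)
  expect_identical(env$reward_dense, rew_o)
  expect_identical(env$illegal, ill_o)
  expect_identical(env$done, done_o)
})

test_that("taxi walls block movement; pickup/dropoff rules are enforced", {
  env <- taxi_env()
  # wall east of (0,1): eastward move leaves the state unchanged
  s <- taxi_encode(0, 1, 0, 1)
  res <- taxi_step(env, s, 3)
  expect_equal(res$state, s)
  expect_equal(res$reward, 0)
  expect_false(res$done)
  # successful dropoff: passenger aboard, taxi at destination R=(0,0)
  s <- taxi_encode(0, 0, 4, 0)
  res <- taxi_step(env, s, 6)
  expect_equal(res$reward, 20)
  expect_true(res$done)
  expect_false(res$illegal)
  # pickup at a non-landmark cell is illegal and leaves the state alone
  s <- taxi_encode(2, 2, 0, 1)
  res <- taxi_step(env, s, 5)
  expect_equal(res$state, s)
  expect_true(res$illegal)
  expect_equal(res$reward, 0)      # sparse channel carries no penalty
  expect_equal(res$dense, -10)
  expect_error(taxi_step(env, 501, 1), "malformed")
})

test_that("taxi resets are uniform over non-terminal states and seeded", {
  env <- taxi_env()
  set.seed(10)
  draws <- replicate(3000, taxi_reset(env))
  expect_true(all(!env$is_terminal[draws]))
  d <- taxi_decode(draws)
  expect_true(all(d$passenger != d$destination | d$passenger == 4L))
  set.seed(77)
  a <- replicate(50, taxi_reset(env))
  set.seed(77)
  b <- replicate(50, taxi_reset(env))
  expect_identical(a, b)
})

test_that("location grid matches the taxi location transitions", {
  env <- taxi_env()
  loc <- taxi_locations_env()
  # movement of the full task restricted to (row, col) equals the grid env
  for (s in seq_len(25)) {
    row <- (s - 1) %/% 5; col <- (s - 1) %% 5
    full <- taxi_encode(row, col, 0, 1)
    for (a in 1:4) {
      d2 <- taxi_decode(env$nxt[full, a])
      expect_equal(loc$nxt[s, a], d2$row * 5 + d2$col + 1)
    }
  }
  expect_equal(sum(loc$adjacency), 68L)  # 34 undirected grid edges
})

test_that("delaunay triangulation satisfies the empty-circumcircle property", {
  set.seed(5)
  pts <- cbind(runif(40), runif(40))
  edges <- dynroute:::.delaunay_edges(pts)
  # rebuild triangles from mutual edges and verify no point falls inside
  # any triangle circumcircle
  nb <- lapply(seq_len(40), function(i) {
    sort(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
  })
  in_cc <- function(a, b, c, p) {
    m <- cbind(pts[c(a, b, c), 1] - pts[p, 1], pts[c(a, b, c), 2] - pts[p, 2])
    m <- cbind(m, rowSums(m^2))
    s <- sign((pts[b, 1] - pts[a, 1]) * (pts[c, 2] - pts[a, 2]) -
              (pts[b, 2] - pts[a, 2]) * (pts[c, 1] - pts[a, 1]))
    s * det(m) > 1e-12
  }
  n_tri <- 0L
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    common <- intersect(nb[[i]], nb[[j]])
    for (k in common[common > j]) {
      n_tri <- n_tri + 1L
      others <- setdiff(seq_len(40), c(i, j, k))
      expect_false(any(vapply(others, function(p) in_cc(i, j, k, p),
                              logical(1))),
                   info = paste("triangle", i, j, k))
    }
  }
  expect_gt(n_tri, 30)
})

test_that("voronoi worlds are connected delaunay subgraphs with 150 states", {
  set.seed(3)
  w <- voronoi_world(150)
  expect_equal(w$n_states, 150L)
  expect_equal(nrow(w$points), 150L)
  # every passable edge is a Delaunay edge
  key_del <- paste(w$delaunay[, 1], w$delaunay[, 2])
  key_pass <- paste(w$passable[, 1], w$passable[, 2])
  expect_true(all(key_pass %in% key_del))
  # connected (union-find via component count)
  A <- matrix(0, 150, 150)
  A[w$passable] <- 1
  A[w$passable[, c(2, 1)]] <- 1
  expect_equal(graph_components(A, threshold = 0.5), 1L)
  # Poisson-disk spacing: no two locations closer than the tuned radius
  dmin <- min(dist(cbind(w$points$x, w$points$y)))
  expect_gt(dmin, 0.02)
  # deterministic under seed
  set.seed(3)
  w2 <- voronoi_world(150)
  expect_identical(w2$points, w$points)
  expect_identical(w2$passable, w$passable)
})

test_that("voronoi actions index the sorted neighbour list, with reverses", {
  set.seed(4)
  w <- voronoi_world(60)
  for (loc in c(1, 7, 23, 60)) {
    nb <- w$neighbors[[loc]]
    expect_equal(nb, sort(nb))
    for (a in seq_along(nb)) {
      res <- voronoi_step(w, loc, a, targets = integer(0))
      expect_equal(res$state, nb[a])
      # the reverse move exists
      expect_true(loc %in% w$neighbors[[res$state]])
    }
    expect_error(voronoi_step(w, loc, length(nb) + 1L, integer(0)),
                 "not available")
  }
})

test_that("voronoi resets chain episodes and avoid the start location", {
  set.seed(6)
  w <- voronoi_world(40)
  r1 <- voronoi_reset(w)
  expect_false(r1$state %in% r1$targets)
  r2 <- voronoi_reset(w, prev_state = 17L)
  expect_equal(r2$state, 17L)
  expect_false(17L %in% r2$targets)
  r3 <- voronoi_reset(w, prev_state = 5L, n_goals = 2L)
  expect_equal(length(unique(r3$targets)), 2L)
  expect_false(5L %in% r3$targets)
  # reaching either target ends a two-goal episode
  nb <- w$neighbors[[r3$targets[1]]][1]
  res <- voronoi_step(w, nb, which(w$neighbors[[nb]] == r3$targets[1]),
                      r3$targets)
  expect_true(res$done)
  expect_equal(res$reward, 20)
})

test_that("petri dishes implement the published odour layouts", {
  aon <- petri_dish("AON")
  expect_equal(petri_perceive(aon, 0), 2L)  # AM side
  expect_equal(petri_perceive(aon, 2), 4L)  # mixture
  expect_equal(petri_perceive(aon, 4), 3L)  # OCT side
  oon <- petri_dish("OON")
  for (pos in 0:4) expect_equal(petri_perceive(oon, pos), 3L)
  expect_equal(petri_perceive(oon, 1, consumed = TRUE), 5L)
  expect_error(petri_dish("XXX"))
})

test_that("appetitive actions in a fructose dish yield the fructose state", {
  # dish AAF, perceiving AM: an appetitive-AM action lands in an AM
  # location and consumes the substrate
  set.seed(9)
  aaf <- petri_dish("AAF")
  res <- petri_step(aaf, 1L, 2L)
  expect_equal(res$state, 5L)
  expect_equal(res$reward, 1)
  # appetitive OCT in an AM-only dish never consumes
  res2 <- petri_step(aaf, 1L, 4L)
  expect_equal(res2$reward, 0)
  expect_equal(res2$state, 2L)
  # no-reinforcer dish never rewards
  oon <- petri_dish("OON")
  for (a in 1:5) expect_equal(petri_step(oon, 2L, a)$reward, 0)
})

test_that("petri positions stay in the dish and follow the gradient", {
  aof <- petri_dish("AOF")
  # appetitive AM moves left (up the AM gradient), aversive AM right
  set.seed(2)
  expect_equal(petri_step(aof, 2L, 2L)$position, 1L)
  expect_equal(petri_step(aof, 2L, 3L)$position, 3L)
  expect_equal(petri_step(aof, 2L, 4L)$position, 3L)
  expect_equal(petri_step(aof, 2L, 5L)$position, 1L)
  expect_equal(petri_step(aof, 2L, 1L)$position, 2L)
  # clipping at the ends
  expect_equal(petri_step(aof, 0L, 2L)$position, 0L)
  expect_equal(petri_step(aof, 4L, 3L)$position, 4L)
})

test_that("side counts never exceed the population", {
  set.seed(13)
  counts <- run_maggot_protocol(1, n_maggots = 10L, steps_per_dish = 15L)
  expect_equal(nrow(counts), 15L)
  expect_true(all(counts$n_am + counts$n_oct <= 10L))
  expect_true(all(counts$pref >= -1 & counts$pref <= 1))
})

test_that("naive maggots show no side preference in AON", {
  # untrained agents act uniformly; the two-odour dish is symmetric, so
  # the preference index averages to zero over seeds
  prefs <- numeric(12)
  for (s in seq_along(prefs)) {
    set.seed(500 + s)
    dish <- petri_dish("AON")
    n_am <- 0L; n_oct <- 0L
    for (m in 1:30) {
      agent <- drm_agent(5L, agent_params("maggot"), n_actions = 5L)
      pos <- 2L
      st <- petri_perceive(dish, pos)
      agent_begin_episode(agent, st)
      r <- 0
      for (t in 1:40) {
        a <- agent_step(agent, st, r, available = 1:5)
        res <- petri_step(dish, pos, a)
        pos <- res$position; st <- res$state; r <- res$reward
        if (pos <= 1L) n_am <- n_am + 1L
        if (pos >= 3L) n_oct <- n_oct + 1L
      }
    }
    prefs[s] <- (n_am - n_oct) / (30 * 40)
  }
  expect_lt(abs(mean(prefs)), 0.1)
})

test_that("voronoi worlds serialize to plain text", {
  set.seed(8)
  w <- voronoi_world(30)
  prefix <- file.path(withr::local_tempdir(), "world")
  write_voronoi_world(w, prefix)
  pts <- utils::read.csv(paste0(prefix, "_locations.csv"))
  expect_equal(nrow(pts), 30L)
  expect_equal(names(pts), c("index", "x", "y"))
  net <- read_edgelist(paste0(prefix, "_passable.tsv"))
  expect_equal(sum(net$conductance > 0), 2L * nrow(w$passable))
  expect_equal(net$conductance, t(net$conductance))  # both directions
})
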