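# Learning rules, grounding, subgoal and action selection of the routing
# agent. Arithmetic expectations use the Taxi parameter preset
# (dt = 0.02, alpha = 0.05, beta = 2, c = 400, w1max = 1).

taxi_p <- agent_params("taxi")

test_that("first-order learning follows the saturating Euler update", {
  a <- drm_agent(5, taxi_p)
  observe_transition(a, 1, 2)
  expect_equal(a$W[1, 2], 0.001)           # dt * alpha * w1max
  expect_equal(sum(a$W), 0.001)            # nothing else touched
  # fixed point at w1max
  a$W[3, 4] <- 1
  observe_transition(a, 3, 4)
  expect_equal(a$W[3, 4], 1)
  # closed-form geometric growth: w_n = w1max * (1 - (1 - dt*alpha)^n)
  a2 <- drm_agent(3, taxi_p)
  for (n in 1:500) observe_transition(a2, 1, 2)
  expect_equal(a2$W[1, 2], 1 * (1 - (1 - 0.001)^500), tolerance = 1e-12)
  # monotone and bounded
  expect_true(a2$W[1, 2] > 0 && a2$W[1, 2] < 1)
})

test_that("self-transitions leave the diagonal at zero", {
  a <- drm_agent(4, taxi_p)
  observe_transition(a, 2, 2)
  expect_equal(diag(a$W), rep(0, 4))
})

test_that("reward grounding is persistent, idempotent and cumulative", {
  a <- drm_agent(10, taxi_p)
  mark_rewarded(a, 7)
  expect_equal(a$ground[7], 1)             # w2max
  mark_rewarded(a, 7)
  expect_equal(a$ground[7], 1)
  mark_rewarded(a, 3)
  expect_equal(which(a$ground > 0), c(3L, 7L))
})

test_that("explicit targets are released when the announcement changes", {
  a <- drm_agent(12, taxi_p)
  set_explicit_target(a, 3)
  expect_equal(a$ground[3], 1)
  set_explicit_target(a, 9)
  expect_equal(a$ground[3], 0)
  expect_equal(a$ground[9], 1)
  # re-announcing the same target changes nothing
  set_explicit_target(a, 9)
  expect_equal(which(a$ground > 0), 9L)
  # two simultaneous targets both grounded
  set_explicit_target(a, c(4, 11))
  expect_equal(which(a$ground > 0), c(4L, 11L))
  expect_equal(a$ground[c(4, 11)], c(1, 1))
  # empty set releases everything announced
  set_explicit_target(a, integer(0))
  expect_equal(sum(a$ground), 0)
  # reward-grounded states are not touched by announcements
  mark_rewarded(a, 2)
  set_explicit_target(a, 5)
  set_explicit_target(a, 6)
  expect_equal(a$ground[2], 1)
})

test_that("subgoal selection takes the maximum-power edge", {
  a <- drm_agent(6, taxi_p)
  a$W[1, 2] <- 0.4; a$W[1, 5] <- 0.1
  a$V <- c(1, 0, 0.5, 0, 0, 0)   # drops: to 2: 1.0, to 5: 1.0 -> powers 0.4, 0.1
  expect_equal(select_subgoal(a, 1), 2L)
})

test_that("all-zero powers give a uniform random subgoal over n-1 nodes", {
  a <- drm_agent(5, taxi_p)
  set.seed(11)
  draws <- replicate(4000, select_subgoal(a, 3))
  expect_false(3 %in% draws)
  freq <- table(factor(draws, levels = c(1, 2, 4, 5))) / 4000
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("stochastic subgoal mode samples proportionally to power", {
  p <- agent_params("taxi", stochastic_subgoal = TRUE)
  a <- drm_agent(4, p)
  a$W[1, 2] <- 0.3; a$W[1, 3] <- 0.1
  a$V <- c(1, 0, 0, 1)
  set.seed(12)
  draws <- replicate(20000, select_subgoal(a, 1))
  expect_equal(mean(draws == 2), 0.75, tolerance = 0.02)
  expect_equal(mean(draws == 3), 0.25, tolerance = 0.05)
})

test_that("action input modes agree after normalisation", {
  a <- drm_agent(5, taxi_p, n_actions = 2L)
  a$W2[1, 3, ] <- c(0.01, 0.03)
  a$W[1, 3] <- 2
  a$V <- c(1, 0, 0.5, 0, 0)
  I_simp <- action_inputs(a, 1, 3, mode = "simplified")
  expect_equal(unname(I_simp), c(0.01, 0.03))
  I_pow <- action_inputs(a, 1, 3, mode = "single_edge_power")
  # power factor: w * drop^2 = 2 * 0.25 = 0.5
  expect_equal(unname(I_pow), c(0.005, 0.015))
  expect_equal(action_probabilities(I_simp), action_probabilities(I_pow))
})

test_that("single-edge power input is weight times current times drop", {
  # I_{i,j'} = 1.0 and V_{i,j'} = 0.5 with w2 = 0.02 gives 0.01
  a <- drm_agent(3, taxi_p, n_actions = 1L)
  a$W[1, 2] <- 2         # current = 2 * 0.5 = 1.0
  a$V <- c(1, 0.5, 0)
  a$W2[1, 2, 1] <- 0.02
  expect_equal(unname(action_inputs(a, 1, 2, mode = "single_edge_power")),
               0.01)
})

test_that("multi-edge inputs sum power-weighted contributions over edges", {
  a <- drm_agent(4, taxi_p, n_actions = 2L)
  a$W[1, 2] <- 1; a$W[1, 3] <- 2
  a$V <- c(1, 0.5, 0.75, 0)
  a$W2[1, 2, ] <- c(0.1, 0.2)
  a$W2[1, 3, ] <- c(0.4, 0.3)
  p2 <- 1 * 0.5^2; p3 <- 2 * 0.25^2
  expect_equal(unname(action_inputs(a, 1, 2, mode = "multi_edge")),
               c(0.1 * p2 + 0.4 * p3, 0.2 * p2 + 0.3 * p3))
})

test_that("action probabilities normalise, fall back to uniform, reject negatives", {
  expect_equal(action_probabilities(c(3, 1)), c(0.75, 0.25))
  expect_equal(action_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(action_probabilities(5), 1)
  expect_error(action_probabilities(c(-1, 2)), "nonnegative")
  expect_equal(sum(action_probabilities(runif(6), use_softmax = TRUE)), 1)
})

test_that("second-order plasticity increments hits and decays misses", {
  a <- drm_agent(5, taxi_p, n_actions = 3L)
  # hit: actual transition strengthens the taken action
  update_action_weights(a, 1, j_expected = 2, j_actual = 2, k = 1)
  expect_equal(a$W2[1, 2, 1], 0.01 + 0.002)   # + dt * alpha * beta
  # miss: expected edge decays by (1 - dt * alpha * c) = 0.6
  a$W2[1, 3, 2] <- 0.01
  update_action_weights(a, 1, j_expected = 3, j_actual = 4, k = 2)
  expect_equal(a$W2[1, 3, 2], 0.006)
  expect_equal(a$W2[1, 4, 2], 0.012)          # actual transition still credited
  # wall bump: no self-edge credit, miss decay still applies
  before <- a$W2[2, 2, 1]
  update_action_weights(a, 2, j_expected = 5, j_actual = 2, k = 1)
  expect_equal(a$W2[2, 2, 1], before)
  expect_equal(a$W2[2, 5, 1], 0.01 * 0.6)
})

test_that("weights stay inside their bounds under random hammering", {
  set.seed(5)
  a <- drm_agent(6, taxi_p, n_actions = 3L)
  for (t in 1:3000) {
    ij <- sample.int(6, 2)
    observe_transition(a, ij[1], ij[2])
    update_action_weights(a, ij[1], sample.int(6, 1), ij[2],
                          sample.int(3, 1))
  }
  expect_true(all(a$W >= 0 & a$W <= 1))
  expect_true(all(a$W2 >= 0))
  expect_equal(diag(a$W), rep(0, 6))
})

test_that("a naive agent acts uniformly at random", {
  set.seed(21)
  a <- drm_agent(8, taxi_p, n_actions = 4L)
  agent_begin_episode(a, 1)
  acts <- integer(2000)
  for (i in seq_along(acts)) {
    a2 <- drm_agent(8, taxi_p, n_actions = 4L)
    agent_begin_episode(a2, 1)
    acts[i] <- agent_step(a2, 1, 0)
  }
  freq <- table(factor(acts, levels = 1:4)) / length(acts)
  expect_true(all(abs(freq - 0.25) < 0.035))
})

test_that("agent_step composes learning, grounding and decision", {
  set.seed(31)
  a <- drm_agent(6, taxi_p, n_actions = 2L)
  agent_begin_episode(a, 1)
  k1 <- agent_step(a, 1, 0)
  expect_true(k1 %in% 1:2)
  sub1 <- a$last_subgoal
  agent_step(a, 2, 0)                       # transition 1 -> 2 after k1
  expect_equal(a$W[1, 2], 0.001)            # latent learning applied
  expect_equal(a$W2[1, 2, k1], 0.012)       # actual-transition credit
  if (sub1 != 2) {
    expect_equal(a$W2[1, sub1, k1], 0.006)  # missed-subgoal decay
  }
  agent_step(a, 3, reward = 1, terminal = TRUE)
  expect_equal(a$ground[3], 1)              # rewarded state grounded
  expect_true(is.null(a$last_action))
})

test_that("seeded agent runs are bit-reproducible", {
  run_once <- function() {
    set.seed(99)
    a <- drm_agent(10, taxi_p, n_actions = 3L)
    agent_begin_episode(a, 1)
    s <- 1L
    acts <- integer(200)
    for (t in 1:200) {
      k <- agent_step(a, s, reward = as.numeric(s == 7),
                      explicit_target = 7L)
      acts[t] <- k
      s <- ((s + k - 1L) %% 10L) + 1L
    }
    list(acts = acts, W = a$W, W2 = a$W2, V = a$V)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1, r2)
})

test_that("latent learning on the location grid recovers the adjacency", {
  env <- taxi_locations_env()
  set.seed(8)
  a <- drm_agent(env$n_states, taxi_p, n_actions = 4L)
  s <- 1L
  for (t in 1:150000) {
    act <- sample.int(4, 1)
    s2 <- env$nxt[s, act]
    observe_transition(a, s, s2)
    s <- s2
  }
  rec <- graph_recovery(a$W, env$adjacency, threshold_fraction = 0.5,
                        w1max = 1)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
})

test_that("greedy subgoal chains follow shortest paths on learned trees", {
  # uniformly learned tree graphs, one grounded goal: the route of least
  # resistance is the unique simple path, so the subgoal sequence from
  # every start must reach the goal in exactly the breadth-first distance
  for (seed in 1:12) {
    set.seed(300 + seed)
    n <- sample(8:25, 1)
    A <- .random_tree(n)
    a <- drm_agent(n, agent_params("taxi"))
    a$W[] <- A * 0.8
    goal <- sample.int(n, 1)
    mark_rewarded(a, goal)
    dist <- oracle_bfs_dist(A, goal)
    for (start in seq_len(n)[-goal]) {
      expect_equal(.subgoal_chain_length(a, start, goal), dist[start],
                   info = paste("seed", seed, "start", start))
    }
  }
})

test_that("subgoal chains on loopy graphs reach the goal near-optimally", {
  # with cycles, current follows the route of least effective resistance,
  # which parallel branches can make one hop longer than the BFS
  # distance; the chain must always reach the goal and never wander
  for (seed in 1:8) {
    set.seed(330 + seed)
    n <- sample(10:25, 1)
    A <- .random_tree(n)
    for (e in 1:3) {
      ij <- sample.int(n, 2)
      A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1
    }
    diag(A) <- 0
    a <- drm_agent(n, agent_params("taxi"))
    a$W[] <- A * 0.8
    goal <- sample.int(n, 1)
    mark_rewarded(a, goal)
    dist <- oracle_bfs_dist(A, goal)
    for (start in seq_len(n)[-goal]) {
      hops <- .subgoal_chain_length(a, start, goal)
      expect_false(is.na(hops), info = paste("seed", seed, "start", start))
      expect_gte(hops, dist[start])
      expect_lte(hops, dist[start] + 2L)
    }
  }
})

test_that("trained location agent picks grid-optimal subgoals (cell 16 to 20)", {
  env <- taxi_locations_env()
  set.seed(14)
  a <- drm_agent(25, taxi_p, n_actions = 4L)
  s <- 1L
  for (t in 1:150000) {
    act <- sample.int(4, 1)
    s2 <- env$nxt[s, act]
    observe_transition(a, s, s2)
    s <- s2
  }
  # goal at published cell 20 (R index 21), current state cell 16 (17)
  mark_rewarded(a, 21)
  a$state <- 17L
  dynroute:::.agent_solve(a)
  j <- select_subgoal(a, 17L)
  A <- (env$adjacency + t(env$adjacency)) > 0
  dist <- oracle_bfs_dist(A, 21L)
  expect_true(A[17L, j])
  expect_equal(dist[j], dist[17L] - 1L)    # subgoal lies on a shortest path
})

test_that("agent checkpoints round-trip through plain text", {
  set.seed(44)
  a <- drm_agent(8, taxi_p, n_actions = 3L)
  for (t in 1:50) {
    ij <- sample.int(8, 2)
    observe_transition(a, ij[1], ij[2])
    update_action_weights(a, ij[1], sample.int(8, 1), ij[2], sample.int(3, 1))
  }
  mark_rewarded(a, 5)
  prefix <- file.path(withr::local_tempdir(), "ckpt")
  write_agent(a, prefix)
  b <- read_agent(prefix)
  expect_equal(b$W, a$W)
  expect_equal(b$W2, a$W2)
  expect_equal(b$ground, a$ground)
  expect_equal(b$params$alpha, a$params$alpha)
})

test_that("unknown parameters are rejected", {
  expect_error(agent_params("taxi", alpha = 0.1, nonsense = 2), "unknown")
  expect_error(drm_agent(5, list(alpha = 1)), "agent_params")
})
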