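# Tabular Q-learning baseline, run under the identical sparse-reward
# configuration as the routing agent for the comparison figures.
#
# The episode loop is compiled (see src/solver.cpp) because sparse-reward
# episodes can run to a 100000-step cap; the single-step update and the
# epsilon-greedy rule are also exposed as plain R functions for testing.

#' Create a Q table
#'
#' @param n_states,n_actions Table dimensions.
#' @param init Initial action value, default 0.
#' @return An `n_states x n_actions` numeric matrix.
#' @export
q_table <- function(n_states, n_actions, init = 0) {
  matrix(init, n_states, n_actions)
}

#' One tabular Q-learning backup
#'
#' `Q(s,a) <- Q(s,a) + lr * (r + gamma * max_a' Q(s',a') * (1 - done) - Q(s,a))`.
#'
#' @param Q Q table (matrix); returned updated (value semantics).
#' @param s,a 1-based state and action of the transition.
#' @param r Reward received.
#' @param s_next Next state.
#' @param done Whether the transition was terminal (no bootstrap).
#' @param lr Learning rate, default 0.1.
#' @param gamma Discount factor, default 0.99.
#' @return The updated Q table.
#' @export
q_update <- function(Q, s, a, r, s_next, done, lr = 0.1, gamma = 0.99) {
  target <- r + if (done) 0 else gamma * max(Q[s_next, ])
  Q[s, a] <- Q[s, a] + lr * (target - Q[s, a])
  Q
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action; otherwise the
#' greedy action. Value ties are broken uniformly at random by default
#' (`tie_break = "random"`); `tie_break = "first"` reproduces the
#' first-index argmax convention of common array-library implementations,
#' which matters under sparse reward where the Q table stays identically
#' zero for a long time (see the methods vignette).
#'
#' @param Q Q table.
#' @param s Current state.
#' @param epsilon Exploration rate in `[0, 1]`.
#' @param n_avail Number of available actions in `s` (first columns),
#'   default all.
#' @param tie_break `"random"` or `"first"`.
#' @return The chosen action index.
#' @export
epsilon_greedy <- function(Q, s, epsilon = 0.1, n_avail = ncol(Q),
                           tie_break = c("random", "first")) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  tie_break <- match.arg(tie_break)
  if (runif(1) < epsilon) return(sample.int(n_avail, 1L))
  v <- Q[s, seq_len(n_avail)]
  best <- which(v == max(v))
  if (tie_break == "first" || length(best) == 1L) {
    best[1]
  } else {
    best[sample.int(length(best), 1L)]
  }
}

# env spec for the compiled episode runner: 0-based transition table plus
# reward/done/illegal channels and per-state action counts
.qlearn_tables <- function(nxt, reward, done, illegal, n_avail) {
  list(nxt0 = nxt - 1L, reward = reward, done = done,
       illegal = illegal, n_avail = as.integer(n_avail))
}

#' Run tabular Q-learning on the sparse-reward Taxi task
#'
#' The baseline comparison run: goal-only +20 reward, episode cap
#' `step_cap` (default 100000), uniformly random non-terminal resets.
#' The per-episode evaluation reward uses the dense accounting (-1 per
#' step, -10 per illegal pickup/dropoff attempt, +20 on success) but the
#' agent trains on the sparse signal only. With
#' `reward_scheme = "dense"` the agent instead trains on the conventional
#' dense reward (the configuration under which tabular Q-learning is known
#' to converge; used as a sanity check).
#'
#' @param episodes Number of episodes.
#' @param step_cap Episode step cap, default 100000.
#' @param lr,gamma,epsilon Q-learning hyperparameters (defaults 0.1, 0.99,
#'   0.1).
#' @param tie_break Greedy tie-breaking, `"first"` (default, the
#'   array-argmax convention) or `"random"`.
#' @param reward_scheme `"sparse"` (default) or `"dense"` training signal.
#' @param env A [taxi_env()] (built if missing).
#' @return A list of class `qlearn_run` with the final `Q` table and an
#'   `episodes` tibble (`episode`, `steps`, `train_reward`, `eval_reward`,
#'   `n_illegal`, `reached`, `cap_hit`, `cum_steps`).
#' @export
run_qlearning_taxi <- function(episodes = 100L, step_cap = 100000L,
                               lr = 0.1, gamma = 0.99, epsilon = 0.1,
                               tie_break = c("first", "random"),
                               reward_scheme = c("sparse", "dense"),
                               env = taxi_env()) {
  tie_break <- match.arg(tie_break)
  reward_scheme <- match.arg(reward_scheme)
  train_r <- if (reward_scheme == "sparse") env$reward_sparse else env$reward_dense
  tb <- .qlearn_tables(env$nxt, train_r, env$done, env$illegal,
                       rep(6L, env$n_states))
  Q <- q_table(env$n_states, env$n_actions)
  log <- vector("list", episodes)
  cum <- 0L
  for (e in seq_len(episodes)) {
    s0 <- taxi_reset(env)
    res <- .qlearn_episode_cpp(Q, tb$nxt0, tb$reward, tb$done, tb$illegal,
                               tb$n_avail, s0 - 1L, step_cap, lr, gamma,
                               epsilon, tie_break == "first")
    cum <- cum + res$steps
    log[[e]] <- tibble::tibble(
      episode = e, steps = res$steps,
      train_reward = res$train_reward,
      eval_reward = .taxi_eval_scalar(res$steps, res$n_illegal, res$reached),
      n_illegal = res$n_illegal, reached = res$reached,
      cap_hit = res$cap_hit, cum_steps = cum)
  }
  structure(list(Q = Q, episodes = dplyr::bind_rows(log),
                 task = paste0("qlearn_taxi_", reward_scheme)),
            class = "qlearn_run")
}

#' Run tabular Q-learning on the sparse-reward Voronoi task
#'
#' The Q state is the (location, target) pair — 150 x 150 composite states
#' — since the target changes every episode. Reward is +20 at the target
#' only; episode cap 10000; episodes chain (each starts where the previous
#' ended) as in the routing-agent runs.
#'
#' @param world A [voronoi_world()].
#' @param episodes Number of episodes.
#' @param step_cap Episode step cap, default 10000.
#' @inheritParams run_qlearning_taxi
#' @return A `qlearn_run` (the `Q` table has one row per composite state).
#' @export
run_qlearning_voronoi <- function(world, episodes = 200L, step_cap = 10000L,
                                  lr = 0.1, gamma = 0.99, epsilon = 0.1,
                                  tie_break = c("first", "random")) {
  tie_break <- match.arg(tie_break)
  n <- world$n_states
  K <- world$n_actions
  # composite state (loc, target) -> 1-based index loc + (target-1)*n
  nxt <- matrix(1L, n * n, K)
  reward <- matrix(0, n * n, K)
  done <- matrix(FALSE, n * n, K)
  illegal <- matrix(FALSE, n * n, K)
  n_avail <- integer(n * n)
  for (tgt in seq_len(n)) {
    off <- (tgt - 1L) * n
    for (loc in seq_len(n)) {
      nb <- world$neighbors[[loc]]
      n_avail[off + loc] <- length(nb)
      for (a in seq_along(nb)) {
        nxt[off + loc, a] <- off + nb[a]
        if (nb[a] == tgt) {
          reward[off + loc, a] <- 20
          done[off + loc, a] <- TRUE
        }
      }
    }
  }
  tb <- .qlearn_tables(nxt, reward, done, illegal, n_avail)
  Q <- q_table(n * n, K)
  log <- vector("list", episodes)
  cum <- 0L
  loc <- NULL
  for (e in seq_len(episodes)) {
    rs <- voronoi_reset(world, prev_state = loc)
    loc <- rs$state
    tgt <- rs$targets[1]
    s0 <- (tgt - 1L) * n + loc
    res <- .qlearn_episode_cpp(Q, tb$nxt0, tb$reward, tb$done, tb$illegal,
                               tb$n_avail, s0 - 1L, step_cap, lr, gamma,
                               epsilon, tie_break == "first")
    loc <- (res$end_state - 1L) %% n + 1L
    cum <- cum + res$steps
    log[[e]] <- tibble::tibble(
      episode = e, steps = res$steps, train_reward = res$train_reward,
      eval_reward = voronoi_eval_reward(res$steps, res$reached),
      n_illegal = 0L, reached = res$reached, cap_hit = res$cap_hit,
      cum_steps = cum)
  }
  structure(list(Q = Q, episodes = dplyr::bind_rows(log),
                 task = "qlearn_voronoi"),
            class = "qlearn_run")
}

#' Average dense-reward return of the greedy policy on Taxi
#'
#' Rolls out the deterministic greedy policy of a trained Q table from
#' random starts under the dense accounting; used to verify that the same
#' Q-learning code converges under the conventional configuration.
#'
#' @param Q Trained Q table.
#' @param n_episodes Number of evaluation rollouts.
#' @param step_cap Rollout cap, default 200.
#' @param env A [taxi_env()].
#' @return A tibble with `mean_reward` and `success_rate`.
#' @export
greedy_taxi_eval <- function(Q, n_episodes = 100L, step_cap = 200L,
                             env = taxi_env()) {
  rewards <- numeric(n_episodes)
  reached <- logical(n_episodes)
  for (e in seq_len(n_episodes)) {
    s0 <- taxi_reset(env)
    res <- .greedy_episode_cpp(Q, env$nxt - 1L, env$reward_dense, env$done,
                               rep(6L, env$n_states), s0 - 1L, step_cap)
    rewards[e] <- res$total_reward
    reached[e] <- res$reached
  }
  tibble::tibble(mean_reward = mean(rewards), success_rate = mean(reached))
}

#' @export
print.qlearn_run <- function(x, ...) {
  ep <- x$episodes
  cat("<qlearn_run> ", x$task, ": ", nrow(ep), " episodes, mean eval reward ",
      format(mean(ep$eval_reward), digits = 4), ", cap hit in ",
      sum(ep$cap_hit), " episodes\n", sep = "")
  invisible(x)
}
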