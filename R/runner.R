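# Experiment runner: canned pipelines for every benchmark task, per-episode
# logging, convergence summaries, and reproducibility from a single seed.
#
# One master seed (set.seed at the start of run_experiment) drives every
# stochastic choice — world generation, resets, subgoal ties, action
# sampling — through R's sequential RNG stream, so identical (task, seed,
# config) always reproduces identical logs bit for bit.

.drm_tasks <- c("taxi", "taxi_locations_only", "voronoi", "voronoi_two_goal",
                "maggot", "qlearn_taxi", "qlearn_voronoi")

.default_episodes <- c(taxi = 1000L, taxi_locations_only = 300L,
                       voronoi = 2000L, voronoi_two_goal = 2000L,
                       maggot = NA, qlearn_taxi = 100L, qlearn_voronoi = 200L)

#' Train the routing agent on sparse-reward Taxi
#'
#' The full 500-state task with goal-only reward (+20 at a successful
#' dropoff, nothing otherwise) and a 100000-step episode cap. Rewarded
#' terminal states are grounded permanently; no target is announced by the
#' environment.
#'
#' @param episodes Number of training episodes.
#' @param params Agent parameters ([agent_params()] Taxi preset).
#' @param env A [taxi_env()] (built if missing).
#' @return List with the trained `agent` and an `episodes` tibble
#'   (`episode`, `steps`, `train_reward`, `eval_reward`, `n_illegal`,
#'   `reached`, `cap_hit`, `cum_steps`).
#' @export
run_drm_taxi <- function(episodes = 1000L, params = agent_params("taxi"),
                         env = taxi_env()) {
  agent <- drm_agent(env$n_states, params, n_actions = 6L)
  cap <- params$max_steps
  log <- vector("list", episodes)
  cum <- 0L
  for (e in seq_len(episodes)) {
    s <- taxi_reset(env)
    agent_begin_episode(agent, s)
    a <- agent_step(agent, s, 0)
    steps <- 0L; n_illegal <- 0L; train_r <- 0; success <- FALSE
    repeat {
      res <- taxi_step(env, s, a)
      steps <- steps + 1L
      if (res$illegal) n_illegal <- n_illegal + 1L
      train_r <- train_r + res$reward
      s <- res$state
      if (res$done || steps >= cap) {
        agent_step(agent, s, res$reward, terminal = TRUE)
        success <- res$done
        break
      }
      a <- agent_step(agent, s, res$reward)
    }
    cum <- cum + steps
    log[[e]] <- tibble::tibble(
      episode = e, steps = steps, train_reward = train_r,
      eval_reward = .taxi_eval_scalar(steps, n_illegal, success),
      n_illegal = n_illegal, reached = success, cap_hit = !success,
      cum_steps = cum)
  }
  list(agent = agent, episodes = dplyr::bind_rows(log))
}

#' Train the routing agent in a Voronoi world
#'
#' The target (one location, or two in the two-goal variant) is announced
#' by the environment at every reset and grounded explicitly; the previous
#' target is released. Episodes chain: each starts where the previous
#' ended. No reward value is fed to the agent.
#'
#' @param world A [voronoi_world()].
#' @param episodes Number of training episodes.
#' @param params Agent parameters ([agent_params()] Voronoi preset).
#' @param n_goals 1 (default) or 2 simultaneous reward sources; with 2 the
#'   episode ends at whichever is reached first.
#' @return List with the trained `agent` and an `episodes` tibble.
#' @export
run_drm_voronoi <- function(world, episodes = 2000L,
                            params = agent_params("voronoi"), n_goals = 1L) {
  agent <- drm_agent(world$n_states, params, n_actions = world$n_actions)
  cap <- params$max_steps
  avail <- lapply(world$neighbors, seq_along)
  log <- vector("list", episodes)
  cum <- 0L
  loc <- NULL
  for (e in seq_len(episodes)) {
    rs <- voronoi_reset(world, prev_state = loc, n_goals = n_goals)
    s <- rs$state
    agent_begin_episode(agent, s)
    a <- agent_step(agent, s, 0, explicit_target = rs$targets,
                    available = avail[[s]])
    steps <- 0L; reached <- FALSE
    repeat {
      res <- voronoi_step(world, s, a, rs$targets)
      steps <- steps + 1L
      s <- res$state
      if (res$done || steps >= cap) {
        agent_step(agent, s, 0, terminal = TRUE)
        reached <- res$done
        break
      }
      a <- agent_step(agent, s, 0, available = avail[[s]])
    }
    loc <- s
    cum <- cum + steps
    log[[e]] <- tibble::tibble(
      episode = e, steps = steps, train_reward = if (reached) 20 else 0,
      eval_reward = voronoi_eval_reward(steps, reached),
      n_illegal = 0L, reached = reached, cap_hit = !reached,
      cum_steps = cum)
  }
  list(agent = agent, episodes = dplyr::bind_rows(log))
}

#' Train the routing agent on the 25-cell location grid
#'
#' The location-only variant of the Taxi task: the agent sees just the
#' taxi cell (25 states, 4 movement actions) and is asked to reach a
#' random target cell each episode (announced explicitly). Used to
#' demonstrate latent learning of the grid topology.
#'
#' @param episodes Number of episodes.
#' @param params Agent parameters; defaults to the Taxi preset with 4
#'   actions and a 1000-step cap.
#' @param env A [taxi_locations_env()].
#' @return List with `agent`, `episodes` tibble, and the true `adjacency`.
#' @export
run_drm_locations <- function(episodes = 300L,
                              params = agent_params("taxi", n_actions = 4L,
                                                    max_steps = 1000L),
                              env = taxi_locations_env()) {
  agent <- drm_agent(env$n_states, params, n_actions = 4L)
  cap <- params$max_steps
  log <- vector("list", episodes)
  cum <- 0L
  for (e in seq_len(episodes)) {
    s <- sample.int(env$n_states, 1L)
    tgt <- sample(seq_len(env$n_states)[-s], 1L)
    agent_begin_episode(agent, s)
    a <- agent_step(agent, s, 0, explicit_target = tgt)
    steps <- 0L; reached <- FALSE
    repeat {
      s2 <- env$nxt[s, a]
      steps <- steps + 1L
      s <- s2
      if (s == tgt || steps >= cap) {
        agent_step(agent, s, 0, terminal = TRUE)
        reached <- s == tgt
        break
      }
      a <- agent_step(agent, s, 0)
    }
    cum <- cum + steps
    log[[e]] <- tibble::tibble(
      episode = e, steps = steps, train_reward = if (reached) 20 else 0,
      eval_reward = voronoi_eval_reward(steps, reached),
      n_illegal = 0L, reached = reached, cap_hit = !reached,
      cum_steps = cum)
  }
  list(agent = agent, episodes = dplyr::bind_rows(log), adjacency = env$adjacency)
}

#' Run a benchmark experiment
#'
#' Seeds R's RNG, dispatches to the task pipeline, and returns a `drm_run`
#' object whose episode log is a tibble; optionally writes plain-text
#' artifacts (episode CSV, summary CSV, learned-network edge list, agent
#' checkpoint) to `out_dir`. Identical `(task, seed, ...)` calls reproduce
#' identical logs.
#'
#' @param task One of `"taxi"`, `"taxi_locations_only"`, `"voronoi"`,
#'   `"voronoi_two_goal"`, `"maggot"`, `"qlearn_taxi"`,
#'   `"qlearn_voronoi"`.
#' @param episodes Episode count; a per-task default is used if `NULL`
#'   (1000 Taxi, 2000 Voronoi, 300 locations-only, 100/200 for the
#'   Q-learning baselines). Ignored by `"maggot"`.
#' @param seed Master seed (integer).
#' @param params Optional [agent_params()] override.
#' @param out_dir Optional output directory for CSV/edge-list artifacts.
#' @param ... Passed to the task pipeline (e.g. `n_maggots`, `tie_break`,
#'   `step_cap`, `world`).
#' @return A list of class `drm_run`: `task`, `seed`, `episodes` tibble
#'   (or per-step `li` tibble for `"maggot"`), `agent`/`Q` when
#'   applicable, `world` for Voronoi tasks, and the effective `params`.
#' @export
run_experiment <- function(task, episodes = NULL, seed = 1L, params = NULL,
                           out_dir = NULL, ...) {
  if (!task %in% .drm_tasks) {
    stop("unknown task '", task, "'; expected one of: ",
         paste(.drm_tasks, collapse = ", "))
  }
  if (!is.null(params) && !inherits(params, "agent_params")) {
    stop("params must be an agent_params() object")
  }
  episodes <- as.integer(episodes %||% .default_episodes[[task]])
  set.seed(as.integer(seed))
  dots <- list(...)
  world <- NULL
  out <- switch(task,
    taxi = {
      p <- params %||% agent_params("taxi")
      c(run_drm_taxi(episodes, p), list(params = p))
    },
    taxi_locations_only = {
      p <- params %||% agent_params("taxi", n_actions = 4L, max_steps = 1000L)
      c(run_drm_locations(episodes, p), list(params = p))
    },
    voronoi = ,
    voronoi_two_goal = {
      p <- params %||% agent_params("voronoi")
      world <- dots$world %||% voronoi_world()
      c(run_drm_voronoi(world, episodes, p,
                        n_goals = if (task == "voronoi_two_goal") 2L else 1L),
        list(params = p))
    },
    maggot = {
      p <- params %||% agent_params("maggot")
      list(episodes = run_maggot_experiment(
        n_maggots = dots$n_maggots %||% 30L,
        steps_per_dish = dots$steps_per_dish %||% 40L, params = p),
        params = p)
    },
    qlearn_taxi = {
      do.call(run_qlearning_taxi,
              c(list(episodes = episodes), dots[names(dots) %in%
                c("step_cap", "lr", "gamma", "epsilon", "tie_break",
                  "reward_scheme")]))
    },
    qlearn_voronoi = {
      world <- dots$world %||% voronoi_world()
      do.call(run_qlearning_voronoi,
              c(list(world = world, episodes = episodes), dots[names(dots) %in%
                c("step_cap", "lr", "gamma", "epsilon", "tie_break")]))
    })
  run <- structure(list(task = task, seed = as.integer(seed),
                        episodes = out$episodes, agent = out$agent,
                        Q = out$Q, world = world,
                        adjacency = out$adjacency, params = out$params),
                   class = "drm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Summarise an episode log
#'
#' Computes the convergence point (first episode whose 100-episode moving
#' average of evaluation reward reaches `threshold`), the cumulative step
#' count at that episode, and the final moving averages.
#'
#' @param x A `drm_run`, an episode-log data frame with columns `episode`,
#'   `steps`, `eval_reward`, `cum_steps`, or a path to such a CSV.
#' @param threshold Convergence threshold on the moving-average evaluation
#'   reward, default -10.
#' @param window Moving-average window, default 100 episodes.
#' @return One-row tibble: `n_episodes`, `total_steps`,
#'   `convergence_episode`, `steps_to_convergence`, `final_ma_eval`,
#'   `final_ma_steps`.
#' @export
summarise_run <- function(x, threshold = -10, window = 100L) {
  ep <- if (inherits(x, "drm_run")) {
    x$episodes
  } else if (is.character(x)) {
    tibble::as_tibble(utils::read.csv(x))
  } else {
    tibble::as_tibble(x)
  }
  need <- c("episode", "steps", "eval_reward", "cum_steps")
  if (nrow(ep) == 0L) stop("empty episode log")
  if (!all(need %in% names(ep))) {
    stop("episode log must have columns: ", paste(need, collapse = ", "))
  }
  conv <- convergence_episode(ep$eval_reward, threshold, window)
  last <- utils::tail(ep, window)
  tibble::tibble(
    n_episodes = nrow(ep),
    total_steps = ep$cum_steps[nrow(ep)],
    convergence_episode = conv,
    steps_to_convergence = if (is.na(conv)) NA_integer_ else ep$cum_steps[conv],
    final_ma_eval = mean(last$eval_reward),
    final_ma_steps = mean(last$steps)
  )
}

#' Write run artifacts to a directory
#'
#' `episodes.csv` (per-episode log with the 100-episode moving average
#' appended), `summary.csv`, and — for routing-agent runs — the learned
#' network edge list and a full agent checkpoint.
#'
#' @param run A `drm_run`.
#' @param out_dir Directory (created if needed).
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ep <- run$episodes
  if ("eval_reward" %in% names(ep)) {
    ep$ma100_eval_reward <- moving_average(ep$eval_reward, 100L)
    utils::write.csv(ep, file.path(out_dir, "episodes.csv"), row.names = FALSE)
    utils::write.csv(summarise_run(run), file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  } else {
    utils::write.csv(ep, file.path(out_dir, "episodes.csv"), row.names = FALSE)
  }
  if (!is.null(run$agent)) {
    write_edgelist(agent_network(run$agent),
                   file.path(out_dir, "learned_network.tsv"))
    write_agent(run$agent, file.path(out_dir, "checkpoint"))
  }
  invisible(out_dir)
}

#' @export
print.drm_run <- function(x, ...) {
  cat("<drm_run> task ", x$task, ", seed ", x$seed, ": ", sep = "")
  if ("eval_reward" %in% names(x$episodes)) {
    s <- summarise_run(x)
    cat(s$n_episodes, " episodes, ", s$total_steps, " steps; ",
        "final MA100 eval reward ", format(s$final_ma_eval, digits = 4),
        ", steps/episode ", format(s$final_ma_steps, digits = 4), "\n",
        sep = "")
  } else {
    cat(nrow(x$episodes), " rows\n", sep = "")
  }
  invisible(x)
}

#' @param x A `drm_run`.
#' @param ... Unused.
#' @rdname run_experiment
#' @method tidy drm_run
#' @export
tidy.drm_run <- function(x, ...) {
  ep <- tibble::as_tibble(x$episodes)
  if ("eval_reward" %in% names(ep)) {
    ep$ma100_eval_reward <- moving_average(ep$eval_reward, 100L)
  }
  ep
}

#' @rdname run_experiment
#' @method glance drm_run
#' @export
glance.drm_run <- function(x, ...) {
  if (!"eval_reward" %in% names(x$episodes)) {
    return(tibble::tibble(task = x$task, seed = x$seed,
                          n_rows = nrow(x$episodes)))
  }
  dplyr::bind_cols(tibble::tibble(task = x$task, seed = x$seed),
                   summarise_run(x))
}

#' Plot a run's evaluation reward per episode
#'
#' Episode evaluation reward (points) with the 100-episode moving average
#' (line), the standard convergence picture for these tasks.
#'
#' @param object A `drm_run`.
#' @param window Moving-average window.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drm_run
#' @export
autoplot.drm_run <- function(object, window = 100L, ...) {
  if (!"eval_reward" %in% names(object$episodes)) {
    dat <- object$episodes
    return(ggplot2::ggplot(dat, ggplot2::aes(x = .data$step, y = .data$li,
                                             colour = .data$condition)) +
             ggplot2::geom_line() +
             ggplot2::labs(x = "test step", y = "learning index",
                           colour = NULL) +
             ggplot2::theme_minimal())
  }
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$episode)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$eval_reward),
                        alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = moving_average(.data$eval_reward,
                                                       window)),
                       colour = "orange", linewidth = 0.8) +
    ggplot2::labs(x = "episode", y = "evaluation reward",
                  title = paste0(object$task, " (seed ", object$seed, ")"),
                  subtitle = paste0(window, "-episode moving average in orange")) +
    ggplot2::theme_minimal()
}
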