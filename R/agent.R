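# The dynamic routing agent.
#
# The agent's memory is environment-backed (reference semantics): the
# first-order weight matrix W is also the conductance matrix of the
# resistive world model, and per-step updates must not trigger R's
# copy-on-write, so all entry writes go through in-place C++ setters.

#' Agent parameters
#'
#' Bundles the learning and decision parameters of the dynamic routing
#' model, with per-task presets matching the published benchmark
#' configurations.
#'
#' @param task Preset: `"taxi"` (500 states, 6 actions), `"voronoi"`
#'   (150 locations, actions = node degree), or `"maggot"` (5 perceptual
#'   states, 5 actions, slow learning, `w1max = 10`).
#' @param ... Named overrides of any preset field.
#'
#' @details Fields (units in parentheses):
#' * `dt` — Euler time step per environment step (s), default 0.02.
#' * `alpha` — first-order learning rate (1/s).
#' * `beta` — second-order learning-rate ratio (dimensionless).
#' * `c` — second-order decrease factor (1/s), typical value 400.
#' * `w_ij0` — initial first-order weight (conductance units).
#' * `w1max` — saturation bound of first-order weights.
#' * `w_ijk0` — initial second-order (edge-to-action) weight.
#' * `w2max` — ground conductance given to a target/rewarded node.
#' * `n_actions` — maximum number of action nodes N.
#' * `max_steps` — episode step cap for the preset task.
#' * `recalc_interval` — environment steps between circuit re-solves
#'   (>= 1); between re-solves decisions use the stale potentials.
#' * `stochastic_subgoal` — sample the subgoal with probability
#'   proportional to edge power instead of taking the argmax.
#' * `use_softmax` — softmax action probabilities (off by default).
#' * `action_input_mode` — `"simplified"` (action input = second-order
#'   weight on the subgoal edge), `"single_edge_power"` (weight times the
#'   subgoal edge's power), or `"multi_edge"` (every outgoing edge
#'   contributes, weighted by its power).
#' * `weight_decay` — optional slow decay rate of first-order weights
#'   (1/s), 0 = off.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(task = c("taxi", "voronoi", "maggot"), ...) {
  task <- match.arg(task)
  p <- list(
    dt = 0.02, alpha = 0.05, beta = 2, c = 400,
    w_ij0 = 0, w1max = 1, w_ijk0 = 0.01, w2max = 1,
    n_actions = 6L, max_steps = 100000L,
    recalc_interval = 1L, stochastic_subgoal = FALSE, use_softmax = FALSE,
    action_input_mode = "simplified", weight_decay = 0
  )
  if (task == "voronoi") {
    p$n_actions <- 5L
    p$max_steps <- 10000L
    # navigation uses a stale current field between re-solves: within a
    # window the potentials form a fixed, strictly descending gradient to
    # the target, which rules out the subgoal ping-pong that per-step
    # re-pinning of the moving source can produce (and is ~10x cheaper)
    p$recalc_interval <- 10L
  } else if (task == "maggot") {
    p$alpha <- 0.001
    p$w1max <- 10
    p$w_ijk0 <- 1e-10
    p$n_actions <- 5L
    p$max_steps <- 40L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  stopifnot(p$dt > 0, p$alpha >= 0, p$beta >= 0, p$c >= 0,
            p$w1max >= 0, p$w_ijk0 >= 0, p$w2max >= 0,
            p$recalc_interval >= 1)
  p$task <- task
  class(p) <- "agent_params"
  p
}

#' Create a dynamic routing agent
#'
#' The agent holds first-order state-to-state weights `W` (the conductances
#' of its resistive world model, each in `[w_ij0, w1max]`), second-order
#' edge-to-action weights `W2[i, j, k]`, and a ground-conductance vector
#' marking goal states. The object has reference semantics: the learning
#' functions ([observe_transition()], [mark_rewarded()],
#' [update_action_weights()], [agent_step()], ...) modify it in place and
#' return it invisibly.
#'
#' @param n_states Number of state nodes (the implicit ground node is not
#'   counted).
#' @param params An [agent_params()] list.
#' @param n_actions Number of action nodes; defaults to `params$n_actions`.
#' @return An environment of class `drm_agent` with fields `W` (n x n
#'   matrix), `W2` (n x n x K array), `ground` (length n), `V` (last solved
#'   potentials or NULL), `state`, `last_subgoal`, `last_action`,
#'   `step_count`, `explicit_targets`, `params`.
#' @export
drm_agent <- function(n_states, params = agent_params(), n_actions = NULL) {
  stopifnot(inherits(params, "agent_params"), n_states >= 1)
  K <- as.integer(n_actions %||% params$n_actions)
  a <- new.env(parent = emptyenv())
  a$n <- as.integer(n_states)
  a$K <- K
  a$params <- params
  a$W <- matrix(params$w_ij0, n_states, n_states)
  diag(a$W) <- 0
  a$W2 <- array(params$w_ijk0, dim = c(n_states, n_states, K))
  a$ground <- numeric(n_states)
  a$V <- NULL
  a$state <- NULL
  a$last_subgoal <- NULL
  a$last_action <- NULL
  a$step_count <- 0L
  a$explicit_targets <- integer(0)
  class(a) <- "drm_agent"
  a
}

#' @export
print.drm_agent <- function(x, ...) {
  cat("<drm_agent> ", x$n, " states, ", x$K, " actions; ",
      sum(x$W > 0), " learned edges; ", sum(x$ground > 0),
      " grounded goal(s); step ", x$step_count, "\n", sep = "")
  invisible(x)
}

#' First-order network as a resistive network or tidy edge table
#'
#' @param agent A [drm_agent].
#' @export
agent_network <- function(agent) {
  stopifnot(inherits(agent, "drm_agent"))
  resistive_network(agent$W, agent$ground)
}

#' @param x A [drm_agent].
#' @param ... Unused.
#' @rdname agent_network
#' @method tidy drm_agent
#' @export
tidy.drm_agent <- function(x, ...) {
  idx <- which(x$W > 0, arr.ind = TRUE)
  tibble::tibble(from = as.integer(idx[, 1]), to = as.integer(idx[, 2]),
                 weight = x$W[idx]) |>
    dplyr::arrange(.data$from, .data$to)
}

.w2_flat <- function(agent, i, j, k) {
  as.double(i) + (as.double(j) - 1) * agent$n +
    (as.double(k) - 1) * agent$n * agent$n
}

#' Latent learning of a state transition
#'
#' Saturating Euler update of the first-order weight on the experienced
#' transition: `W[i,j] <- W[i,j] + dt * alpha * (w1max - W[i,j])`. The
#' weight approaches `w1max` geometrically with the number of traversals
#' and can never exceed it. Self-transitions (`i == j`) are ignored: the
#' network stays a transition model with a zero diagonal.
#'
#' @param agent A [drm_agent] (modified in place).
#' @param i,j Previous and current state node (1-based).
#' @return The agent, invisibly.
#' @export
observe_transition <- function(agent, i, j) {
  stopifnot(inherits(agent, "drm_agent"))
  if (i == j) return(invisible(agent))
  p <- agent$params
  w <- agent$W[i, j]
  .set_entry_cpp(agent$W, i, j, w + p$dt * p$alpha * (p$w1max - w))
  invisible(agent)
}

#' Ground a rewarded state
#'
#' Experiencing reward in state `i` connects its node to ground with
#' conductance `w2max`, marking it as a target that attracts current in all
#' future episodes. Idempotent; several states can be grounded at once.
#'
#' @inheritParams observe_transition
#' @export
mark_rewarded <- function(agent, i) {
  stopifnot(inherits(agent, "drm_agent"))
  .set_flat_cpp(agent$ground, i, agent$params$w2max)
  invisible(agent)
}

#' Set (or clear) environment-announced target states
#'
#' For tasks where the goal is announced each episode: grounds each new
#' target at `w2max` and releases the previously announced targets by
#' setting their ground conductance back to 0. States grounded through
#' reward experience ([mark_rewarded()]) are not touched. An empty target
#' set releases all explicit targets. Invalidate the cached potentials so
#' the next decision re-solves the circuit.
#'
#' @param agent A [drm_agent] (modified in place).
#' @param targets Integer vector of target nodes (possibly empty).
#' @export
set_explicit_target <- function(agent, targets) {
  stopifnot(inherits(agent, "drm_agent"))
  targets <- as.integer(targets)
  if (identical(sort(targets), sort(agent$explicit_targets))) {
    return(invisible(agent))
  }
  for (t in setdiff(agent$explicit_targets, targets)) {
    .set_flat_cpp(agent$ground, t, 0)
  }
  for (t in targets) .set_flat_cpp(agent$ground, t, agent$params$w2max)
  agent$explicit_targets <- targets
  agent$V <- NULL
  invisible(agent)
}

.edge_powers_from <- function(agent, state, V) {
  if (is.null(V)) return(numeric(agent$n))
  drop <- V[state] - V
  drop[drop < 0] <- 0
  agent$W[state, ] * drop * drop
}

#' Select the next subgoal from local edge powers
#'
#' The subgoal is the neighbouring state on the edge with maximal power
#' consumption out of the active state node (deterministic mode). If all
#' powers are equal — in particular all zero, as in the first episode —
#' the subgoal is drawn uniformly at random among the other `n - 1` nodes;
#' power ties are broken uniformly. In stochastic mode
#' (`params$stochastic_subgoal`) the subgoal is sampled with probability
#' proportional to edge power.
#'
#' @param agent A [drm_agent].
#' @param state Active state node; defaults to the agent's current state.
#' @param solution Optional [solve_circuit()] result; by default the
#'   agent's cached potentials from its last re-solve are used.
#' @return The subgoal node index.
#' @export
select_subgoal <- function(agent, state = agent$state, solution = NULL) {
  stopifnot(inherits(agent, "drm_agent"))
  V <- if (!is.null(solution)) solution$potentials else agent$V
  pw <- .edge_powers_from(agent, state, V)
  mx <- max(pw)
  # powers below numerical noise (potential plateaus solve to 1 +/- 1e-16,
  # squaring to ~1e-32) mean "no current": fall back to uniform exploration
  # rather than deterministically following solver dust
  if (mx <= 1e-18) {
    cand <- seq_len(agent$n)[-state]
    return(cand[sample.int(length(cand), 1L)])
  }
  if (agent$params$stochastic_subgoal) {
    return(sample.int(agent$n, 1L, prob = pw))
  }
  cand <- which(pw >= mx * (1 - 1e-9))
  if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
}

#' Inputs to the action nodes
#'
#' Given the active state `i` and subgoal `j'`, computes the postsynaptic
#' input `I_k` of each available action node:
#' * `"simplified"`: `I_k = W2[i, j', k]` — the power factor common to all
#'   actions cancels after normalisation, so this reproduces the
#'   single-edge probabilities at no solver cost;
#' * `"single_edge_power"`: `I_k = W2[i, j', k] * I[i,j'] * V[i,j']`;
#' * `"multi_edge"`: `I_k = sum_j W2[i, j, k] * I[i,j] * V[i,j]`, letting
#'   every outgoing edge act as a power-weighted subgoal (the `subgoal`
#'   argument is ignored).
#'
#' @param agent A [drm_agent].
#' @param state Active state node.
#' @param subgoal Selected subgoal node.
#' @param available Integer vector of available action indices (default all).
#' @param mode Override of `params$action_input_mode`.
#' @return Named numeric vector of nonnegative inputs, one per available
#'   action.
#' @export
action_inputs <- function(agent, state, subgoal,
                          available = seq_len(agent$K), mode = NULL) {
  stopifnot(inherits(agent, "drm_agent"))
  mode <- mode %||% agent$params$action_input_mode
  w2 <- agent$W2[state, , , drop = FALSE]
  dim(w2) <- c(agent$n, agent$K)
  I_k <- switch(mode,
    simplified = w2[subgoal, available],
    single_edge_power = {
      V <- agent$V
      pwr <- if (is.null(V)) 0 else {
        d <- max(V[state] - V[subgoal], 0)
        agent$W[state, subgoal] * d * d
      }
      w2[subgoal, available] * pwr
    },
    multi_edge = {
      pw <- .edge_powers_from(agent, state, agent$V)
      as.numeric(crossprod(w2[, available, drop = FALSE], pw))
    },
    stop("unknown action_input_mode: ", mode)
  )
  names(I_k) <- available
  I_k
}

#' Action probabilities from action-node inputs
#'
#' Normalises the nonnegative inputs to probabilities,
#' `P(a) = I_a / sum_k I_k` (a lateral-inhibition readout). If all inputs
#' are zero the distribution is uniform over the available actions. The
#' softmax variant (off by default) first scales the inputs to maximum 1
#' and applies softmax, which flattens the distribution and increases
#' exploration.
#'
#' @param I Nonnegative numeric vector of action inputs.
#' @param use_softmax Apply the softmax variant.
#' @return Numeric vector of probabilities summing to 1.
#' @export
action_probabilities <- function(I, use_softmax = FALSE) {
  if (any(I < 0)) stop("action inputs must be nonnegative")
  if (use_softmax) {
    z <- if (max(I) > 0) I / max(I) else I
    e <- exp(z)
    return(e / sum(e))
  }
  s <- sum(I)
  if (s <= 0) rep(1 / length(I), length(I)) else I / s
}

#' Sample one action from a probability vector
#'
#' @param probs Probabilities over actions (summing to 1).
#' @return The sampled index into `probs`.
#' @export
sample_action <- function(probs) {
  sample.int(length(probs), 1L, prob = probs)
}

#' Second-order (edge-to-action) plasticity
#'
#' After action `k` produced the transition `i -> j_actual` while the
#' selected subgoal was `j_expected`:
#' * the weight on the actual transition grows linearly,
#'   `W2[i, j_actual, k] <- W2[i, j_actual, k] + dt * alpha * beta`
#'   (skipped when the state did not change, so no self-edge weights are
#'   created);
#' * if the subgoal was missed (`j_actual != j_expected`), the weight that
#'   recommended `k` for the expected edge decays multiplicatively,
#'   `W2[i, j_expected, k] <- W2[i, j_expected, k] * (1 - dt * alpha * c)`,
#'   which keeps it nonnegative.
#'
#' @param agent A [drm_agent] (modified in place).
#' @param i State in which the action was taken.
#' @param j_expected Subgoal that was selected (or `NULL` if none).
#' @param j_actual State actually reached.
#' @param k Action index taken.
#' @export
update_action_weights <- function(agent, i, j_expected, j_actual, k) {
  stopifnot(inherits(agent, "drm_agent"))
  p <- agent$params
  if (j_actual != i) {
    idx <- .w2_flat(agent, i, j_actual, k)
    .set_flat_cpp(agent$W2, idx, .get_flat_cpp(agent$W2, idx) +
                    p$dt * p$alpha * p$beta)
  }
  if (!is.null(j_expected) && j_actual != j_expected) {
    idx <- .w2_flat(agent, i, j_expected, k)
    .set_flat_cpp(agent$W2, idx, .get_flat_cpp(agent$W2, idx) *
                    (1 - p$dt * p$alpha * p$c))
  }
  invisible(agent)
}

#' Start a new episode
#'
#' Sets the active state without learning a transition (episode resets are
#' teleports, not experienced state changes) and clears the pending
#' subgoal/action.
#'
#' @param agent A [drm_agent] (modified in place).
#' @param state Initial state of the episode.
#' @export
agent_begin_episode <- function(agent, state) {
  stopifnot(inherits(agent, "drm_agent"))
  agent$state <- as.integer(state)
  agent$last_subgoal <- NULL
  agent$last_action <- NULL
  invisible(agent)
}

.agent_solve <- function(agent) {
  if (all(agent$ground == 0)) {
    agent$V <- NULL
    return(invisible(agent))
  }
  raw <- .solve_rectified_cpp(agent$W, agent$ground, agent$state,
                              1.0, 1e-10, 100L)
  agent$V <- if (isTRUE(raw$converged)) raw$potentials else NULL
  invisible(agent)
}

#' One perception-decision step of the agent
#'
#' Composes the full learning/decision loop. In order: (1) latent learning
#' of the experienced transition `last state -> new_state`; (2) second-order
#' plasticity for the action just taken; (3) grounding of `new_state` if
#' reward was received; (4) explicit-target update, if announced; (5)
#' circuit re-solve at the configured interval (decisions between re-solves
#' reuse the stale potentials); (6) subgoal selection, action-input
#' computation and stochastic action choice.
#'
#' If the circuit cannot be solved (or nothing is grounded yet) the edge
#' powers are all zero, so the subgoal is random and the action follows the
#' second-order weights alone — uniform on a naive agent.
#'
#' @param agent A [drm_agent] (modified in place).
#' @param new_state State returned by the environment.
#' @param reward Raw (sparse) reward of the transition; any positive value
#'   grounds `new_state`.
#' @param explicit_target Optional integer vector of announced targets
#'   (`NULL` = task without announcements).
#' @param available Available action indices in `new_state`.
#' @param terminal If `TRUE`, apply the learning phases only and return
#'   `NA` (no action is needed in a terminal state).
#' @return The chosen action index (or `NA_integer_` if `terminal`).
#' @export
agent_step <- function(agent, new_state, reward = 0, explicit_target = NULL,
                       available = seq_len(agent$K), terminal = FALSE) {
  stopifnot(inherits(agent, "drm_agent"))
  new_state <- as.integer(new_state)
  p <- agent$params

  if (!is.null(agent$state) && !is.null(agent$last_action)) {
    i <- agent$state
    if (new_state != i) observe_transition(agent, i, new_state)
    update_action_weights(agent, i, agent$last_subgoal, new_state,
                          agent$last_action)
  }
  if (reward > 0) mark_rewarded(agent, new_state)
  if (!is.null(explicit_target)) set_explicit_target(agent, explicit_target)
  if (p$weight_decay > 0) {
    agent$W <- agent$W * (1 - p$dt * p$weight_decay)
  }
  agent$state <- new_state
  agent$step_count <- agent$step_count + 1L

  if (terminal) {
    agent$last_subgoal <- NULL
    agent$last_action <- NULL
    return(invisible(NA_integer_))
  }

  if (agent$step_count %% p$recalc_interval == 0L || is.null(agent$V)) {
    .agent_solve(agent)
  }

  j_sub <- select_subgoal(agent, new_state)
  I_k <- action_inputs(agent, new_state, j_sub, available = available)
  probs <- action_probabilities(I_k, use_softmax = p$use_softmax)
  k <- available[sample_action(probs)]
  agent$last_subgoal <- j_sub
  agent$last_action <- k
  k
}

#' Checkpoint an agent to plain-text files
#'
#' Writes `<prefix>_network.tsv` (first-order weights and grounds in the
#' edge-list format of [write_edgelist()]), `<prefix>_actions.tsv`
#' (second-order weights differing from `w_ijk0`, one `i j k weight` row
#' per line) and `<prefix>_params.tsv` (key-value block).
#'
#' @param agent A [drm_agent].
#' @param prefix File path prefix.
#' @return `prefix`, invisibly.
#' @export
write_agent <- function(agent, prefix) {
  stopifnot(inherits(agent, "drm_agent"))
  write_edgelist(agent_network(agent), paste0(prefix, "_network.tsv"))
  idx <- which(agent$W2 != agent$params$w_ijk0, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  writeLines(sprintf("%d\t%d\t%d\t%.17g", idx[, 1], idx[, 2], idx[, 3],
                     agent$W2[idx]),
             paste0(prefix, "_actions.tsv"))
  p <- agent$params
  keys <- c("dt", "alpha", "beta", "c", "w_ij0", "w1max", "w_ijk0", "w2max",
            "n_actions", "max_steps", "recalc_interval", "weight_decay")
  writeLines(c(sprintf("task\t%s", p$task),
               sprintf("n_states\t%d", agent$n),
               sprintf("n_actions_used\t%d", agent$K),
               sprintf("action_input_mode\t%s", p$action_input_mode),
               sprintf("%s\t%.17g", keys, as.numeric(p[keys]))),
             paste0(prefix, "_params.tsv"))
  invisible(prefix)
}

#' @rdname write_agent
#' @export
read_agent <- function(prefix) {
  kv <- utils::read.delim(paste0(prefix, "_params.tsv"), header = FALSE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  val <- function(k) kv$value[kv$key == k]
  num <- function(k) as.numeric(val(k))
  p <- agent_params(task = val("task"),
                    dt = num("dt"), alpha = num("alpha"), beta = num("beta"),
                    c = num("c"), w_ij0 = num("w_ij0"), w1max = num("w1max"),
                    w_ijk0 = num("w_ijk0"), w2max = num("w2max"),
                    n_actions = as.integer(num("n_actions")),
                    max_steps = as.integer(num("max_steps")),
                    recalc_interval = as.integer(num("recalc_interval")),
                    weight_decay = num("weight_decay"),
                    action_input_mode = val("action_input_mode"))
  net <- read_edgelist(paste0(prefix, "_network.tsv"))
  agent <- drm_agent(net$n_nodes, p, n_actions = as.integer(num("n_actions_used")))
  agent$W[] <- net$conductance
  agent$ground[] <- net$ground
  af <- paste0(prefix, "_actions.tsv")
  lines <- readLines(af)
  if (length(lines)) {
    m <- do.call(rbind, lapply(strsplit(lines, "\t"), as.numeric))
    agent$W2[cbind(m[, 1], m[, 2], m[, 3])] <- m[, 4]
  }
  agent
}
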