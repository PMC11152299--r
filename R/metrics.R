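# Evaluation-reward accounting, moving averages, convergence detection,
# graph-recovery scoring and the maggot preference/learning indexes.
#
# Training uses only the sparse goal reward; everything here is evaluation
# bookkeeping and is never fed back to the learning agent.

#' Dense evaluation reward of a Taxi trajectory
#'
#' -1 per step, with -10 replacing the step penalty on an illegal
#' pickup/dropoff attempt, and +20 on a successful final dropoff. Only the
#' +20 is ever used in training; this accounting exists for comparison
#' with conventionally-configured runs. Set `illegal_replaces = FALSE` to
#' make the -10 additional to the per-step -1 instead.
#'
#' @param trajectory A data frame with one row per step and a logical
#'   column `illegal`; success is taken from a logical `success` column
#'   (last row) if present, else from attribute or argument.
#' @param success Whether the episode ended with a successful dropoff
#'   (overrides the `success` column).
#' @param illegal_replaces If `TRUE` (default) the -10 replaces that
#'   step's -1; otherwise it is added to it.
#' @return The episode evaluation reward (a single number; 0 for an empty
#'   trajectory).
#' @export
taxi_eval_reward <- function(trajectory, success = NULL,
                             illegal_replaces = TRUE) {
  n <- nrow(trajectory)
  if (is.null(n) || n == 0L) return(0)
  n_illegal <- sum(trajectory$illegal)
  if (is.null(success)) {
    success <- if ("success" %in% names(trajectory)) {
      isTRUE(trajectory$success[n])
    } else FALSE
  }
  per_step <- if (illegal_replaces) {
    -1 * (n - n_illegal) - 10 * n_illegal
  } else {
    -1 * n - 10 * n_illegal
  }
  per_step + if (success) 20 else 0
}

.taxi_eval_scalar <- function(n_steps, n_illegal, success,
                              illegal_replaces = TRUE) {
  base <- if (illegal_replaces) {
    -(n_steps - n_illegal) - 10 * n_illegal
  } else {
    -n_steps - 10 * n_illegal
  }
  base + if (success) 20 else 0
}

#' Dense evaluation reward of a Voronoi trajectory
#'
#' -1 per step (energy cost) and +20 on reaching the target.
#'
#' @param n_steps Number of steps taken.
#' @param reached Whether a target was reached.
#' @return The episode evaluation reward.
#' @export
voronoi_eval_reward <- function(n_steps, reached) {
  -n_steps + if (reached) 20 else 0
}

#' Trailing moving average
#'
#' Entry `t` is the mean of the last `min(window, t)` values, so the early
#' entries average over a partial window.
#'
#' @param x Numeric series.
#' @param window Window length (>= 1), default 100 episodes.
#' @return Numeric series of the same length.
#' @export
moving_average <- function(x, window = 100L) {
  stopifnot(window >= 1L)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  i <- seq_len(n)
  lag <- pmax(i - window, 0L)
  (cs - c(0, cs)[lag + 1L]) / pmin(i, window)
}

#' First episode at which the moving average reaches a threshold
#'
#' The convergence detector: the first episode index `e >= window` whose
#' trailing full-window mean is at least `threshold` (partial windows do
#' not count, so a constant series converges exactly when the window
#' fills).
#'
#' @param x Per-episode series (e.g. evaluation reward).
#' @param threshold Threshold value.
#' @param window Moving-average window, default 100.
#' @return Episode index, or `NA_integer_` if never reached.
#' @export
convergence_episode <- function(x, threshold, window = 100L) {
  n <- length(x)
  if (n < window) return(NA_integer_)
  ma <- moving_average(x, window)
  ok <- which(seq_len(n) >= window & ma >= threshold)
  if (length(ok)) ok[1] else NA_integer_
}

#' Preference index of a maggot population
#'
#' `PREF = (n_am - n_oct) / n_total`; maggots at the middle location count
#' toward neither side but stay in the denominator.
#'
#' @param counts Data frame with columns `n_am`, `n_oct`, `n_total`
#'   (one row per test step).
#' @return The input with a `pref` column added (replaced if present).
#' @export
preference_index <- function(counts) {
  if (any(counts$n_total <= 0)) stop("n_total must be positive")
  dplyr::mutate(tibble::as_tibble(counts),
                pref = (.data$n_am - .data$n_oct) / .data$n_total)
}

#' Learning index from reciprocal protocols
#'
#' `LI = (PREF[AM+/OCT] - PREF[AM/OCT+]) / 2`, vectorised over test steps.
#' Positive values indicate appetitive memory.
#'
#' @param pref_plus Preference index (series) after AM+/OCT training.
#' @param pref_minus Preference index (series) after AM/OCT+ training.
#' @export
learning_index <- function(pref_plus, pref_minus) {
  (pref_plus - pref_minus) / 2
}

#' Precision and recall of the learned transition graph
#'
#' Binarises the first-order weight matrix at
#' `threshold_fraction * w1max` and scores the surviving directed edges
#' against the environment's true transition adjacency.
#'
#' @param learned_W Learned n x n weight matrix.
#' @param true_adjacency n x n 0/1 matrix of true directed transitions.
#' @param threshold_fraction Fraction of `w1max` below which an edge is
#'   ignored, default 0.1 (the display threshold used for learned-graph
#'   figures); exact-recovery checks use 0.5.
#' @param w1max Weight ceiling, default 1.
#' @return A one-row tibble with `n_edges`, `precision`, `recall`
#'   (precision is 1 when no edges survive; recall is 1 when the true
#'   graph is empty).
#' @export
graph_recovery <- function(learned_W, true_adjacency,
                           threshold_fraction = 0.1, w1max = 1) {
  stopifnot(all(dim(learned_W) == dim(true_adjacency)))
  est <- learned_W >= threshold_fraction * w1max
  truth <- true_adjacency > 0
  tp <- sum(est & truth)
  tibble::tibble(
    n_edges = sum(est),
    precision = if (sum(est) == 0L) 1 else tp / sum(est),
    recall = if (sum(truth) == 0L) 1 else tp / sum(truth)
  )
}

#' Weakly-connected components of a thresholded weight graph
#'
#' Counts components among the nodes that retain at least one incident
#' edge after thresholding (isolated, never-visited states are not
#' counted). The fully trained Taxi state graph has exactly four: one per
#' destination, since destinations never change within an episode.
#'
#' @param W n x n weight matrix.
#' @param threshold Absolute weight threshold.
#' @return Number of weakly-connected components.
#' @export
graph_components <- function(W, threshold = 0.1) {
  A <- (W >= threshold) | (t(W) >= threshold)
  keep <- which(rowSums(A) > 0)
  if (!length(keep)) return(0L)
  A <- A[keep, keep, drop = FALSE]
  n <- length(keep)
  comp <- integer(n)
  ncomp <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    ncomp <- ncomp + 1L
    queue <- v
    comp[v] <- ncomp
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(A[u, ] & comp == 0L)
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  ncomp
}
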