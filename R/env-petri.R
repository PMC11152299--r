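# Linear Petri-dish environments for the larval olfactory conditioning
# paradigm: five locations (0..4), an odour layout and optional fructose
# substrate per dish, and a 5-action / 5-perceptual-state maggot model.
#
# Actions (1-based R index <-> published action node number - 1):
#   1 none; 2 appetitive AM; 3 aversive AM; 4 appetitive OCT; 5 aversive OCT
# Perceptual state nodes (1-based <-> published node number - 1):
#   1 default; 2 AM; 3 OCT; 4 both odours; 5 fructose
# In two-odour dishes AM decreases (and OCT increases) left to right, so
# "appetitive AM" moves left; in single-odour dishes there is no gradient
# and the four move actions step left or right at random.

.petri_layouts <- list(
  AAN = list(odour = "AM",  fructose = FALSE),
  AAF = list(odour = "AM",  fructose = TRUE),
  OON = list(odour = "OCT", fructose = FALSE),
  OOF = list(odour = "OCT", fructose = TRUE),
  AON = list(odour = "BOTH", fructose = FALSE),
  AOF = list(odour = "BOTH", fructose = TRUE)
)

#' A linear Petri dish
#'
#' The six dishes of the conditioning paradigm: uniform single-odour
#' training dishes (AAN, AAF, OON, OOF) and two-odour test dishes (AON,
#' AOF) where locations 0-1 carry amylacetate (AM), location 2 the
#' mixture, and locations 3-4 1-octanol (OCT). Dishes whose name ends in F
#' contain fructose (the appetitive reinforcer) uniformly in the
#' substrate.
#'
#' @param name One of `"AAN"`, `"AAF"`, `"OON"`, `"OOF"`, `"AON"`,
#'   `"AOF"`.
#' @return A list of class `petri_dish` with `name`, `fructose`,
#'   `gradient` (TRUE for two-odour dishes) and `odours_at` — a list
#'   giving the odours present at each of the 5 locations.
#' @export
petri_dish <- function(name) {
  name <- match.arg(name, names(.petri_layouts))
  lay <- .petri_layouts[[name]]
  odours_at <- if (lay$odour == "BOTH") {
    list(c("AM"), c("AM"), c("AM", "OCT"), c("OCT"), c("OCT"))
  } else {
    rep(list(lay$odour), 5L)
  }
  structure(list(name = name, fructose = lay$fructose,
                 gradient = lay$odour == "BOTH", odours_at = odours_at),
            class = "petri_dish")
}

#' Perceptual state at a Petri-dish location
#'
#' Priority mapping of perception to state node: fructose (5) beats both
#' odours (4) beats OCT (3) beats AM (2) beats the no-odour default (1).
#' Fructose is perceived only on the step at which it was consumed.
#'
#' @param dish A [petri_dish()].
#' @param position Location 0..4.
#' @param consumed Whether fructose was consumed on this step.
#' @return State node index 1..5.
#' @export
petri_perceive <- function(dish, position, consumed = FALSE) {
  if (consumed) return(5L)
  od <- dish$odours_at[[position + 1L]]
  if (all(c("AM", "OCT") %in% od)) return(4L)
  if ("OCT" %in% od) return(3L)
  if ("AM" %in% od) return(2L)
  1L
}

#' Step the Petri-dish environment
#'
#' Moves the maggot along (appetitive) or against (aversive) the gradient
#' of the action's odour — or left/right at random when the dish has no
#' gradient — clipping the position to the dish. The reinforcer is
#' experienced iff the dish contains fructose, the action was appetitive,
#' and the move lands in a location containing the approached odour.
#'
#' @param dish A [petri_dish()].
#' @param position Current location 0..4.
#' @param action Action index 1..5 (none, appetitive AM, aversive AM,
#'   appetitive OCT, aversive OCT).
#' @return List with `position`, perceptual `state` (1..5) and `reward`
#'   (1 if fructose was consumed, else 0).
#' @export
petri_step <- function(dish, position, action) {
  stopifnot(position >= 0L, position <= 4L, action >= 1L, action <= 5L)
  move <- 0L
  if (action > 1L) {
    if (dish$gradient) {
      # AM is up-gradient to the left, OCT to the right
      move <- switch(action - 1L, -1L, +1L, +1L, -1L)
    } else {
      move <- if (runif(1) < 0.5) -1L else 1L
    }
  }
  pos2 <- min(max(position + move, 0L), 4L)
  odour <- if (action == 2L) "AM" else if (action == 4L) "OCT" else NA
  consumed <- dish$fructose && !is.na(odour) &&
    odour %in% dish$odours_at[[pos2 + 1L]]
  list(position = pos2, state = petri_perceive(dish, pos2, consumed),
       reward = if (consumed) 1 else 0)
}

.protocols <- list(
  `1` = list(train = rep(c("AAF", "OON"), 3L), test = "AON"),
  `2` = list(train = rep(c("OOF", "AAN"), 3L), test = "AON"),
  `3` = list(train = rep(c("AAF", "OON"), 3L), test = "AOF"),
  `4` = list(train = rep(c("OOF", "AAN"), 3L), test = "AOF")
)

#' Run one conditioning protocol for a population of maggot models
#'
#' Each maggot is an independent dynamic routing agent (5 perceptual
#' states, 5 actions, slow-learning parameter preset). It passes through
#' the protocol's six training dishes and then the test dish, 40 steps in
#' each, starting every dish at the middle location; learning continues
#' during testing. During the test dish the number of maggots on the AM
#' side (locations 0-1) and the OCT side (locations 3-4) is counted at
#' every step; the middle location counts toward neither side.
#'
#' @param protocol Protocol number 1..4 (1: train AM+/OCT, test AON; 2:
#'   train AM/OCT+, test AON; 3: train AM+/OCT, test AOF; 4: train
#'   AM/OCT+, test AOF).
#' @param n_maggots Number of naive maggot models, default 30.
#' @param steps_per_dish Steps spent in each dish, default 40.
#' @param params Agent parameters (maggot preset by default).
#' @return A tibble with one row per test step: `protocol`, `dish`,
#'   `step`, `n_am`, `n_oct`, `n_total`, `pref` (the preference index
#'   `(n_am - n_oct) / n_total`).
#' @export
run_maggot_protocol <- function(protocol, n_maggots = 30L,
                                steps_per_dish = 40L,
                                params = agent_params("maggot")) {
  proto <- .protocols[[as.character(protocol)]]
  if (is.null(proto)) stop("protocol must be 1, 2, 3 or 4")
  dishes <- c(proto$train, proto$test)
  test_idx <- length(dishes)
  counts_am <- integer(steps_per_dish)
  counts_oct <- integer(steps_per_dish)
  for (m in seq_len(n_maggots)) {
    agent <- drm_agent(5L, params, n_actions = 5L)
    for (di in seq_along(dishes)) {
      dish <- petri_dish(dishes[di])
      pos <- 2L  # middle location
      s <- petri_perceive(dish, pos)
      r <- 0
      agent_begin_episode(agent, s)
      for (t in seq_len(steps_per_dish)) {
        a <- agent_step(agent, s, r, available = 1:5)
        res <- petri_step(dish, pos, a)
        pos <- res$position
        s <- res$state
        r <- res$reward
        if (di == test_idx) {
          if (pos <= 1L) counts_am[t] <- counts_am[t] + 1L
          if (pos >= 3L) counts_oct[t] <- counts_oct[t] + 1L
        }
      }
      # absorb learning of the final transition before the dish changes
      agent_step(agent, s, r, terminal = TRUE)
    }
  }
  tibble::tibble(protocol = as.integer(protocol), dish = proto$test,
                 step = seq_len(steps_per_dish),
                 n_am = counts_am, n_oct = counts_oct,
                 n_total = as.integer(n_maggots),
                 pref = (counts_am - counts_oct) / n_maggots)
}

#' Run all four protocols and compute per-step learning indexes
#'
#' The learning index contrasts reciprocal protocols to control for innate
#' side bias: `LI = (PREF[odour+ training] - PREF[reciprocal]) / 2`,
#' computed per test step. Protocols 1 vs 2 give the index for maggots
#' trained with fructose and tested without (FN); protocols 3 vs 4 for
#' maggots trained and tested with fructose (FF). Positive LI indicates
#' appetitive memory.
#'
#' @inheritParams run_maggot_protocol
#' @return A tibble with columns `condition` ("FN" or "FF"), `step`, `li`.
#' @export
run_maggot_experiment <- function(n_maggots = 30L, steps_per_dish = 40L,
                                  params = agent_params("maggot")) {
  prefs <- lapply(1:4, function(p) {
    run_maggot_protocol(p, n_maggots, steps_per_dish, params)$pref
  })
  dplyr::bind_rows(
    tibble::tibble(condition = "FN", step = seq_len(steps_per_dish),
                   li = learning_index(prefs[[1]], prefs[[2]])),
    tibble::tibble(condition = "FF", step = seq_len(steps_per_dish),
                   li = learning_index(prefs[[3]], prefs[[4]]))
  )
}
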