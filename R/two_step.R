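# Hybrid model-based / model-free learner for the two-stage sequential task.
# Two equivalent initial states hold two spaceships each; spaceships A and C
# fly deterministically to alien 1, B and D to alien 2, so a model-based
# controller can transfer outcome information across initial states while a
# model-free controller cannot.

TWO_STEP_SHIPS <- list(`1` = c("A", "B"), `2` = c("C", "D"))

#' Parameters of the hybrid two-stage learner
#'
#' @param alpha learning rate in \[0, 1\].
#' @param beta inverse temperature, >= 0.
#' @param lam eligibility-trace decay in \[0, 1\].
#' @param pi perseveration weight on repeating the previously visited alien.
#' @param rho stickiness weight on repeating the previous response key.
#' @param w model-based weight in \[0, 1\]; the habit index reported from a
#'   fit is [two_step_habit_index()], i.e. `1 - w`.
#' @return list of class `two_step_params`.
#' @export
two_step_params <- function(alpha, beta, lam, pi, rho, w) {
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, lam >= 0, lam <= 1,
            w >= 0, w <= 1, is.finite(pi), is.finite(rho))
  structure(list(alpha = alpha, beta = beta, lam = lam, pi = pi, rho = rho, w = w),
            class = "two_step_params")
}

#' Habit index from the model-based weight
#'
#' The fitted model-based weight `w` is inverted so that values near 1 mean
#' predominantly model-free (presumed habitual) control.
#'
#' @param w model-based weight in \[0, 1\].
#' @return `1 - w`.
#' @export
two_step_habit_index <- function(w) {
  stopifnot(all(w >= 0 & w <= 1))
  1 - w
}

#' Fresh learner state for the two-stage task
#'
#' @return list with `q_mf` (2 states x 2 actions), alien values `v`, and the
#'   previous trial's alien and response key (`NA` before the first trial).
#' @export
init_two_step_state <- function() {
  list(q_mf = matrix(0, 2, 2), v = c(0, 0),
       prev_alien = NA_integer_, prev_key = NA_character_)
}

two_step_action_index <- function(state_id, ship) {
  match(ship, TWO_STEP_SHIPS[[as.character(state_id)]])
}

# Choice probability of the left spaceship given learner state and trial layout.
two_step_p_left <- function(params, st, state_id, left_ship, right_ship, transition) {
  a <- vapply(c(left_ship, right_ship), two_step_action_index,
              integer(1), state_id = state_id)
  aliens <- transition[c(left_ship, right_ship)]
  q_net <- params$w * st$v[aliens] + (1 - params$w) * st$q_mf[state_id, a]
  rep_alien <- if (is.na(st$prev_alien)) c(0, 0) else as.numeric(aliens == st$prev_alien)
  rep_key <- if (is.na(st$prev_key)) c(0, 0) else
    as.numeric(c("left", "right") == st$prev_key)
  plogis(params$beta * (q_net[1] - q_net[2]) +
           params$pi * (rep_alien[1] - rep_alien[2]) +
           params$rho * (rep_key[1] - rep_key[2]))
}

two_step_update <- function(params, st, state_id, ship, alien, reward) {
  a <- two_step_action_index(state_id, ship)
  d1 <- st$v[alien] - st$q_mf[state_id, a]
  st$q_mf[state_id, a] <- st$q_mf[state_id, a] + params$alpha * d1
  d2 <- reward - st$v[alien]
  st$v[alien] <- st$v[alien] + params$alpha * d2
  st$q_mf[state_id, a] <- st$q_mf[state_id, a] + params$alpha * params$lam * d2
  st$prev_alien <- alien
  st
}

#' One trial of the hybrid two-stage learner
#'
#' Samples the spaceship choice (softmax over the net values
#' `w Q_mb + (1 - w) Q_mf` plus perseveration and key-stickiness bonuses),
#' observes the reached alien's outcome, and applies the model-free update
#' with eligibility trace (`delta_1` to `Q_mf`, then `delta_2` to the alien
#' value and, weighted by `lam`, to `Q_mf`).
#'
#' @param params a [two_step_params()].
#' @param st learner state from [init_two_step_state()].
#' @param trial list with `state` (1 or 2), `left_ship`, `right_ship`, and
#'   `outcomes` (points for aliens 1 and 2 on this trial).
#' @param config a [two_step_config()] (supplies the transition map).
#' @return list with the `choice` (ship, key, alien, reward) and updated `state`.
#' @export
two_step_hybrid_step <- function(params, st, trial, config) {
  stopifnot(inherits(params, "two_step_params"), inherits(config, "two_step_config"))
  p_left <- two_step_p_left(params, st, trial$state, trial$left_ship,
                            trial$right_ship, config$transition)
  take_left <- runif(1) < p_left
  ship <- if (take_left) trial$left_ship else trial$right_ship
  key <- if (take_left) "left" else "right"
  alien <- config$transition[[ship]]
  reward <- trial$outcomes[alien]
  st <- two_step_update(params, st, trial$state, ship, alien, reward)
  st$prev_key <- key
  list(choice = list(ship = ship, key = key, alien = alien, reward = reward),
       state = st)
}

#' Simulate a full two-stage session
#'
#' Initial state and spaceship screen sides are randomised per trial; alien
#' outcomes follow the supplied random walks.
#'
#' @inheritParams two_step_hybrid_step
#' @param walks outcome matrix from [build_two_step_walks()].
#' @param seed integer seed.
#' @return data frame with one row per trial: `trial`, `state`, `left_ship`,
#'   `right_ship`, `chosen_ship`, `key_side`, `alien`, `points`.
#' @export
simulate_two_step <- function(params, walks, config, seed = 1L) {
  stopifnot(nrow(walks) >= 1)
  with_seed(seed, {
    st <- init_two_step_state()
    n <- nrow(walks)
    out <- data.frame(trial = seq_len(n), state = NA_integer_,
                      left_ship = NA_character_, right_ship = NA_character_,
                      chosen_ship = NA_character_, key_side = NA_character_,
                      alien = NA_integer_, points = NA_integer_,
                      stringsAsFactors = FALSE)
    for (t in seq_len(n)) {
      s <- sample(1:2, 1)
      ships <- sample(TWO_STEP_SHIPS[[as.character(s)]])
      step <- two_step_hybrid_step(params, st,
                                   list(state = s, left_ship = ships[1],
                                        right_ship = ships[2],
                                        outcomes = walks[t, ]),
                                   config)
      st <- step$state
      out$state[t] <- s
      out$left_ship[t] <- ships[1]
      out$right_ship[t] <- ships[2]
      out$chosen_ship[t] <- step$choice$ship
      out$key_side[t] <- step$choice$key
      out$alien[t] <- step$choice$alien
      out$points[t] <- step$choice$reward
    }
    out
  })
}

# Replayed negative log-likelihood of a two-stage session log under the
# hybrid learner; updates are driven by the observed choices and outcomes.
nll_two_step <- function(params, log) {
  stopifnot(inherits(params, "two_step_params"))
  transition <- c(A = 1L, B = 2L, C = 1L, D = 2L)
  st <- init_two_step_state()
  nll <- 0
  for (t in seq_len(nrow(log))) {
    p_left <- two_step_p_left(params, st, log$state[t], log$left_ship[t],
                              log$right_ship[t], transition)
    chose_left <- log$chosen_ship[t] == log$left_ship[t]
    p <- if (chose_left) p_left else 1 - p_left
    nll <- nll - log(max(p, 1e-12))
    st <- two_step_update(params, st, log$state[t], log$chosen_ship[t],
                          log$alien[t], log$points[t])
    st$prev_key <- log$key_side[t]
  }
  nll
}
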