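# Generative choice models for the two binary-choice tasks. Learned values q
# (reinforcement) and ck (choice kernel) live on [0,1]: point outcomes are
# rescaled by /9 so both controllers share a scale, which is what makes the
# reduced model's constraint beta_q = 10 - beta_h interpretable (equal
# weighting at beta_h = 5).

MODEL_IDS <- c("random", "rl", "ck", "rl_ck", "rl_ck_reduced")
REWARD_SCALE <- 9

#' Inverse temperature of the reinforcement controller in the reduced model
#'
#' In the reduced combined model the two inverse temperatures are tied:
#' `beta_q = 10 - beta_h`, so more weight on choice frequency automatically
#' means less weight on reinforcement value. The two controllers are weighted
#' equally where `beta_q == beta_h`.
#'
#' @param beta_h choice-kernel inverse temperature in \[0, 10\].
#' @return the implied reinforcement inverse temperature.
#' @export
reduced_beta_q <- function(beta_h) {
  stopifnot(all(beta_h >= 0 & beta_h <= 10))
  10 - beta_h
}

#' Parameters of one candidate choice model
#'
#' @param model_id one of `"random"` (no parameters), `"rl"` (`alpha_q`,
#'   `beta_q`), `"ck"` (`alpha_h`, `beta_h`), `"rl_ck"` (all four), or
#'   `"rl_ck_reduced"` (`alpha_q`, `alpha_h`, `beta_h`, with
#'   `beta_q = 10 - beta_h`).
#' @param alpha_q,alpha_h learning rates in \[0, 1\].
#' @param beta_q,beta_h inverse temperatures in \[0, 10\].
#' @return list of class `model_params`.
#' @export
model_params <- function(model_id, alpha_q = NULL, beta_q = NULL,
                         alpha_h = NULL, beta_h = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  need <- model_param_names(model_id)
  given <- list(alpha_q = alpha_q, beta_q = beta_q,
                alpha_h = alpha_h, beta_h = beta_h)
  for (nm in need) {
    v <- given[[nm]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("model '", model_id, "' requires scalar parameter '", nm, "'",
           call. = FALSE)
    lim <- if (startsWith(nm, "alpha")) c(0, 1) else c(0, 10)
    if (v < lim[1] || v > lim[2])
      stop("'", nm, "' must lie in [", lim[1], ", ", lim[2], "]", call. = FALSE)
  }
  p <- given[need]
  if (model_id == "rl_ck_reduced") p$beta_q <- reduced_beta_q(p$beta_h)
  structure(c(list(model_id = model_id), p), class = "model_params")
}

model_param_names <- function(model_id) {
  switch(model_id,
         random = character(0),
         rl = c("alpha_q", "beta_q"),
         ck = c("alpha_h", "beta_h"),
         rl_ck = c("alpha_q", "beta_q", "alpha_h", "beta_h"),
         rl_ck_reduced = c("alpha_q", "alpha_h", "beta_h"))
}

# Effective (beta_q, beta_h, alpha_q, alpha_h) with zeros for absent
# components; the likelihood kernel consumes this flat form.
effective_params <- function(params) {
  stopifnot(inherits(params, "model_params"))
  g <- function(nm, default = 0) if (is.null(params[[nm]])) default else params[[nm]]
  c(alpha_q = g("alpha_q"), beta_q = g("beta_q"),
    alpha_h = g("alpha_h"), beta_h = g("beta_h"))
}

#' Initial learner state
#'
#' @param stimuli character vector of stimulus ids.
#' @param q0,ck0 initial reinforcement and choice-kernel values (default the
#'   unbiased midpoint 0.5).
#' @return list of class `rl_state` with named vectors `q` and `ck`.
#' @export
init_rl_state <- function(stimuli, q0 = 0.5, ck0 = 0.5) {
  stopifnot(length(stimuli) >= 2, !anyDuplicated(stimuli),
            q0 >= 0, q0 <= 1, ck0 >= 0, ck0 <= 1)
  structure(list(q = setNames(rep(q0, length(stimuli)), stimuli),
                 ck = setNames(rep(ck0, length(stimuli)), stimuli)),
            class = "rl_state")
}

check_stims <- function(state, ...) {
  ids <- c(...)
  missing <- setdiff(ids, names(state$q))
  if (length(missing))
    stop("unknown stimulus: ", paste(missing, collapse = ", "), call. = FALSE)
}

#' Probability of choosing the left stimulus
#'
#' Logistic choice rule over the weighted value differences:
#' `P(left) = logistic(beta_q (q_L - q_R) + beta_h (ck_L - ck_R))`.
#' The random model returns 0.5 regardless of state.
#'
#' @param state an [init_rl_state()] object.
#' @param params a [model_params()] object.
#' @param left,right stimulus ids shown on each side.
#' @return probability in (0, 1).
#' @export
choice_probability <- function(state, params, left, right) {
  check_stims(state, left, right)
  if (params$model_id == "random") return(0.5)
  ep <- effective_params(params)
  plogis(ep[["beta_q"]] * (state$q[[left]] - state$q[[right]]) +
           ep[["beta_h"]] * (state$ck[[left]] - state$ck[[right]]))
}

#' Delta-rule reinforcement update
#'
#' `q_s <- q_s + alpha_q (r_s - q_s)` for the stimuli selected by `feedback`:
#' in training both outcomes were displayed (`"both"`), `"chosen_only"` is a
#' sensitivity variant, and in the test phase no outcomes are shown
#' (`"none"`). Rewards must already be on the \[0,1\] scale (points / 9).
#'
#' @inheritParams choice_probability
#' @param chosen,unchosen stimulus ids.
#' @param r_chosen,r_unchosen rescaled rewards in \[0, 1\].
#' @param alpha_q learning rate in \[0, 1\].
#' @param feedback which outcomes drive learning.
#' @return updated state.
#' @export
rl_update <- function(state, chosen, unchosen, r_chosen, r_unchosen, alpha_q,
                      feedback = c("both", "chosen_only", "none")) {
  feedback <- match.arg(feedback)
  check_stims(state, chosen, unchosen)
  if (alpha_q < 0 || alpha_q > 1) stop("'alpha_q' must lie in [0, 1]", call. = FALSE)
  if (feedback %in% c("both", "chosen_only"))
    state$q[[chosen]] <- state$q[[chosen]] + alpha_q * (r_chosen - state$q[[chosen]])
  if (feedback == "both")
    state$q[[unchosen]] <- state$q[[unchosen]] + alpha_q * (r_unchosen - state$q[[unchosen]])
  state
}

#' Choice-kernel update
#'
#' The kernel tracks recent choice frequency: the chosen stimulus moves toward
#' 1, the unchosen toward 0, stimuli not on screen are untouched. Applied on
#' every completed trial of training *and* test (choosing happens even when
#' outcomes are hidden).
#'
#' @inheritParams rl_update
#' @param alpha_h kernel learning rate in \[0, 1\].
#' @return updated state.
#' @export
ck_update <- function(state, chosen, unchosen, alpha_h) {
  check_stims(state, chosen, unchosen)
  if (alpha_h < 0 || alpha_h > 1) stop("'alpha_h' must lie in [0, 1]", call. = FALSE)
  state$ck[[chosen]] <- state$ck[[chosen]] + alpha_h * (1 - state$ck[[chosen]])
  state$ck[[unchosen]] <- state$ck[[unchosen]] + alpha_h * (0 - state$ck[[unchosen]])
  state
}

#' Simulate an agent on a schedule
#'
#' Samples a choice from [choice_probability()] on every trial, then applies
#' [ck_update()] always and [rl_update()] on training trials where a reward
#' map is supplied (per-trial outcomes are deterministic stimulus values).
#' Test-phase trials update only the choice kernel.
#'
#' @param params a [model_params()] object.
#' @param schedule a schedule data frame from the schedule builders.
#' @param reward_map named numeric vector of point values per stimulus, or
#'   `NULL` for the unrewarded task.
#' @param seed integer seed for choice sampling.
#' @param state carried-over learner state; defaults to a fresh
#'   [init_rl_state()] over the schedule's stimuli.
#' @param feedback feedback regime for training-phase reinforcement updates.
#' @param miss_prob per-trial probability that no response is recorded
#'   (missed trials trigger no learning update).
#' @return list with `log` (trial-log data frame with responses filled),
#'   the final `state`, and `signals`, a per-trial data frame of the
#'   decision-time value differences `q_diff` and `ck_diff` (left minus
#'   right; `NA` on missed trials).
#' @export
simulate_task <- function(params, schedule, reward_map = NULL, seed = 1L,
                          state = NULL, feedback = "both", miss_prob = 0) {
  stopifnot(inherits(params, "model_params"))
  stims <- sort(unique(c(schedule$left_stim, schedule$right_stim)))
  if (is.null(state)) state <- init_rl_state(stims)
  check_stims(state, stims)
  if (!is.null(reward_map)) {
    if (!all(stims %in% names(reward_map)))
      stop("reward_map must cover every scheduled stimulus", call. = FALSE)
  }
  log <- schedule
  log$choice_side <- NA_character_
  log$chosen_stim <- NA_character_
  log$outcome_points_left <- NA_integer_
  log$outcome_points_right <- NA_integer_
  log$rt_ms <- NA_integer_
  log$missed <- 0L
  signals <- data.frame(q_diff = rep(NA_real_, nrow(log)),
                        ck_diff = rep(NA_real_, nrow(log)))
  ep <- effective_params(params)
  stopifnot(miss_prob >= 0, miss_prob < 0.5)
  with_seed(seed, {
    for (i in seq_len(nrow(log))) {
      if (miss_prob > 0 && runif(1) < miss_prob) {
        log$missed[i] <- 1L
        next
      }
      left <- log$left_stim[i]; right <- log$right_stim[i]
      signals$q_diff[i] <- state$q[[left]] - state$q[[right]]
      signals$ck_diff[i] <- state$ck[[left]] - state$ck[[right]]
      p_left <- choice_probability(state, params, left, right)
      take_left <- runif(1) < p_left
      chosen <- if (take_left) left else right
      unchosen <- if (take_left) right else left
      log$choice_side[i] <- if (take_left) "left" else "right"
      log$chosen_stim[i] <- chosen
      training <- identical(log$phase[i], "training")
      if (training && !is.null(reward_map)) {
        log$outcome_points_left[i] <- as.integer(reward_map[[left]])
        log$outcome_points_right[i] <- as.integer(reward_map[[right]])
        state <- rl_update(state, chosen, unchosen,
                           reward_map[[chosen]] / REWARD_SCALE,
                           reward_map[[unchosen]] / REWARD_SCALE,
                           ep[["alpha_q"]], feedback)
      }
      state <- ck_update(state, chosen, unchosen, ep[["alpha_h"]])
    }
  })
  list(log = log, state = state, signals = signals)
}

#' Simulate instructed-choice training of the unrewarded task
#'
#' The agent follows the cue with probability `compliance`; completed trials
#' drive a choice-kernel update with rate `alpha_h`, and a configurable miss
#' probability leaves trials unanswered (no update).
#'
#' @param compliance probability of choosing the cued stimulus, in \[0.5, 1\].
#' @param schedule training schedule from [build_unrewarded_training_session()].
#' @param alpha_h choice-kernel learning rate used for the simulated learner.
#' @param miss_prob per-trial probability of a missed response.
#' @inheritParams simulate_task
#' @return list with `log`, the final `state`, and per-trial `signals` as in
#'   [simulate_task()].
#' @export
simulate_unrewarded_training <- function(compliance, schedule, alpha_h = 0.1,
                                         seed = 1L, state = NULL, miss_prob = 0) {
  stopifnot(compliance >= 0.5, compliance <= 1, miss_prob >= 0, miss_prob < 0.5)
  stims <- sort(unique(c(schedule$left_stim, schedule$right_stim)))
  if (is.null(state)) state <- init_rl_state(stims)
  log <- schedule
  log$choice_side <- NA_character_
  log$chosen_stim <- NA_character_
  log$outcome_points_left <- NA_integer_
  log$outcome_points_right <- NA_integer_
  log$rt_ms <- NA_integer_
  log$missed <- 0L
  signals <- data.frame(q_diff = rep(NA_real_, nrow(log)),
                        ck_diff = rep(NA_real_, nrow(log)))
  with_seed(seed, {
    for (i in seq_len(nrow(log))) {
      if (miss_prob > 0 && runif(1) < miss_prob) {
        log$missed[i] <- 1L
        next
      }
      signals$q_diff[i] <- 0
      signals$ck_diff[i] <- state$ck[[log$left_stim[i]]] - state$ck[[log$right_stim[i]]]
      cue <- log$cue_side[i]
      obey <- runif(1) < compliance
      side <- if (obey) cue else setdiff(c("left", "right"), cue)
      chosen <- if (side == "left") log$left_stim[i] else log$right_stim[i]
      unchosen <- if (side == "left") log$right_stim[i] else log$left_stim[i]
      log$choice_side[i] <- side
      log$chosen_stim[i] <- chosen
      state <- ck_update(state, chosen, unchosen, alpha_h)
    }
  })
  list(log = log, state = state, signals = signals)
}
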