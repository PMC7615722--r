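# Schedule generators. All schedules are data frames in the trial-log layout
# (see write_trial_log) with the response columns left empty; counts are fixed
# by the design and invariant to the seed, which only permutes trial order and
# resolves side assignments.

RP_WINDOW_MS <- 800L
UH_WINDOW_MS <- 500L

#' Stimulus set of the rewarded stimulus-pair learning task
#'
#' Eight stimuli with deterministic point values \{1,3,3,5,5,7,7,9\}. At each
#' intermediate value (3, 5, 7) one stimulus is *frequent* (paired mostly with
#' a less valuable partner during training, hence chosen often by a reward
#' maximiser) and one is *rare* (the reverse); the 1- and 9-point stimuli are
#' value extremes.
#'
#' @return data frame with columns `id`, `reward_value`, `role`.
#' @export
reward_pairs_stimuli <- function() {
  data.frame(
    id = c("v1", "v3f", "v3r", "v5f", "v5r", "v7f", "v7r", "v9"),
    reward_value = c(1L, 3L, 3L, 5L, 5L, 7L, 7L, 9L),
    role = c("extreme", "frequent", "rare", "frequent", "rare",
             "frequent", "rare", "extreme"),
    stringsAsFactors = FALSE
  )
}

#' Stimulus set of the unrewarded instructed-choice task
#'
#' Two pairs of four stimuli: in one pair the cue instructs one stimulus on
#' 80% of trials (`freq80` vs `rare20`); in the other both are cued equally
#' (`even50a`/`even50b`). Screen sides are fixed within participant.
#'
#' @param sides named character vector mapping the four stimulus ids to
#'   `"left"`/`"right"`; one stimulus of each pair must sit on each side.
#' @return data frame with columns `id`, `role`, `fixed_side`.
#' @export
unrewarded_stimuli <- function(sides = c(f80 = "left", r20 = "right",
                                         e50a = "left", e50b = "right")) {
  ids <- c("f80", "r20", "e50a", "e50b")
  stopifnot(setequal(names(sides), ids),
            all(sides %in% c("left", "right")),
            sides[["f80"]] != sides[["r20"]],
            sides[["e50a"]] != sides[["e50b"]])
  data.frame(
    id = ids,
    role = c("freq80", "rare20", "even50a", "even50b"),
    fixed_side = unname(sides[ids]),
    stringsAsFactors = FALSE
  )
}

# Per-session pairing table: each row is an unordered stimulus pair and how
# often it is shown. Frequent stimuli meet their value-2 neighbour 30 times
# and their value+2 neighbour 10 times; rare stimuli the reverse. Row/column
# sums give every stimulus exactly 40 appearances and force the 640/960
# obtainable-point bounds whatever the seed.
reward_pairs_pairing_table <- function() {
  data.frame(
    a = c("v1", "v1", "v3f", "v3r", "v5f", "v5r", "v7f", "v7r"),
    b = c("v3f", "v3r", "v5r", "v5f", "v7r", "v7f", "v9", "v9"),
    count = c(30L, 10L, 10L, 30L, 10L, 30L, 10L, 30L),
    stringsAsFactors = FALSE
  )
}

empty_schedule <- function(n) {
  data.frame(
    task = character(n), phase = character(n), day = integer(n),
    index = integer(n), left_stim = character(n), right_stim = character(n),
    cue_side = character(n), response_window_ms = integer(n),
    stringsAsFactors = FALSE
  )
}

# Expand a pairing table into trials with per-pair balanced side assignment;
# an odd per-side split is resolved by a coin flip from the active RNG.
expand_pairs <- function(pairs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    n <- pairs$count[i]
    n_a_left <- n %/% 2L + if (n %% 2L == 1L && runif(1) < 0.5) 1L else 0L
    a_left <- sample(rep(c(TRUE, FALSE), c(n_a_left, n - n_a_left)))
    data.frame(
      left_stim  = ifelse(a_left, pairs$a[i], pairs$b[i]),
      right_stim = ifelse(a_left, pairs$b[i], pairs$a[i]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

finish_schedule <- function(trials, task, phase, day, window,
                            cue_side = "none", shuffle = TRUE) {
  if (shuffle) trials <- trials[sample(nrow(trials)), , drop = FALSE]
  out <- empty_schedule(nrow(trials))
  out$task <- task
  out$phase <- phase
  out$day <- as.integer(day)
  out$index <- seq_len(nrow(trials)) - 1L
  out$left_stim <- trials$left_stim
  out$right_stim <- trials$right_stim
  out$cue_side <- if (length(cue_side) == 1L) rep(cue_side, nrow(trials)) else trials$cue_side
  out$response_window_ms <- as.integer(window)
  out
}

check_day <- function(day) {
  if (!is.numeric(day) || length(day) != 1L || is.na(day) || day < 1 || day > 5 ||
      day != round(day))
    stop("'day' must be an integer between 1 and 5", call. = FALSE)
  as.integer(day)
}

#' Training schedule for one session of the rewarded pair task
#'
#' 160 trials in which each of the eight stimuli appears exactly 40 times,
#' frequent stimuli 30 times with their lower-valued and 10 times with their
#' higher-valued neighbour (rare stimuli the reverse). A reward maximiser
#' earns 960 points per session, the worst possible policy 640.
#'
#' @param day session day, 1-5.
#' @param seed integer seed; only the trial order and odd side splits depend
#'   on it.
#' @return trial-schedule data frame (see [write_trial_log()] for columns).
#' @export
build_reward_pairs_training_session <- function(day, seed) {
  day <- check_day(day)
  with_seed(seed, {
    trials <- expand_pairs(reward_pairs_pairing_table())
    finish_schedule(trials, "reward_pairs", "training", day, RP_WINDOW_MS)
  })
}

#' Test schedule for the rewarded pair task
#'
#' Every unordered pair of the eight stimuli appears four times, plus eight
#' extra presentations of each of the three same-reward pairs: 136 trials,
#' sides balanced within pair.
#'
#' @param seed integer seed.
#' @param day nominal day of the test phase (5 after training; 1 for the
#'   pre-training test).
#' @inherit build_reward_pairs_training_session return
#' @export
build_reward_pairs_test <- function(seed, day = 5) {
  day <- check_day(day)
  stim <- reward_pairs_stimuli()
  cmb <- utils::combn(stim$id, 2)
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ], count = 4L,
                      stringsAsFactors = FALSE)
  same <- data.frame(a = c("v3f", "v5f", "v7f"), b = c("v3r", "v5r", "v7r"),
                     count = 8L, stringsAsFactors = FALSE)
  with_seed(seed, {
    trials <- expand_pairs(rbind(pairs, same))
    finish_schedule(trials, "reward_pairs", "test", day, RP_WINDOW_MS)
  })
}

#' Training schedule for one session of the unrewarded instructed-choice task
#'
#' Six blocks of 20 trials per stimulus pair (240 trials), with blocks of the
#' two pairs interleaved in alternation from a seeded starting pair. In the
#' 80/20 pair the cue points to the frequent stimulus on exactly 16 of each
#' block's 20 trials; in the even pair on 10. Stimulus screen sides are fixed
#' by `sides`.
#'
#' @inheritParams build_reward_pairs_training_session
#' @param sides side mapping as in [unrewarded_stimuli()].
#' @export
build_unrewarded_training_session <- function(day, seed,
                                              sides = c(f80 = "left", r20 = "right",
                                                        e50a = "left", e50b = "right")) {
  day <- check_day(day)
  stim <- unrewarded_stimuli(sides)
  side_of <- setNames(stim$fixed_side, stim$id)
  pair_block <- function(a, b, n_cue_a) {
    cued <- sample(rep(c(a, b), c(n_cue_a, 20L - n_cue_a)))
    data.frame(
      left_stim  = ifelse(side_of[[a]] == "left", a, b),
      right_stim = ifelse(side_of[[a]] == "left", b, a),
      cue_side = unname(side_of[cued]),
      stringsAsFactors = FALSE
    )
  }
  with_seed(seed, {
    first <- sample(c("p80", "p50"), 1)
    order12 <- if (first == "p80") c("p80", "p50") else c("p50", "p80")
    blocks <- lapply(seq_len(12L), function(k) {
      pair <- order12[(k - 1L) %% 2L + 1L]
      if (pair == "p80") pair_block("f80", "r20", 16L) else pair_block("e50a", "e50b", 10L)
    })
    trials <- do.call(rbind, blocks)
    finish_schedule(trials, "unrewarded_habit", "training", day, UH_WINDOW_MS,
                    cue_side = trials$cue_side, shuffle = FALSE)
  })
}

#' Test schedule for the unrewarded instructed-choice task
#'
#' 64 free-choice trials (no cue): first the two trained pairs 10 times each
#' in their trained screen locations, then -- randomly interleaved -- each of
#' the four stimuli paired with each other four times with balanced locations
#' (24 trials) plus 10 further presentations of each trained pair in switched
#' locations (20 trials).
#'
#' @inheritParams build_unrewarded_training_session
#' @param day nominal day (5, or 1 for the pre-training test).
#' @export
build_unrewarded_test <- function(seed, day = 5,
                                  sides = c(f80 = "left", r20 = "right",
                                            e50a = "left", e50b = "right")) {
  day <- check_day(day)
  stim <- unrewarded_stimuli(sides)
  side_of <- setNames(stim$fixed_side, stim$id)
  trained_same <- function(a, b, n) {
    la <- side_of[[a]] == "left"
    data.frame(left_stim = rep(if (la) a else b, n),
               right_stim = rep(if (la) b else a, n),
               stringsAsFactors = FALSE)
  }
  trained_switched <- function(a, b, n) {
    la <- side_of[[a]] == "left"
    data.frame(left_stim = rep(if (la) b else a, n),
               right_stim = rep(if (la) a else b, n),
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    head20 <- rbind(trained_same("f80", "r20", 10L), trained_same("e50a", "e50b", 10L))
    head20 <- head20[sample(20L), , drop = FALSE]
    cmb <- utils::combn(stim$id, 2)
    balanced <- expand_pairs(data.frame(a = cmb[1, ], b = cmb[2, ], count = 4L,
                                        stringsAsFactors = FALSE))
    tail44 <- rbind(balanced,
                    trained_switched("f80", "r20", 10L),
                    trained_switched("e50a", "e50b", 10L))
    tail44 <- tail44[sample(nrow(tail44)), , drop = FALSE]
    finish_schedule(rbind(head20, tail44), "unrewarded_habit", "test", day,
                    UH_WINDOW_MS, shuffle = FALSE)
  })
}

#' Configuration for the two-stage task's outcome random walks
#'
#' @param n_trials number of trials.
#' @param walk_sd step standard deviation in points.
#' @param walk_min,walk_max reflecting boundaries in points.
#' @return list of class `two_step_config`, including the deterministic
#'   spaceship-to-alien `transition` map (spaceships A and C fly to alien 1,
#'   B and D to alien 2).
#' @export
two_step_config <- function(n_trials, walk_sd = 2, walk_min = -4, walk_max = 5) {
  stopifnot(n_trials >= 1, walk_sd > 0, walk_min < walk_max)
  structure(list(
    n_trials = as.integer(n_trials), walk_sd = walk_sd,
    walk_min = walk_min, walk_max = walk_max,
    transition = c(A = 1L, B = 2L, C = 1L, D = 2L)
  ), class = "two_step_config")
}

#' Gaussian random-walk outcome sequences for the two aliens
#'
#' Each alien's point value starts at 0 and evolves by mean-zero Gaussian
#' steps (sd `walk_sd`) with reflecting boundaries at `walk_min`/`walk_max`;
#' emitted values are rounded to integers.
#'
#' @param config a [two_step_config()].
#' @param seed integer seed.
#' @return integer matrix `n_trials` x 2 (columns = aliens).
#' @export
build_two_step_walks <- function(config, seed) {
  stopifnot(inherits(config, "two_step_config"))
  reflect <- function(x, lo, hi) {
    while (x < lo || x > hi) {
      if (x > hi) x <- 2 * hi - x
      if (x < lo) x <- 2 * lo - x
    }
    x
  }
  with_seed(seed, {
    out <- matrix(0L, config$n_trials, 2L,
                  dimnames = list(NULL, c("alien1", "alien2")))
    for (a in 1:2) {
      v <- 0
      for (t in seq_len(config$n_trials)) {
        v <- reflect(v + rnorm(1, 0, config$walk_sd), config$walk_min, config$walk_max)
        out[t, a] <- as.integer(round(v))
      }
    }
    out
  })
}
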