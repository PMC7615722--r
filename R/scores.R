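# Per-participant habit scores. Each score is the printed formula of its
# task; missing inputs propagate to NA, never to silent zeros. RT inputs are
# in seconds (logs store integer milliseconds; the log-level helpers convert
# and discard responses faster than 50 ms).

RT_MIN_S <- 0.05
RT_MIN_CELL <- 3L

score_mean3 <- function(x) {
  stopifnot(length(x) == 3)
  if (anyNA(x)) return(NA_real_)
  mean(x)
}

#' Choice score of the rewarded pair task
#'
#' Mean over the three same-reward pairs of
#' `p(choose frequent) - p(choose rare)`, computed over the test trials that
#' present the same-reward pair. 1 means exclusive preference for the
#' stimulus chosen more often in training, -1 the reverse.
#'
#' @param p_frequent,p_rare length-3 choice proportions in \[0, 1\] for the
#'   frequent and rare member of the 3-, 5- and 7-point pair; `NA` for a pair
#'   with no valid trials.
#' @return score in \[-1, 1\], or `NA` if any pair is missing.
#' @export
reward_pairs_choice_score <- function(p_frequent, p_rare) {
  stopifnot(length(p_frequent) == 3, length(p_rare) == 3,
            all(is.na(p_frequent) | (p_frequent >= 0 & p_frequent <= 1)),
            all(is.na(p_rare) | (p_rare >= 0 & p_rare <= 1)))
  score_mean3(p_frequent - p_rare)
}

#' Response-time score of the rewarded pair task
#'
#' Mean over the three same-reward pairs of
#' `median RT(rare chosen) - median RT(frequent chosen)` in seconds. Bounded
#' by the 0.8 s response window: values near +0.8 mean maximal speeding for
#' frequently trained stimuli.
#'
#' @param mdn_rare,mdn_frequent length-3 median RTs in seconds within
#'   (0.05, 0.8\].
#' @return score in \[-0.8, 0.8\], or `NA` if any cell is missing.
#' @export
reward_pairs_rt_score <- function(mdn_rare, mdn_frequent) {
  stopifnot(length(mdn_rare) == 3, length(mdn_frequent) == 3)
  ok <- function(x) all(is.na(x) | (x > 0 & x <= 0.8))
  stopifnot(ok(mdn_rare), ok(mdn_frequent))
  score_mean3(mdn_rare - mdn_frequent)
}

#' Rating-change score of the rewarded pair task
#'
#' Mean over the three same-reward pairs of the differential pre-to-post
#' rating change, `(post - pre | frequent) - (post - pre | rare)`, on the
#' 0-100 rating scale.
#'
#' @param pre_frequent,post_frequent,pre_rare,post_rare length-3 mean ratings
#'   in \[0, 100\] (the two ratings per stimulus and timepoint averaged
#'   upstream).
#' @return score, or `NA` if any rating is missing.
#' @export
reward_pairs_rating_score <- function(pre_frequent, post_frequent,
                                      pre_rare, post_rare) {
  ratings <- list(pre_frequent, post_frequent, pre_rare, post_rare)
  stopifnot(all(vapply(ratings, length, integer(1)) == 3),
            all(vapply(ratings, function(x)
              all(is.na(x) | (x >= 0 & x <= 100)), logical(1))))
  score_mean3((post_frequent - pre_frequent) - (post_rare - pre_rare))
}

#' Scores of the unrewarded instructed-choice task
#'
#' Single-pair analogues of the rewarded-pair scores for the 80/20 pair:
#' `p(choose frequent) - p(choose rare)`, `median RT(rare) - median
#' RT(frequent)` (seconds, 0.5 s window), and the differential rating change.
#'
#' @param p_frequent,p_rare choice proportions over test trials presenting
#'   the 80/20 pair.
#' @return score, or `NA` on missing input.
#' @export
unrewarded_choice_score <- function(p_frequent, p_rare) {
  stopifnot(length(p_frequent) == 1, length(p_rare) == 1)
  if (is.na(p_frequent) || is.na(p_rare)) return(NA_real_)
  stopifnot(p_frequent >= 0, p_frequent <= 1, p_rare >= 0, p_rare <= 1)
  p_frequent - p_rare
}

#' @rdname unrewarded_choice_score
#' @param mdn_rare,mdn_frequent median RTs in seconds.
#' @export
unrewarded_rt_score <- function(mdn_rare, mdn_frequent) {
  if (is.na(mdn_rare) || is.na(mdn_frequent)) return(NA_real_)
  stopifnot(mdn_rare > 0, mdn_rare <= 0.5, mdn_frequent > 0, mdn_frequent <= 0.5)
  mdn_rare - mdn_frequent
}

#' @rdname unrewarded_choice_score
#' @param pre_frequent,post_frequent,pre_rare,post_rare mean ratings in
#'   \[0, 100\].
#' @export
unrewarded_rating_score <- function(pre_frequent, post_frequent,
                                    pre_rare, post_rare) {
  r <- c(pre_frequent, post_frequent, pre_rare, post_rare)
  if (anyNA(r)) return(NA_real_)
  stopifnot(all(r >= 0 & r <= 100))
  (post_frequent - pre_frequent) - (post_rare - pre_rare)
}

#' Devaluation scores of the stimulus-response-outcome switching task
#'
#' Choice score: `p(choose devalued | test) - p(choose devalued | last
#' training block)`; -1 is perfect goal-directed switching, 0 habitual
#' perseveration. RT switch cost: `median RT(successful switch, test) -
#' median RT(same stimulus before devaluation)` in seconds. Both are computed
#' per devaluation condition (previously high- and low-valued outcome) and
#' averaged with equal weight.
#'
#' @param p_test,p_train per-condition proportions of responses toward the
#'   devalued outcome (length 1 or 2).
#' @param mdn_switch_test,mdn_train per-condition median RTs in seconds;
#'   `NA` when there are no successful switch trials.
#' @return list with `dval_choice`, `dval_rt_switch_cost`, and the
#'   per-condition values.
#' @export
dval_scores <- function(p_test, p_train, mdn_switch_test = NA_real_,
                        mdn_train = NA_real_) {
  stopifnot(length(p_test) == length(p_train),
            length(mdn_switch_test) == length(mdn_train))
  ok_p <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  stopifnot(ok_p(p_test), ok_p(p_train))
  choice_by_cond <- p_test - p_train
  rt_by_cond <- mdn_switch_test - mdn_train
  list(
    dval_choice = if (anyNA(choice_by_cond)) NA_real_ else mean(choice_by_cond),
    dval_rt_switch_cost = if (anyNA(rt_by_cond)) NA_real_ else mean(rt_by_cond),
    choice_by_condition = choice_by_cond,
    rt_by_condition = rt_by_cond
  )
}

#' Behavioral adaptation index of the satiation devaluation task
#'
#' `BAI = [m(bp/s | valued, post) - m(bp/s | valued, pre)] -
#'        [m(bp/s | devalued, post) - m(bp/s | devalued, pre)]`,
#' where pre is the second free-operant training session and post the
#' extinction test. Values near 0 indicate devaluation-insensitive
#' (habitual) responding.
#'
#' @param valued_pre,valued_post,devalued_pre,devalued_post mean button
#'   presses per second, >= 0.
#' @return the index (responses/s).
#' @export
bai <- function(valued_pre, valued_post, devalued_pre, devalued_post) {
  r <- c(valued_pre, valued_post, devalued_pre, devalued_post)
  if (anyNA(r)) return(NA_real_)
  stopifnot(all(r >= 0))
  (valued_post - valued_pre) - (devalued_post - devalued_pre)
}

#' Contingency-degradation ratio score
#'
#' `m(presses | degraded) / [m(presses | degraded) + m(presses |
#' non-degraded)]` over the last day's blocks: 0.5 means equal responding
#' under degraded and intact contingencies (habitual insensitivity), 0 means
#' full sensitivity to degradation.
#'
#' @param degraded,non_degraded mean button presses in the (fully and
#'   partially) degraded vs. contingent blocks, >= 0.
#' @return ratio in \[0, 1\]; `NA` if both means are zero.
#' @export
dgrd_ratio <- function(degraded, non_degraded) {
  if (is.na(degraded) || is.na(non_degraded)) return(NA_real_)
  stopifnot(degraded >= 0, non_degraded >= 0)
  if (degraded + non_degraded == 0) return(NA_real_)
  degraded / (degraded + non_degraded)
}

#' Training-effect magnitude of a habit score
#'
#' `(last-day score - first-day score) / divisor`; the divisor is 2 for the
#' choice/RT scores compared across the two test phases and 1 for the
#' contingency-degradation ratio.
#'
#' @param first_day_score,last_day_score scores on the parent score's scale.
#' @param divisor 2 or 1.
#' @return magnitude, or `NA` if either score is missing.
#' @export
training_effect <- function(first_day_score, last_day_score, divisor = 2) {
  stopifnot(divisor > 0)
  if (is.na(first_day_score) || is.na(last_day_score)) return(NA_real_)
  (last_day_score - first_day_score) / divisor
}

# ---- log-level helpers -------------------------------------------------

rt_seconds <- function(log) {
  rt <- log$rt_ms / 1000
  rt[!is.na(rt) & rt < RT_MIN_S] <- NA
  rt
}

completed <- function(log) {
  keep <- !is.na(log$chosen_stim) & (is.na(log$missed) | log$missed == 0)
  log[keep, , drop = FALSE]
}

pair_trials <- function(log, a, b) {
  log[(log$left_stim == a & log$right_stim == b) |
        (log$left_stim == b & log$right_stim == a), , drop = FALSE]
}

cell_median <- function(rt) {
  rt <- rt[!is.na(rt)]
  if (length(rt) < RT_MIN_CELL) NA_real_ else median(rt)
}

#' Habit scores of the rewarded pair task from a test-phase log
#'
#' Computes the choice and RT scores from the completed same-reward-pair
#' trials of one participant's test log: choice proportions over each pair's
#' presentations, RT cell medians over at least 3 valid trials (responses
#' under 50 ms discarded).
#'
#' @param test_log trial-log data frame of the test phase with responses.
#' @return list with `choice` and `rt` scores (either may be `NA`).
#' @export
reward_pairs_scores_from_log <- function(test_log) {
  log <- completed(test_log)
  log$rt_s <- rt_seconds(log)
  freq <- c("v3f", "v5f", "v7f")
  rare <- c("v3r", "v5r", "v7r")
  p_f <- mdn_f <- mdn_r <- rep(NA_real_, 3)
  for (i in 1:3) {
    tr <- pair_trials(log, freq[i], rare[i])
    if (nrow(tr) > 0) p_f[i] <- mean(tr$chosen_stim == freq[i])
    mdn_f[i] <- cell_median(tr$rt_s[tr$chosen_stim == freq[i]])
    mdn_r[i] <- cell_median(tr$rt_s[tr$chosen_stim == rare[i]])
  }
  list(choice = reward_pairs_choice_score(p_f, 1 - p_f),
       rt = if (anyNA(c(mdn_f, mdn_r))) NA_real_ else mean(mdn_r - mdn_f))
}

#' Habit scores of the unrewarded task from a test-phase log
#'
#' Choice and RT scores over all completed test trials presenting the 80/20
#' pair, regardless of screen location (set `location = "same"` or
#' `"switched"` for the location-stratified variant, classified against the
#' training side map).
#'
#' @param test_log trial-log data frame of the test phase.
#' @param location `"all"`, `"same"`, or `"switched"`.
#' @param sides training side map as in [unrewarded_stimuli()] (used only for
#'   stratification).
#' @return list with `choice` and `rt` scores.
#' @export
unrewarded_scores_from_log <- function(test_log, location = c("all", "same", "switched"),
                                       sides = c(f80 = "left", r20 = "right",
                                                 e50a = "left", e50b = "right")) {
  location <- match.arg(location)
  log <- completed(test_log)
  log$rt_s <- rt_seconds(log)
  tr <- pair_trials(log, "f80", "r20")
  if (location != "all") {
    same <- (tr$left_stim == "f80") == (sides[["f80"]] == "left")
    tr <- tr[if (location == "same") same else !same, , drop = FALSE]
  }
  if (nrow(tr) == 0)
    return(list(choice = NA_real_, rt = NA_real_))
  p_f <- mean(tr$chosen_stim == "f80")
  mdn_f <- cell_median(tr$rt_s[tr$chosen_stim == "f80"])
  mdn_r <- cell_median(tr$rt_s[tr$chosen_stim == "r20"])
  list(choice = unrewarded_choice_score(p_f, 1 - p_f),
       rt = if (is.na(mdn_f) || is.na(mdn_r)) NA_real_ else mdn_r - mdn_f)
}

#' Rating scores from a ratings table
#'
#' Averages the repeated ratings per stimulus and timepoint, then applies the
#' differential pre/post change formulas of the rewarded-pair and unrewarded
#' tasks.
#'
#' @param ratings data frame with columns `stimulus`, `timepoint`
#'   (`"pre"`/`"post"`) and `rating` for one participant.
#' @return list with `reward_pairs` and `unrewarded` rating scores.
#' @export
rating_scores_from_table <- function(ratings) {
  stopifnot(all(c("stimulus", "timepoint", "rating") %in% names(ratings)))
  m <- function(stim, tp) {
    r <- ratings$rating[ratings$stimulus == stim & ratings$timepoint == tp]
    if (length(r) == 0 || anyNA(r)) NA_real_ else mean(r)
  }
  rp <- reward_pairs_rating_score(
    pre_frequent = vapply(c("v3f", "v5f", "v7f"), m, numeric(1), tp = "pre"),
    post_frequent = vapply(c("v3f", "v5f", "v7f"), m, numeric(1), tp = "post"),
    pre_rare = vapply(c("v3r", "v5r", "v7r"), m, numeric(1), tp = "pre"),
    post_rare = vapply(c("v3r", "v5r", "v7r"), m, numeric(1), tp = "post"))
  uh <- unrewarded_rating_score(m("f80", "pre"), m("f80", "post"),
                                m("r20", "pre"), m("r20", "post"))
  list(reward_pairs = rp, unrewarded = uh)
}
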