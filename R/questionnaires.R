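# Habit questionnaire scoring. Reverse-keyed items are assumed recoded
# upstream so that higher responses always mean stronger habits.

check_items <- function(x, lo, hi, what) {
  if (any(!is.finite(x)) || any(x < lo | x > hi) || any(x != round(x)))
    stop(what, " responses must be integers in [", lo, ", ", hi, "]",
         call. = FALSE)
}

#' Self-report habit index over real-life behaviors
#'
#' Twelve 0-6 items per behavior are summed and divided by the maximum of 72,
#' giving a per-behavior habit strength in \[0, 1\]. Only behaviors performed
#' frequently (response >= 3 on the "I do frequently" item) enter the final
#' mean; with fewer than three frequent behaviors the score is missing.
#'
#' @param responses numeric matrix, behaviors x 12 items, values 0-6.
#' @param freq_item column index of the "I do frequently" item.
#' @return mean habit strength in \[0, 1\], or `NA`.
#' @export
srhi_score <- function(responses, freq_item = 1L) {
  responses <- as.matrix(responses)
  stopifnot(ncol(responses) == 12, freq_item >= 1, freq_item <= 12)
  check_items(responses, 0, 6, "SRHI")
  per_behavior <- rowSums(responses) / 72
  frequent <- responses[, freq_item] >= 3
  if (sum(frequent) < 3) return(NA_real_)
  mean(per_behavior[frequent])
}

#' Creature-of-habit subscale scores
#'
#' Means of the automaticity (11 items) and routine (16 items) subscales of
#' the 27-item scale; the two subscales are kept separate.
#'
#' @param responses 27 item responses, 1-5, ordered so that
#'   `automaticity_items`/`routine_items` index them correctly.
#' @param automaticity_items,routine_items item indices of the two subscales.
#' @return list with `automaticity` and `routine` means.
#' @export
cohs_scores <- function(responses, automaticity_items = 1:11,
                        routine_items = 12:27) {
  stopifnot(length(responses) == 27,
            length(automaticity_items) == 11, length(routine_items) == 16,
            !anyDuplicated(c(automaticity_items, routine_items)))
  check_items(responses, 1, 5, "COHS")
  list(automaticity = mean(responses[automaticity_items]),
       routine = mean(responses[routine_items]))
}

#' Habitual-tendencies questionnaire scores
#'
#' Total = sum of all eleven 0-6 items (aversion-to-novelty items already
#' reverse-coded); subscales are sums of their 4 (compulsivity), 4
#' (regularity) and 3 (aversion to novelty) items.
#'
#' @param responses 11 item responses, 0-6.
#' @param compulsivity_items,regularity_items,novelty_items subscale indices.
#' @return list with `total`, `compulsivity`, `regularity`,
#'   `aversion_to_novelty`.
#' @export
htq_scores <- function(responses, compulsivity_items = 1:4,
                       regularity_items = 5:8, novelty_items = 9:11) {
  stopifnot(length(responses) == 11,
            length(compulsivity_items) == 4, length(regularity_items) == 4,
            length(novelty_items) == 3,
            !anyDuplicated(c(compulsivity_items, regularity_items, novelty_items)))
  check_items(responses, 0, 6, "HTQ")
  list(total = sum(responses),
       compulsivity = sum(responses[compulsivity_items]),
       regularity = sum(responses[regularity_items]),
       aversion_to_novelty = sum(responses[novelty_items]))
}
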