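# Shared fixtures, built in code.

rp_value_map <- function() {
  stim <- reward_pairs_stimuli()
  setNames(stim$reward_value, stim$id)
}

# Smallest complete log: n trials of one stimulus pair with given choices.
tiny_log <- function(chosen, left = "a", right = "b", phase = "test",
                     rt_ms = NA_integer_) {
  n <- length(chosen)
  data.frame(
    task = "toy", phase = phase, day = 1L, index = seq_len(n) - 1L,
    left_stim = left, right_stim = right, cue_side = "none",
    response_window_ms = 800L,
    choice_side = ifelse(chosen == left, "left", "right"),
    chosen_stim = chosen,
    outcome_points_left = NA_integer_, outcome_points_right = NA_integer_,
    rt_ms = rt_ms, missed = 0L, stringsAsFactors = FALSE)
}

# Pair-count table of a schedule, keyed by sorted stimulus pair.
pair_counts <- function(sched) {
  key <- apply(cbind(sched$left_stim, sched$right_stim), 1,
               function(x) paste(sort(x), collapse = "|"))
  table(key)
}
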