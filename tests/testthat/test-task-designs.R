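test_that("reward-pair training sessions have the printed structure for any seed", {
  vmap <- rp_value_map()
  ref_counts <- NULL
  for (seed in c(1L, 17L, 983L)) {
    s <- build_reward_pairs_training_session(1, seed)
    expect_equal(nrow(s), 160L)
    appearances <- table(c(s$left_stim, s$right_stim))
    expect_true(all(appearances == 40L))
    expect_equal(sum(pmax(vmap[s$left_stim], vmap[s$right_stim])), 960)
    expect_equal(sum(pmin(vmap[s$left_stim], vmap[s$right_stim])), 640)
    # pair-type multiset is invariant to the seed
    if (is.null(ref_counts)) ref_counts <- pair_counts(s)
    expect_equal(pair_counts(s), ref_counts)
    # sides balanced: every pair count is even, so exactly 20 lefts each
    expect_true(all(table(s$left_stim) == 20L))
  }
})

test_that("frequent stimuli meet their cheaper neighbour 30 times, rare 10 times", {
  s <- build_reward_pairs_training_session(3, 11)
  cnt <- pair_counts(s)
  expect_equal(unname(cnt[["v1|v3f"]]), 30L)
  expect_equal(unname(cnt[["v1|v3r"]]), 10L)
  expect_equal(unname(cnt[["v3f|v5r"]]), 10L)
  expect_equal(unname(cnt[["v3r|v5f"]]), 30L)
  expect_equal(unname(cnt[["v5r|v7f"]]), 30L)
  expect_equal(unname(cnt[["v7r|v9"]]), 30L)
})

test_that("invalid training day is rejected", {
  expect_error(build_reward_pairs_training_session(0, 1), "day")
  expect_error(build_reward_pairs_training_session(6, 1), "day")
  expect_error(build_unrewarded_training_session(2.5, 1), "day")
})

test_that("reward-pair test phase pairs every stimulus and boosts same-reward pairs", {
  for (seed in c(4L, 99L)) {
    s <- build_reward_pairs_test(seed)
    expect_equal(nrow(s), 136L)
    cnt <- pair_counts(s)
    expect_equal(length(cnt), 28L)
    same <- c("v3f|v3r", "v5f|v5r", "v7f|v7r")
    expect_true(all(cnt[same] == 12L))
    expect_true(all(cnt[setdiff(names(cnt), same)] == 4L))
    # left/right balanced within each pair (all counts even)
    left_of_pair <- tapply(s$left_stim, apply(
      cbind(s$left_stim, s$right_stim), 1,
      function(x) paste(sort(x), collapse = "|")),
      function(x) max(table(x)))
    expect_true(all(left_of_pair <= ceiling(cnt / 2)))
  }
})

test_that("schedules are deterministic in the seed and shuffled across seeds", {
  expect_identical(build_reward_pairs_training_session(1, 5),
                   build_reward_pairs_training_session(1, 5))
  a <- build_reward_pairs_training_session(1, 5)
  b <- build_reward_pairs_training_session(1, 6)
  expect_false(identical(a$left_stim, b$left_stim))
})

test_that("unrewarded training sessions cue 80/20 and 50/50 as instructed", {
  s <- build_unrewarded_training_session(1, 21)
  expect_equal(nrow(s), 240L)
  p80 <- s[s$left_stim %in% c("f80", "r20") | s$right_stim %in% c("f80", "r20"), ]
  p50 <- s[s$left_stim %in% c("e50a", "e50b"), ]
  expect_equal(nrow(p80), 120L)
  expect_equal(nrow(p50), 120L)
  cued80 <- ifelse(p80$cue_side == "left", p80$left_stim, p80$right_stim)
  expect_equal(sum(cued80 == "f80"), 96L)   # 80% of 120
  cued50 <- ifelse(p50$cue_side == "left", p50$left_stim, p50$right_stim)
  expect_equal(sum(cued50 == "e50a"), 60L)  # 50% of 120
  # fixed sides within the session
  expect_true(all(p80$left_stim == p80$left_stim[1]))
  expect_equal(s$response_window_ms[1], 500L)
})

test_that("five unrewarded sessions give 600 trials and 480 frequent cues per pair", {
  sessions <- lapply(1:5, function(d) build_unrewarded_training_session(d, 300 + d))
  all5 <- do.call(rbind, sessions)
  p80 <- all5[all5$left_stim %in% c("f80", "r20"), ]
  expect_equal(nrow(p80), 600L)
  cued <- ifelse(p80$cue_side == "left", p80$left_stim, p80$right_stim)
  expect_equal(sum(cued == "f80"), 480L)
  expect_equal(nrow(all5) - nrow(p80), 600L)
})

test_that("unrewarded test phase has the printed composition", {
  sides <- c(f80 = "left", r20 = "right", e50a = "left", e50b = "right")
  for (seed in c(2L, 77L)) {
    s <- build_unrewarded_test(seed, sides = sides)
    expect_equal(nrow(s), 64L)
    head20 <- s[1:20, ]
    # only trained pairings, trained locations
    expect_true(all((head20$left_stim == "f80" & head20$right_stim == "r20") |
                      (head20$left_stim == "e50a" & head20$right_stim == "e50b")))
    expect_equal(sum(head20$left_stim == "f80"), 10L)
    tail44 <- s[21:64, ]
    cnt <- pair_counts(tail44)
    expect_equal(unname(cnt[["e50a|f80"]]), 4L)  # untrained pairings 4x
    expect_equal(unname(cnt[["f80|r20"]]), 14L)  # 4 balanced + 10 switched
    switched80 <- sum(tail44$left_stim == "r20" & tail44$right_stim == "f80")
    expect_equal(switched80, 12L)  # 10 switched-block + 2 of the balanced 4
    switched50 <- sum(tail44$left_stim == "e50b" & tail44$right_stim == "e50a")
    expect_equal(switched50, 12L)
    expect_true(all(s$cue_side == "none"))
  }
})

test_that("outcome walks stay inside the reflecting boundaries and are seeded", {
  cfg <- two_step_config(10000)
  w <- build_two_step_walks(cfg, 8)
  expect_true(all(w >= -4 & w <= 5))
  expect_true(all(w == round(w)))
  expect_identical(w, build_two_step_walks(cfg, 8))
  expect_false(identical(w, build_two_step_walks(cfg, 9)))
})

test_that("walk increments have the stated standard deviation when unreflected", {
  # boundaries wide enough that no reflection occurs; rounding adds 2/12 to
  # the increment variance
  cfg <- two_step_config(20000, walk_sd = 2, walk_min = -1e6, walk_max = 1e6)
  w <- build_two_step_walks(cfg, 31)
  sds <- apply(w, 2, function(x) sd(diff(x)))
  expect_true(all(abs(sds - sqrt(4 + 2 / 12)) < 0.08))
})
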