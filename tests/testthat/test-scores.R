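test_that("rewarded-pair choice score averages the frequency preference over pairs", {
  expect_equal(reward_pairs_choice_score(c(1, 1, 1), c(0, 0, 0)), 1)
  expect_equal(reward_pairs_choice_score(rep(.5, 3), rep(.5, 3)), 0)
  expect_equal(reward_pairs_choice_score(c(.75, .5, 1), c(.25, .5, 0)), 0.5)
  expect_true(is.na(reward_pairs_choice_score(c(.5, NA, .5), c(.5, .5, .5))))
  expect_error(reward_pairs_choice_score(c(2, 0, 0), c(0, 0, 0)))
})

test_that("rewarded-pair RT score is the median slowing for rare choices, capped by the window", {
  expect_equal(reward_pairs_rt_score(rep(.6, 3), rep(.5, 3)), 0.1)
  expect_equal(reward_pairs_rt_score(rep(.4, 3), rep(.4, 3)), 0)
  near_max <- reward_pairs_rt_score(rep(.8, 3), rep(1e-9, 3))
  expect_lt(abs(near_max - 0.8), 1e-6)
  expect_error(reward_pairs_rt_score(rep(.9, 3), rep(.5, 3)))  # beyond the window
  expect_true(is.na(reward_pairs_rt_score(c(.5, NA, .5), rep(.4, 3))))
})

test_that("rating scores track differential pre-to-post change", {
  expect_equal(reward_pairs_rating_score(rep(40, 3), rep(60, 3),
                                         rep(40, 3), rep(40, 3)), 20)
  expect_equal(reward_pairs_rating_score(rep(50, 3), rep(50, 3),
                                         rep(50, 3), rep(50, 3)), 0)
  expect_equal(unrewarded_rating_score(40, 50, 45, 40), 15)
})

test_that("unrewarded-task scores are single-pair analogues", {
  expect_equal(unrewarded_choice_score(1, 0), 1)
  expect_equal(unrewarded_rt_score(.4, .4), 0)
  expect_equal(unrewarded_rt_score(.45, .35), 0.1, tolerance = 1e-12)
  expect_true(is.na(unrewarded_choice_score(NA, .5)))
})

test_that("devaluation scores capture switching and its RT cost", {
  s <- dval_scores(p_test = 0, p_train = 1)
  expect_equal(s$dval_choice, -1)
  expect_equal(dval_scores(.4, .4)$dval_choice, 0)
  s2 <- dval_scores(c(.2, .4), c(.9, .8), c(.55, .65), c(.45, .55))
  expect_equal(s2$dval_rt_switch_cost, 0.1, tolerance = 1e-12)
  expect_equal(s2$dval_choice, mean(c(.2 - .9, .4 - .8)))
  expect_true(is.na(dval_scores(.5, .5, NA, .4)$dval_rt_switch_cost))
})

test_that("the behavioral adaptation index contrasts valued and devalued rate changes", {
  expect_equal(bai(2.0, 1.8, 2.0, 1.0), 0.8)
  expect_equal(bai(1.5, 1.5, 1.2, 1.2), 0)
  expect_equal(bai(2, 1, 2, 1), 0)  # equal drops: devaluation-insensitive
})

test_that("the contingency-degradation ratio behaves as a normalized insensitivity index", {
  expect_equal(dgrd_ratio(3, 3), 0.5)
  expect_equal(dgrd_ratio(0, 5), 0)
  expect_equal(dgrd_ratio(3, 1), 0.75)
  expect_true(is.na(dgrd_ratio(0, 0)))
})

test_that("training effects divide the last-minus-first difference", {
  expect_equal(training_effect(0.2, 0.6, 2), 0.2)
  expect_equal(training_effect(0.3, 0.3, 2), 0)
  expect_equal(training_effect(0.2, 0.4, 1), 0.2)
  expect_true(is.na(training_effect(NA, 0.4, 2)))
})

test_that("every score is antisymmetric under swapping the condition labels", {
  set.seed(77)
  for (i in 1:20) {
    pf <- runif(3); pr <- runif(3)
    expect_equal(reward_pairs_choice_score(pf, pr),
                 -reward_pairs_choice_score(pr, pf))
    mr <- runif(3, .1, .8); mf <- runif(3, .1, .8)
    expect_equal(reward_pairs_rt_score(mr, mf), -reward_pairs_rt_score(mf, mr))
    a <- runif(4, 0, 100)
    expect_equal(reward_pairs_rating_score(rep(a[1], 3), rep(a[2], 3),
                                           rep(a[3], 3), rep(a[4], 3)),
                 -reward_pairs_rating_score(rep(a[3], 3), rep(a[4], 3),
                                            rep(a[1], 3), rep(a[2], 3)))
    x <- runif(2)
    expect_equal(unrewarded_choice_score(x[1], x[2]),
                 -unrewarded_choice_score(x[2], x[1]))
    r <- runif(4)
    expect_equal(bai(r[1], r[2], r[3], r[4]), -bai(r[3], r[4], r[1], r[2]))
    d <- runif(2, 0.1, 5)
    expect_equal(dgrd_ratio(d[1], d[2]), 1 - dgrd_ratio(d[2], d[1]))
  }
})

test_that("log-level scores respect the trial filters", {
  # 12 same-reward trials per pair: frequent chosen in 9, 6, 12
  mk_pair <- function(f, r, n_f) {
    tiny_log(c(rep(f, n_f), rep(r, 12 - n_f)), left = f, right = r,
             rt_ms = c(rep(400L, 6), rep(500L, 6)))
  }
  log <- rbind(mk_pair("v3f", "v3r", 9), mk_pair("v5f", "v5r", 6),
               mk_pair("v7f", "v7r", 12))
  s <- reward_pairs_scores_from_log(log)
  expect_equal(s$choice, mean(c(2 * 9 / 12 - 1, 0, 1)))
  expect_true(is.na(s$rt))  # the all-frequent pair has no rare-choice RTs
  # sub-50 ms responses are discarded from RT cells
  log2 <- tiny_log(rep(c("v3f", "v3r"), 6), left = "v3f", right = "v3r",
                   rt_ms = rep(c(400L, 30L), 6))
  cells <- habitkit:::cell_median(habitkit:::rt_seconds(log2))
  expect_equal(cells, 0.4)
})

test_that("unrewarded log scores use only the 80/20 pair and can stratify by location", {
  log <- rbind(
    tiny_log(rep("f80", 8), left = "f80", right = "r20", rt_ms = 400L),
    tiny_log(rep(c("f80", "r20"), 4), left = "r20", right = "f80", rt_ms = 450L),
    tiny_log(rep("e50a", 10), left = "e50a", right = "e50b", rt_ms = 300L))
  log$response_window_ms <- 500L
  s_all <- unrewarded_scores_from_log(log)
  expect_equal(s_all$choice, 2 * (12 / 16) - 1)
  s_same <- unrewarded_scores_from_log(log, location = "same")
  expect_equal(s_same$choice, 1)  # trained-location trials all chose frequent
  s_sw <- unrewarded_scores_from_log(log, location = "switched")
  expect_equal(s_sw$choice, 0)
})

test_that("rating tables average repeated ratings before scoring", {
  ratings <- data.frame(
    stimulus = rep(c("v3f", "v3r", "v5f", "v5r", "v7f", "v7r", "f80", "r20"),
                   each = 4),
    timepoint = rep(rep(c("pre", "post"), each = 2), 8),
    rating = rep(c(50, 50, 60, 60, 50, 50, 50, 50), each = 4))
  # frequent stimuli rose by 10, rare unchanged -> both scores 10 ... except
  # the table above gives +10 only to the first stimulus of each quadruple
  ratings$rating <- 50
  ratings$rating[ratings$timepoint == "post" &
                   ratings$stimulus %in% c("v3f", "v5f", "v7f", "f80")] <- 60
  s <- rating_scores_from_table(ratings)
  expect_equal(s$reward_pairs, 10)
  expect_equal(s$unrewarded, 10)
})
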