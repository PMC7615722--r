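test_that("choice probability is 0.5 under indifference and sums to 1 across sides", {
  st <- init_rl_state(c("a", "b"))
  expect_equal(choice_probability(st, model_params("random"), "a", "b"), 0.5)
  p0 <- model_params("rl_ck", alpha_q = .5, beta_q = 0, alpha_h = .5, beta_h = 0)
  expect_equal(choice_probability(st, p0, "a", "b"), 0.5)
  # complementarity over random states and parameters
  set.seed(42)
  for (i in 1:25) {
    st$q[] <- runif(2); st$ck[] <- runif(2)
    p <- model_params("rl_ck", alpha_q = runif(1), beta_q = runif(1, 0, 10),
                      alpha_h = runif(1), beta_h = runif(1, 0, 10))
    expect_equal(choice_probability(st, p, "a", "b") +
                   choice_probability(st, p, "b", "a"), 1)
  }
  expect_error(choice_probability(st, p0, "a", "zzz"), "unknown stimulus")
})

test_that("raising the kernel temperature sharpens preference for the higher-kernel option", {
  st <- init_rl_state(c("a", "b"))
  st$ck <- c(a = 0.8, b = 0.3)
  probs <- vapply(c(0, 2, 5, 9), function(b)
    choice_probability(st, model_params("ck", alpha_h = .2, beta_h = b), "a", "b"),
    numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("the reduced model ties the temperatures and weights equally at beta_h = 5", {
  expect_equal(reduced_beta_q(5), 5)
  expect_equal(reduced_beta_q(0), 10)
  p <- model_params("rl_ck_reduced", alpha_q = .3, alpha_h = .2, beta_h = 5)
  expect_identical(p$beta_q, p$beta_h)
  st <- init_rl_state(c("a", "b"))
  st$q <- c(a = 0.7, b = 0.4); st$ck <- c(a = 0.4, b = 0.7)
  # equal and opposite value differences cancel exactly under equal weighting
  expect_equal(choice_probability(st, p, "a", "b"), 0.5)
})

test_that("delta-rule updates move q toward the observed reward", {
  st <- init_rl_state(c("a", "b"), q0 = 0)
  st1 <- rl_update(st, "a", "b", 5 / 9, 3 / 9, alpha_q = 0.5)
  expect_equal(st1$q[["a"]], 5 / 18)
  expect_equal(rl_update(st, "a", "b", 1, 1, alpha_q = 0)$q, st$q)
  # geometric convergence to a fixed reward
  q <- 0
  for (i in 1:40) q <- q + 0.5 * (5 / 9 - q)
  st2 <- st
  for (i in 1:40) st2 <- rl_update(st2, "a", "b", 5 / 9, 0, 0.5, "chosen_only")
  expect_equal(st2$q[["a"]], q)
  expect_lt(abs(st2$q[["a"]] - 5 / 9), 1e-6)
  expect_equal(st2$q[["b"]], 0)  # chosen_only leaves the partner alone
  expect_error(rl_update(st, "a", "b", 1, 1, alpha_q = 1.5), "alpha_q")
})

test_that("the choice kernel tracks choice frequency", {
  st <- init_rl_state(c("a", "b"), ck0 = 0)
  expect_equal(ck_update(st, "a", "b", 0.2)$ck[["a"]], 0.2)
  # choosing one stimulus forever drives its kernel to 1 and the partner's to 0
  st1 <- init_rl_state(c("a", "b"))
  for (i in 1:100) st1 <- ck_update(st1, "a", "b", 0.2)
  expect_lt(abs(st1$ck[["a"]] - 1), 1e-6)
  expect_lt(st1$ck[["b"]], 1e-6)
  # balanced alternation keeps both kernels near 0.5 for small rates
  st2 <- init_rl_state(c("a", "b"))
  for (i in 1:400) st2 <- ck_update(st2, c("a", "b")[i %% 2 + 1],
                                    c("b", "a")[i %% 2 + 1], 0.05)
  expect_true(all(abs(st2$ck - 0.5) < 0.1))
})

test_that("a greedy reinforcement learner ends up choosing the better stimulus", {
  # training pairs always differ by 2 points, so on the 0-1 value scale the
  # asymptotic accuracy at the maximal temperature is plogis(10 * 2/9) = 0.90
  p <- model_params("rl", alpha_q = 0.3, beta_q = 10)
  sim <- simulate_reward_pairs_participant(p, days = 5, seed = 7)
  final <- sim$log[sim$log$phase == "training" & sim$log$day == 5, ]
  vmap <- rp_value_map()
  better <- ifelse(vmap[final$left_stim] >= vmap[final$right_stim],
                   final$left_stim, final$right_stim)
  expect_gt(mean(final$chosen_stim == better), 0.85)
})

test_that("a random agent chooses each side about half the time", {
  sched <- build_reward_pairs_training_session(1, 3)
  sim <- simulate_task(model_params("random"), sched,
                       reward_map = rp_value_map(), seed = 5)
  p_left <- mean(sim$log$choice_side == "left")
  expect_lt(abs(p_left - 0.5), 3 * sqrt(0.25 / 160))
})

test_that("a slow choice kernel on top of value learning prefers frequently trained stimuli", {
  # a slow kernel accumulates the value-driven choice-frequency asymmetry
  # without overriding value during training (fast kernels can lock onto an
  # arbitrary stimulus instead)
  for (seed in c(12, 33)) {
    p <- model_params("rl_ck", alpha_q = 0.3, beta_q = 8, alpha_h = 0.05, beta_h = 5)
    sim <- simulate_reward_pairs_participant(p, days = 5, seed = seed)
    scores <- reward_pairs_scores_from_log(sim$log[sim$log$phase == "test", ])
    expect_gt(scores$choice, 0.3)
  }
})

test_that("instructed training follows the cue and strengthens the frequent kernel", {
  sched <- build_unrewarded_training_session(1, 9)
  sim <- simulate_unrewarded_training(1, sched, alpha_h = 0.1, seed = 2)
  cued <- ifelse(sim$log$cue_side == "left", sim$log$left_stim, sim$log$right_stim)
  expect_true(all(sim$log$chosen_stim == cued))
  st <- NULL
  for (d in 1:5) {
    s <- simulate_unrewarded_training(1, build_unrewarded_training_session(d, d),
                                      alpha_h = 0.1, seed = 40 + d, state = st)
    st <- s$state
  }
  expect_gt(st$ck[["f80"]], st$ck[["r20"]])
  miss <- simulate_unrewarded_training(1, sched, seed = 3, miss_prob = 0.1)
  expect_lt(abs(mean(miss$log$missed) - 0.1), 0.06)
  expect_true(all(is.na(miss$log$chosen_stim[miss$log$missed == 1])))
})

test_that("missed trials carry no response and leave learning untouched", {
  sched <- build_reward_pairs_training_session(1, 4)
  p <- model_params("rl", alpha_q = 0.3, beta_q = 5)
  sim <- simulate_task(p, sched, rp_value_map(), seed = 8, miss_prob = 0.2)
  expect_true(all(is.na(sim$log$chosen_stim[sim$log$missed == 1])))
  expect_true(all(is.na(sim$signals$q_diff[sim$log$missed == 1])))
  expect_gt(sum(sim$log$missed), 0)
})
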