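# Synthetic participants with the statistical structure the analyses assume:
# choices from the candidate models, log-normal response times that speed up
# with value and choice-frequency differences, bounded 0-100 stimulus
# ratings, and Likert questionnaire items loading on a single latent habit
# trait. Every stage is seeded so cohorts are byte-identical across runs.

#' Configuration of a synthetic cohort
#'
#' Defaults: generating models drawn from the combined RL + choice-kernel
#' model, learning rates Beta(2, 2), inverse temperatures Uniform(1, 9),
#' instructed-choice compliance Beta(20, 2); response times log-normal around
#' `exp(mu0_log_ms)` ms, sped up by `b_value` per unit scaled value
#' difference and `b_freq` per unit choice-kernel difference; ratings carry
#' the pre rating plus value and choice-frequency effects.
#'
#' @param n_participants number of participants.
#' @param seed integer master seed.
#' @param model_mixture named probabilities over model ids, summing to 1.
#' @param rt_model list with `mu0_log_ms`, `b_value`, `b_freq`, `sigma_log`,
#'   `miss_prob`.
#' @param rating_model list with `w_pre`, `w_value`, `w_freq`, `sigma`.
#' @param q_loading loading of questionnaire items on the latent habit trait
#'   (0 reproduces a null association).
#' @param days training sessions per task.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20, seed = 1L,
                          model_mixture = c(rl_ck = 1),
                          rt_model = list(mu0_log_ms = log(420), b_value = 0.25,
                                          b_freq = 0.25, sigma_log = 0.2,
                                          miss_prob = 0.05),
                          rating_model = list(w_pre = 1, w_value = 20,
                                              w_freq = 20, sigma = 5),
                          q_loading = 1, days = 5) {
  stopifnot(n_participants >= 1,
            all(names(model_mixture) %in% MODEL_IDS),
            abs(sum(model_mixture) - 1) < 1e-8,
            rt_model$miss_prob >= 0, rt_model$miss_prob < 0.5,
            days >= 1, days <= 5)
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), model_mixture = model_mixture,
                 rt_model = rt_model, rating_model = rating_model,
                 q_loading = q_loading, days = as.integer(days)),
            class = "cohort_config")
}

#' Simulate one participant on the rewarded pair task
#'
#' Builds the training schedules and test phase, simulates the agent with the
#' learner state carried across sessions, and returns the concatenated log
#' (training days 1..`days`, then test).
#'
#' @param params a [model_params()] object.
#' @param days number of training sessions.
#' @param seed integer seed.
#' @param feedback training feedback regime.
#' @param miss_prob per-trial miss probability.
#' @return list with `log`, final `state`, and per-trial `signals`.
#' @export
simulate_reward_pairs_participant <- function(params, days = 5, seed = 1L,
                                              feedback = "both", miss_prob = 0) {
  stim <- reward_pairs_stimuli()
  reward_map <- setNames(stim$reward_value, stim$id)
  state <- init_rl_state(stim$id)
  logs <- list(); sigs <- list()
  for (d in seq_len(days)) {
    sched <- build_reward_pairs_training_session(d, child_seed(seed, d))
    sim <- simulate_task(params, sched, reward_map, seed = child_seed(seed, 100 + d),
                         state = state, feedback = feedback, miss_prob = miss_prob)
    state <- sim$state
    logs[[length(logs) + 1L]] <- sim$log
    sigs[[length(sigs) + 1L]] <- sim$signals
  }
  sched <- build_reward_pairs_test(child_seed(seed, 200), day = days)
  sim <- simulate_task(params, sched, reward_map = NULL,
                       seed = child_seed(seed, 201), state = state,
                       miss_prob = miss_prob)
  logs[[length(logs) + 1L]] <- sim$log
  sigs[[length(sigs) + 1L]] <- sim$signals
  list(log = do.call(rbind, logs), state = sim$state,
       signals = do.call(rbind, sigs))
}

# The simulated log is returned by simulate_reward_pairs_participant without
# response times; draw them from the cohort's log-normal RT model.
draw_rts <- function(log, signals, rt_model, value_map = NULL) {
  n <- nrow(log)
  rt <- rep(NA_integer_, n)
  done <- which(log$missed == 0L & !is.na(log$chosen_stim))
  if (!length(done)) {
    log$rt_ms <- rt
    return(log)
  }
  sgn <- ifelse(log$choice_side[done] == "left", 1, -1)
  dv <- if (is.null(value_map)) rep(0, length(done)) else
    sgn * (value_map[log$left_stim[done]] - value_map[log$right_stim[done]]) / REWARD_SCALE
  dck <- sgn * signals$ck_diff[done]
  mu <- rt_model$mu0_log_ms - rt_model$b_value * dv - rt_model$b_freq * dck
  raw <- exp(rnorm(length(done), mu, rt_model$sigma_log))
  window <- log$response_window_ms[done]
  rt[done] <- as.integer(round(pmin(pmax(raw, 51), window)))
  log$rt_ms <- rt
  log
}

clip01_100 <- function(x) pmin(pmax(x, 0), 100)

likert <- function(n, mid, lo, hi, trait, loading, sd = 1.2) {
  pmin(pmax(round(mid + loading * trait + rnorm(n, 0, sd)), lo), hi)
}

#' Generate a complete synthetic cohort
#'
#' Per participant: draws a generating model and parameters, simulates the
#' rewarded pair task (pre-training test, `days` training sessions, final
#' test) and the unrewarded task (instructed training, free-choice test),
#' attaches response times and missingness, produces pre/post stimulus
#' ratings (two per timepoint) and questionnaire item responses, and records
#' the ground truth.
#'
#' @param config a [cohort_config()].
#' @return list with data frames `trial_logs`, `ratings`, `questionnaires`
#'   and `ground_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  logs <- list(); ratings <- list(); quest <- list(); truth <- list()
  rp_stim <- reward_pairs_stimuli()
  value_map <- setNames(rp_stim$reward_value, rp_stim$id)
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("sub%03d", p)
    ps <- child_seed(config$seed, p)
    with_seed(ps, {
      model_id <- sample(names(config$model_mixture), 1,
                         prob = config$model_mixture)
      params <- draw_model_params(model_id)
      compliance <- rbeta(1, 20, 2)
      trait <- rnorm(1)
    })
    ep <- effective_params(params)
    alpha_uh <- if (ep[["alpha_h"]] > 0) ep[["alpha_h"]] else 0.2
    miss <- config$rt_model$miss_prob

    # rewarded pair task: pre-training test with a naive learner, then
    # training + final test with state carried across sessions
    pre_sched <- build_reward_pairs_test(child_seed(ps, 300), day = 1)
    pre <- simulate_task(params, pre_sched, reward_map = NULL,
                         seed = child_seed(ps, 301), miss_prob = miss)
    main <- simulate_reward_pairs_participant(params, days = config$days,
                                              seed = ps, miss_prob = miss)
    # unrewarded task: instructed training then free choice driven by the
    # learned choice kernel
    uh_state <- NULL
    uh_logs <- list(); uh_sigs <- list()
    for (d in seq_len(config$days)) {
      sched <- build_unrewarded_training_session(d, child_seed(ps, 400 + d))
      sim <- simulate_unrewarded_training(compliance, sched, alpha_h = alpha_uh,
                                          seed = child_seed(ps, 450 + d),
                                          state = uh_state, miss_prob = miss)
      uh_state <- sim$state
      uh_logs[[d]] <- sim$log
      uh_sigs[[d]] <- sim$signals
    }
    uh_test_params <- if (ep[["beta_h"]] > 0)
      model_params("ck", alpha_h = alpha_uh, beta_h = ep[["beta_h"]])
    else model_params("random")
    uh_test <- simulate_task(uh_test_params,
                             build_unrewarded_test(child_seed(ps, 500)),
                             seed = child_seed(ps, 501), state = uh_state,
                             miss_prob = miss)
    final_uh_state <- uh_test$state

    with_seed(child_seed(ps, 600), {
      rp_log <- draw_rts(rbind(pre$log, main$log),
                         rbind(pre$signals, main$signals),
                         config$rt_model, value_map)
      uh_log <- draw_rts(rbind(do.call(rbind, uh_logs), uh_test$log),
                         rbind(do.call(rbind, uh_sigs), uh_test$signals),
                         config$rt_model)
    })
    plog <- rbind(rp_log, uh_log)
    plog <- cbind(participant_id = pid, plog, stringsAsFactors = FALSE)
    logs[[p]] <- plog

    # ratings: two per stimulus and timepoint; post carries value and
    # choice-frequency effects through the final learner states
    rm_cfg <- config$rating_model
    ck_all <- c(main$state$ck, final_uh_state$ck)
    stims <- c(rp_stim$id, unrewarded_stimuli()$id)
    vals <- c(value_map[rp_stim$id] / REWARD_SCALE,
              setNames(rep(NA_real_, 4), unrewarded_stimuli()$id))
    ratings[[p]] <- with_seed(child_seed(ps, 700), {
      pre_mean <- clip01_100(rnorm(length(stims), 50, 10))
      post_mean <- clip01_100(
        rm_cfg$w_pre * pre_mean +
          rm_cfg$w_value * (ifelse(is.na(vals), 0, vals - 0.5)) +
          rm_cfg$w_freq * (ck_all[stims] - 0.5) +
          rnorm(length(stims), 0, rm_cfg$sigma))
      data.frame(
        participant_id = pid,
        stimulus = rep(stims, times = 4),
        timepoint = rep(rep(c("pre", "post"), each = length(stims)), 2),
        rep = rep(1:2, each = 2 * length(stims)),
        rating = round(clip01_100(c(pre_mean, post_mean, pre_mean, post_mean) +
                                    rnorm(4 * length(stims), 0, rm_cfg$sigma))),
        stringsAsFactors = FALSE)
    })

    quest[[p]] <- with_seed(child_seed(ps, 800), {
      srhi <- likert(11 * 12, 3, 0, 6, trait, config$q_loading)
      cohs <- likert(27, 3, 1, 5, trait, 0.8 * config$q_loading, sd = 1)
      htq <- likert(11, 3, 0, 6, trait, config$q_loading)
      data.frame(
        participant_id = pid,
        instrument = c(rep("srhi", 132), rep("cohs", 27), rep("htq", 11)),
        item = c(sprintf("b%02d_i%02d", rep(1:11, each = 12), rep(1:12, 11)),
                 sprintf("i%02d", 1:27), sprintf("i%02d", 1:11)),
        response = c(srhi, cohs, htq),
        stringsAsFactors = FALSE)
    })

    gt <- c(as.list(params[model_param_names(model_id)]),
            list(compliance = compliance, alpha_uh = alpha_uh,
                 habit_trait = trait))
    truth[[p]] <- data.frame(participant_id = pid, model_id = model_id,
                             param = names(gt), value = unlist(gt),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  list(trial_logs = do.call(rbind, logs),
       ratings = do.call(rbind, ratings),
       questionnaires = do.call(rbind, quest),
       ground_truth = do.call(rbind, truth))
}

#' Parameter- and model-recovery experiment
#'
#' Generates a cohort, refits each participant's rewarded-pair data
#' (training plus final test) with the generating model and a comparison
#' model set, and reports generating-vs-recovered parameter correlations
#' (with 95% CI) plus the lowest-BIC model confusion matrix.
#'
#' @param config a [cohort_config()]; needs `n_participants >= 20` for the
#'   correlation report.
#' @param fit_models model ids to fit for the confusion matrix.
#' @param n_starts optimisation restarts per fit.
#' @return list of class `recovery_report` with `param_recovery` (data frame
#'   `param`, `r`, `ci_lower`, `ci_upper`, `n`), `confusion`, and `fits`.
#' @export
recovery_experiment <- function(config, fit_models = c("random", "rl", "ck", "rl_ck"),
                                n_starts = 5) {
  stopifnot(inherits(config, "cohort_config"), config$n_participants >= 20)
  cohort <- generate_cohort(config)
  pids <- unique(cohort$trial_logs$participant_id)
  gen_models <- character(length(pids))
  recovered <- list()
  selected <- character(length(pids))
  fits <- list()
  for (i in seq_along(pids)) {
    pid <- pids[i]
    gt <- cohort$ground_truth[cohort$ground_truth$participant_id == pid, ]
    gen_models[i] <- gt$model_id[1]
    log <- cohort$trial_logs[
      cohort$trial_logs$participant_id == pid &
        cohort$trial_logs$task == "reward_pairs" &
        !(cohort$trial_logs$phase == "test" & cohort$trial_logs$day == 1), ]
    fseed <- child_seed(config$seed, 9000 + i)
    gen_fit <- fit_mle(gen_models[i], log, n_starts = n_starts, seed = fseed,
                       participant_id = pid)
    recovered[[i]] <- gen_fit$estimates
    bics <- vapply(fit_models, function(m)
      fit_mle(m, log, n_starts = n_starts,
              seed = child_seed(fseed, match(m, fit_models)),
              participant_id = pid)$bic, numeric(1))
    selected[i] <- fit_models[which.min(bics)]
    fits[[i]] <- gen_fit
  }
  par_names <- unique(unlist(lapply(recovered, names)))
  rows <- lapply(par_names, function(nm) {
    gen <- vapply(seq_along(pids), function(i) {
      gt <- cohort$ground_truth[cohort$ground_truth$participant_id == pids[i], ]
      v <- gt$value[gt$param == nm]
      if (length(v)) v else NA_real_
    }, numeric(1))
    rec <- vapply(recovered, function(r) {
      if (nm %in% names(r)) r[[nm]] else NA_real_
    }, numeric(1))
    ok <- !is.na(gen) & !is.na(rec)
    if (sum(ok) < 4 || stats::sd(gen[ok]) == 0 || stats::sd(rec[ok]) == 0)
      return(data.frame(param = nm, r = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, n = sum(ok)))
    ct <- stats::cor.test(gen[ok], rec[ok])
    data.frame(param = nm, r = unname(ct$estimate),
               ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2],
               n = sum(ok), stringsAsFactors = FALSE)
  })
  gens <- sort(unique(gen_models))
  confusion <- matrix(0, length(gens), length(fit_models),
                      dimnames = list(generating = gens, selected = fit_models))
  for (i in seq_along(pids))
    confusion[gen_models[i], selected[i]] <-
      confusion[gen_models[i], selected[i]] + 1
  confusion <- confusion / rowSums(confusion)
  structure(list(param_recovery = do.call(rbind, rows), confusion = confusion,
                 fits = fits), class = "recovery_report")
}
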