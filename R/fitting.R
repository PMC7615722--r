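# Maximum-likelihood fitting of the candidate choice models. The likelihood
# replays learning from the observed choices and outcomes (never from
# model-sampled choices); missed trials are excluded and advance no update.

FIT_NLL_FLOOR <- 1e-12

# Flatten a trial log into the vectors the compiled likelihood consumes.
prepare_choice_data <- function(logs, feedback = "both") {
  stopifnot(all(c("left_stim", "right_stim", "phase", "choice_side") %in% names(logs)))
  stims <- sort(unique(c(logs$left_stim, logs$right_stim)))
  missed <- if ("missed" %in% names(logs)) as.integer(logs$missed == 1) else
    rep(0L, nrow(logs))
  missed[is.na(logs$choice_side)] <- 1L
  r_left <- r_right <- rep(NA_real_, nrow(logs))
  if ("outcome_points_left" %in% names(logs)) {
    r_left <- logs$outcome_points_left / REWARD_SCALE
    r_right <- logs$outcome_points_right / REWARD_SCALE
  }
  has_outcome <- is.finite(r_left) & is.finite(r_right)
  update_q <- integer(nrow(logs))
  if (feedback != "none")
    update_q[logs$phase == "training" & has_outcome] <-
      if (feedback == "both") 2L else 1L
  list(
    left = match(logs$left_stim, stims),
    right = match(logs$right_stim, stims),
    chose_left = as.integer(!is.na(logs$choice_side) & logs$choice_side == "left"),
    r_left = r_left, r_right = r_right,
    update_q = update_q, missed = missed,
    n_stim = length(stims),
    n_completed = sum(missed == 0L)
  )
}

nll_from_theta <- function(theta, data, q0, ck0) {
  .nll_rlck(data$left, data$right, data$chose_left, data$r_left, data$r_right,
            data$update_q, data$missed, data$n_stim,
            theta[["alpha_q"]], theta[["beta_q"]],
            theta[["alpha_h"]], theta[["beta_h"]], q0, ck0)
}

#' Negative log-likelihood of a model on a session log
#'
#' Sums `-log P(observed choice)` over completed trials, replaying the
#' learning updates from the observed choices and outcomes. For the random
#' model the result is exactly `n log 2`.
#'
#' @param params a [model_params()] or [two_step_params()] object.
#' @param logs trial-log data frame, chronologically ordered (training
#'   sessions followed by test), or a two-stage session log for
#'   [two_step_params()].
#' @param q0,ck0 initial learner values.
#' @param feedback feedback regime assumed for training-phase q updates.
#' @return negative log-likelihood in nats.
#' @export
nll <- function(params, logs, q0 = 0.5, ck0 = 0.5, feedback = "both") {
  if (inherits(params, "two_step_params")) return(nll_two_step(params, logs))
  stopifnot(inherits(params, "model_params"))
  data <- prepare_choice_data(logs, feedback)
  if (params$model_id == "random") return(data$n_completed * log(2))
  nll_from_theta(effective_params(params), data, q0, ck0)
}

model_bounds <- function(model_id) {
  if (model_id == "twostep_hybrid")
    return(list(lower = c(alpha = 0, beta = 0, lam = 0, pi = -5, rho = -5, w = 0),
                upper = c(alpha = 1, beta = 20, lam = 1, pi = 5, rho = 5, w = 1)))
  nm <- model_param_names(model_id)
  lower <- setNames(rep(0, length(nm)), nm)
  upper <- setNames(ifelse(startsWith(nm, "alpha"), 1, 10), nm)
  list(lower = lower, upper = upper)
}

theta_to_params <- function(model_id, theta) {
  if (model_id == "twostep_hybrid")
    return(two_step_params(theta[["alpha"]], theta[["beta"]], theta[["lam"]],
                           theta[["pi"]], theta[["rho"]], theta[["w"]]))
  do.call(model_params, c(list(model_id = model_id), as.list(theta)))
}

#' Akaike and Bayesian information criteria
#'
#' @param nll negative log-likelihood in nats.
#' @param n_params number of free parameters.
#' @param n_trials number of completed trials entering the likelihood.
#' @return list with `aic = 2 k + 2 nll` and `bic = k log n + 2 nll`.
#' @export
information_criteria <- function(nll, n_params, n_trials) {
  stopifnot(n_trials >= 1, n_params >= 0, nll >= 0)
  list(aic = 2 * n_params + 2 * nll, bic = n_params * log(n_trials) + 2 * nll)
}

#' Multi-start bounded maximum-likelihood fit
#'
#' Runs L-BFGS-B from `n_starts` seeded uniform draws within the parameter
#' bounds (learning rates and `w` in \[0,1\], inverse temperatures in \[0,10\],
#' two-stage `beta` in \[0,20\], `pi`/`rho` in \[-5,5\]) and keeps the lowest
#' negative log-likelihood, ties broken by the earliest start.
#'
#' @param model_id one of `"random"`, `"rl"`, `"ck"`, `"rl_ck"`,
#'   `"rl_ck_reduced"`, or `"twostep_hybrid"`.
#' @param logs session log(s) as in [nll()].
#' @param n_starts number of optimisation restarts.
#' @param seed integer seed for the start draws.
#' @param participant_id identifier stored in the result.
#' @param min_trials refuse to fit logs with fewer completed trials than this
#'   (signalled as an error of class `habitkit_too_few_trials`, distinct from
#'   convergence failure).
#' @inheritParams nll
#' @return object of class `fit_result` with elements `params`, `estimates`,
#'   `nll`, `n_params`, `n_trials`, `aic`, `bic`, `n_starts`,
#'   `best_start_index`, `converged` and `seed`.
#' @export
fit_mle <- function(model_id, logs, n_starts = 10, seed = 1L,
                    participant_id = NA_character_, min_trials = 30,
                    q0 = 0.5, ck0 = 0.5, feedback = "both") {
  model_id <- match.arg(model_id, c(MODEL_IDS, "twostep_hybrid"))
  two_step <- model_id == "twostep_hybrid"
  if (two_step) {
    n_completed <- nrow(logs)
    obj <- function(theta) nll_two_step(theta_to_params(model_id, theta), logs)
  } else {
    data <- prepare_choice_data(logs, feedback)
    n_completed <- data$n_completed
  }
  if (n_completed < min_trials)
    stop(structure(class = c("habitkit_too_few_trials", "error", "condition"),
                   list(message = sprintf(
                     "only %d completed trials; need at least %d", n_completed,
                     min_trials), call = sys.call())))

  if (model_id == "random") {
    value <- n_completed * log(2)
    ic <- information_criteria(value, 0L, n_completed)
    return(structure(list(
      participant_id = participant_id, model_id = model_id,
      params = model_params("random"), estimates = setNames(numeric(0), character(0)),
      nll = value, n_params = 0L, n_trials = n_completed,
      aic = ic$aic, bic = ic$bic, n_starts = 0L, best_start_index = 0L,
      converged = TRUE, seed = as.integer(seed)), class = "fit_result"))
  }

  b <- model_bounds(model_id)
  k <- length(b$lower)
  if (!two_step) {
    theta_full <- function(theta) {
      ep <- c(alpha_q = 0, beta_q = 0, alpha_h = 0, beta_h = 0)
      ep[names(theta)] <- theta
      if (model_id == "rl_ck_reduced") ep[["beta_q"]] <- 10 - ep[["beta_h"]]
      ep
    }
    obj <- function(theta) {
      names(theta) <- names(b$lower)
      nll_from_theta(theta_full(theta), data, q0, ck0)
    }
  } else {
    obj_named <- obj
    obj <- function(theta) {
      names(theta) <- names(b$lower)
      obj_named(theta)
    }
  }

  starts <- with_seed(seed, {
    matrix(runif(n_starts * k, rep(b$lower, each = n_starts),
                 rep(b$upper, each = n_starts)), n_starts, k,
           dimnames = list(NULL, names(b$lower)))
  })
  best <- NULL
  best_i <- 0L
  any_ok <- FALSE
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B",
            lower = b$lower, upper = b$upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$convergence == 0
    any_ok <- any_ok || ok
    if (is.null(best) || res$value < best$value - FIT_NLL_FLOOR) {
      best <- res
      best_i <- i
    }
  }
  if (is.null(best))
    stop("all optimisation starts failed", call. = FALSE)
  theta <- setNames(best$par, names(b$lower))
  ic <- information_criteria(best$value, k, n_completed)
  structure(list(
    participant_id = participant_id, model_id = model_id,
    params = theta_to_params(model_id, theta), estimates = theta,
    nll = best$value, n_params = k, n_trials = n_completed,
    aic = ic$aic, bic = ic$bic, n_starts = as.integer(n_starts),
    best_start_index = best_i, converged = any_ok,
    seed = as.integer(seed)), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model=%s participant=%s\n", x$model_id,
              x$participant_id))
  cat(sprintf("  nll=%.3f aic=%.3f bic=%.3f (k=%d, n=%d, converged=%s)\n",
              x$nll, x$aic, x$bic, x$n_params, x$n_trials, x$converged))
  if (length(x$estimates))
    cat("  ", paste(sprintf("%s=%.3f", names(x$estimates), x$estimates),
                    collapse = " "), "\n")
  invisible(x)
}

#' Flatten fit results into a summary table
#'
#' @param fits list of `fit_result` objects.
#' @return data frame with one row per fit; parameter estimates in columns
#'   prefixed `par_`.
#' @export
fits_to_data_frame <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "fit_result")))
  par_names <- unique(unlist(lapply(fits, function(f) names(f$estimates))))
  rows <- lapply(fits, function(f) {
    row <- data.frame(participant_id = f$participant_id, model_id = f$model_id,
                      nll = f$nll, n_params = f$n_params, n_trials = f$n_trials,
                      aic = f$aic, bic = f$bic, converged = f$converged,
                      stringsAsFactors = FALSE)
    for (nm in par_names)
      row[[paste0("par_", nm)]] <-
        if (nm %in% names(f$estimates)) f$estimates[[nm]] else NA_real_
    row
  })
  do.call(rbind, rows)
}
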