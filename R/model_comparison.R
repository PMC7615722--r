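# Group-level random-effects Bayesian model selection: each subject is
# allowed their own generating model, model frequencies get a Dirichlet
# prior, and the variational scheme of Stephan-style BMS estimates the
# posterior concentration from per-subject log model evidence (approximated
# as -AIC/2 or -BIC/2).

#' Evidence category for an absolute BIC difference
#'
#' Differences below 6 are insufficient evidence for either model, 6-10
#' strong, and above 10 very strong evidence for the lower-BIC model.
#'
#' @param delta_bic non-negative absolute BIC difference(s).
#' @return factor with levels `insufficient`, `strong`, `very_strong`.
#' @export
bic_evidence_category <- function(delta_bic) {
  if (any(!is.finite(delta_bic)) || any(delta_bic < 0))
    stop("'delta_bic' must be non-negative and finite", call. = FALSE)
  factor(ifelse(delta_bic > 10, "very_strong",
                ifelse(delta_bic >= 6, "strong", "insufficient")),
         levels = c("insufficient", "strong", "very_strong"))
}

#' Random-effects group Bayesian model selection
#'
#' Variational scheme over per-subject log model evidence `L` (N subjects x K
#' models): starting from a uniform Dirichlet prior (concentration 1 per
#' model), iterate responsibilities
#' `u_nk` proportional to `exp(L_nk + digamma(alpha_k) - digamma(sum alpha))`,
#' then `alpha = 1 + colSums(u)`, until the concentration stabilises.
#' Exceedance probabilities (the posterior probability that each model is the
#' most frequent in the population) are computed analytically via the Beta
#' distribution when K = 2, otherwise by Dirichlet Monte Carlo.
#'
#' @param log_evidence N x K matrix of per-subject log evidence; adding any
#'   per-row constant leaves the result unchanged.
#' @param n_samples Dirichlet draws for the exceedance estimate.
#' @param seed integer seed for the sampling.
#' @param prior_alpha Dirichlet prior concentration per model.
#' @param max_iter,tol convergence controls for the variational loop.
#' @return list of class `bms_result`: `alpha`, `expected_freq`, `exceedance`,
#'   `n_subjects`, `n_samples`, `seed`, `converged`.
#' @export
group_bms <- function(log_evidence, n_samples = 1e5, seed = 1L,
                      prior_alpha = 1, max_iter = 1e4, tol = 1e-6) {
  log_evidence <- as.matrix(log_evidence)
  if (!all(is.finite(log_evidence)))
    stop("log evidence must be finite", call. = FALSE)
  K <- ncol(log_evidence)
  N <- nrow(log_evidence)
  if (K < 2) stop("need at least two models", call. = FALSE)
  alpha <- rep(prior_alpha, K)
  converged <- FALSE
  if (N > 0) {
    for (it in seq_len(max_iter)) {
      w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
      w <- w - apply(w, 1, max)
      u <- exp(w)
      u <- u / rowSums(u)
      alpha_new <- prior_alpha + colSums(u)
      if (max(abs(alpha_new - alpha)) < tol) {
        alpha <- alpha_new
        converged <- TRUE
        break
      }
      alpha <- alpha_new
    }
  } else converged <- TRUE
  expected_freq <- alpha / sum(alpha)
  if (N == 0) {
    exceedance <- rep(1 / K, K)
  } else if (K == 2) {
    p1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    exceedance <- c(p1, 1 - p1)
  } else {
    exceedance <- with_seed(seed, {
      draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                      n_samples, K)
      tabulate(max.col(draws, ties.method = "random"), K) / n_samples
    })
  }
  nms <- colnames(log_evidence)
  if (!is.null(nms)) {
    names(alpha) <- names(expected_freq) <- names(exceedance) <- nms
  }
  structure(list(alpha = alpha, expected_freq = expected_freq,
                 exceedance = exceedance, n_subjects = N,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 converged = converged), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result> N=%d subjects, K=%d models (converged=%s)\n",
              x$n_subjects, length(x$alpha), x$converged))
  print(round(rbind(alpha = x$alpha, expected_freq = x$expected_freq,
                    exceedance = x$exceedance), 4))
  invisible(x)
}

# Draw parameters for one model from the default recovery priors:
# learning rates Beta(2,2), inverse temperatures Uniform(1,9). Uses the
# active RNG.
draw_model_params <- function(model_id,
                              rate_draw = function() rbeta(1, 2, 2),
                              beta_draw = function() runif(1, 1, 9)) {
  switch(model_id,
         random = model_params("random"),
         rl = model_params("rl", alpha_q = rate_draw(), beta_q = beta_draw()),
         ck = model_params("ck", alpha_h = rate_draw(), beta_h = beta_draw()),
         rl_ck = model_params("rl_ck", alpha_q = rate_draw(), beta_q = beta_draw(),
                              alpha_h = rate_draw(), beta_h = beta_draw()),
         rl_ck_reduced = model_params("rl_ck_reduced", alpha_q = rate_draw(),
                                      alpha_h = rate_draw(), beta_h = beta_draw()))
}

#' Model-recovery confusion matrix
#'
#' For each generating model, simulates `n_subjects` synthetic participants
#' on the rewarded pair task (training plus test), fits every model in the
#' set, and assigns each subject to the lowest-BIC model. Rows (generating)
#' sum to 1.
#'
#' @param model_set character vector of model ids.
#' @param n_subjects simulated subjects per generating model.
#' @param days number of training sessions per subject.
#' @param seed integer seed.
#' @param n_starts optimisation restarts per fit.
#' @param param_priors optional list with `rate_draw`/`beta_draw` functions
#'   overriding the default priors (rates Beta(2,2), temperatures U(1,9)).
#' @return K x K matrix, rows = generating model, columns = selected model.
#' @export
model_recovery <- function(model_set = MODEL_IDS, n_subjects = 10, days = 5,
                           seed = 1L, n_starts = 5, param_priors = list()) {
  model_set <- match.arg(model_set, MODEL_IDS, several.ok = TRUE)
  K <- length(model_set)
  conf <- matrix(0, K, K, dimnames = list(generating = model_set,
                                          selected = model_set))
  draw_args <- param_priors[intersect(names(param_priors),
                                      c("rate_draw", "beta_draw"))]
  idx <- 0L
  for (g in model_set) {
    for (s in seq_len(n_subjects)) {
      idx <- idx + 1L
      sub_seed <- child_seed(seed, idx)
      gen <- with_seed(sub_seed, do.call(draw_model_params, c(list(g), draw_args)))
      log <- simulate_reward_pairs_participant(gen, days = days, seed = sub_seed)$log
      bics <- vapply(model_set, function(m) {
        fit_mle(m, log, n_starts = n_starts, seed = child_seed(sub_seed, match(m, model_set)))$bic
      }, numeric(1))
      conf[g, which.min(bics)] <- conf[g, which.min(bics)] + 1
    }
  }
  conf / n_subjects
}
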