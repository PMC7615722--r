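# Analytic power for the independent-groups t test, using the exact
# noncentral-t distribution (no normal approximation -- the approximation
# shifts the boundary sample sizes).

#' Power of a two-sample t test with equal groups
#'
#' Exact noncentral-t evaluation: with `n_total` split evenly, the test
#' statistic under the alternative follows a noncentral t with
#' `df = n_total - 2` and noncentrality `d * sqrt(n_total / 4)`.
#'
#' @param n_total total sample size (even; both groups `n_total / 2`).
#' @param d Cohen's d > 0.
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return power in (0, 1).
#' @export
power_two_sample_t <- function(n_total, d, alpha = 0.05, tails = 2) {
  stopifnot(d > 0, alpha > 0, alpha < 1, tails %in% c(1, 2))
  if (n_total %% 2 != 0 || n_total < 4)
    stop("'n_total' must be an even total of at least 4 (equal groups)",
         call. = FALSE)
  df <- n_total - 2
  ncp <- d * sqrt(n_total / 4)
  if (tails == 2) {
    tcrit <- qt(1 - alpha / 2, df)
    (1 - pt(tcrit, df, ncp)) + pt(-tcrit, df, ncp)
  } else {
    1 - pt(qt(1 - alpha, df), df, ncp)
  }
}

#' Smallest even total sample size reaching a target power
#'
#' Integer search over even totals with [power_two_sample_t()].
#'
#' @inheritParams power_two_sample_t
#' @param target_power required power in (0, 1).
#' @param n_max search ceiling.
#' @return list with `n_total` and `achieved_power`.
#' @export
required_n_two_sample_t <- function(d, alpha = 0.05, target_power = 0.95,
                                    tails = 2, n_max = 1e6) {
  stopifnot(d > 0, target_power > 0, target_power < 1)
  n <- 4
  while (n <= n_max) {
    pw <- power_two_sample_t(n, d, alpha, tails)
    if (pw >= target_power) return(list(n_total = n, achieved_power = pw))
    n <- n + 2
  }
  stop("target power not attainable below n_max = ", n_max, call. = FALSE)
}
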