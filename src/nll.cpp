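#include <Rcpp.h>
using namespace Rcpp;

// Replayed negative log-likelihood for the RL / choice-kernel model family.
// Learning state is advanced from the observed choices and outcomes; missed
// trials contribute nothing and trigger no update. Rewards must already be
// rescaled to [0,1]; update_q codes the feedback regime per trial
// (0 = none, 1 = chosen only, 2 = both displayed outcomes).
// [[Rcpp::export(name = ".nll_rlck")]]
double nll_rlck(IntegerVector left, IntegerVector right, IntegerVector chose_left,
                NumericVector r_left, NumericVector r_right,
                IntegerVector update_q, IntegerVector missed, int n_stim,
                double alpha_q, double beta_q, double alpha_h, double beta_h,
                double q0, double ck0) {
  int n = left.size();
  std::vector<double> q(n_stim, q0), ck(n_stim, ck0);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (missed[t] == 1) continue;
    int l = left[t] - 1, r = right[t] - 1;
    double x = beta_q * (q[l] - q[r]) + beta_h * (ck[l] - ck[r]);
    // log P(observed side) via stable log(1 + exp(-|x|)) form
    double p_log;
    if (chose_left[t] == 1) {
      p_log = (x >= 0) ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
    } else {
      p_log = (x <= 0) ? -log1p(std::exp(x)) : -x - log1p(std::exp(-x));
    }
    nll -= p_log;
    int ch = (chose_left[t] == 1) ? l : r;
    int un = (chose_left[t] == 1) ? r : l;
    double r_ch = (chose_left[t] == 1) ? r_left[t] : r_right[t];
    double r_un = (chose_left[t] == 1) ? r_right[t] : r_left[t];
    if (update_q[t] >= 1 && R_finite(r_ch)) q[ch] += alpha_q * (r_ch - q[ch]);
    if (update_q[t] == 2 && R_finite(r_un)) q[un] += alpha_q * (r_un - q[un]);
    ck[ch] += alpha_h * (1.0 - ck[ch]);
    ck[un] += alpha_h * (0.0 - ck[un]);
  }
  return nll;
}
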