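#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of softmax Q-learning choices over one subject's
// trial record. Q values reset to zero at each run boundary (new stimulus
// pairs per run). Only the chosen stimulus's Q is updated.
// condition: 0 = gain, 1 = loss, 2 = neutral; run: 1-based run index;
// chose_correct: 0/1; outcome in normalized currency units.
// [[Rcpp::export]]
double qlik_nll_cpp(IntegerVector condition, IntegerVector chose_correct,
                    NumericVector outcome, IntegerVector run,
                    double alpha_gain, double alpha_loss, double alpha_neutral,
                    double beta, double eps = 1e-12) {
  int n = condition.size();
  double q[3][2];           // [condition][0 = incorrect, 1 = correct]
  double alphas[3] = {alpha_gain, alpha_loss, alpha_neutral};
  int cur_run = -2147483647;
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (run[t] != cur_run) {
      cur_run = run[t];
      for (int c = 0; c < 3; ++c) { q[c][0] = 0.0; q[c][1] = 0.0; }
    }
    int c = condition[t];
    double dq = q[c][1] - q[c][0];
    double pc = 1.0 / (1.0 + std::exp(-beta * dq));
    double p = chose_correct[t] ? pc : 1.0 - pc;
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    nll -= std::log(p);
    int ch = chose_correct[t] ? 1 : 0;
    q[c][ch] += alphas[c] * (outcome[t] - q[c][ch]);
  }
  return nll;
}
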