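#include <Rcpp.h>
using namespace Rcpp;

// numerically stable logistic; large |x| saturates without overflow
static inline double logistic(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Forward pass of the delta-rule / softmax-with-perseveration model.
// choice, high_side: per-trial, coded 1 = right, 0 = left.
// value_low/value_high: per-trial reward values of the two solutions;
// the reward delivered is value_high when the chosen side is the high side.
// Values persist across session boundaries; only the side mapping changes.
// [[Rcpp::export]]
double rl_nll_core(IntegerVector choice, IntegerVector high_side,
                   NumericVector value_low, NumericVector value_high,
                   double alpha, double beta, double chi, double v0,
                   double p_floor) {
  int n = choice.size();
  double vL = v0, vR = v0, nll = 0.0;
  int prev = -1;  // no previous choice before the first trial
  for (int t = 0; t < n; ++t) {
    double persev = (prev < 0) ? 0.0 : (prev == 1 ? 1.0 : -1.0);
    double pR = logistic(beta * (vR - vL) + chi * persev);
    double p = (choice[t] == 1) ? pR : 1.0 - pR;
    if (p < p_floor) p = p_floor;
    nll -= std::log(p);
    double reward = (choice[t] == high_side[t]) ? value_high[t] : value_low[t];
    if (choice[t] == 1) vR += alpha * (reward - vR);
    else                vL += alpha * (reward - vL);
    prev = choice[t];
  }
  return nll;
}

// Generative counterpart of rl_nll_core; draws choices from R's RNG so
// set.seed() gives full reproducibility.
// [[Rcpp::export]]
IntegerVector rl_simulate_core(IntegerVector high_side,
                               NumericVector value_low, NumericVector value_high,
                               double alpha, double beta, double chi, double v0) {
  int n = high_side.size();
  IntegerVector choice(n);
  double vL = v0, vR = v0;
  int prev = -1;
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    double persev = (prev < 0) ? 0.0 : (prev == 1 ? 1.0 : -1.0);
    double pR = logistic(beta * (vR - vL) + chi * persev);
    int c = (unif_rand() < pR) ? 1 : 0;
    choice[t] = c;
    double reward = (c == high_side[t]) ? value_high[t] : value_low[t];
    if (c == 1) vR += alpha * (reward - vR);
    else        vL += alpha * (reward - vL);
    prev = c;
  }
  return choice;
}
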