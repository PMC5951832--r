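#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the standard trial-level RL model. The value resets at
// every block start (trial_in_block == 1) to the initial value conditioned
// on the previous block's type (ctx: 0 none, 1 s1, 2 s2) and is updated by
// the delta rule within the block.
// [[Rcpp::export]]
List rl_forward_standard(IntegerVector trial_in_block, NumericVector reward,
                         IntegerVector ctx, double alpha, double gain,
                         double offset, NumericVector init_values) {
  int n = trial_in_block.size();
  NumericVector value_pre(n), rpe(n), predicted(n);
  double v = init_values[0];
  for (int i = 0; i < n; ++i) {
    if (trial_in_block[i] == 1) v = init_values[ctx[i]];
    double d = reward[i] - v;
    value_pre[i] = v;
    rpe[i] = d;
    predicted[i] = gain * d + offset;
    v += alpha * d;
  }
  return List::create(_["value_pre"] = value_pre, _["rpe"] = rpe,
                      _["predicted_da"] = predicted);
}

// Forward pass of the belief-state RL model. The belief resets at block
// start to the context-conditioned prior (rows of `prior`: none, s1, s2);
// the value on each trial uses the pre-outcome belief and the current
// weights; the posterior is computed in log space from Gaussian reward
// likelihoods N(r; mean_s, sigma2); weights are updated with the post-
// outcome belief (credit_post) or the pre-outcome belief, and carry across
// blocks.
// [[Rcpp::export]]
List rl_forward_belief(IntegerVector trial_in_block, NumericVector reward,
                       IntegerVector ctx, double alpha, double gain,
                       double offset, NumericMatrix prior,
                       NumericVector state_means, double sigma2,
                       NumericVector weights_init, bool credit_post) {
  int n = trial_in_block.size();
  int k = state_means.size();
  NumericVector value_pre(n), rpe(n), predicted(n);
  NumericMatrix belief_pre(n, k), belief_post(n, k), weights(n, k);
  std::vector<double> b(k), bpost(k), w(k), logp(k);
  for (int j = 0; j < k; ++j) w[j] = weights_init[j];
  double inv2s2 = 1.0 / (2.0 * sigma2);

  for (int i = 0; i < n; ++i) {
    if (trial_in_block[i] == 1) {
      int c = ctx[i];
      for (int j = 0; j < k; ++j) b[j] = prior(c, j);
    }
    double v = 0.0;
    for (int j = 0; j < k; ++j) v += w[j] * b[j];
    double d = reward[i] - v;
    value_pre[i] = v;
    rpe[i] = d;
    predicted[i] = gain * d + offset;

    // Bayes update in log space
    double mx = -std::numeric_limits<double>::infinity();
    for (int j = 0; j < k; ++j) {
      double dr = reward[i] - state_means[j];
      logp[j] = (b[j] > 0.0) ? std::log(b[j]) - dr * dr * inv2s2
                             : -std::numeric_limits<double>::infinity();
      if (logp[j] > mx) mx = logp[j];
    }
    double tot = 0.0;
    for (int j = 0; j < k; ++j) {
      bpost[j] = std::exp(logp[j] - mx);
      tot += bpost[j];
    }
    for (int j = 0; j < k; ++j) bpost[j] /= tot;

    for (int j = 0; j < k; ++j) {
      belief_pre(i, j) = b[j];
      belief_post(i, j) = bpost[j];
      weights(i, j) = w[j];
    }
    const std::vector<double>& credit = credit_post ? bpost : b;
    for (int j = 0; j < k; ++j) w[j] += alpha * d * credit[j];
    b = bpost;
  }
  return List::create(_["value_pre"] = value_pre, _["rpe"] = rpe,
                      _["predicted_da"] = predicted,
                      _["belief_pre"] = belief_pre,
                      _["belief_post"] = belief_post, _["weights"] = weights);
}

// Mean of x within integer groups 1..ngroups (used to form predicted
// condition averages inside the likelihood).
// [[Rcpp::export]]
NumericVector group_means_cpp(NumericVector x, IntegerVector group, int ngroups) {
  NumericVector sums(ngroups), counts(ngroups);
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    int g = group[i] - 1;
    sums[g] += x[i];
    counts[g] += 1.0;
  }
  for (int g = 0; g < ngroups; ++g) sums[g] = counts[g] > 0 ? sums[g] / counts[g] : NA_REAL;
  return sums;
}
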