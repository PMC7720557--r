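#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for one state-count class of unordered characters
// under the k-state Markov model with (possibly non-uniform) stationary
// frequencies, mixed over discrete rate and frequency categories.
//
// Transition probabilities use the closed form of the equal-exchange model:
//   P_ij(v) = e^{-mu v} delta_ij + (1 - e^{-mu v}) pi_j,
// with mu = 1 / (1 - sum pi^2) so that v is in expected substitutions per
// character (uniform pi gives the familiar Mk form with mu = k/(k-1)).
//
// tip_partials is a k x n_tip x n_char array (column-major). nu holds the
// effective length of the branch above each node (ignored at the root).
// children is (n_tip - 1) x 2, row i giving the children of postorder[i].
// When correct = true the Mkv variable-characters-only ascertainment
// denominator 1 - sum_s Pr(all tips in state s) is subtracted in log space
// from every character of the class (complete constant pseudo-patterns).
//
// Returns per-character log-likelihoods.

// [[Rcpp::export]]
NumericVector mk_class_loglik_cpp(IntegerVector postorder,
                                  IntegerMatrix children,
                                  NumericVector nu,
                                  NumericVector tip_partials,
                                  int k, int n_tip,
                                  NumericVector rates, NumericVector rate_w,
                                  NumericMatrix freqs, NumericVector freq_w,
                                  bool correct) {
  const int m = nu.size();                       // total nodes
  const int n_char = tip_partials.size() / (k * n_tip);
  const int n_const = correct ? k : 0;
  const int nc = n_char + n_const;
  const int n_rate = rates.size();
  const int n_freq = freqs.nrow();

  std::vector<double> part((size_t)m * k * nc);
  std::vector<double> acc(nc, 0.0);
  std::vector<double> pmat((size_t)m * k * k);

  // tips: copy data partials, append constant pseudo-patterns
  for (int t = 0; t < n_tip; ++t) {
    for (int c = 0; c < n_char; ++c)
      for (int i = 0; i < k; ++i)
        part[((size_t)t * k + i) * nc + c] =
          tip_partials[(size_t)c * k * n_tip + (size_t)t * k + i];
    for (int s = 0; s < n_const; ++s)
      for (int i = 0; i < k; ++i)
        part[((size_t)t * k + i) * nc + n_char + s] = (i == s) ? 1.0 : 0.0;
  }

  for (int f = 0; f < n_freq; ++f) {
    double sumsq = 0.0;
    for (int i = 0; i < k; ++i) sumsq += freqs(f, i) * freqs(f, i);
    const double mu = 1.0 / (1.0 - sumsq);
    for (int r = 0; r < n_rate; ++r) {
      const double w = rate_w[r] * freq_w[f];
      // per-node transition matrices
      for (int v = 0; v < m; ++v) {
        double e = std::exp(-mu * nu[v] * rates[r]);
        for (int i = 0; i < k; ++i)
          for (int j = 0; j < k; ++j)
            pmat[((size_t)v * k + i) * k + j] =
              (1.0 - e) * freqs(f, j) + (i == j ? e : 0.0);
      }
      // postorder combine
      for (int idx = 0; idx < postorder.size(); ++idx) {
        const int v = postorder[idx] - 1;
        const int c1 = children(idx, 0) - 1, c2 = children(idx, 1) - 1;
        for (int c = 0; c < nc; ++c) {
          for (int i = 0; i < k; ++i) {
            double l1 = 0.0, l2 = 0.0;
            for (int j = 0; j < k; ++j) {
              l1 += pmat[((size_t)c1 * k + i) * k + j] * part[((size_t)c1 * k + j) * nc + c];
              l2 += pmat[((size_t)c2 * k + i) * k + j] * part[((size_t)c2 * k + j) * nc + c];
            }
            part[((size_t)v * k + i) * nc + c] = l1 * l2;
          }
        }
      }
      // root: weight by stationary frequencies
      const int root = postorder[postorder.size() - 1] - 1;
      for (int c = 0; c < nc; ++c) {
        double s = 0.0;
        for (int i = 0; i < k; ++i)
          s += freqs(f, i) * part[((size_t)root * k + i) * nc + c];
        acc[c] += w * s;
      }
    }
  }

  double log_denom = 0.0;
  if (correct) {
    double p_const = 0.0;
    for (int s = 0; s < n_const; ++s) p_const += acc[n_char + s];
    log_denom = std::log1p(-p_const);
  }
  NumericVector out(n_char);
  for (int c = 0; c < n_char; ++c)
    out[c] = std::log(acc[c]) - log_denom;
  return out;
}

// Whole-matrix log-likelihood in one call: state-count classes are passed
// as a list of (k, tip-partial block, frequency mixture) entries and the
// per-character corrected log-likelihoods are summed in C++.
// [[Rcpp::export]]
double mk_matrix_loglik_cpp(IntegerVector postorder,
                            IntegerMatrix children,
                            NumericVector nu, List classes, int n_tip,
                            NumericVector rates, NumericVector rate_w,
                            bool correct) {
  double total = 0.0;
  for (int ci = 0; ci < classes.size(); ++ci) {
    List cl = classes[ci];
    int k = as<int>(cl["k"]);
    NumericVector tp = cl["tp"];
    NumericMatrix freqs = cl["freqs"];
    NumericVector fw = cl["fweights"];
    NumericVector out = mk_class_loglik_cpp(postorder, children, nu, tp, k,
                                            n_tip, rates, rate_w, freqs, fw,
                                            correct);
    for (int j = 0; j < out.size(); ++j) total += out[j];
    if (!std::isfinite(total)) return total;
  }
  return total;
}
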