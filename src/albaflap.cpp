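#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// LULU operators on a finite sequence, evaluated as on the bi-infinite
// constant extension (replicate padding by n at both ends). This keeps the
// defining properties -- monotone sequences are fixed points, impulses of
// width <= n are removed -- exact at the edges.

// padded vector: x[-n .. T-1+n] with end values replicated
static std::vector<double> pad_replicate(const NumericVector& x, int n) {
  int T = x.size();
  std::vector<double> p(T + 2 * n);
  for (int i = 0; i < n; ++i) p[i] = x[0];
  for (int i = 0; i < T; ++i) p[n + i] = x[i];
  for (int i = 0; i < n; ++i) p[n + T + i] = x[T - 1];
  return p;
}

// L_n(x)_i = max_{j in [i-n, i]} min_{k in [j, j+n]} x_k
// [[Rcpp::export(name = ".lulu_floor_cpp")]]
NumericVector lulu_floor_cpp(NumericVector x, int n) {
  int T = x.size();
  std::vector<double> p = pad_replicate(x, n);
  int P = (int)p.size();
  std::vector<double> m(P, 0.0); // m[j] = min over p[j .. j+n]
  for (int j = 0; j < P; ++j) {
    double v = p[j];
    int hi = std::min(P - 1, j + n);
    for (int k = j + 1; k <= hi; ++k) if (p[k] < v) v = p[k];
    m[j] = v;
  }
  NumericVector out(T);
  for (int i = 0; i < T; ++i) {
    int c = i + n; // index of sample i in the padded array
    double v = m[c - n];
    for (int j = c - n + 1; j <= c; ++j) if (m[j] > v) v = m[j];
    out[i] = v;
  }
  return out;
}

// U_n is the dual: min over j of max over k.
// [[Rcpp::export(name = ".lulu_ceil_cpp")]]
NumericVector lulu_ceil_cpp(NumericVector x, int n) {
  int T = x.size();
  std::vector<double> p = pad_replicate(x, n);
  int P = (int)p.size();
  std::vector<double> m(P, 0.0); // m[j] = max over p[j .. j+n]
  for (int j = 0; j < P; ++j) {
    double v = p[j];
    int hi = std::min(P - 1, j + n);
    for (int k = j + 1; k <= hi; ++k) if (p[k] > v) v = p[k];
    m[j] = v;
  }
  NumericVector out(T);
  for (int i = 0; i < T; ++i) {
    int c = i + n;
    double v = m[c - n];
    for (int j = c - n + 1; j <= c; ++j) if (m[j] < v) v = m[j];
    out[i] = v;
  }
  return out;
}

// Forward log-likelihood of an HMM with dense log-emission matrix.
// logdens: T x K; tpm: K x K row-stochastic; delta: initial distribution.
// Scaled recursion in log space via per-step log-sum-exp.
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(NumericMatrix logdens, NumericMatrix tpm, NumericVector delta) {
  int T = logdens.nrow(), K = logdens.ncol();
  std::vector<double> la(K), lb(K);
  double ll = 0.0;
  for (int k = 0; k < K; ++k)
    la[k] = std::log(delta[k]) + logdens(0, k);
  double mx = la[0];
  for (int k = 1; k < K; ++k) mx = std::max(mx, la[k]);
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(la[k] - mx);
  ll += mx + std::log(s);
  for (int k = 0; k < K; ++k) la[k] -= mx + std::log(s); // normalized log alpha
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += std::exp(la[j]) * tpm(j, k);
      lb[k] = std::log(acc) + logdens(t, k);
    }
    mx = lb[0];
    for (int k = 1; k < K; ++k) mx = std::max(mx, lb[k]);
    s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(lb[k] - mx);
    ll += mx + std::log(s);
    for (int k = 0; k < K; ++k) la[k] = lb[k] - (mx + std::log(s));
  }
  return ll;
}

// Viterbi most-probable path; ties broken toward the lower state index.
// Returns 1-based state indices.
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logdens, NumericMatrix tpm, NumericVector delta) {
  int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix v(T, K);
  IntegerMatrix bp(T, K);
  for (int k = 0; k < K; ++k) v(0, k) = std::log(delta[k]) + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int best = 0;
      double bv = v(t - 1, 0) + std::log(tpm(0, k));
      for (int j = 1; j < K; ++j) {
        double cand = v(t - 1, j) + std::log(tpm(j, k));
        if (cand > bv) { bv = cand; best = j; }
      }
      v(t, k) = bv + logdens(t, k);
      bp(t, k) = best;
    }
  }
  IntegerVector path(T);
  int best = 0;
  double bv = v(T - 1, 0);
  for (int k = 1; k < K; ++k) if (v(T - 1, k) > bv) { bv = v(T - 1, k); best = k; }
  path[T - 1] = best + 1;
  for (int t = T - 1; t > 0; --t) {
    best = bp(t, best);
    path[t - 1] = best + 1;
  }
  return path;
}

// Greedy refractory acceptance: candidates are supplied in descending-height
// order; a candidate is kept iff no already-kept peak lies within `refractory`
// seconds. Returns a keep flag per candidate (in the supplied order).
// [[Rcpp::export(name = ".greedy_refractory_cpp")]]
LogicalVector greedy_refractory_cpp(NumericVector times, double refractory) {
  int n = times.size();
  LogicalVector keep(n);
  std::set<double> acc;
  for (int i = 0; i < n; ++i) {
    double t = times[i];
    bool ok = true;
    std::set<double>::iterator it = acc.lower_bound(t);
    if (it != acc.end() && *it - t < refractory) ok = false;
    if (ok && it != acc.begin()) {
      --it;
      if (t - *it < refractory) ok = false;
    }
    if (ok) acc.insert(t);
    keep[i] = ok;
  }
  return keep;
}
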