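#include <Rcpp.h>
using namespace Rcpp;

// Periodized orthogonal filter-bank steps. The analysis operator is the
// matrix whose rows are even shifts of the filters; synthesis is its
// transpose, so perfect reconstruction holds exactly for orthonormal
// (Daubechies) filters.

// [[Rcpp::export]]
NumericVector wt_analysis_step(NumericVector x, NumericVector f) {
  int N = x.size(), L = f.size(), K = N / 2;
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    double s = 0.0;
    int base = 2 * k;
    for (int n = 0; n < L; ++n) {
      int idx = base + n;
      while (idx >= N) idx -= N;
      s += f[n] * x[idx];
    }
    out[k] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wt_synthesis_step(NumericVector a, NumericVector d,
                                NumericVector lo, NumericVector hi) {
  int K = a.size(), N = 2 * K, L = lo.size();
  NumericVector out(N);
  for (int k = 0; k < K; ++k) {
    int base = 2 * k;
    for (int n = 0; n < L; ++n) {
      int idx = base + n;
      while (idx >= N) idx -= N;
      out[idx] += a[k] * lo[n] + d[k] * hi[n];
    }
  }
  return out;
}

// Full wavelet-packet expansion to `depth`; returns the 2^depth leaves in
// natural (filter-path) order. Length of x must be divisible by 2^depth.
// [[Rcpp::export]]
List wpt_leaves(NumericVector x, NumericVector lo, NumericVector hi, int depth) {
  std::vector<NumericVector> nodes;
  nodes.push_back(x);
  for (int l = 0; l < depth; ++l) {
    std::vector<NumericVector> nxt;
    nxt.reserve(nodes.size() * 2);
    for (size_t i = 0; i < nodes.size(); ++i) {
      nxt.push_back(wt_analysis_step(nodes[i], lo));
      nxt.push_back(wt_analysis_step(nodes[i], hi));
    }
    nodes.swap(nxt);
  }
  List out(nodes.size());
  for (size_t i = 0; i < nodes.size(); ++i) out[i] = nodes[i];
  return out;
}

// Pattern-match counts for the approximate-entropy correlation integrals
// C_i^m(r) and C_i^(m+1)(r) (Chebyshev distance, self-match included) in a
// single symmetric O(N^2) pair scan with early exit: a length-(m+1) match
// shares its first m comparisons with the length-m match.
// [[Rcpp::export]]
List apen_counts(NumericVector x, int m, double r) {
  int N = x.size();
  int Mm = N - m + 1;   // number of length-m templates
  int Mm1 = N - m;      // number of length-(m+1) templates
  if (Mm1 < 1) stop("epoch shorter than pattern length");
  IntegerVector cm(Mm, 1), cm1(Mm1, 1);  // self matches
  const double* px = &x[0];
  int* pcm = &cm[0];
  int* pcm1 = &cm1[0];
  for (int i = 0; i < Mm; ++i) {
    const double* xi = px + i;
    for (int j = i + 1; j < Mm; ++j) {
      const double* xj = px + j;
      bool okm = true;
      for (int k = 0; k < m; ++k) {
        double d = xi[k] - xj[k];
        if (d < 0) d = -d;
        if (d > r) { okm = false; break; }
      }
      if (!okm) continue;
      pcm[i]++; pcm[j]++;
      if (j < Mm1) {
        double d = xi[m] - xj[m];
        if (d < 0) d = -d;
        if (d <= r) { pcm1[i]++; pcm1[j]++; }
      }
    }
  }
  return List::create(Rcpp::Named("cm") = cm, Rcpp::Named("cm1") = cm1);
}
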