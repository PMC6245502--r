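// Numeric kernels: semi-global DTW and the 1-D CNN primitives
// (same-padding convolution, max pooling) used by the network module.
// Batches are held as cubes with dimensions [length, channels, batch].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Semi-global dynamic time warping: the template must align end-to-end,
// the read has free (unpenalised) start and end. Local distance |a - b|;
// steps are diagonal, template-advance and read-advance (symmetric,
// unweighted). Returns the minimal path cost, the matched read interval
// (0-based, half-open) and the full warping path (1-based index pairs).
// [[Rcpp::export]]
List cpp_semiglobal_dtw(const arma::vec& tmpl, const arma::vec& read,
                        double skip_weight = 1.0) {
  const int m = tmpl.n_elem, n = read.n_elem;
  if (m > n) stop("template longer than read");
  arma::mat D(m + 1, n + 1);
  D.row(0).zeros();                 // free read prefix
  D.col(0).fill(arma::datum::inf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double d = std::abs(tmpl[i - 1] - read[j - 1]);
      // non-diagonal steps may carry extra weight on the local distance
      double best = D(i - 1, j - 1) + d;                     // diagonal
      double up = D(i - 1, j) + skip_weight * d;     // advance template
      double left = D(i, j - 1) + skip_weight * d;       // advance read
      if (up < best) best = up;
      if (left < best) best = left;
      D(i, j) = best;
    }
  }
  // free read suffix: best cell anywhere in the last row (first on ties)
  int jend = 1;
  double cost = D(m, 1);
  for (int j = 2; j <= n; ++j) {
    if (D(m, j) < cost) { cost = D(m, j); jend = j; }
  }
  // traceback, preferring diagonal, then template-advance, then read-advance
  std::vector<int> pi, pj;
  int i = m, j = jend;
  while (i >= 1) {
    pi.push_back(i);
    pj.push_back(j);
    if (i == 1 && j == 1) break;
    double d = std::abs(tmpl[i - 1] - read[j - 1]);
    double diag = D(i - 1, j - 1) + d, up = D(i - 1, j) + skip_weight * d,
           left = (j > 1) ? D(i, j - 1) + skip_weight * d
                          : arma::datum::inf;
    if (i == 1) {
      // row 1: a diagonal step into the free row 0 ends the alignment
      break;
    }
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left)            { --i; }
    else                            { --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  IntegerMatrix path(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    path(k, 0) = pi[k];
    path(k, 1) = pj[k];
  }
  return List::create(_["cost"] = cost,
                      _["read_start"] = pj.front() - 1,  // 0-based half-open
                      _["read_end"] = jend,
                      _["path"] = path);
}

// Stacked im2col over the whole batch: rows are (t within slice, slice),
// columns are (kernel offset o, input channel c) with index o*Cin + c.
// One gemm then covers every slice at once. Convolution arithmetic runs
// in single precision — the standard precision for network training,
// and roughly twice the gemm throughput — with double precision at the
// interfaces.
static arma::fmat im2col_batch_f(const arma::fcube& X, int K, int pad) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  arma::fmat Xcol(L * B, K * Cin, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int o = 0; o < K; ++o) {
      int lo = std::max(0, pad - o);          // first t with valid source
      int hi = std::min(L, L + pad - o);      // one past last valid t
      if (lo >= hi) continue;
      Xcol.submat(s * L + lo, o * Cin, s * L + hi - 1, (o + 1) * Cin - 1) =
        X.slice(s).rows(lo + o - pad, hi + o - pad - 1);
    }
  }
  return Xcol;
}

// Same-padding 1-D convolution with fused ReLU. W is [K*Cin, F] with
// row index o*Cin + c (kernel offset o, input channel c); K must be
// odd. The ReLU is applied in place so the pre-activation never has to
// be returned: the backward pass can mask on the (cached) output, since
// Y > 0 exactly where the pre-activation was > 0.
static arma::mat im2col_batch_d(const arma::cube& X, int K, int pad) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  arma::mat Xcol(L * B, K * Cin, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int o = 0; o < K; ++o) {
      int lo = std::max(0, pad - o);
      int hi = std::min(L, L + pad - o);
      if (lo >= hi) continue;
      Xcol.submat(s * L + lo, o * Cin, s * L + hi - 1, (o + 1) * Cin - 1) =
        X.slice(s).rows(lo + o - pad, hi + o - pad - 1);
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
arma::cube cpp_conv1d_forward(const arma::cube& X, const arma::mat& W,
                              const arma::rowvec& b, bool relu = true,
                              bool single = true) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int K = W.n_rows / Cin, F = W.n_cols, pad = (K - 1) / 2;
  if (!single) {   // double-precision path (used for gradient checks)
    arma::mat Xcol = im2col_batch_d(X, K, pad);
    arma::mat Yf = Xcol * W;
    Yf.each_row() += b;
    if (relu) Yf.transform([](double v) { return v > 0 ? v : 0; });
    arma::cube Y(L, F, B);
    for (int s = 0; s < B; ++s) Y.slice(s) = Yf.rows(s * L, (s + 1) * L - 1);
    return Y;
  }
  arma::fcube Xf = arma::conv_to<arma::fcube>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::frowvec bf = arma::conv_to<arma::frowvec>::from(b);
  arma::fmat Xcol = im2col_batch_f(Xf, K, pad);
  arma::fmat Yf = Xcol * Wf;               // [L*B, F]
  Yf.each_row() += bf;
  if (relu) Yf.transform([](float v) { return v > 0 ? v : 0; });
  arma::cube Y(L, F, B);
  for (int s = 0; s < B; ++s) {
    Y.slice(s) = arma::conv_to<arma::mat>::from(
      Yf.rows(s * L, (s + 1) * L - 1));
  }
  return Y;
}

// Backward pass; rebuilds the im2col matrix from the cached input
// (cheaper than round-tripping the much larger Xcol through R). With
// `want_dx = false` the input gradient is skipped entirely — used for
// the first convolution, whose input gradient has no consumer.
// [[Rcpp::export]]
List cpp_conv1d_backward(const arma::cube& X, const arma::mat& W,
                         const arma::cube& dY, bool want_dx = true,
                         bool single = true) {
  const int L = X.n_rows, Cin = X.n_cols, B = X.n_slices;
  const int K = W.n_rows / Cin, F = W.n_cols, pad = (K - 1) / 2;
  if (!single) {
    arma::mat Xcol = im2col_batch_d(X, K, pad);
    arma::mat dYf(L * B, F);
    for (int s = 0; s < B; ++s) dYf.rows(s * L, (s + 1) * L - 1) = dY.slice(s);
    arma::mat dW = Xcol.t() * dYf;
    arma::rowvec db = arma::sum(dYf, 0);
    if (!want_dx) {
      return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = R_NilValue);
    }
    arma::mat dXcol = dYf * W.t();
    arma::cube dX(L, Cin, B, arma::fill::zeros);
    for (int s = 0; s < B; ++s) {
      for (int o = 0; o < K; ++o) {
        int lo = std::max(0, pad - o);
        int hi = std::min(L, L + pad - o);
        if (lo >= hi) continue;
        dX.slice(s).rows(lo + o - pad, hi + o - pad - 1) +=
          dXcol.submat(s * L + lo, o * Cin, s * L + hi - 1,
                       (o + 1) * Cin - 1);
      }
    }
    return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
  }
  arma::fcube Xf = arma::conv_to<arma::fcube>::from(X);
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat Xcol = im2col_batch_f(Xf, K, pad);
  arma::fmat dYf(L * B, F);
  for (int s = 0; s < B; ++s) {
    dYf.rows(s * L, (s + 1) * L - 1) =
      arma::conv_to<arma::fmat>::from(dY.slice(s));
  }
  arma::mat dW = arma::conv_to<arma::mat>::from(Xcol.t() * dYf);
  arma::rowvec db = arma::conv_to<arma::rowvec>::from(arma::sum(dYf, 0));
  if (!want_dx) {
    return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = R_NilValue);
  }
  arma::fmat dXcol = dYf * Wf.t();         // [L*B, K*Cin]
  arma::fcube dXf(L, Cin, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int o = 0; o < K; ++o) {
      int lo = std::max(0, pad - o);
      int hi = std::min(L, L + pad - o);
      if (lo >= hi) continue;
      dXf.slice(s).rows(lo + o - pad, hi + o - pad - 1) +=
        dXcol.submat(s * L + lo, o * Cin, s * L + hi - 1, (o + 1) * Cin - 1);
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db,
                      _["dX"] = arma::conv_to<arma::cube>::from(dXf));
}

// Non-overlapping max pooling (width = stride = p). idx stores the 0-based
// input row of each maximum so the gradient can be routed back exactly.
// [[Rcpp::export]]
List cpp_maxpool_forward(const arma::cube& X, int p) {
  const int L = X.n_rows, C = X.n_cols, B = X.n_slices, Lo = L / p;
  arma::cube Y(Lo, C, B);
  arma::ucube idx(Lo, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* x = X.slice_colptr(s, c);
      double* y = Y.slice_colptr(s, c);
      arma::uword* ix = idx.slice_colptr(s, c);
      for (int t = 0; t < Lo; ++t) {
        int best = t * p;
        double bv = x[best];
        for (int o = 1; o < p; ++o)
          if (x[t * p + o] > bv) { bv = x[t * p + o]; best = t * p + o; }
        y[t] = bv;
        ix[t] = best;
      }
    }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_backward(const arma::cube& dY, const arma::ucube& idx,
                                int Lin) {
  const int Lo = dY.n_rows, C = dY.n_cols, B = dY.n_slices;
  arma::cube dX(Lin, C, B, arma::fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c) {
      const double* dy = dY.slice_colptr(s, c);
      const arma::uword* ix = idx.slice_colptr(s, c);
      double* dx = dX.slice_colptr(s, c);
      for (int t = 0; t < Lo; ++t) dx[ix[t]] += dy[t];
    }
  return dX;
}

// Stride-1 same-padding max pooling (odd width), used by the pooled path
// of the inception-style module.
// [[Rcpp::export]]
List cpp_maxpool_same_forward(const arma::cube& X, int w) {
  const int L = X.n_rows, C = X.n_cols, B = X.n_slices, h = (w - 1) / 2;
  arma::cube Y(L, C, B);
  arma::ucube idx(L, C, B);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < L; ++t) {
        int lo = std::max(0, t - h), hi = std::min(L - 1, t + h), best = lo;
        double bv = X(lo, c, s);
        for (int u = lo + 1; u <= hi; ++u)
          if (X(u, c, s) > bv) { bv = X(u, c, s); best = u; }
        Y(t, c, s) = bv;
        idx(t, c, s) = best;
      }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}
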