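// Compiled kernels for the hot layers: same-padded 1D convolution
// (im2col/col2im), LayerNorm, exact-erf GELU and fused multi-head
// attention, each with an analytic backward pass. The R tape wraps these;
// gradients are validated against finite differences in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& x, int k) {
  const int L = x.n_rows, d = x.n_cols, hw = (k - 1) / 2;
  mat out(L, k * d, fill::zeros);
  for (int o = 0; o < k; ++o) {
    int shift = o - hw;
    int lo = std::max(0, -shift), hi = std::min(L, L - shift);
    if (lo < hi)
      out.submat(lo, o * d, hi - 1, (o + 1) * d - 1) =
          x.rows(lo + shift, hi - 1 + shift);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& g2, int k, int L, int d) {
  const int hw = (k - 1) / 2;
  mat gx(L, d, fill::zeros);
  for (int o = 0; o < k; ++o) {
    int shift = o - hw;
    int lo = std::max(0, -shift), hi = std::min(L, L - shift);
    if (lo < hi)
      gx.rows(lo + shift, hi - 1 + shift) +=
          g2.submat(lo, o * d, hi - 1, (o + 1) * d - 1);
  }
  return gx;
}

// [[Rcpp::export]]
List cpp_layernorm_forward(const arma::mat& x, const arma::rowvec& gamma,
                           const arma::rowvec& beta, double eps) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec inv = 1.0 / sqrt(mean(xc % xc, 1) + eps);
  mat xhat = xc.each_col() % inv;
  mat y = (xhat.each_row() % gamma).each_row() + beta;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_layernorm_backward(const arma::mat& g, const arma::mat& xhat,
                            const arma::vec& inv, const arma::rowvec& gamma) {
  mat dxhat = g.each_row() % gamma;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  rowvec dgamma = sum(g % xhat, 0);
  rowvec dbeta = sum(g, 0);
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

static inline double norm_cdf(double z) {
  return 0.5 * std::erfc(-z * M_SQRT1_2);
}
static inline double norm_pdf(double z) {
  return std::exp(-0.5 * z * z) / std::sqrt(2.0 * M_PI);
}

// [[Rcpp::export]]
arma::mat cpp_gelu_forward(const arma::mat& x) {
  mat y = x;
  y.transform([](double v) { return v * norm_cdf(v); });
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_gelu_backward(const arma::mat& g, const arma::mat& x) {
  mat d = x;
  d.transform([](double v) { return norm_cdf(v) + v * norm_pdf(v); });
  return g % d;
}

static mat softmax_rows_c(mat S) {
  S.each_col() -= max(S, 1);
  S = exp(S);
  S.each_col() /= sum(S, 1);
  return S;
}

// Multi-head attention forward. mask: length-0 vector = no mask, else
// 1 = usable key, 0 = masked. Returns the output plus the cache needed
// by the backward pass.
// [[Rcpp::export]]
List cpp_mha_forward(const arma::mat& xq, const arma::mat& xkv,
                     const arma::mat& Wq, const arma::mat& Wk,
                     const arma::mat& Wv, const arma::mat& Wo,
                     int heads, const arma::ivec& mask) {
  const int d = Wq.n_cols, dh = d / heads;
  const double sc = 1.0 / std::sqrt((double)dh);
  mat Q = xq * Wq, K = xkv * Wk, V = xkv * Wv;
  cube A(Q.n_rows, K.n_rows, heads);
  mat O(Q.n_rows, d);
  uvec masked;
  if (mask.n_elem > 0) masked = find(mask == 0);
  for (int h = 0; h < heads; ++h) {
    span cols(h * dh, (h + 1) * dh - 1);
    mat S = Q.cols(cols) * K.cols(cols).t() * sc;
    if (masked.n_elem > 0) S.cols(masked).fill(-1e30);
    A.slice(h) = softmax_rows_c(S);
    O.cols(cols) = A.slice(h) * V.cols(cols);
  }
  return List::create(_["out"] = O * Wo, _["Q"] = Q, _["K"] = K,
                      _["V"] = V, _["A"] = A, _["O"] = O);
}

// [[Rcpp::export]]
List cpp_mha_backward(const arma::mat& g, const arma::mat& xq,
                      const arma::mat& xkv, const arma::mat& Q,
                      const arma::mat& K, const arma::mat& V,
                      const arma::cube& A, const arma::mat& O,
                      const arma::mat& Wq, const arma::mat& Wk,
                      const arma::mat& Wv, const arma::mat& Wo, int heads) {
  const int d = Wq.n_cols, dh = d / heads;
  const double sc = 1.0 / std::sqrt((double)dh);
  mat dWo = O.t() * g;
  mat dO = g * Wo.t();
  mat dQ(Q.n_rows, d), dK(K.n_rows, d), dV(V.n_rows, d);
  for (int h = 0; h < heads; ++h) {
    span cols(h * dh, (h + 1) * dh - 1);
    const mat& Ah = A.slice(h);
    mat dOh = dO.cols(cols);
    mat dA = dOh * V.cols(cols).t();
    dV.cols(cols) = Ah.t() * dOh;
    mat dS = (Ah % (dA.each_col() - sum(dA % Ah, 1))) * sc;
    dQ.cols(cols) = dS * K.cols(cols);
    dK.cols(cols) = dS.t() * Q.cols(cols);
  }
  return List::create(
      _["dxq"] = dQ * Wq.t(),
      _["dxkv"] = dK * Wk.t() + dV * Wv.t(),
      _["dWq"] = xq.t() * dQ, _["dWk"] = xkv.t() * dK,
      _["dWv"] = xkv.t() * dV, _["dWo"] = dWo);
}
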