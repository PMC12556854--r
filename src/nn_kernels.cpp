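// Computational kernels for the four-branch Tm regressor: valid 1-D
// convolution (im2col), LSTM forward/backward (BPTT), and the Nadam
// update. Layout conventions match the R callers exactly: batch is the
// fastest-varying index, R arrays (B, L, C) map onto arma::cube
// (rows, cols, slices) unchanged.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col: (B, L, C) -> (B*P, k*C), column j*C+c holds X[, j+p, c]
static arma::mat im2col(const arma::cube& X, int k) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int P = L - k + 1;
  arma::mat M(B * P, k * C);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c)
      M.col(j * C + c) = arma::vectorise(X.slice(c).cols(j, j + P - 1));
  return M;
}

// [[Rcpp::export(name = ".cppConv1dFwd")]]
List cppConv1dFwd(const arma::cube& X, const arma::mat& W,
                  const arma::vec& b, int k) {
  arma::mat M = im2col(X, k);
  arma::mat Y = M * W;
  Y.each_row() += b.t();
  return List::create(_["Y"] = Y, _["B"] = (int)X.n_rows,
                      _["P"] = (int)(X.n_cols - k + 1));
}

// dY: (B*P, F). Recomputes im2col from X rather than caching it.
// [[Rcpp::export(name = ".cppConv1dBwd")]]
List cppConv1dBwd(const arma::cube& X, const arma::mat& W,
                  const arma::mat& dY, int k) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int P = L - k + 1;
  arma::mat M = im2col(X, k);
  arma::mat dW = M.t() * dY;
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dM = dY * W.t();
  arma::cube dX(B, L, C, arma::fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      arma::mat block(dM.colptr(j * C + c), B, P, false, true);
      dX.slice(c).cols(j, j + P - 1) += block;
    }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// xcat: (T*B, D) stacked timesteps. Gate order: i, f, g, o.
// [[Rcpp::export(name = ".cppLstmFwd")]]
List cppLstmFwd(const arma::mat& xcat, const arma::mat& Wx,
                const arma::mat& Wh, const arma::vec& b, int Tn, int B) {
  const int H = Wh.n_cols / 4;
  arma::mat zx = xcat * Wx;
  zx.each_row() += b.t();
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  arma::mat HS(Tn * B, H), I(Tn * B, H), F(Tn * B, H), G(Tn * B, H),
      O(Tn * B, H), TC(Tn * B, H), CP(Tn * B, H), HP(Tn * B, H);
  for (int t = 0; t < Tn; ++t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    arma::mat z = zx.rows(r0, r1) + h * Wh;
    arma::mat i = sigm(z.cols(0, H - 1));
    arma::mat f = sigm(z.cols(H, 2 * H - 1));
    arma::mat g = arma::tanh(z.cols(2 * H, 3 * H - 1));
    arma::mat o = sigm(z.cols(3 * H, 4 * H - 1));
    CP.rows(r0, r1) = c;
    HP.rows(r0, r1) = h;
    c = f % c + i % g;
    arma::mat tc = arma::tanh(c);
    h = o % tc;
    I.rows(r0, r1) = i; F.rows(r0, r1) = f; G.rows(r0, r1) = g;
    O.rows(r0, r1) = o; TC.rows(r0, r1) = tc;
    HS.rows(r0, r1) = h;
  }
  return List::create(_["hs"] = HS, _["I"] = I, _["F"] = F, _["G"] = G,
                      _["O"] = O, _["TC"] = TC, _["CP"] = CP, _["HP"] = HP,
                      _["H"] = H);
}

// dhs: (T*B, H) external gradients per timestep.
// [[Rcpp::export(name = ".cppLstmBwd")]]
List cppLstmBwd(const arma::mat& dhs, const arma::mat& xcat,
                const arma::mat& Wx, const arma::mat& Wh,
                const arma::mat& HS, const arma::mat& I, const arma::mat& F,
                const arma::mat& G, const arma::mat& O, const arma::mat& TC,
                const arma::mat& CP, const arma::mat& HP, int Tn, int B) {
  const int H = Wh.n_cols / 4;
  arma::mat dWh(Wh.n_rows, Wh.n_cols, arma::fill::zeros);
  arma::mat dZcat(Tn * B, 4 * H);
  arma::mat tWh = Wh.t();
  arma::mat dh_rec(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    arma::mat i = I.rows(r0, r1), f = F.rows(r0, r1), g = G.rows(r0, r1),
        o = O.rows(r0, r1), tc = TC.rows(r0, r1), cp = CP.rows(r0, r1);
    arma::mat dh = dhs.rows(r0, r1) + dh_rec;
    arma::mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    arma::mat di = dc % g;
    arma::mat dg = dc % i;
    arma::mat df = dc % cp;
    dc = dc % f;
    arma::mat dZ(B, 4 * H);
    dZ.cols(0, H - 1) = di % i % (1.0 - i);
    dZ.cols(H, 2 * H - 1) = df % f % (1.0 - f);
    dZ.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dZ.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dZcat.rows(r0, r1) = dZ;
    dWh += HP.rows(r0, r1).t() * dZ;
    dh_rec = dZ * tWh;
  }
  arma::mat dWx = xcat.t() * dZcat;
  arma::vec db = arma::sum(dZcat, 0).t();
  arma::mat dxcat = dZcat * Wx.t();
  return List::create(_["dxcat"] = dxcat, _["dWx"] = dWx, _["dWh"] = dWh,
                      _["db"] = db);
}

// Flat Nadam update with decoupled weight decay; m, v, theta updated
// in fresh copies (R semantics preserved).
// [[Rcpp::export(name = ".cppNadam")]]
List cppNadam(const arma::vec& theta0, const arma::vec& g,
              const arma::vec& m0, const arma::vec& v0,
              const arma::uvec& decay_mask, int t, double lr, double beta1,
              double beta2, double weight_decay, double eps) {
  arma::vec m = beta1 * m0 + (1.0 - beta1) * g;
  arma::vec v = beta2 * v0 + (1.0 - beta2) * (g % g);
  const double bc1 = 1.0 - std::pow(beta1, (double)t);
  const double bc2 = 1.0 - std::pow(beta2, (double)t);
  arma::vec theta = theta0 -
    lr * (beta1 * m / bc1 + (1.0 - beta1) * g / bc1) /
      (arma::sqrt(v / bc2) + eps);
  if (weight_decay > 0) {
    arma::vec dec = theta % arma::conv_to<arma::vec>::from(decay_mask);
    theta -= (lr * weight_decay) * dec;
  }
  return List::create(_["theta"] = theta, _["m"] = m, _["v"] = v);
}
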