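// Full compiled implementation of the four-branch Tm regressor:
// forward pass, backpropagation, Nadam updates and the epoch loop run
// inside one .Call so no intermediate tensors cross the R boundary.
// The R-level graph in R/model.R is the reference implementation; the
// test suite asserts that this path reproduces its losses and
// gradients. All randomness (shuffling, dropout) is drawn from R's RNG
// so set.seed() governs training end to end.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
// The network runs in single precision internally: training is memory-
// bandwidth bound and float halves the traffic; parameters cross the R
// boundary as doubles.
using Mat = arma::fmat;
using Vec = arma::fvec;
using Cube = arma::fcube;
using arma::uvec;

namespace {

struct Cfg {
  int k, pool, f1, f2, cd1, cd2, H1, H2, kd1, kd2, kd3, nd1, nd2, pd1, pd2,
      hd1, hd2;
  int P1, Q1, P2, Q2, flat;
  double conv_drop, ph_drop, head_drop;
  double lr, b1, b2, wd, eps;
};

Cfg readCfg(const List& config) {
  Cfg c;
  IntegerVector cf = config["conv_filters"], cd = config["conv_dense"],
      lu = config["lstm_units"], kd = config["kmer_dense"],
      nd = config["cond_dense"], pd = config["ph_dense"],
      hd = config["head_dense"];
  c.k = as<int>(config["conv_kernel"]);
  c.pool = as<int>(config["pool_size"]);
  c.f1 = cf[0]; c.f2 = cf[1]; c.cd1 = cd[0]; c.cd2 = cd[1];
  c.H1 = lu[0]; c.H2 = lu[1];
  c.kd1 = kd[0]; c.kd2 = kd[1]; c.kd3 = kd[2];
  c.nd1 = nd[0]; c.nd2 = nd[1]; c.pd1 = pd[0]; c.pd2 = pd[1];
  c.hd1 = hd[0]; c.hd2 = hd[1];
  c.P1 = 100 - c.k + 1;
  c.Q1 = c.P1 / c.pool;
  c.P2 = c.Q1 - c.k + 1;
  c.Q2 = c.P2 / c.pool;
  c.flat = c.Q2 * c.f2;
  c.conv_drop = as<double>(config["conv_dropout"]);
  c.ph_drop = as<double>(config["ph_dropout"]);
  c.head_drop = as<double>(config["head_dropout"]);
  c.lr = as<double>(config["learning_rate"]);
  c.b1 = as<double>(config["beta1"]);
  c.b2 = as<double>(config["beta2"]);
  c.wd = as<double>(config["weight_decay"]);
  c.eps = as<double>(config["epsilon"]);
  return c;
}


// R-boundary conversions: doubles outside, floats inside
static Mat asF(SEXP x) {
  return arma::conv_to<Mat>::from(Rcpp::as<arma::mat>(x));
}
static Vec asFv(SEXP x) {
  return arma::conv_to<Vec>::from(Rcpp::as<arma::vec>(x));
}
static Cube asFc(const arma::cube& x) {
  return arma::conv_to<Cube>::from(x);
}
static Cube asFc(SEXP x) {
  return arma::conv_to<Cube>::from(Rcpp::as<arma::cube>(x));
}
static Rcpp::NumericMatrix outM(const Mat& x) {
  return Rcpp::wrap(arma::conv_to<arma::mat>::from(x));
}
static Rcpp::NumericVector outV(const Vec& x) {
  return Rcpp::wrap(arma::conv_to<arma::vec>::from(x));
}

// parameter bundle; field order defines the flat layout everywhere
struct Pars {
  Mat conv1_W, conv2_W, cnn_fc1_W, cnn_fc2_W;
  Vec conv1_b, conv2_b, cnn_fc1_b, cnn_fc2_b;
  Mat l1f_Wx, l1f_Wh, l1b_Wx, l1b_Wh, l2f_Wx, l2f_Wh, l2b_Wx, l2b_Wh;
  Vec l1f_b, l1b_b, l2f_b, l2b_b;
  Mat km1_W, km2_W, km3_W, cond1_W, cond2_W, ph1_W, ph2_W;
  Vec km1_b, km2_b, km3_b, cond1_b, cond2_b, ph1_b, ph2_b;
  Mat head1_W, head2_W, out_W;
  Vec head1_b, head2_b, out_b;
};

Pars readPars(const List& p) {
  Pars q;
  q.conv1_W = asF(p["conv1_W"]); q.conv1_b = asFv(p["conv1_b"]);
  q.conv2_W = asF(p["conv2_W"]); q.conv2_b = asFv(p["conv2_b"]);
  q.cnn_fc1_W = asF(p["cnn_fc1_W"]); q.cnn_fc1_b = asFv(p["cnn_fc1_b"]);
  q.cnn_fc2_W = asF(p["cnn_fc2_W"]); q.cnn_fc2_b = asFv(p["cnn_fc2_b"]);
  q.l1f_Wx = asF(p["lstm1f_Wx"]); q.l1f_Wh = asF(p["lstm1f_Wh"]);
  q.l1f_b = asFv(p["lstm1f_b"]);
  q.l1b_Wx = asF(p["lstm1b_Wx"]); q.l1b_Wh = asF(p["lstm1b_Wh"]);
  q.l1b_b = asFv(p["lstm1b_b"]);
  q.l2f_Wx = asF(p["lstm2f_Wx"]); q.l2f_Wh = asF(p["lstm2f_Wh"]);
  q.l2f_b = asFv(p["lstm2f_b"]);
  q.l2b_Wx = asF(p["lstm2b_Wx"]); q.l2b_Wh = asF(p["lstm2b_Wh"]);
  q.l2b_b = asFv(p["lstm2b_b"]);
  q.km1_W = asF(p["km_fc1_W"]); q.km1_b = asFv(p["km_fc1_b"]);
  q.km2_W = asF(p["km_fc2_W"]); q.km2_b = asFv(p["km_fc2_b"]);
  q.km3_W = asF(p["km_fc3_W"]); q.km3_b = asFv(p["km_fc3_b"]);
  q.cond1_W = asF(p["cond_fc1_W"]); q.cond1_b = asFv(p["cond_fc1_b"]);
  q.cond2_W = asF(p["cond_fc2_W"]); q.cond2_b = asFv(p["cond_fc2_b"]);
  q.ph1_W = asF(p["ph_fc1_W"]); q.ph1_b = asFv(p["ph_fc1_b"]);
  q.ph2_W = asF(p["ph_fc2_W"]); q.ph2_b = asFv(p["ph_fc2_b"]);
  q.head1_W = asF(p["head_fc1_W"]); q.head1_b = asFv(p["head_fc1_b"]);
  q.head2_W = asF(p["head_fc2_W"]); q.head2_b = asFv(p["head_fc2_b"]);
  q.out_W = asF(p["out_W"]); q.out_b = asFv(p["out_b"]);
  return q;
}

List writePars(Pars& q) {
  return List::create(
      _["conv1_W"] = outM(q.conv1_W), _["conv1_b"] = outV(q.conv1_b),
      _["conv2_W"] = outM(q.conv2_W), _["conv2_b"] = outV(q.conv2_b),
      _["cnn_fc1_W"] = outM(q.cnn_fc1_W), _["cnn_fc1_b"] = outV(q.cnn_fc1_b),
      _["cnn_fc2_W"] = outM(q.cnn_fc2_W), _["cnn_fc2_b"] = outV(q.cnn_fc2_b),
      _["lstm1f_Wx"] = outM(q.l1f_Wx), _["lstm1f_Wh"] = outM(q.l1f_Wh),
      _["lstm1f_b"] = outV(q.l1f_b),
      _["lstm1b_Wx"] = outM(q.l1b_Wx), _["lstm1b_Wh"] = outM(q.l1b_Wh),
      _["lstm1b_b"] = outV(q.l1b_b),
      _["lstm2f_Wx"] = outM(q.l2f_Wx), _["lstm2f_Wh"] = outM(q.l2f_Wh),
      _["lstm2f_b"] = outV(q.l2f_b),
      _["lstm2b_Wx"] = outM(q.l2b_Wx), _["lstm2b_Wh"] = outM(q.l2b_Wh),
      _["lstm2b_b"] = outV(q.l2b_b));
}

// List::create is limited to 20 named entries; a second block follows.
List writeParsTail(Pars& q) {
  return List::create(
      _["km_fc1_W"] = outM(q.km1_W), _["km_fc1_b"] = outV(q.km1_b),
      _["km_fc2_W"] = outM(q.km2_W), _["km_fc2_b"] = outV(q.km2_b),
      _["km_fc3_W"] = outM(q.km3_W), _["km_fc3_b"] = outV(q.km3_b),
      _["cond_fc1_W"] = outM(q.cond1_W), _["cond_fc1_b"] = outV(q.cond1_b),
      _["cond_fc2_W"] = outM(q.cond2_W), _["cond_fc2_b"] = outV(q.cond2_b),
      _["ph_fc1_W"] = outM(q.ph1_W), _["ph_fc1_b"] = outV(q.ph1_b),
      _["ph_fc2_W"] = outM(q.ph2_W), _["ph_fc2_b"] = outV(q.ph2_b),
      _["head_fc1_W"] = outM(q.head1_W), _["head_fc1_b"] = outV(q.head1_b),
      _["head_fc2_W"] = outM(q.head2_W), _["head_fc2_b"] = outV(q.head2_b),
      _["out_W"] = outM(q.out_W), _["out_b"] = outV(q.out_b));
}

struct Norm { Vec mu, inv; };

Norm readNorm(const List& ns) {
  Norm n; n.mu = asFv(ns["mu"]); n.inv = asFv(ns["inv"]);
  return n;
}

// inputs for one batch, already normalised and reshaped
struct Batch {
  Cube onehot;   // B x 100 x 4 (standardised)
  Mat kmer17;    // (17*B) x 20 stacked timesteps, standardised
  Mat cond, ph;  // B x 3, B x 1 (standardised)
  int B;
};

// standardise a (B, L, C) Cube with per-element stats (length L*C)
Cube normCube(const Cube& X, const Norm& n) {
  Cube Z = X;
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < L; ++l) {
      const int j = l + c * L;
      Z.slice(c).col(l) = (Z.slice(c).col(l) - n.mu[j]) * n.inv[j];
    }
  return Z;
}

Mat normMat(const Mat& X, const Norm& n) {
  Mat Z = X;
  for (arma::uword j = 0; j < Z.n_cols; ++j)
    Z.col(j) = (Z.col(j) - n.mu[j]) * n.inv[j];
  return Z;
}

Batch makeBatch(const Cube& onehot, const Cube& kmer, const Mat& cond,
                const Mat& ph, const uvec& idx, const Norm& n_oh,
                const Norm& n_km, const Norm& n_cd, const Norm& n_ph) {
  Batch b;
  b.B = idx.n_elem;
  Cube oh(b.B, onehot.n_cols, onehot.n_slices);
  for (arma::uword c = 0; c < onehot.n_slices; ++c)
    oh.slice(c) = onehot.slice(c).rows(idx);
  b.onehot = normCube(oh, n_oh);
  Cube km(b.B, kmer.n_cols, kmer.n_slices);
  for (arma::uword c = 0; c < kmer.n_slices; ++c)
    km.slice(c) = kmer.slice(c).rows(idx);
  km = normCube(km, n_km);
  const int Tn = km.n_cols, D = km.n_slices;
  b.kmer17.set_size(Tn * b.B, D);
  for (int d = 0; d < D; ++d)
    b.kmer17.col(d) = arma::vectorise(km.slice(d));  // row t*B+b = km(b,t,d)
  b.cond = normMat(cond.rows(idx), n_cd);
  b.ph = normMat(ph.rows(idx), n_ph);
  return b;
}

inline Mat sigm(const Mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

inline Mat dense(const Mat& X, const Mat& W, const Vec& b) {
  Mat Y = X * W;
  Y.each_row() += b.t();
  return Y;
}

Mat dropMask(int r, int c, double p) {
  Mat M(r, c);
  const double inv = 1.0 / (1.0 - p);
  for (arma::uword i = 0; i < M.n_elem; ++i)
    M[i] = (unif_rand() >= p) ? inv : 0.0;
  return M;
}

struct LstmCache { Mat I, F, G, O, TC, CP, HP, HS; };

// xcat: (T*B) x D; returns stacked hidden states, fills cache
Mat lstmF(const Mat& xcat, const Mat& Wx, const Mat& Wh, const Vec& b,
          int Tn, int B, LstmCache& cc) {
  const int H = Wh.n_cols / 4;
  Mat zx = xcat * Wx;
  zx.each_row() += b.t();
  Mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  cc.I.set_size(Tn * B, H); cc.F.set_size(Tn * B, H);
  cc.G.set_size(Tn * B, H); cc.O.set_size(Tn * B, H);
  cc.TC.set_size(Tn * B, H); cc.CP.set_size(Tn * B, H);
  cc.HP.set_size(Tn * B, H); cc.HS.set_size(Tn * B, H);
  for (int t = 0; t < Tn; ++t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    Mat z = zx.rows(r0, r1) + h * Wh;
    Mat i = sigm(z.cols(0, H - 1));
    Mat f = sigm(z.cols(H, 2 * H - 1));
    Mat g = arma::tanh(z.cols(2 * H, 3 * H - 1));
    Mat o = sigm(z.cols(3 * H, 4 * H - 1));
    cc.CP.rows(r0, r1) = c;
    cc.HP.rows(r0, r1) = h;
    c = f % c + i % g;
    Mat tc = arma::tanh(c);
    h = o % tc;
    cc.I.rows(r0, r1) = i; cc.F.rows(r0, r1) = f; cc.G.rows(r0, r1) = g;
    cc.O.rows(r0, r1) = o; cc.TC.rows(r0, r1) = tc;
    cc.HS.rows(r0, r1) = h;
  }
  return cc.HS;
}

// dhs: (T*B) x H external gradients; returns dxcat, accumulates dW
Mat lstmB(const Mat& dhs, const Mat& xcat, const Mat& Wx, const Mat& Wh,
          const LstmCache& cc, int Tn, int B, Mat& dWx, Mat& dWh, Vec& db) {
  const int H = Wh.n_cols / 4;
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  Mat dZcat(Tn * B, 4 * H);
  Mat tWh = Wh.t();
  Mat dh_rec(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = (t + 1) * B - 1;
    Mat dh = dhs.rows(r0, r1) + dh_rec;
    Mat tc = cc.TC.rows(r0, r1), o = cc.O.rows(r0, r1),
        i = cc.I.rows(r0, r1), f = cc.F.rows(r0, r1),
        g = cc.G.rows(r0, r1), cp = cc.CP.rows(r0, r1);
    Mat do_ = dh % tc;
    dc += dh % o % (1.0 - tc % tc);
    Mat di = dc % g, dg = dc % i, df = dc % cp;
    dc = dc % f;
    Mat dZ(B, 4 * H);
    dZ.cols(0, H - 1) = di % i % (1.0 - i);
    dZ.cols(H, 2 * H - 1) = df % f % (1.0 - f);
    dZ.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dZ.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dZcat.rows(r0, r1) = dZ;
    dWh += cc.HP.rows(r0, r1).t() * dZ;
    dh_rec = dZ * tWh;
  }
  dWx = xcat.t() * dZcat;
  db = arma::sum(dZcat, 0).t();
  return dZcat * Wx.t();
}

// reverse the timestep blocks of a (T*B) x D stacked matrix
Mat revTime(const Mat& X, int Tn, int B) {
  Mat R(X.n_rows, X.n_cols);
  for (int t = 0; t < Tn; ++t)
    R.rows(t * B, (t + 1) * B - 1) =
        X.rows((Tn - 1 - t) * B, (Tn - t) * B - 1);
  return R;
}

Mat im2colQ(const Cube& X, int k) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int P = L - k + 1;
  Mat M(B * P, k * C);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c)
      M.col(j * C + c) = arma::vectorise(X.slice(c).cols(j, j + P - 1));
  return M;
}

Cube col2imQ(const Mat& dM, int B, int L, int C, int k) {
  const int P = L - k + 1;
  Cube dX(B, L, C, arma::fill::zeros);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c) {
      Mat block(const_cast<float*>(dM.colptr(j * C + c)), B, P, false, true);
      dX.slice(c).cols(j, j + P - 1) += block;
    }
  return dX;
}

// max pooling of size s over the column blocks of a (B*P, F) matrix
// seen as Cube (B, P, F); ties take the earlier position
void pool2F(const Mat& Yin, int B, int P, int s, Mat& Yout,
            arma::umat& argm) {
  const int Q = P / s, F = Yin.n_cols;
  Yout.set_size(B * Q, F);
  argm.set_size(B * Q, F);
  for (int f = 0; f < F; ++f)
    for (int q = 0; q < Q; ++q)
      for (int b = 0; b < B; ++b) {
        double best = Yin(b + (q * s) * B, f);
        int besti = 0;
        for (int j = 1; j < s; ++j) {
          const double v = Yin(b + (q * s + j) * B, f);
          if (v > best) { best = v; besti = j; }
        }
        Yout(b + q * B, f) = best;
        argm(b + q * B, f) = q * s + besti;
      }
}

struct Cache {
  Mat M1, C1, R1mask, P1Y; arma::umat P1arg; Mat D1mask;
  Mat M2, C2, R2mask, P2Y; arma::umat P2arg; Mat D2mask;
  Mat flat, cf1, cr1, cnn_out;
  Mat xcat, xrev, ys, yrev;
  LstmCache l1f, l1b, l2f, l2b;
  Mat lstm_out, kf1, kf2, kf3;
  Mat sf1, sf2;
  Mat pf1, pd1m, pf2, pd2m;
  Mat concat, hf1, hf2, hdm, yhat;
};

Vec forward(const Pars& p, const Cfg& c, const Batch& bt, bool training,
            Cache& cc) {
  const int B = bt.B, Tn = 17;
  // branch 1
  cc.M1 = im2colQ(bt.onehot, c.k);
  cc.C1 = dense(cc.M1, p.conv1_W, p.conv1_b);       // (B*P1, f1)
  cc.R1mask = arma::conv_to<Mat>::from(cc.C1 > 0);
  Mat r1 = cc.C1 % cc.R1mask;
  pool2F(r1, B, c.P1, c.pool, cc.P1Y, cc.P1arg);    // (B*Q1, f1)
  Mat d1 = cc.P1Y;
  if (training && c.conv_drop > 0) {
    cc.D1mask = dropMask(d1.n_rows, d1.n_cols, c.conv_drop);
    d1 %= cc.D1mask;
  } else cc.D1mask.reset();
  Cube d1c(d1.memptr(), B, c.Q1, c.f1);
  cc.M2 = im2colQ(d1c, c.k);
  cc.C2 = dense(cc.M2, p.conv2_W, p.conv2_b);       // (B*P2, f2)
  cc.R2mask = arma::conv_to<Mat>::from(cc.C2 > 0);
  Mat r2 = cc.C2 % cc.R2mask;
  pool2F(r2, B, c.P2, c.pool, cc.P2Y, cc.P2arg);    // (B*Q2, f2)
  Mat d2 = cc.P2Y;
  if (training && c.conv_drop > 0) {
    cc.D2mask = dropMask(d2.n_rows, d2.n_cols, c.conv_drop);
    d2 %= cc.D2mask;
  } else cc.D2mask.reset();
  cc.flat = Mat(d2.memptr(), B, c.flat);            // (B, Q2*f2) view copy
  cc.cf1 = dense(cc.flat, p.cnn_fc1_W, p.cnn_fc1_b);
  cc.cr1 = cc.cf1 % arma::conv_to<Mat>::from(cc.cf1 > 0);
  cc.cnn_out = dense(cc.cr1, p.cnn_fc2_W, p.cnn_fc2_b);

  // branch 2
  cc.xcat = bt.kmer17;
  cc.xrev = revTime(cc.xcat, Tn, B);
  Mat hsf = lstmF(cc.xcat, p.l1f_Wx, p.l1f_Wh, p.l1f_b, Tn, B, cc.l1f);
  Mat hsb = lstmF(cc.xrev, p.l1b_Wx, p.l1b_Wh, p.l1b_b, Tn, B, cc.l1b);
  cc.ys.set_size(Tn * B, 2 * c.H1);
  cc.ys.cols(0, c.H1 - 1) = hsf;
  cc.ys.cols(c.H1, 2 * c.H1 - 1) = revTime(hsb, Tn, B);
  cc.yrev = revTime(cc.ys, Tn, B);
  Mat hs2f = lstmF(cc.ys, p.l2f_Wx, p.l2f_Wh, p.l2f_b, Tn, B, cc.l2f);
  Mat hs2b = lstmF(cc.yrev, p.l2b_Wx, p.l2b_Wh, p.l2b_b, Tn, B, cc.l2b);
  cc.lstm_out.set_size(B, 2 * c.H2);
  cc.lstm_out.cols(0, c.H2 - 1) = hs2f.rows((Tn - 1) * B, Tn * B - 1);
  cc.lstm_out.cols(c.H2, 2 * c.H2 - 1) = hs2b.rows((Tn - 1) * B, Tn * B - 1);
  cc.kf1 = dense(cc.lstm_out, p.km1_W, p.km1_b);
  Mat kr1 = cc.kf1 % arma::conv_to<Mat>::from(cc.kf1 > 0);
  cc.kf2 = dense(kr1, p.km2_W, p.km2_b);
  Mat kr2 = cc.kf2 % arma::conv_to<Mat>::from(cc.kf2 > 0);
  cc.kf3 = dense(kr2, p.km3_W, p.km3_b);
  Mat km_out = cc.kf3 % arma::conv_to<Mat>::from(cc.kf3 > 0);

  // branch 3
  cc.sf1 = dense(bt.cond, p.cond1_W, p.cond1_b);
  Mat sr1 = cc.sf1 % arma::conv_to<Mat>::from(cc.sf1 > 0);
  cc.sf2 = dense(sr1, p.cond2_W, p.cond2_b);
  Mat cond_out = cc.sf2 % arma::conv_to<Mat>::from(cc.sf2 > 0);

  // branch 4
  cc.pf1 = dense(bt.ph, p.ph1_W, p.ph1_b);
  Mat pr1 = cc.pf1 % arma::conv_to<Mat>::from(cc.pf1 > 0);
  if (training && c.ph_drop > 0) {
    cc.pd1m = dropMask(pr1.n_rows, pr1.n_cols, c.ph_drop);
    pr1 %= cc.pd1m;
  } else cc.pd1m.reset();
  cc.pf2 = dense(pr1, p.ph2_W, p.ph2_b);
  Mat pr2 = cc.pf2 % arma::conv_to<Mat>::from(cc.pf2 > 0);
  if (training && c.ph_drop > 0) {
    cc.pd2m = dropMask(pr2.n_rows, pr2.n_cols, c.ph_drop);
    pr2 %= cc.pd2m;
  } else cc.pd2m.reset();

  // head
  cc.concat.set_size(B, c.cd2 + c.kd3 + c.nd2 + c.pd2);
  cc.concat.cols(0, c.cd2 - 1) = cc.cnn_out;
  cc.concat.cols(c.cd2, c.cd2 + c.kd3 - 1) = km_out;
  cc.concat.cols(c.cd2 + c.kd3, c.cd2 + c.kd3 + c.nd2 - 1) = cond_out;
  cc.concat.cols(c.cd2 + c.kd3 + c.nd2, cc.concat.n_cols - 1) = pr2;
  cc.hf1 = dense(cc.concat, p.head1_W, p.head1_b);
  Mat hr1 = cc.hf1 % arma::conv_to<Mat>::from(cc.hf1 > 0);
  cc.hf2 = dense(hr1, p.head2_W, p.head2_b);
  Mat hr2 = cc.hf2 % arma::conv_to<Mat>::from(cc.hf2 > 0);
  if (training && c.head_drop > 0) {
    cc.hdm = dropMask(hr2.n_rows, hr2.n_cols, c.head_drop);
    hr2 %= cc.hdm;
  } else cc.hdm.reset();
  cc.yhat = dense(hr2, p.out_W, p.out_b);
  return cc.yhat.col(0);
}

void backward(const Pars& p, const Cfg& c, const Batch& bt, const Cache& cc,
              const Vec& dy, Pars& g) {
  const int B = bt.B, Tn = 17;
  Mat hr1 = cc.hf1 % arma::conv_to<Mat>::from(cc.hf1 > 0);
  Mat hr2 = cc.hf2 % arma::conv_to<Mat>::from(cc.hf2 > 0);
  Mat hr2d = cc.hdm.n_elem ? Mat(hr2 % cc.hdm) : hr2;
  Mat dY(dy);
  g.out_W = hr2d.t() * dY;
  g.out_b = arma::sum(dY, 0).t();
  Mat d = dY * p.out_W.t();
  if (cc.hdm.n_elem) d %= cc.hdm;
  d %= arma::conv_to<Mat>::from(cc.hf2 > 0);
  g.head2_W = hr1.t() * d;
  g.head2_b = arma::sum(d, 0).t();
  d = d * p.head2_W.t();
  d %= arma::conv_to<Mat>::from(cc.hf1 > 0);
  g.head1_W = cc.concat.t() * d;
  g.head1_b = arma::sum(d, 0).t();
  d = d * p.head1_W.t();
  Mat dcnn = d.cols(0, c.cd2 - 1);
  Mat dkm = d.cols(c.cd2, c.cd2 + c.kd3 - 1);
  Mat dcond = d.cols(c.cd2 + c.kd3, c.cd2 + c.kd3 + c.nd2 - 1);
  Mat dph = d.cols(c.cd2 + c.kd3 + c.nd2, d.n_cols - 1);

  // branch 1 backward
  Mat cr1 = cc.cr1;
  g.cnn_fc2_W = cr1.t() * dcnn;
  g.cnn_fc2_b = arma::sum(dcnn, 0).t();
  Mat d1 = dcnn * p.cnn_fc2_W.t();
  d1 %= arma::conv_to<Mat>::from(cc.cf1 > 0);
  g.cnn_fc1_W = cc.flat.t() * d1;
  g.cnn_fc1_b = arma::sum(d1, 0).t();
  Mat dflat = d1 * p.cnn_fc1_W.t();                 // (B, flat)
  Mat dP2(B * c.Q2, c.f2);
  std::memcpy(dP2.memptr(), dflat.memptr(), sizeof(float) * dflat.n_elem);
  if (cc.D2mask.n_elem) dP2 %= cc.D2mask;
  Mat dC2(B * c.P2, c.f2, arma::fill::zeros);
  for (int f = 0; f < c.f2; ++f)
    for (int q = 0; q < c.Q2; ++q)
      for (int b = 0; b < B; ++b)
        dC2(b + cc.P2arg(b + q * B, f) * B, f) += dP2(b + q * B, f);
  dC2 %= cc.R2mask;
  g.conv2_W = cc.M2.t() * dC2;
  g.conv2_b = arma::sum(dC2, 0).t();
  Mat dM2 = dC2 * p.conv2_W.t();
  Cube dD1 = col2imQ(dM2, B, c.Q1, c.f1, c.k);
  Mat dP1(dD1.memptr(), B * c.Q1, c.f1);
  if (cc.D1mask.n_elem) dP1 %= cc.D1mask;
  Mat dC1(B * c.P1, c.f1, arma::fill::zeros);
  for (int f = 0; f < c.f1; ++f)
    for (int q = 0; q < c.Q1; ++q)
      for (int b = 0; b < B; ++b)
        dC1(b + cc.P1arg(b + q * B, f) * B, f) += dP1(b + q * B, f);
  dC1 %= cc.R1mask;
  g.conv1_W = cc.M1.t() * dC1;
  g.conv1_b = arma::sum(dC1, 0).t();

  // branch 2 backward
  Mat kr2 = cc.kf2 % arma::conv_to<Mat>::from(cc.kf2 > 0);
  Mat kr1 = cc.kf1 % arma::conv_to<Mat>::from(cc.kf1 > 0);
  Mat d2 = dkm % arma::conv_to<Mat>::from(cc.kf3 > 0);
  g.km3_W = kr2.t() * d2;
  g.km3_b = arma::sum(d2, 0).t();
  d2 = d2 * p.km3_W.t();
  d2 %= arma::conv_to<Mat>::from(cc.kf2 > 0);
  g.km2_W = kr1.t() * d2;
  g.km2_b = arma::sum(d2, 0).t();
  d2 = d2 * p.km2_W.t();
  d2 %= arma::conv_to<Mat>::from(cc.kf1 > 0);
  g.km1_W = cc.lstm_out.t() * d2;
  g.km1_b = arma::sum(d2, 0).t();
  d2 = d2 * p.km1_W.t();                            // (B, 2*H2)
  Mat dh2f(Tn * B, c.H2, arma::fill::zeros);
  Mat dh2b(Tn * B, c.H2, arma::fill::zeros);
  dh2f.rows((Tn - 1) * B, Tn * B - 1) = d2.cols(0, c.H2 - 1);
  dh2b.rows((Tn - 1) * B, Tn * B - 1) = d2.cols(c.H2, 2 * c.H2 - 1);
  Mat dys = lstmB(dh2f, cc.ys, p.l2f_Wx, p.l2f_Wh, cc.l2f, Tn, B,
                  g.l2f_Wx, g.l2f_Wh, g.l2f_b);
  Mat dyrev = lstmB(dh2b, cc.yrev, p.l2b_Wx, p.l2b_Wh, cc.l2b, Tn, B,
                    g.l2b_Wx, g.l2b_Wh, g.l2b_b);
  dys += revTime(dyrev, Tn, B);
  Mat dh1f = dys.cols(0, c.H1 - 1);
  Mat dh1b = revTime(dys.cols(c.H1, 2 * c.H1 - 1), Tn, B);
  Mat dx1 = lstmB(dh1f, cc.xcat, p.l1f_Wx, p.l1f_Wh, cc.l1f, Tn, B,
                  g.l1f_Wx, g.l1f_Wh, g.l1f_b);
  Mat dx2 = lstmB(dh1b, cc.xrev, p.l1b_Wx, p.l1b_Wh, cc.l1b, Tn, B,
                  g.l1b_Wx, g.l1b_Wh, g.l1b_b);
  (void)dx1; (void)dx2;  // gradients stop at the (fixed) encodings

  // branch 3 backward
  Mat sr1 = cc.sf1 % arma::conv_to<Mat>::from(cc.sf1 > 0);
  Mat d3 = dcond % arma::conv_to<Mat>::from(cc.sf2 > 0);
  g.cond2_W = sr1.t() * d3;
  g.cond2_b = arma::sum(d3, 0).t();
  d3 = d3 * p.cond2_W.t();
  d3 %= arma::conv_to<Mat>::from(cc.sf1 > 0);
  g.cond1_W = bt.cond.t() * d3;
  g.cond1_b = arma::sum(d3, 0).t();

  // branch 4 backward
  Mat pr1 = cc.pf1 % arma::conv_to<Mat>::from(cc.pf1 > 0);
  if (cc.pd1m.n_elem) pr1 %= cc.pd1m;
  Mat d4 = dph;
  if (cc.pd2m.n_elem) d4 %= cc.pd2m;
  d4 %= arma::conv_to<Mat>::from(cc.pf2 > 0);
  g.ph2_W = pr1.t() * d4;
  g.ph2_b = arma::sum(d4, 0).t();
  d4 = d4 * p.ph2_W.t();
  if (cc.pd1m.n_elem) d4 %= cc.pd1m;
  d4 %= arma::conv_to<Mat>::from(cc.pf1 > 0);
  g.ph1_W = bt.ph.t() * d4;
  g.ph1_b = arma::sum(d4, 0).t();
}

// Nadam state per parameter, decoupled L2 decay on weight matrices
// only (biases are excluded, matching the R reference).
struct NadamFull {
  std::vector<Mat> m_w, v_w;
  std::vector<Vec> m_b, v_b;
  int t = 0;
  static std::vector<Mat*> wts(Pars& q) {
    return {&q.conv1_W, &q.conv2_W, &q.cnn_fc1_W, &q.cnn_fc2_W,
            &q.l1f_Wx, &q.l1f_Wh, &q.l1b_Wx, &q.l1b_Wh,
            &q.l2f_Wx, &q.l2f_Wh, &q.l2b_Wx, &q.l2b_Wh,
            &q.km1_W, &q.km2_W, &q.km3_W, &q.cond1_W, &q.cond2_W,
            &q.ph1_W, &q.ph2_W, &q.head1_W, &q.head2_W, &q.out_W};
  }
  static std::vector<Vec*> bss(Pars& q) {
    return {&q.conv1_b, &q.conv2_b, &q.cnn_fc1_b, &q.cnn_fc2_b,
            &q.l1f_b, &q.l1b_b, &q.l2f_b, &q.l2b_b,
            &q.km1_b, &q.km2_b, &q.km3_b, &q.cond1_b, &q.cond2_b,
            &q.ph1_b, &q.ph2_b, &q.head1_b, &q.head2_b, &q.out_b};
  }
  void init(Pars& p) {
    for (Mat* w : wts(p)) { m_w.push_back(arma::zeros<Mat>(w->n_rows, w->n_cols));
                            v_w.push_back(arma::zeros<Mat>(w->n_rows, w->n_cols)); }
    for (Vec* b : bss(p)) { m_b.push_back(arma::zeros<Vec>(b->n_elem));
                            v_b.push_back(arma::zeros<Vec>(b->n_elem)); }
  }
  void step(Pars& p, Pars& g, const Cfg& c) {
    ++t;
    const double bc1 = 1.0 - std::pow(c.b1, t);
    const double bc2 = 1.0 - std::pow(c.b2, t);
    auto pw = wts(p); auto gw = wts(g);
    for (size_t i = 0; i < pw.size(); ++i) {
      m_w[i] = c.b1 * m_w[i] + (1.0 - c.b1) * (*gw[i]);
      v_w[i] = c.b2 * v_w[i] + (1.0 - c.b2) * ((*gw[i]) % (*gw[i]));
      *pw[i] -= c.lr * (c.b1 * m_w[i] / bc1 + (1.0 - c.b1) * (*gw[i]) / bc1) /
                (arma::sqrt(v_w[i] / bc2) + c.eps);
      *pw[i] -= (c.lr * c.wd) * (*pw[i]);
    }
    auto pb = bss(p); auto gb = bss(g);
    for (size_t i = 0; i < pb.size(); ++i) {
      m_b[i] = c.b1 * m_b[i] + (1.0 - c.b1) * (*gb[i]);
      v_b[i] = c.b2 * v_b[i] + (1.0 - c.b2) * ((*gb[i]) % (*gb[i]));
      *pb[i] -= c.lr * (c.b1 * m_b[i] / bc1 + (1.0 - c.b1) * (*gb[i]) / bc1) /
                (arma::sqrt(v_b[i] / bc2) + c.eps);
    }
  }
};
}  // namespace

// [[Rcpp::export(name = ".cppModelForward")]]
NumericVector cppModelForward(const List& params, const arma::cube& onehot,
                              const arma::cube& kmer, const arma::mat& cond,
                              const arma::mat& ph, const List& normStats,
                              const List& config) {
  Cfg c = readCfg(config);
  Pars p = readPars(params);
  Norm n_oh = readNorm(normStats["onehot"]), n_km = readNorm(normStats["kmer"]),
       n_cd = readNorm(normStats["cond"]), n_ph = readNorm(normStats["ph"]);
  uvec idx = arma::regspace<uvec>(0, onehot.n_rows - 1);
  Batch bt = makeBatch(asFc(onehot), asFc(kmer), asF(wrap(cond)),
                       asF(wrap(ph)), idx, n_oh, n_km, n_cd, n_ph);
  Cache cc;
  Vec yh = forward(p, c, bt, false, cc);
  return outV(yh);
}

// [[Rcpp::export(name = ".cppLossGrad")]]
List cppLossGrad(const List& params, const arma::cube& onehot,
                 const arma::cube& kmer, const arma::mat& cond,
                 const arma::mat& ph, const arma::vec& y_in,
                 const List& normStats, const List& config, bool training) {
  Cfg c = readCfg(config);
  Pars p = readPars(params);
  Norm n_oh = readNorm(normStats["onehot"]), n_km = readNorm(normStats["kmer"]),
       n_cd = readNorm(normStats["cond"]), n_ph = readNorm(normStats["ph"]);
  Vec y = arma::conv_to<Vec>::from(y_in);
  uvec idx = arma::regspace<uvec>(0, onehot.n_rows - 1);
  Batch bt = makeBatch(asFc(onehot), asFc(kmer), asF(wrap(cond)),
                       asF(wrap(ph)), idx, n_oh, n_km, n_cd, n_ph);
  Cache cc;
  Vec yh = forward(p, c, bt, training, cc);
  Vec resid = yh - y;
  double loss = arma::mean(resid % resid);
  Vec dy = 2.0 * resid / (float)y.n_elem;
  Pars g = p;  // shapes
  backward(p, c, bt, cc, dy, g);
  List head = writePars(g), tail = writeParsTail(g);
  List grads(head.size() + tail.size());
  CharacterVector nm(head.size() + tail.size());
  CharacterVector hn = head.names(), tn = tail.names();
  for (int i = 0; i < head.size(); ++i) { grads[i] = head[i]; nm[i] = hn[i]; }
  for (int i = 0; i < tail.size(); ++i) {
    grads[head.size() + i] = tail[i]; nm[head.size() + i] = tn[i];
  }
  grads.names() = nm;
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["yhat"] = outV(yh));
}

// [[Rcpp::export(name = ".cppTrainLoop")]]
List cppTrainLoop(const List& params, const arma::cube& onehot,
                  const arma::cube& kmer, const arma::mat& cond,
                  const arma::mat& ph, const arma::vec& y_in,
                  const List& normStats, const List& config,
                  Nullable<List> val_inputs, int epochs, int batch_size,
                  int patience, int report_every = 0) {
  Cfg c = readCfg(config);
  Pars p = readPars(params);
  Norm n_oh = readNorm(normStats["onehot"]), n_km = readNorm(normStats["kmer"]),
       n_cd = readNorm(normStats["cond"]), n_ph = readNorm(normStats["ph"]);
  const int n = onehot.n_rows;
  const int bs = std::min(batch_size, n);
  Cube onehotF = asFc(onehot), kmerF = asFc(kmer);
  Mat condF = asF(wrap(cond)), phF = asF(wrap(ph));
  Vec y = arma::conv_to<Vec>::from(y_in);

  bool has_val = val_inputs.isNotNull();
  Cube v_oh, v_km; Mat v_cd, v_ph; Vec v_y; Batch vb;
  if (has_val) {
    List vl(val_inputs);
    v_oh = asFc((SEXP)vl["onehot"]); v_km = asFc((SEXP)vl["kmer"]);
    v_cd = asF(vl["cond"]); v_ph = asF(vl["ph"]);
    v_y = asFv(vl["y"]);
    uvec vidx = arma::regspace<uvec>(0, v_oh.n_rows - 1);
    vb = makeBatch(v_oh, v_km, v_cd, v_ph, vidx, n_oh, n_km, n_cd, n_ph);
  }

  NadamFull opt;
  opt.init(p);
  Pars best = p;
  double best_val = R_PosInf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> hist_train, hist_val;
  Cache cc;
  Pars g = p;

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double tot = 0;
    for (int s = 0; s < n; s += bs) {
      const int e = std::min(s + bs, n);
      uvec idx(e - s);
      for (int i = s; i < e; ++i) idx[i - s] = perm[i];
      Batch bt = makeBatch(onehotF, kmerF, condF, phF, idx, n_oh, n_km,
                           n_cd, n_ph);
      Vec yb(e - s);
      for (int i = s; i < e; ++i) yb[i - s] = y[perm[i]];
      Vec yh = forward(p, c, bt, true, cc);
      Vec resid = yh - yb;
      double loss = arma::mean(resid % resid);
      if (!std::isfinite(loss))
        stop("training diverged at epoch %d (non-finite loss); lower the learning rate",
             epoch);
      Vec dy = 2.0f * resid / (float)yb.n_elem;
      backward(p, c, bt, cc, dy, g);
      opt.step(p, g, c);
      tot += loss * (e - s);
    }
    hist_train.push_back(tot / n);
    if (report_every > 0 && epoch % report_every == 0) {
      Rcpp::Rcout << "epoch " << epoch << " train " << tot / n;
      if (has_val && !hist_val.empty())
        Rcpp::Rcout << " (last val " << hist_val.back() << ")";
      Rcpp::Rcout << std::endl;
      Rcpp::checkUserInterrupt();
    }
    epochs_run = epoch;
    if (has_val) {
      Cache vcc;
      Vec vp = forward(p, c, vb, false, vcc);
      double vmse = arma::mean(arma::square(vp - v_y));
      hist_val.push_back(vmse);
      if (vmse < best_val) {
        best_val = vmse; best = p; best_epoch = epoch; wait = 0;
      } else if (++wait > patience) break;
    } else {
      hist_val.push_back(NA_REAL);
    }
  }
  if (has_val && std::isfinite(best_val)) p = best;

  List ph_ = writePars(p), pt_ = writeParsTail(p);
  List out_params(ph_.size() + pt_.size());
  CharacterVector nm(ph_.size() + pt_.size());
  CharacterVector hn = ph_.names(), tn = pt_.names();
  for (int i = 0; i < ph_.size(); ++i) { out_params[i] = ph_[i]; nm[i] = hn[i]; }
  for (int i = 0; i < pt_.size(); ++i) {
    out_params[ph_.size() + i] = pt_[i]; nm[ph_.size() + i] = tn[i];
  }
  out_params.names() = nm;
  return List::create(_["params"] = out_params,
                      _["train_mse"] = wrap(hist_train),
                      _["val_mse"] = wrap(hist_val),
                      _["best_epoch"] = best_epoch,
                      _["epochs_run"] = epochs_run);
}
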