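// CPU training engine for the trio pileup-image classifier.
//
// Architecture: L same-padded 3x3 conv layers (ReLU); after every
// `se_every`-th conv, batch normalization (statistics over the batch and
// all pixels, per channel) followed by a squeeze-and-excitation (SE)
// channel-attention block; head = concat of global max pooling and global
// average pooling feeding a single sigmoid unit whose weights carry an L1
// penalty. Loss is binary cross-entropy. Pixel intensities are scaled to
// [0, 1] on entry.
//
// Layout: feature maps are channels x pixels matrices, pixel index
// p = x * H2 + (y + 1) with H2 = H + 2: each image column keeps one zero
// "pad" row above and below, so every 3x3 kernel shift is a contiguous
// flat column shift and convolutions run as 9 shift-GEMMs on
// cache-resident per-image blocks (no im2col materialization). Pad
// entries are re-zeroed after each operation; because they are zero,
// full-matrix row sums equal valid-pixel sums, which keeps BN statistics
// exact. A batch is channels x (H2*W*N) with per-image column blocks.
//
// Optimizer updates and the epoch loop live in R (R/network.R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;
static const double INPUT_SCALE = 1.0 / 255.0;

struct Config {
  int H, W, C, L, F, se_every, se_ratio, nbn, r;
  int H2, HWp;      // padded rows, padded pixels per image
  double Mv;        // valid pixels per image (H * W)
};

static Config read_config(const List& cfg) {
  Config c;
  c.H = as<int>(cfg["rows"]);
  c.W = as<int>(cfg["cols"]);
  c.C = as<int>(cfg["channels"]);
  c.L = as<int>(cfg["conv_layers"]);
  c.F = as<int>(cfg["filters"]);
  c.se_every = as<int>(cfg["se_every"]);
  c.se_ratio = as<int>(cfg["se_ratio"]);
  c.nbn = c.L / c.se_every;
  c.r = std::max(1, c.F / c.se_ratio);
  c.H2 = c.H + 2;
  c.HWp = c.H2 * c.W;
  c.Mv = (double)c.H * c.W;
  return c;
}

struct Params {
  std::vector<mat> conv_W;               // L of F x (Cin*9)
  std::vector<vec> conv_b;               // L of F
  std::vector<vec> bn_gamma, bn_beta, bn_rmean, bn_rvar;  // nbn of F
  std::vector<mat> se_W1, se_W2;         // nbn of r x F, F x r
  std::vector<vec> se_b1, se_b2;         // nbn of r, F
  vec head_w;                            // 2F
  double head_b;
};

static Params read_params(const List& p, const Config& c) {
  Params q;
  List cW = p["conv_W"], cb = p["conv_b"];
  for (int l = 0; l < c.L; ++l) {
    q.conv_W.push_back(as<mat>(cW[l]));
    q.conv_b.push_back(as<vec>(cb[l]));
  }
  List g = p["bn_gamma"], be = p["bn_beta"], rm = p["bn_rmean"],
       rv = p["bn_rvar"], w1 = p["se_W1"], b1 = p["se_b1"],
       w2 = p["se_W2"], b2 = p["se_b2"];
  for (int s = 0; s < c.nbn; ++s) {
    q.bn_gamma.push_back(as<vec>(g[s]));
    q.bn_beta.push_back(as<vec>(be[s]));
    q.bn_rmean.push_back(as<vec>(rm[s]));
    q.bn_rvar.push_back(as<vec>(rv[s]));
    q.se_W1.push_back(as<mat>(w1[s]));
    q.se_b1.push_back(as<vec>(b1[s]));
    q.se_W2.push_back(as<mat>(w2[s]));
    q.se_b2.push_back(as<vec>(b2[s]));
  }
  q.head_w = as<vec>(p["head_w"]);
  q.head_b = as<double>(p["head_b"]);
  return q;
}

// zero the pad rows (y = -1 and y = H) of one image block
static void zero_pads(mat& A, const Config& c) {
  for (int x = 0; x < c.W; ++x) {
    A.col((size_t)x * c.H2).zeros();
    A.col((size_t)x * c.H2 + c.H + 1).zeros();
  }
}

// alias into column block [n*HWp, (n+1)*HWp) of a batch matrix
static mat block(mat& A, const Config& c, int n) {
  return mat(A.colptr((size_t)n * c.HWp), A.n_rows, c.HWp, false, true);
}

// deep copy of an image block
static mat copy_block(mat& A, const Config& c, int n) {
  return mat(A.colptr((size_t)n * c.HWp), A.n_rows, c.HWp);  // copies
}

// Load image n from the R array (dim H, W, C, N) into padded layout.
static void load_image(const double* x, const Config& c, int n, mat& X) {
  X.zeros(c.C, c.HWp);
  const size_t img = (size_t)c.H * c.W * c.C;
  for (int ch = 0; ch < c.C; ++ch) {
    const double* src = x + n * img + (size_t)ch * c.H * c.W;
    for (int xx = 0; xx < c.W; ++xx) {
      for (int yy = 0; yy < c.H; ++yy) {
        X(ch, (size_t)xx * c.H2 + yy + 1) =
          src[yy + (size_t)c.H * xx] * INPUT_SCALE;
      }
    }
  }
}

// 3x3 kernel shift table; kernel tap k pairs with flat offset
// off = dx*H2 + dy and target x-range [xa, xb].
struct Shift { int dx, dy, off, xa, xb; };
static std::vector<Shift> shifts(const Config& c) {
  std::vector<Shift> s;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      Shift sh;
      sh.dx = dx; sh.dy = dy; sh.off = dx * c.H2 + dy;
      sh.xa = std::max(0, -dx); sh.xb = c.W - 1 - std::max(0, dx);
      s.push_back(sh);
    }
  }
  return s;
}

// Z = conv(X) + b, ReLU, pads zeroed. Wk: 9 taps of F x Cin.
static void conv_forward(const mat& X, mat& Z, const std::vector<mat>& Wk,
                         const vec& b, const std::vector<Shift>& sh,
                         const Config& c) {
  Z.zeros();
  for (int k = 0; k < 9; ++k) {
    const Shift& s = sh[k];
    if (s.xa > s.xb) continue;
    const size_t t0 = (size_t)s.xa * c.H2 + 1, t1 = (size_t)s.xb * c.H2 + c.H;
    Z.cols(t0, t1) += Wk[k] * X.cols(t0 + s.off, t1 + s.off);
  }
  Z.each_col() += b;
  Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
  zero_pads(Z, c);
}

static std::vector<mat> split_taps(const mat& W, int Cin) {
  std::vector<mat> Wk(9);
  for (int k = 0; k < 9; ++k) Wk[k] = W.cols(k * Cin, (k + 1) * Cin - 1);
  return Wk;
}

static double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Forward in evaluation mode (running BN statistics), one image at a time.
// [[Rcpp::export(name = ".cnn_predict")]]
NumericVector cnn_predict_cpp(List params, List cfg, NumericVector x) {
  Config c = read_config(cfg);
  Params q = read_params(params, c);
  std::vector<Shift> sh = shifts(c);
  IntegerVector dims = x.attr("dim");
  const int N = dims.length() == 4 ? dims[3] : 1;
  NumericVector out(N);
  mat A, Z;
  for (int n = 0; n < N; ++n) {
    load_image(REAL(x), c, n, A);
    int bn_i = 0;
    for (int l = 0; l < c.L; ++l) {
      std::vector<mat> Wk = split_taps(q.conv_W[l], A.n_rows);
      Z.set_size(c.F, c.HWp);
      conv_forward(A, Z, Wk, q.conv_b[l], sh, c);
      A = Z;
      if ((l + 1) % c.se_every == 0) {
        vec sd = arma::sqrt(q.bn_rvar[bn_i] + BN_EPS);
        vec scale = q.bn_gamma[bn_i] / sd;
        vec shift = q.bn_beta[bn_i] - q.bn_rmean[bn_i] % scale;
        A.each_col() %= scale;
        A.each_col() += shift;
        zero_pads(A, c);
        vec s = arma::sum(A, 1) / c.Mv;
        vec z1 = arma::clamp(q.se_W1[bn_i] * s + q.se_b1[bn_i], 0.0,
                             arma::datum::inf);
        vec g = 1.0 / (1.0 + arma::exp(-(q.se_W2[bn_i] * z1 +
                                         q.se_b2[bn_i])));
        A.each_col() %= g;
        ++bn_i;
      }
    }
    // head over valid pixels only (activations may be all-negative)
    vec mx(c.F), av = arma::sum(A, 1) / c.Mv;
    mx.fill(-arma::datum::inf);
    for (int xx = 0; xx < c.W; ++xx) {
      for (int yy = 1; yy <= c.H; ++yy) {
        const size_t p = (size_t)xx * c.H2 + yy;
        for (int f = 0; f < c.F; ++f) {
          if (A(f, p) > mx(f)) mx(f) = A(f, p);
        }
      }
    }
    double logit = arma::dot(q.head_w.subvec(0, c.F - 1), mx) +
      arma::dot(q.head_w.subvec(c.F, 2 * c.F - 1), av) + q.head_b;
    out[n] = sigmoid(logit);
  }
  return out;
}

// Forward + backward over a mini-batch in training mode (batch BN
// statistics). Returns mean BCE loss (incl. L1 on head weights),
// gradients in the parameter structure, per-BN-stage batch mean/var (for
// running-stat updates), and the predicted probabilities.
// [[Rcpp::export(name = ".cnn_batch_grad")]]
List cnn_batch_grad_cpp(List params, List cfg, NumericVector x,
                        NumericVector y, double l1) {
  Config c = read_config(cfg);
  Params q = read_params(params, c);
  std::vector<Shift> sh = shifts(c);
  IntegerVector dims = x.attr("dim");
  const int N = dims.length() == 4 ? dims[3] : 1;
  const size_t BW = (size_t)c.HWp * N;   // batch width
  const double Mv_batch = c.Mv * N;

  // stored activations
  mat X0(c.C, BW);
  std::vector<mat> conv_out(c.L);
  for (int l = 0; l < c.L; ++l) conv_out[l].set_size(c.F, BW);
  std::vector<mat> seg_out(c.nbn);
  for (int s = 0; s < c.nbn; ++s) seg_out[s].set_size(c.F, BW);
  std::vector<vec> bn_mean(c.nbn), bn_var(c.nbn);
  std::vector<mat> se_s(c.nbn), se_z1(c.nbn), se_g(c.nbn);

  mat Xi;
  for (int n = 0; n < N; ++n) {
    load_image(REAL(x), c, n, Xi);
    block(X0, c, n) = Xi;
  }

  std::vector<std::vector<mat>> Wk(c.L);
  for (int l = 0; l < c.L; ++l) {
    Wk[l] = split_taps(q.conv_W[l], l == 0 ? c.C : c.F);
  }

  // ---- forward, one BN/SE segment at a time ----
  for (int s = 0; s < c.nbn; ++s) {
    const int l0 = s * c.se_every, l1_ = l0 + c.se_every - 1;
    vec bsum(c.F, arma::fill::zeros), bsq(c.F, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      for (int l = l0; l <= l1_; ++l) {
        mat in = l == 0 ? block(X0, c, n)
               : (l == l0 ? block(seg_out[s - 1], c, n)
                          : block(conv_out[l - 1], c, n));
        mat out = block(conv_out[l], c, n);
        conv_forward(in, out, Wk[l], q.conv_b[l], sh, c);
      }
      mat last = block(conv_out[l1_], c, n);
      bsum += arma::sum(last, 1);
      bsq += arma::sum(arma::square(last), 1);
    }
    vec mu = bsum / Mv_batch;
    vec var = bsq / Mv_batch - arma::square(mu);
    var.transform([](double v) { return v > 0.0 ? v : 0.0; });
    bn_mean[s] = mu; bn_var[s] = var;
    vec sd = arma::sqrt(var + BN_EPS);
    vec scale = q.bn_gamma[s] / sd;
    vec shift = q.bn_beta[s] - mu % scale;
    se_s[s].set_size(c.F, N);
    se_z1[s].set_size(c.r, N);
    se_g[s].set_size(c.F, N);
    for (int n = 0; n < N; ++n) {
      seg_out[s].cols((size_t)n * c.HWp, (size_t)(n + 1) * c.HWp - 1) =
        conv_out[l1_].cols((size_t)n * c.HWp, (size_t)(n + 1) * c.HWp - 1);
      mat Yn = block(seg_out[s], c, n);
      Yn.each_col() %= scale;
      Yn.each_col() += shift;
      zero_pads(Yn, c);
      vec sv = arma::sum(Yn, 1) / c.Mv;
      vec z1 = arma::clamp(q.se_W1[s] * sv + q.se_b1[s], 0.0,
                           arma::datum::inf);
      vec g = 1.0 / (1.0 + arma::exp(-(q.se_W2[s] * z1 + q.se_b2[s])));
      se_s[s].col(n) = sv;
      se_z1[s].col(n) = z1;
      se_g[s].col(n) = g;
      Yn.each_col() %= g;
    }
  }

  // ---- head ----
  mat feat(2 * c.F, N);
  arma::umat argmax(c.F, N);
  NumericVector probs(N);
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    mat A = block(seg_out[c.nbn - 1], c, n);
    vec mx(c.F);
    mx.fill(-arma::datum::inf);
    for (int xx = 0; xx < c.W; ++xx) {
      for (int yy = 1; yy <= c.H; ++yy) {
        const size_t p = (size_t)xx * c.H2 + yy;
        for (int f = 0; f < c.F; ++f) {
          if (A(f, p) > mx(f)) { mx(f) = A(f, p); argmax(f, n) = p; }
        }
      }
    }
    feat.col(n).subvec(0, c.F - 1) = mx;
    feat.col(n).subvec(c.F, 2 * c.F - 1) = arma::sum(A, 1) / c.Mv;
    double p = sigmoid(arma::dot(q.head_w, feat.col(n)) + q.head_b);
    probs[n] = p;
    double pc = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
    loss -= y[n] * std::log(pc) + (1.0 - y[n]) * std::log(1.0 - pc);
  }
  loss /= N;
  loss += l1 * arma::accu(arma::abs(q.head_w));

  // ---- backward ----
  vec d_head_w(2 * c.F, arma::fill::zeros);
  double d_head_b = 0.0;
  mat dA(c.F, BW, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    double dlogit = (probs[n] - y[n]) / N;
    d_head_w += dlogit * feat.col(n);
    d_head_b += dlogit;
    mat dAn = block(dA, c, n);
    for (int f = 0; f < c.F; ++f) {
      dAn(f, argmax(f, n)) += dlogit * q.head_w[f];
    }
    vec dav = dlogit * q.head_w.subvec(c.F, 2 * c.F - 1) / c.Mv;
    for (int xx = 0; xx < c.W; ++xx) {
      dAn.cols((size_t)xx * c.H2 + 1, (size_t)xx * c.H2 + c.H)
        .each_col() += dav;
    }
  }
  d_head_w += l1 * arma::sign(q.head_w);

  std::vector<mat> d_conv_W(c.L);
  std::vector<vec> d_conv_b(c.L);
  std::vector<vec> d_bn_gamma(c.nbn), d_bn_beta(c.nbn);
  std::vector<mat> d_se_W1(c.nbn), d_se_W2(c.nbn);
  std::vector<vec> d_se_b1(c.nbn), d_se_b2(c.nbn);

  int bn_i = c.nbn - 1;
  for (int l = c.L - 1; l >= 0; --l) {
    if ((l + 1) % c.se_every == 0) {
      // recompute the BN affine of this stage
      vec sd = arma::sqrt(bn_var[bn_i] + BN_EPS);
      vec scale = q.bn_gamma[bn_i] / sd;
      vec shift = q.bn_beta[bn_i] - bn_mean[bn_i] % scale;
      d_se_W1[bn_i].zeros(c.r, c.F);
      d_se_W2[bn_i].zeros(c.F, c.r);
      d_se_b1[bn_i].zeros(c.r);
      d_se_b2[bn_i].zeros(c.F);
      d_bn_gamma[bn_i].zeros(c.F);
      d_bn_beta[bn_i].zeros(c.F);
      vec m1(c.F, arma::fill::zeros), m2(c.F, arma::fill::zeros);
      // SE backward (per image), accumulating BN sums in the same pass
      for (int n = 0; n < N; ++n) {
        mat Xbn = copy_block(conv_out[l], c, n);   // BN output pre-gate
        Xbn.each_col() %= scale;
        Xbn.each_col() += shift;
        zero_pads(Xbn, c);
        mat dYn = block(dA, c, n);
        vec g = se_g[bn_i].col(n), z1 = se_z1[bn_i].col(n),
            sv = se_s[bn_i].col(n);
        vec dg = arma::sum(dYn % Xbn, 1);
        dYn.each_col() %= g;                  // now gradient w.r.t. BN out
        vec dz2 = dg % g % (1.0 - g);
        d_se_W2[bn_i] += dz2 * z1.t();
        d_se_b2[bn_i] += dz2;
        vec dz1 = q.se_W2[bn_i].t() * dz2;
        dz1.elem(arma::find(z1 <= 0)).zeros();
        d_se_W1[bn_i] += dz1 * sv.t();
        d_se_b1[bn_i] += dz1;
        vec ds = q.se_W1[bn_i].t() * dz1 / c.Mv;
        for (int xx = 0; xx < c.W; ++xx) {
          dYn.cols((size_t)xx * c.H2 + 1, (size_t)xx * c.H2 + c.H)
            .each_col() += ds;
        }
        // xhat = (conv_out - mu)/sd
        mat xhat = copy_block(conv_out[l], c, n);
        xhat.each_col() /= sd;
        vec mush = bn_mean[bn_i] / sd;
        xhat.each_col() -= mush;
        d_bn_gamma[bn_i] += arma::sum(dYn % xhat, 1);
        d_bn_beta[bn_i] += arma::sum(dYn, 1);
        vec gvec = q.bn_gamma[bn_i];
        m1 += arma::sum(dYn, 1) % gvec;
        m2 += arma::sum(dYn % xhat, 1) % gvec;
      }
      m1 /= Mv_batch;
      m2 /= Mv_batch;
      // second pass: dX = (dxhat - m1 - xhat * m2) / sd
      for (int n = 0; n < N; ++n) {
        mat dYn = block(dA, c, n);            // already times g
        mat xhat = copy_block(conv_out[l], c, n);
        xhat.each_col() /= sd;
        vec mush = bn_mean[bn_i] / sd;
        xhat.each_col() -= mush;
        dYn.each_col() %= q.bn_gamma[bn_i];
        dYn.each_col() -= m1;
        xhat.each_col() %= m2;
        dYn -= xhat;
        dYn.each_col() /= sd;
        zero_pads(dYn, c);
      }
      --bn_i;
    }
    // ReLU mask (conv_out pads are zero, so pad grads vanish too)
    {
      const double* o = conv_out[l].memptr();
      double* d = dA.memptr();
      const size_t nn = conv_out[l].n_elem;
      for (size_t i = 0; i < nn; ++i) if (o[i] <= 0.0) d[i] = 0.0;
    }
    const int Cin = l == 0 ? c.C : c.F;
    d_conv_W[l].zeros(c.F, Cin * 9);
    d_conv_b[l] = arma::sum(dA, 1);
    mat dAprev(Cin, BW, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      mat in = l == 0 ? block(X0, c, n)
             : (l % c.se_every == 0 ? block(seg_out[l / c.se_every - 1], c, n)
                                    : block(conv_out[l - 1], c, n));
      mat dZn = block(dA, c, n);
      mat dXn = block(dAprev, c, n);
      for (int k = 0; k < 9; ++k) {
        const Shift& s = sh[k];
        if (s.xa > s.xb) continue;
        const size_t t0 = (size_t)s.xa * c.H2 + 1,
                     t1 = (size_t)s.xb * c.H2 + c.H;
        d_conv_W[l].cols(k * Cin, (k + 1) * Cin - 1) +=
          dZn.cols(t0, t1) * in.cols(t0 + s.off, t1 + s.off).t();
        dXn.cols(t0 + s.off, t1 + s.off) += Wk[l][k].t() * dZn.cols(t0, t1);
      }
      zero_pads(dXn, c);
    }
    dA = std::move(dAprev);
  }

  List gW(c.L), gb(c.L);
  for (int l = 0; l < c.L; ++l) {
    gW[l] = wrap(d_conv_W[l]);
    gb[l] = wrap(d_conv_b[l]);
  }
  List gg(c.nbn), gbe(c.nbn), gw1(c.nbn), gb1(c.nbn), gw2(c.nbn),
       gb2(c.nbn), bm(c.nbn), bv(c.nbn);
  for (int s = 0; s < c.nbn; ++s) {
    gg[s] = wrap(d_bn_gamma[s]);
    gbe[s] = wrap(d_bn_beta[s]);
    gw1[s] = wrap(d_se_W1[s]);
    gb1[s] = wrap(d_se_b1[s]);
    gw2[s] = wrap(d_se_W2[s]);
    gb2[s] = wrap(d_se_b2[s]);
    bm[s] = wrap(bn_mean[s]);
    bv[s] = wrap(bn_var[s]);
  }
  List grads = List::create(
    _["conv_W"] = gW, _["conv_b"] = gb,
    _["bn_gamma"] = gg, _["bn_beta"] = gbe,
    _["se_W1"] = gw1, _["se_b1"] = gb1,
    _["se_W2"] = gw2, _["se_b2"] = gb2,
    _["head_w"] = wrap(d_head_w), _["head_b"] = d_head_b);
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["bn_mean"] = bm, _["bn_var"] = bv,
                      _["probs"] = probs);
}
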