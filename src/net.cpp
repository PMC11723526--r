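// Three-headed residual encoder-decoder for joint myotube / nuclei /
// centroid prediction, with its own backward pass and Adam optimiser.
// Feature maps are (C x H*W) matrices with row-major spatial index
// idx = r*W + c; convolutions are im2col + GEMM.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;

static void im2col(const mat& X, int H, int W, int k, int s, int p,
                   mat& K, int& Ho, int& Wo) {
  const int Cin = X.n_rows;
  Ho = (H + 2 * p - k) / s + 1;
  Wo = (W + 2 * p - k) / s + 1;
  K.zeros(Cin * k * k, Ho * Wo);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        const int row = ci * k * k + dr * k + dc;
        for (int ro = 0; ro < Ho; ++ro) {
          const int r = ro * s + dr - p;
          if (r < 0 || r >= H) continue;
          for (int co = 0; co < Wo; ++co) {
            const int c = co * s + dc - p;
            if (c < 0 || c >= W) continue;
            K(row, ro * Wo + co) = X(ci, r * W + c);
          }
        }
      }
    }
  }
}

// im2col restricted to output columns [j0, j1): bounds inference memory
static void im2col_block(const mat& X, int H, int W, int k, int s, int p,
                         int Wo, int j0, int j1, mat& K) {
  const int Cin = X.n_rows;
  K.zeros(Cin * k * k, j1 - j0);
  for (int j = j0; j < j1; ++j) {
    const int ro = j / Wo, co = j % Wo;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dr = 0; dr < k; ++dr) {
        const int r = ro * s + dr - p;
        if (r < 0 || r >= H) continue;
        for (int dc = 0; dc < k; ++dc) {
          const int c = co * s + dc - p;
          if (c < 0 || c >= W) continue;
          K(ci * k * k + dr * k + dc, j - j0) = X(ci, r * W + c);
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add columns back onto the (Cin x H*W) grid
static mat col2im(const mat& K, int Cin, int H, int W, int k, int s, int p) {
  const int Ho = (H + 2 * p - k) / s + 1;
  const int Wo = (W + 2 * p - k) / s + 1;
  mat X(Cin, H * W, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dr = 0; dr < k; ++dr) {
      for (int dc = 0; dc < k; ++dc) {
        const int row = ci * k * k + dr * k + dc;
        for (int ro = 0; ro < Ho; ++ro) {
          const int r = ro * s + dr - p;
          if (r < 0 || r >= H) continue;
          for (int co = 0; co < Wo; ++co) {
            const int c = co * s + dc - p;
            if (c < 0 || c >= W) continue;
            X(ci, r * W + c) += K(row, ro * Wo + co);
          }
        }
      }
    }
  }
  return X;
}

struct Param {
  std::string name;
  mat value, grad, m, v;
};

struct NetCfg {
  int in_ch, base, n_res, head_k;
  bool strict_128;
  double lr, beta1, beta2, adam_eps, leaky;
};

// cached tensors for one forward pass
struct Cache {
  std::vector<mat> x;       // per-stage inputs/outputs as needed
  std::vector<int> H, W;    // spatial dims per stage
};

class MyoNet {
public:
  NetCfg cfg;
  std::vector<Param> P;
  std::map<std::string, int> idx;
  long step_count;
  Rcpp::List last_shapes;

  MyoNet(const NetCfg& c) : cfg(c), step_count(0) { build(); }

  int cres() const { return cfg.strict_128 ? 2 * cfg.base : 4 * cfg.base; }

  void add_conv(const std::string& nm, int cin, int cout, int k) {
    Param w;
    w.name = nm + ".W";
    w.value.zeros(cout, cin * k * k);
    P.push_back(w);
    Param b;
    b.name = nm + ".b";
    b.value.zeros(cout, 1);
    P.push_back(b);
  }
  // transposed conv stores V as (Cin x Cout*k*k); see convT_fwd
  void add_convT(const std::string& nm, int cin, int cout, int k) {
    Param w;
    w.name = nm + ".W";
    w.value.zeros(cin, cout * k * k);
    P.push_back(w);
    Param b;
    b.name = nm + ".b";
    b.value.zeros(cout, 1);
    P.push_back(b);
  }
  void add_bn(const std::string& nm, int c) {
    Param g;
    g.name = nm + ".gamma";
    g.value.ones(c, 1);
    P.push_back(g);
    Param b;
    b.name = nm + ".beta";
    b.value.zeros(c, 1);
    P.push_back(b);
  }

  void build() {
    const int b = cfg.base, cr = cres();
    add_conv("d1", cfg.in_ch, b, 3);
    add_conv("d2", b, 2 * b, 3);
    if (!cfg.strict_128) add_conv("pin", 2 * b, cr, 1);
    for (int i = 0; i < cfg.n_res; ++i) {
      std::string nm = "res" + std::to_string(i + 1);
      add_conv(nm + ".convA", cr, cr, 3);
      add_bn(nm + ".bnA", cr);
      add_conv(nm + ".convB", cr, cr, 3);
      add_bn(nm + ".bnB", cr);
    }
    if (!cfg.strict_128) add_conv("pout", cr, 2 * b, 1);
    add_convT("u1", 2 * b, 2 * b, 3);
    add_convT("u2", 2 * b, b, 3);
    add_conv("head1", b, 1, cfg.head_k);
    add_conv("head2", b, 1, cfg.head_k);
    add_conv("head3", b, 1, cfg.head_k);
    for (size_t i = 0; i < P.size(); ++i) {
      P[i].grad.zeros(arma::size(P[i].value));
      P[i].m.zeros(arma::size(P[i].value));
      P[i].v.zeros(arma::size(P[i].value));
      idx[P[i].name] = (int)i;
    }
  }

  Param& par(const std::string& nm) { return P[idx.at(nm)]; }

  void init_weights(int seed) {
    std::mt19937 rng((unsigned)seed);
    std::normal_distribution<double> N(0.0, 1.0);
    for (size_t i = 0; i < P.size(); ++i) {
      const std::string& nm = P[i].name;
      if (nm.size() > 2 && nm.substr(nm.size() - 2) == ".W") {
        const double fan_in = (double)P[i].value.n_cols;  // Cin*k*k
        const double sd = std::sqrt(2.0 / fan_in);        // Kaiming normal
        for (arma::uword j = 0; j < P[i].value.n_elem; ++j)
          P[i].value[j] = sd * N(rng);
      }
      // biases 0, gamma 1, beta 0 already set
    }
    step_count = 0;
    for (size_t i = 0; i < P.size(); ++i) {
      P[i].m.zeros();
      P[i].v.zeros();
    }
  }

  // ---- layer forward/backward helpers -----------------------------------

  mat conv_fwd(const std::string& nm, const mat& X, int H, int W, int k,
               int s, int p, mat& Kcache, int& Ho, int& Wo) {
    im2col(X, H, W, k, s, p, Kcache, Ho, Wo);
    mat Y = par(nm + ".W").value * Kcache;
    Y.each_col() += par(nm + ".b").value;
    return Y;
  }
  // inference-only convolution: chunked im2col keeps peak memory bounded
  // (a full 5x5 im2col at 512x512 and 64 channels would need ~3.4 GB)
  mat conv_fwd_nocache(const std::string& nm, const mat& X, int H, int W,
                       int k, int s, int p, int& Ho, int& Wo) {
    Ho = (H + 2 * p - k) / s + 1;
    Wo = (W + 2 * p - k) / s + 1;
    const mat& Wt = par(nm + ".W").value;
    if (k == 1 && s == 1) {
      mat Y = Wt * X;
      Y.each_col() += par(nm + ".b").value;
      return Y;
    }
    mat Y(Wt.n_rows, (arma::uword)Ho * Wo);
    const int B = 16384;
    mat K;
    for (int j0 = 0; j0 < Ho * Wo; j0 += B) {
      const int j1 = std::min(j0 + B, Ho * Wo);
      im2col_block(X, H, W, k, s, p, Wo, j0, j1, K);
      Y.cols(j0, j1 - 1) = Wt * K;
    }
    Y.each_col() += par(nm + ".b").value;
    return Y;
  }

  mat conv_bwd(const std::string& nm, const mat& dY, const mat& Kcache,
               int Cin, int H, int W, int k, int s, int p) {
    par(nm + ".W").grad += dY * Kcache.t();
    par(nm + ".b").grad += arma::sum(dY, 1);
    mat dK = par(nm + ".W").value.t() * dY;
    return col2im(dK, Cin, H, W, k, s, p);
  }

  // transposed conv stride 2, k 3, pad 1, output twice the spatial size.
  // Weight V is stored as (Cin x Cout*9): the weight of the stride-2 conv
  // whose input-gradient defines this layer's forward map.
  mat convT_fwd(const std::string& nm, const mat& X, int H, int W, int Cout,
                int& Ho, int& Wo) {
    Ho = 2 * H;
    Wo = 2 * W;
    mat G = par(nm + ".W").value.t() * X;            // (Cout*9 x H*W)
    mat Y = col2im(G, Cout, Ho, Wo, 3, 2, 1);
    Y.each_col() += par(nm + ".b").value;
    return Y;
  }
  mat convT_bwd(const std::string& nm, const mat& dY, const mat& X,
                int Ho, int Wo) {
    mat K;
    int h2, w2;
    im2col(dY, Ho, Wo, 3, 2, 1, K, h2, w2);          // (Cout*9 x H*W)
    par(nm + ".W").grad += X * K.t();                // (Cin x Cout*9)
    par(nm + ".b").grad += arma::sum(dY, 1);
    return par(nm + ".W").value * K;                 // (Cin x H*W)
  }

  // instance norm (non-affine): normalise each channel over space
  static mat inorm_fwd(const mat& X, mat& xhat, arma::vec& istd) {
    const double eps = 1e-5;
    mat Y(arma::size(X));
    xhat.set_size(arma::size(X));
    istd.set_size(X.n_rows);
    for (arma::uword c = 0; c < X.n_rows; ++c) {
      const double mu = arma::mean(X.row(c));
      const double var = arma::mean(arma::square(X.row(c) - mu));
      const double is = 1.0 / std::sqrt(var + eps);
      istd(c) = is;
      xhat.row(c) = (X.row(c) - mu) * is;
      Y.row(c) = xhat.row(c);
    }
    return Y;
  }
  static mat inorm_bwd(const mat& dY, const mat& xhat, const arma::vec& istd) {
    mat dX(arma::size(dY));
    for (arma::uword c = 0; c < dY.n_rows; ++c) {
      const double mdy = arma::mean(dY.row(c));
      const double mdyx = arma::mean(dY.row(c) % xhat.row(c));
      dX.row(c) = istd(c) * (dY.row(c) - mdy - xhat.row(c) * mdyx);
    }
    return dX;
  }

  // batch norm with affine params; batch of one, so statistics are the
  // per-channel spatial statistics (identical at train and eval time,
  // keeping eval deterministic for fixed weights)
  mat bn_fwd(const std::string& nm, const mat& X, mat& xhat, arma::vec& istd) {
    mat Y = inorm_fwd(X, xhat, istd);
    Y.each_col() %= par(nm + ".gamma").value.col(0);
    Y.each_col() += par(nm + ".beta").value.col(0);
    return Y;
  }
  mat bn_bwd(const std::string& nm, const mat& dY, const mat& xhat,
             const arma::vec& istd) {
    par(nm + ".gamma").grad += arma::sum(dY % xhat, 1);
    par(nm + ".beta").grad += arma::sum(dY, 1);
    mat dxhat = dY;
    dxhat.each_col() %= par(nm + ".gamma").value.col(0);
    return inorm_bwd(dxhat, xhat, istd);
  }

  static mat relu(const mat& X) { return arma::clamp(X, 0.0, arma::datum::inf); }
  mat lrelu(const mat& X) const {
    return arma::max(X, cfg.leaky * X);
  }

  // ---- full network ------------------------------------------------------

  struct FwdState {
    // caches needed for backward
    mat K_d1, a_d1, xh_d1; arma::vec is_d1;
    mat K_d2, a_d2, xh_d2; arma::vec is_d2;
    mat x_pin;                       // input to pin
    std::vector<mat> res_in, KA, aA, xhA, KB, xhB;
    std::vector<arma::vec> isA, isB;
    mat x_pout;
    mat x_u1, a_u1, xh_u1; arma::vec is_u1;
    mat x_u2, a_u2, xh_u2; arma::vec is_u2;
    mat x_heads;
    mat K_h[3];
    mat z_h[3], p_h[3];
    int H0, W0, H1, W1, H2, W2;
  };

  void forward(const mat& X, int H, int W, FwdState& S, bool cache = true) {
    const int b = cfg.base, cr = cres();
    S.H0 = H; S.W0 = W;
    int Ho, Wo;
    mat z = cache ? conv_fwd("d1", X, H, W, 3, 2, 1, S.K_d1, Ho, Wo)
                  : conv_fwd_nocache("d1", X, H, W, 3, 2, 1, Ho, Wo);
    S.H1 = Ho; S.W1 = Wo;
    mat n1 = inorm_fwd(z, S.xh_d1, S.is_d1);
    S.a_d1 = n1;                      // pre-ReLU normalised activations
    mat a = relu(n1);
    z = cache ? conv_fwd("d2", a, S.H1, S.W1, 3, 2, 1, S.K_d2, Ho, Wo)
              : conv_fwd_nocache("d2", a, S.H1, S.W1, 3, 2, 1, Ho, Wo);
    S.H2 = Ho; S.W2 = Wo;
    mat n2 = inorm_fwd(z, S.xh_d2, S.is_d2);
    S.a_d2 = n2;
    a = relu(n2);
    if (!cfg.strict_128) {
      if (cache) S.x_pin = a;
      int h, w;
      // 1x1 conv: direct GEMM; backward uses x_pin, no im2col cache needed
      a = conv_fwd_nocache("pin", a, S.H2, S.W2, 1, 1, 0, h, w);
    }
    if (cache) {
      S.res_in.assign(cfg.n_res, mat());
      S.KA.assign(cfg.n_res, mat());
      S.aA.assign(cfg.n_res, mat());
      S.xhA.assign(cfg.n_res, mat());
      S.KB.assign(cfg.n_res, mat());
      S.xhB.assign(cfg.n_res, mat());
      S.isA.assign(cfg.n_res, arma::vec());
      S.isB.assign(cfg.n_res, arma::vec());
    }
    mat xh_tmp;
    arma::vec is_tmp;
    for (int i = 0; i < cfg.n_res; ++i) {
      std::string nm = "res" + std::to_string(i + 1);
      if (cache) S.res_in[i] = a;
      int h, w;
      mat zA = cache ? conv_fwd(nm + ".convA", a, S.H2, S.W2, 3, 1, 1,
                                S.KA[i], h, w)
                     : conv_fwd_nocache(nm + ".convA", a, S.H2, S.W2,
                                        3, 1, 1, h, w);
      mat nA = bn_fwd(nm + ".bnA", zA, cache ? S.xhA[i] : xh_tmp,
                      cache ? S.isA[i] : is_tmp);
      if (cache) S.aA[i] = nA;
      mat rA = relu(nA);
      mat zB = cache ? conv_fwd(nm + ".convB", rA, S.H2, S.W2, 3, 1, 1,
                                S.KB[i], h, w)
                     : conv_fwd_nocache(nm + ".convB", rA, S.H2, S.W2,
                                        3, 1, 1, h, w);
      mat nB = bn_fwd(nm + ".bnB", zB, cache ? S.xhB[i] : xh_tmp,
                      cache ? S.isB[i] : is_tmp);
      a = a + nB;                     // identity skip
    }
    if (!cfg.strict_128) {
      if (cache) S.x_pout = a;
      int h, w;
      a = conv_fwd_nocache("pout", a, S.H2, S.W2, 1, 1, 0, h, w);
    }
    if (cache) S.x_u1 = a;
    int Hu, Wu;
    z = convT_fwd("u1", a, S.H2, S.W2, 2 * b, Hu, Wu);
    mat nu1 = inorm_fwd(z, S.xh_u1, S.is_u1);
    S.a_u1 = nu1;
    a = lrelu(nu1);
    if (cache) S.x_u2 = a;
    z = convT_fwd("u2", a, Hu, Wu, b, Hu, Wu);
    mat nu2 = inorm_fwd(z, S.xh_u2, S.is_u2);
    S.a_u2 = nu2;
    a = lrelu(nu2);
    if (cache) S.x_heads = a;
    for (int k = 0; k < 3; ++k) {
      std::string nm = "head" + std::to_string(k + 1);
      int h, w;
      S.z_h[k] = cache ? conv_fwd(nm, a, S.H0, S.W0, cfg.head_k, 1,
                                  (cfg.head_k - 1) / 2, S.K_h[k], h, w)
                       : conv_fwd_nocache(nm, a, S.H0, S.W0, cfg.head_k, 1,
                                          (cfg.head_k - 1) / 2, h, w);
      S.p_h[k] = 1.0 / (1.0 + arma::exp(-S.z_h[k]));
    }
    // record per-block output shapes of this pass
    last_shapes = Rcpp::List::create(
      Rcpp::Named("down1") = Rcpp::IntegerVector::create(b, S.H1, S.W1),
      Rcpp::Named("down2") = Rcpp::IntegerVector::create(2 * b, S.H2, S.W2),
      Rcpp::Named("residual") = Rcpp::IntegerVector::create(cr, S.H2, S.W2),
      Rcpp::Named("up1") = Rcpp::IntegerVector::create(2 * b, 2 * S.H2, 2 * S.W2),
      Rcpp::Named("up2") = Rcpp::IntegerVector::create(b, S.H0, S.W0),
      Rcpp::Named("head") = Rcpp::IntegerVector::create(1, S.H0, S.W0));
  }

  // backward from per-head dL/dz (fused sigmoid + BCE gradients)
  void backward(const FwdState& S, const mat dz[3]) {
    const int b = cfg.base, cr = cres();
    mat da(b, (arma::uword)S.H0 * S.W0, arma::fill::zeros);
    for (int k = 0; k < 3; ++k) {
      std::string nm = "head" + std::to_string(k + 1);
      da += conv_bwd(nm, dz[k], S.K_h[k], b, S.H0, S.W0, cfg.head_k, 1,
                     (cfg.head_k - 1) / 2);
    }
    // up2
    mat dn = da % lrelu_grad(S.a_u2);
    dn = inorm_bwd(dn, S.xh_u2, S.is_u2);
    mat dx = convT_bwd("u2", dn, S.x_u2, S.H0, S.W0);
    // up1
    dn = dx % lrelu_grad(S.a_u1);
    dn = inorm_bwd(dn, S.xh_u1, S.is_u1);
    dx = convT_bwd("u1", dn, S.x_u1, 2 * S.H2, 2 * S.W2);
    if (!cfg.strict_128) {
      // pout: 1x1 conv, im2col is identity
      dx = conv_bwd_1x1("pout", dx, S.x_pout);
    }
    for (int i = cfg.n_res - 1; i >= 0; --i) {
      std::string nm = "res" + std::to_string(i + 1);
      // dx flows to both the skip and the branch
      mat dbr = bn_bwd(nm + ".bnB", dx, S.xhB[i], S.isB[i]);
      mat drA = conv_bwd(nm + ".convB", dbr, S.KB[i], cr, S.H2, S.W2, 3, 1, 1);
      drA %= relu_grad(S.aA[i]);
      mat dnA = bn_bwd(nm + ".bnA", drA, S.xhA[i], S.isA[i]);
      mat dres = conv_bwd(nm + ".convA", dnA, S.KA[i], cr, S.H2, S.W2, 3, 1, 1);
      dx = dx + dres;                 // skip path
    }
    if (!cfg.strict_128) dx = conv_bwd_1x1("pin", dx, S.x_pin);
    // d2
    dn = dx % relu_grad(S.a_d2);
    dn = inorm_bwd(dn, S.xh_d2, S.is_d2);
    dx = conv_bwd("d2", dn, S.K_d2, b, S.H1, S.W1, 3, 2, 1);
    // d1
    dn = dx % relu_grad(S.a_d1);
    dn = inorm_bwd(dn, S.xh_d1, S.is_d1);
    conv_bwd("d1", dn, S.K_d1, cfg.in_ch, S.H0, S.W0, 3, 2, 1);
  }

  mat conv_bwd_1x1(const std::string& nm, const mat& dY, const mat& X) {
    par(nm + ".W").grad += dY * X.t();
    par(nm + ".b").grad += arma::sum(dY, 1);
    return par(nm + ".W").value.t() * dY;
  }

  static mat relu_grad(const mat& pre) {
    return arma::conv_to<mat>::from(pre > 0.0);
  }
  mat lrelu_grad(const mat& pre) const {
    mat g(arma::size(pre));
    for (arma::uword i = 0; i < pre.n_elem; ++i)
      g[i] = pre[i] > 0.0 ? 1.0 : cfg.leaky;
    return g;
  }

  void zero_grad() {
    for (size_t i = 0; i < P.size(); ++i) P[i].grad.zeros();
  }

  void adam_step() {
    ++step_count;
    const double b1 = cfg.beta1, b2 = cfg.beta2;
    const double bc1 = 1.0 - std::pow(b1, (double)step_count);
    const double bc2 = 1.0 - std::pow(b2, (double)step_count);
    for (size_t i = 0; i < P.size(); ++i) {
      Param& p = P[i];
      p.m = b1 * p.m + (1.0 - b1) * p.grad;
      p.v = b2 * p.v + (1.0 - b2) * arma::square(p.grad);
      p.value -= cfg.lr * (p.m / bc1) / (arma::sqrt(p.v / bc2) + cfg.adam_eps);
    }
  }
};

// ---- R interface ----------------------------------------------------------

static mat rarray_to_mat(const Rcpp::NumericVector& x, int& C, int& H, int& W) {
  Rcpp::IntegerVector d = x.attr("dim");
  C = d[0];
  H = d[1];
  W = d[2];
  mat X(C, (arma::uword)H * W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      for (int ch = 0; ch < C; ++ch)
        X(ch, r * W + c) = x[ch + (R_xlen_t)C * (r + (R_xlen_t)H * c)];
  return X;
}

static Rcpp::NumericMatrix map_to_rmat(const mat& Y, int row, int H, int W) {
  Rcpp::NumericMatrix M(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      M(r, c) = Y(row, r * W + c);
  return M;
}

static mat rmat_to_row(const Rcpp::NumericMatrix& M) {
  const int H = M.nrow(), W = M.ncol();
  mat X(1, (arma::uword)H * W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      X(0, r * W + c) = M(r, c);
  return X;
}

// [[Rcpp::export(name = ".net_create")]]
SEXP net_create(Rcpp::List cfg) {
  NetCfg c;
  c.in_ch = Rcpp::as<int>(cfg["in_channels"]);
  c.base = Rcpp::as<int>(cfg["base_channels"]);
  c.n_res = Rcpp::as<int>(cfg["n_residual_blocks"]);
  c.head_k = Rcpp::as<int>(cfg["head_kernel"]);
  c.strict_128 = Rcpp::as<bool>(cfg["strict_128"]);
  c.lr = Rcpp::as<double>(cfg["lr"]);
  c.beta1 = Rcpp::as<double>(cfg["beta1"]);
  c.beta2 = Rcpp::as<double>(cfg["beta2"]);
  c.adam_eps = 1e-8;
  c.leaky = 0.2;
  Rcpp::XPtr<MyoNet> p(new MyoNet(c), true);
  return p;
}

// [[Rcpp::export(name = ".net_init")]]
void net_init(SEXP ptr, int seed) {
  Rcpp::XPtr<MyoNet> net(ptr);
  net->init_weights(seed);
}

// [[Rcpp::export(name = ".net_forward")]]
Rcpp::List net_forward(SEXP ptr, Rcpp::NumericVector x) {
  Rcpp::XPtr<MyoNet> net(ptr);
  int C, H, W;
  mat X = rarray_to_mat(x, C, H, W);
  if (H % 4 != 0 || W % 4 != 0)
    Rcpp::stop("input spatial dims (%d x %d) must be divisible by 4 "
               "(two stride-2 stages)", H, W);
  MyoNet::FwdState S;
  net->forward(X, H, W, S, false);
  return Rcpp::List::create(
    Rcpp::Named("p_myotube") = map_to_rmat(S.p_h[0], 0, H, W),
    Rcpp::Named("p_nuclei") = map_to_rmat(S.p_h[1], 0, H, W),
    Rcpp::Named("p_centroid") = map_to_rmat(S.p_h[2], 0, H, W));
}

// [[Rcpp::export(name = ".net_shapes")]]
Rcpp::List net_shapes(SEXP ptr) {
  Rcpp::XPtr<MyoNet> net(ptr);
  return net->last_shapes;
}

// One optimisation step on a single patch: forward, BCE losses for the three
// heads, fused sigmoid+BCE backward, Adam update. Returns (total, l1, l2, l3).
// [[Rcpp::export(name = ".net_train_step")]]
Rcpp::NumericVector net_train_step(SEXP ptr, Rcpp::NumericVector x,
                                   Rcpp::NumericMatrix t1,
                                   Rcpp::NumericMatrix t2,
                                   Rcpp::NumericMatrix t3,
                                   Rcpp::NumericVector lambda,
                                   bool update = true) {
  Rcpp::XPtr<MyoNet> net(ptr);
  int C, H, W;
  mat X = rarray_to_mat(x, C, H, W);
  MyoNet::FwdState S;
  net->forward(X, H, W, S);
  mat T[3] = {rmat_to_row(t1), rmat_to_row(t2), rmat_to_row(t3)};
  const double N = (double)H * W;
  const double eps = 1e-7;
  double losses[3];
  mat dz[3];
  for (int k = 0; k < 3; ++k) {
    const mat& p = S.p_h[k];
    double L = 0.0;
    for (arma::uword i = 0; i < p.n_elem; ++i) {
      double pi = std::min(std::max(p[i], eps), 1.0 - eps);
      L -= T[k][i] * std::log(pi) + (1.0 - T[k][i]) * std::log(1.0 - pi);
    }
    losses[k] = L / N;
    dz[k] = (p - T[k]) * (lambda[k] / N);
  }
  if (update) {
    net->zero_grad();
    net->backward(S, dz);
    net->adam_step();
  }
  const double tot = lambda[0] * losses[0] + lambda[1] * losses[1] +
                     lambda[2] * losses[2];
  return Rcpp::NumericVector::create(tot, losses[0], losses[1], losses[2]);
}

// Forward + backward only: returns the named gradient list (no update).
// Used by the gradient-consistency tests.
// [[Rcpp::export(name = ".net_gradients")]]
Rcpp::List net_gradients(SEXP ptr, Rcpp::NumericVector x,
                         Rcpp::NumericMatrix t1, Rcpp::NumericMatrix t2,
                         Rcpp::NumericMatrix t3,
                         Rcpp::NumericVector lambda) {
  Rcpp::XPtr<MyoNet> net(ptr);
  int C, H, W;
  mat X = rarray_to_mat(x, C, H, W);
  MyoNet::FwdState S;
  net->forward(X, H, W, S);
  mat T[3] = {rmat_to_row(t1), rmat_to_row(t2), rmat_to_row(t3)};
  const double N = (double)H * W;
  mat dz[3];
  for (int k = 0; k < 3; ++k) dz[k] = (S.p_h[k] - T[k]) * (lambda[k] / N);
  net->zero_grad();
  net->backward(S, dz);
  Rcpp::List out(net->P.size());
  Rcpp::CharacterVector nms(net->P.size());
  for (size_t i = 0; i < net->P.size(); ++i) {
    nms[i] = net->P[i].name;
    out[i] = Rcpp::wrap(net->P[i].grad);
  }
  out.attr("names") = nms;
  return out;
}

// [[Rcpp::export(name = ".net_get_weights")]]
Rcpp::List net_get_weights(SEXP ptr) {
  Rcpp::XPtr<MyoNet> net(ptr);
  Rcpp::List out(net->P.size());
  Rcpp::CharacterVector nms(net->P.size());
  for (size_t i = 0; i < net->P.size(); ++i) {
    nms[i] = net->P[i].name;
    out[i] = Rcpp::wrap(net->P[i].value);
  }
  out.attr("names") = nms;
  return out;
}

// [[Rcpp::export(name = ".net_set_weights")]]
void net_set_weights(SEXP ptr, Rcpp::List w) {
  Rcpp::XPtr<MyoNet> net(ptr);
  Rcpp::CharacterVector nms = w.attr("names");
  for (int i = 0; i < w.size(); ++i) {
    std::string nm = Rcpp::as<std::string>(nms[i]);
    std::map<std::string, int>::const_iterator it = net->idx.find(nm);
    if (it == net->idx.end()) Rcpp::stop("unknown parameter '%s'", nm.c_str());
    mat v = Rcpp::as<mat>(w[i]);
    if (v.n_rows != net->P[it->second].value.n_rows ||
        v.n_cols != net->P[it->second].value.n_cols)
      Rcpp::stop("parameter '%s' has wrong shape", nm.c_str());
    net->P[it->second].value = v;
  }
}

// [[Rcpp::export(name = ".net_n_params")]]
double net_n_params(SEXP ptr) {
  Rcpp::XPtr<MyoNet> net(ptr);
  double n = 0;
  for (size_t i = 0; i < net->P.size(); ++i) n += net->P[i].value.n_elem;
  return n;
}
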