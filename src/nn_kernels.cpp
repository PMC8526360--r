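#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Feature maps are stored as (B*H*W) x C matrices: row index = (b-1)*H*W + r*W + c
// (0-based pixel raster order within each image), one column per channel.
// Patch columns are ordered ((dy*kw + dx)*C + ch), matching the weight-matrix rows.

// Loops are ordered so that both the patch-matrix writes and the source
// reads run down columns (stride-1 in column-major storage).
// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::mat& X, int B, int H, int W,
                     int kh, int kw, int stride, int pad) {
  const int C = X.n_cols;
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (W + 2 * pad - kw) / stride + 1;
  arma::mat P(B * outH * outW, kh * kw * C, fill::zeros);
  const double* xp = X.memptr();
  double* pp = P.memptr();
  const arma::uword pN = P.n_rows, xN = X.n_rows;
  for (int dy = 0; dy < kh; ++dy) {
    for (int dx = 0; dx < kw; ++dx) {
      for (int ch = 0; ch < C; ++ch) {
        const int col = (dy * kw + dx) * C + ch;
        double* pcol = pp + (arma::uword)col * pN;
        const double* xcol = xp + (arma::uword)ch * xN;
        for (int b = 0; b < B; ++b) {
          const int ibase = b * H * W;
          const int obase = b * outH * outW;
          for (int oy = 0; oy < outH; ++oy) {
            const int iy = oy * stride - pad + dy;
            if (iy < 0 || iy >= H) continue;
            const int orow0 = obase + oy * outW;
            for (int ox = 0; ox < outW; ++ox) {
              const int ix = ox * stride - pad + dx;
              if (ix < 0 || ix >= W) continue;
              pcol[orow0 + ox] = xcol[ibase + iy * W + ix];
            }
          }
        }
      }
    }
  }
  return P;
}

// Scatter-add adjoint of im2col: dP is (B*outH*outW) x (kh*kw*C); returns (B*H*W) x C.
// [[Rcpp::export]]
arma::mat col2im_cpp(const arma::mat& dP, int B, int H, int W, int C,
                     int kh, int kw, int stride, int pad) {
  const int outH = (H + 2 * pad - kh) / stride + 1;
  const int outW = (W + 2 * pad - kw) / stride + 1;
  arma::mat dX(B * H * W, C, fill::zeros);
  const double* pp = dP.memptr();
  double* xp = dX.memptr();
  const arma::uword pN = dP.n_rows, xN = dX.n_rows;
  for (int dy = 0; dy < kh; ++dy) {
    for (int dx = 0; dx < kw; ++dx) {
      for (int ch = 0; ch < C; ++ch) {
        const int col = (dy * kw + dx) * C + ch;
        const double* pcol = pp + (arma::uword)col * pN;
        double* xcol = xp + (arma::uword)ch * xN;
        for (int b = 0; b < B; ++b) {
          const int ibase = b * H * W;
          const int obase = b * outH * outW;
          for (int oy = 0; oy < outH; ++oy) {
            const int iy = oy * stride - pad + dy;
            if (iy < 0 || iy >= H) continue;
            const int orow0 = obase + oy * outW;
            for (int ox = 0; ox < outW; ++ox) {
              const int ix = ox * stride - pad + dx;
              if (ix < 0 || ix >= W) continue;
              xcol[ibase + iy * W + ix] += pcol[orow0 + ox];
            }
          }
        }
      }
    }
  }
  return dX;
}

// Fused convolution backward: weight/bias gradients and the input gradient
// in one call. dY: (B*oH*oW) x Cout, P: cached patches, Wm: (possibly
// masked) weight matrix.
// [[Rcpp::export]]
Rcpp::List conv_bwd_cpp(const arma::mat& dY, const arma::mat& P,
                        const arma::mat& Wm, int B, int H, int W, int C,
                        int kh, int kw, int stride, int pad) {
  arma::mat dW = P.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dP = dY * Wm.t();
  arma::mat dX = col2im_cpp(dP, B, H, W, C, kh, kw, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dx") = dX);
}

// Convolution forward returning both output and cached patches.
// [[Rcpp::export]]
Rcpp::List conv_fwd_full_cpp(const arma::mat& X, const arma::mat& Wm,
                             const arma::vec& bias, int B, int H, int W,
                             int kh, int kw, int stride, int pad) {
  arma::mat P = im2col_cpp(X, B, H, W, kh, kw, stride, pad);
  arma::mat Y = P * Wm;
  Y.each_row() += bias.t();
  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("P") = P);
}

// One flat row per image (channel fastest within pixel) from raster-order
// feature maps, and its inverse.
// [[Rcpp::export]]
arma::mat flatten_maps_cpp(const arma::mat& X, int B) {
  const int hw = X.n_rows / B, C = X.n_cols;
  arma::mat F(B, hw * C);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < hw; ++p)
      for (int c = 0; c < C; ++c)
        F(b, p * C + c) = X(b * hw + p, c);
  return F;
}

// [[Rcpp::export]]
arma::mat unflatten_maps_cpp(const arma::mat& F, int B, int C) {
  const int hw = F.n_cols / C;
  arma::mat X(B * hw, C);
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < hw; ++p)
      for (int c = 0; c < C; ++c)
        X(b * hw + p, c) = F(b, p * C + c);
  return X;
}

static inline double sigmoid(double a) { return 1.0 / (1.0 + std::exp(-a)); }

// Discretized logistic mixture negative log-likelihood and its gradient
// with respect to the raw network outputs. `out` is N x 10K (logits, means,
// log-scales, coupling coefficients), `x` is N x 3 integer pixel values
// (0..255). Mirrors the reference R implementation exactly.
// [[Rcpp::export]]
Rcpp::List mixture_loss_cpp(const arma::mat& out, const arma::mat& x,
                            int K, bool want_grad) {
  const int N = out.n_rows;
  const double bw = 1.0 / 255.0;
  arma::mat dout;
  if (want_grad) dout.zeros(N, 10 * K);
  double nll = 0.0;
  std::vector<double> logpi(K), comp(K);
  std::vector<double> P(3 * K), phi_(3 * K), plo_(3 * K), ahi_(3 * K),
      alo_(3 * K), invs_(3 * K), mu_(3 * K);
  for (int i = 0; i < N; ++i) {
    const double xs[3] = {2.0 * x(i, 0) / 255.0 - 1.0,
                          2.0 * x(i, 1) / 255.0 - 1.0,
                          2.0 * x(i, 2) / 255.0 - 1.0};
    // log-softmax of the logits
    double mx = out(i, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, out(i, k));
    double se = 0.0;
    for (int k = 0; k < K; ++k) se += std::exp(out(i, k) - mx);
    const double lse_logits = mx + std::log(se);
    for (int k = 0; k < K; ++k) logpi[k] = out(i, k) - lse_logits;
    // per component, per channel bin probabilities
    for (int k = 0; k < K; ++k) {
      const double t1 = std::tanh(out(i, 7 * K + k));
      const double t2 = std::tanh(out(i, 8 * K + k));
      const double t3 = std::tanh(out(i, 9 * K + k));
      for (int c = 0; c < 3; ++c) {
        const int j = c * K + k;
        double mu = out(i, K + j);
        if (c == 1) mu += t1 * xs[0];
        if (c == 2) mu += t2 * xs[0] + t3 * xs[1];
        double ls = out(i, 4 * K + j);
        if (ls < -7.0) ls = -7.0;
        const double invs = std::exp(-ls);
        const double ahi = (xs[c] + bw - mu) * invs;
        const double alo = (xs[c] - bw - mu) * invs;
        double shi = sigmoid(ahi), slo = sigmoid(alo);
        double phi = shi * (1.0 - shi), plo = slo * (1.0 - slo);
        double ah = ahi, al = alo;
        if (xs[c] > 0.999) { shi = 1.0; phi = 0.0; ah = 0.0; }
        if (xs[c] < -0.999) { slo = 0.0; plo = 0.0; al = 0.0; }
        double p = shi - slo;
        if (p < 1e-12) p = 1e-12;
        mu_[j] = mu; invs_[j] = invs; P[j] = p;
        phi_[j] = phi; plo_[j] = plo; ahi_[j] = ah; alo_[j] = al;
      }
      comp[k] = logpi[k] + std::log(P[k]) + std::log(P[K + k]) +
        std::log(P[2 * K + k]);
    }
    double mc = comp[0];
    for (int k = 1; k < K; ++k) mc = std::max(mc, comp[k]);
    double sc = 0.0;
    for (int k = 0; k < K; ++k) sc += std::exp(comp[k] - mc);
    const double ll = mc + std::log(sc);
    nll -= ll;
    if (!want_grad) continue;
    for (int k = 0; k < K; ++k) {
      const double r = std::exp(comp[k] - ll);
      dout(i, k) = std::exp(logpi[k]) - r;
      double dmu_c[3];
      for (int c = 0; c < 3; ++c) {
        const int j = c * K + k;
        const double dP = -r / P[j];
        dmu_c[c] = dP * (plo_[j] - phi_[j]) * invs_[j];
        double dls = dP * (alo_[j] * plo_[j] - ahi_[j] * phi_[j]);
        if (out(i, 4 * K + j) < -7.0) dls = 0.0;
        dout(i, K + j) = dmu_c[c];
        dout(i, 4 * K + j) = dls;
      }
      const double t1 = std::tanh(out(i, 7 * K + k));
      const double t2 = std::tanh(out(i, 8 * K + k));
      const double t3 = std::tanh(out(i, 9 * K + k));
      dout(i, 7 * K + k) = dmu_c[1] * xs[0] * (1.0 - t1 * t1);
      dout(i, 8 * K + k) = dmu_c[2] * xs[0] * (1.0 - t2 * t2);
      dout(i, 9 * K + k) = dmu_c[2] * xs[1] * (1.0 - t3 * t3);
    }
  }
  if (want_grad)
    return Rcpp::List::create(Rcpp::Named("nll") = nll,
                              Rcpp::Named("dout") = dout);
  return Rcpp::List::create(Rcpp::Named("nll") = nll);
}

// [[Rcpp::export]]
arma::mat relu_cpp(const arma::mat& X) {
  arma::mat Y = X;
  Y.for_each([](double& v) { if (v < 0) v = 0; });
  return Y;
}

// dY masked by the forward output Y (zero where the unit was inactive).
// [[Rcpp::export]]
arma::mat relu_bwd_cpp(const arma::mat& dY, const arma::mat& Y) {
  arma::mat dX = dY;
  const double* yp = Y.memptr();
  double* dp = dX.memptr();
  const arma::uword n = Y.n_elem;
  for (arma::uword i = 0; i < n; ++i) if (yp[i] <= 0) dp[i] = 0;
  return dX;
}

// Fused convolution forward: im2col then GEMM, returning only the output maps.
// Wm is (kh*kw*C) x Cout, bias length Cout.
// [[Rcpp::export]]
arma::mat conv_fwd_cpp(const arma::mat& X, const arma::mat& Wm, const arma::vec& bias,
                       int B, int H, int W, int kh, int kw, int stride, int pad) {
  arma::mat P = im2col_cpp(X, B, H, W, kh, kw, stride, pad);
  arma::mat Y = P * Wm;
  Y.each_row() += bias.t();
  return Y;
}

// 2x2 average pooling (stride 2). X: (B*H*W) x C with even H, W.
// [[Rcpp::export]]
arma::mat avgpool2_cpp(const arma::mat& X, int B, int H, int W) {
  const int C = X.n_cols, oH = H / 2, oW = W / 2;
  arma::mat Y(B * oH * oW, C, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int oy = 0; oy < oH; ++oy)
      for (int ox = 0; ox < oW; ++ox) {
        const int orow = b * oH * oW + oy * oW + ox;
        const int i00 = b * H * W + 2 * oy * W + 2 * ox;
        for (int ch = 0; ch < C; ++ch)
          Y(orow, ch) = 0.25 * (X(i00, ch) + X(i00 + 1, ch) +
                                X(i00 + W, ch) + X(i00 + W + 1, ch));
      }
  return Y;
}

// Nearest-neighbour 2x upsampling (also the adjoint of avgpool2 up to the 1/4 factor).
// [[Rcpp::export]]
arma::mat upsample2_cpp(const arma::mat& X, int B, int H, int W) {
  const int C = X.n_cols, oH = H * 2, oW = W * 2;
  arma::mat Y(B * oH * oW, C, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int iy = 0; iy < H; ++iy)
      for (int ix = 0; ix < W; ++ix) {
        const int irow = b * H * W + iy * W + ix;
        const int o00 = b * oH * oW + 2 * iy * oW + 2 * ix;
        for (int ch = 0; ch < C; ++ch) {
          const double v = X(irow, ch);
          Y(o00, ch) = v; Y(o00 + 1, ch) = v;
          Y(o00 + oW, ch) = v; Y(o00 + oW + 1, ch) = v;
        }
      }
  return Y;
}
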