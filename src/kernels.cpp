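// Numerical kernels: im2col convolution forward/backward, exact Euclidean
// distance transform, connected-component labeling, disk rasterization.
// Tensors are R arrays in (H, W, C, N) column-major layout; convolution
// weights are (K, K, Cin, Cout).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <limits>
using namespace Rcpp;

static void dims4(const NumericVector& a, int* d) {
  IntegerVector dm = a.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Unpack one (H,W,C) sample into a (K*K*C) x (Ho*Wo) matrix of receptive
// fields. Rows are ordered kh-fastest, then kw, then channel, matching the
// column-major layout of the (K,K,Cin,Cout) weight array.
static void im2col(const double* x, int H, int W, int C, int K, int stride,
                   int pad, int Ho, int Wo, arma::mat& cols) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* dst = cols.colptr((arma::uword)ho + (arma::uword)Ho * wo);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      int k = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kw = 0; kw < K; ++kw) {
          int ww = w0 + kw;
          bool wok = (ww >= 0 && ww < W);
          for (int kh = 0; kh < K; ++kh, ++k) {
            int hh = h0 + kh;
            dst[k] = (wok && hh >= 0 && hh < H) ? xc[hh + (size_t)H * ww] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& cols, int H, int W, int C, int K,
                       int stride, int pad, int Ho, int Wo, double* dx) {
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const double* src = cols.colptr((arma::uword)ho + (arma::uword)Ho * wo);
      int h0 = ho * stride - pad, w0 = wo * stride - pad;
      int k = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int kw = 0; kw < K; ++kw) {
          int ww = w0 + kw;
          bool wok = (ww >= 0 && ww < W);
          for (int kh = 0; kh < K; ++kh, ++k) {
            int hh = h0 + kh;
            if (wok && hh >= 0 && hh < H) xc[hh + (size_t)H * ww] += src[k];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  int xd[4], wd[4];
  dims4(x, xd); dims4(w, wd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and kernel");
  int Ho = (H + 2 * pad - K) / stride + 1;
  int Wo = (W + 2 * pad - K) / stride + 1;
  arma::uword KKC = (arma::uword)K * K * Cin;
  arma::uword HWo = (arma::uword)Ho * Wo;
  arma::mat Wm(w.begin(), KKC, (arma::uword)Cout, false, true);
  NumericVector y((R_xlen_t)Ho * Wo * Cout * N);
  // per-sample im2col keeps the working set cache-resident
  arma::mat cols(KKC, HWo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, stride, pad, Ho, Wo,
           cols);
    arma::mat out = Wm.t() * cols;  // Cout x HWo
    double* yn = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      double bc = b[c];
      double* yc = yn + (size_t)Ho * Wo * c;
      const arma::uword cc = (arma::uword)c;
      for (arma::uword i = 0; i < HWo; ++i) yc[i] = out(cc, i) + bc;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         int stride, int pad) {
  int xd[4], wd[4], yd[4];
  dims4(x, xd); dims4(w, wd); dims4(dy, yd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int K = wd[0], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::uword KKC = (arma::uword)K * K * C;
  arma::uword HWo = (arma::uword)Ho * Wo;
  arma::mat Wm(w.begin(), KKC, (arma::uword)Cout, false, true);
  NumericVector dx((R_xlen_t)H * W * C * N);
  arma::mat dW(KKC, (arma::uword)Cout, arma::fill::zeros);
  arma::vec db((arma::uword)Cout, arma::fill::zeros);
  arma::mat cols(KKC, HWo);
  arma::mat dymat((arma::uword)Cout, HWo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, K, stride, pad, Ho, Wo,
           cols);
    const double* dyn = dy.begin() + (size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      const double* dyc = dyn + (size_t)Ho * Wo * c;
      const arma::uword cc = (arma::uword)c;
      double acc = 0.0;
      for (arma::uword i = 0; i < HWo; ++i) {
        dymat(cc, i) = dyc[i];
        acc += dyc[i];
      }
      db[c] += acc;
    }
    dW += cols * dymat.t();
    arma::mat dcols = Wm * dymat;  // KKC x HWo
    col2im_add(dcols, H, W, C, K, stride, pad, Ho, Wo,
               dx.begin() + (size_t)H * W * C * n);
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = IntegerVector::create(K, K, C, Cout);
  NumericVector dbv(db.begin(), db.end());
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// Batch-normalization forward over an (H,W,C,N) array with given per-channel
// statistics; returns the normalized output and xhat for the backward pass.
// [[Rcpp::export]]
List cpp_bn_forward(NumericVector x, NumericVector mu, NumericVector var,
                    NumericVector gamma, NumericVector beta, double eps) {
  int d[4]; dims4(x, d);
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector y(x.size()), xhat(x.size());
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(var[c] + eps);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      double* yc = y.begin() + HW * (c + (size_t)C * n);
      double* hc = xhat.begin() + HW * (c + (size_t)C * n);
      double m = mu[c], iv = inv[c], g = gamma[c], be = beta[c];
      for (size_t i = 0; i < HW; ++i) {
        double h = (xc[i] - m) * iv;
        hc[i] = h;
        yc[i] = g * h + be;
      }
    }
  }
  y.attr("dim") = x.attr("dim");
  xhat.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// Per-channel mean and (biased) variance over (H,W,N).
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  int d[4]; dims4(x, d);
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  NumericVector mu(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    double M = (double)HW * N;
    mu[c] = s / M;
    double v = s2 / M - mu[c] * mu[c];
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericVector dy, NumericVector xhat, NumericVector inv,
                     NumericVector gamma) {
  int d[4]; dims4(dy, d);
  size_t HW = (size_t)d[0] * d[1];
  int C = d[2], N = d[3];
  double M = (double)HW * N;
  NumericVector dgamma(C), dbeta(C), dx(dy.size());
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0, dg = 0, db = 0;
    for (int n = 0; n < N; ++n) {
      const double* dyc = dy.begin() + HW * (c + (size_t)C * n);
      const double* hc = xhat.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        dg += dyc[i] * hc[i];
        db += dyc[i];
      }
    }
    dgamma[c] = dg; dbeta[c] = db;
    s1 = gamma[c] * db;        // sum of dxhat
    s2 = gamma[c] * dg;        // sum of dxhat * xhat
    double g = gamma[c], iv = inv[c];
    for (int n = 0; n < N; ++n) {
      const double* dyc = dy.begin() + HW * (c + (size_t)C * n);
      const double* hc = xhat.begin() + HW * (c + (size_t)C * n);
      double* dxc = dx.begin() + HW * (c + (size_t)C * n);
      for (size_t i = 0; i < HW; ++i) {
        dxc[i] = (iv / M) * (M * g * dyc[i] - s1 - hc[i] * s2);
      }
    }
  }
  dx.attr("dim") = dy.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// 1-d squared distance transform (Felzenszwalb & Huttenlocher). A large
// finite value stands in for infinity so parabola intersections stay finite.
#define DT_BIG 1e20
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -DT_BIG; z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = DT_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance of each foreground pixel to the nearest zero pixel
// of the same matrix. Callers that want the image border treated as
// background pad with a zero ring first.
// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(IntegerMatrix mask) {
  const double INF = DT_BIG;
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix g(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) g(i, j) = mask(i, j) != 0 ? INF : 0.0;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {            // columns
    for (int i = 0; i < H; ++i) f[i] = g(i, j);
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) g(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {            // rows
    for (int j = 0; j < W; ++j) f[j] = g(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) g(i, j) = std::sqrt(d[j]);
  }
  return g;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int t = 0; t < nn; ++t) {
          int r = p.first + dr8[t], c = p.second + dc8[t];
          if (r < 0 || r >= H || c < 0 || c >= W) continue;
          if (mask(r, c) != 0 && lab(r, c) == 0) {
            lab(r, c) = next;
            q.push(std::make_pair(r, c));
          }
        }
      }
    }
  }
  return lab;
}

// Stamp disks of per-point radius onto an H x W binary canvas. Points are
// 1-based (row, col) centers; a pixel is covered when its center lies within
// the radius.
// [[Rcpp::export]]
IntegerMatrix cpp_draw_disks(NumericMatrix pts, NumericVector radius, int H,
                             int W) {
  IntegerMatrix m(H, W);
  for (int p = 0; p < pts.nrow(); ++p) {
    double pr = pts(p, 0), pc = pts(p, 1), rad = radius[p];
    int r0 = std::max(0, (int)std::floor(pr - rad) - 1);
    int r1 = std::min(H - 1, (int)std::ceil(pr + rad));
    int c0 = std::max(0, (int)std::floor(pc - rad) - 1);
    int c1 = std::min(W - 1, (int)std::ceil(pc + rad));
    double r2 = rad * rad;
    for (int c = c0; c <= c1; ++c) {
      double dc = (c + 1) - pc;
      for (int r = r0; r <= r1; ++r) {
        double dr = (r + 1) - pr;
        if (dr * dr + dc * dc <= r2) m(r, c) = 1;
      }
    }
  }
  return m;
}
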