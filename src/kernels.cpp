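// Low-level numeric kernels: 2-D cross-correlation (forward/backward),
// depthwise variant, and separable bilinear resize with antialias.
//
// Tensor layout conventions (R column-major arrays):
//   activations  : dim (C, H, W, N)
//   conv weights : dim (Cout, Cin, k, k)   [k odd, zero padding (k-1)/2]
//   depthwise    : dim (C, k, k)
// All kernels are single-threaded and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat weight_matrix(const NumericVector& w,
                                      int Cout, int Cin, int k) {
  arma::mat W(Cout, Cin * k * k);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kr = 0; kr < k; ++kr)
        for (int kc = 0; kc < k; ++kc)
          W(co, ci * k * k + kr * k + kc) =
            w[co + Cout * (ci + Cin * (kr + k * kc))];
  return W;
}

static void im2col(const double* x, int C, int H, int W,
                   int k, int s, int pad, int Ho, int Wo, arma::mat& col) {
  // col is (C*k*k) x (Ho*Wo), column q = oy + Ho*ox
  col.zeros();
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      int q = oy + Ho * ox;
      for (int ci = 0; ci < C; ++ci) {
        for (int kr = 0; kr < k; ++kr) {
          int iy = oy * s - pad + kr;
          if (iy < 0 || iy >= H) continue;
          for (int kc = 0; kc < k; ++kc) {
            int ix = ox * s - pad + kc;
            if (ix < 0 || ix >= W) continue;
            col(ci * k * k + kr * k + kc, q) = x[ci + C * (iy + H * ix)];
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& col, int C, int H, int W,
                       int k, int s, int pad, int Ho, int Wo, double* dx) {
  for (int ox = 0; ox < Wo; ++ox) {
    for (int oy = 0; oy < Ho; ++oy) {
      int q = oy + Ho * ox;
      for (int ci = 0; ci < C; ++ci) {
        for (int kr = 0; kr < k; ++kr) {
          int iy = oy * s - pad + kr;
          if (iy < 0 || iy >= H) continue;
          for (int kc = 0; kc < k; ++kc) {
            int ix = ox * s - pad + kc;
            if (ix < 0 || ix >= W) continue;
            dx[ci + C * (iy + H * ix)] += col(ci * k * k + kr * k + kc, q);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w,
                           NumericVector bias, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Cout = wd[0], Cin = wd[1], k = wd[2];
  if (Cin != C) stop("conv: input channels (%d) != weight Cin (%d)", C, Cin);
  int pad = (k - 1) / 2;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;

  arma::mat Wm = weight_matrix(w, Cout, Cin, k);
  NumericVector y(Cout * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo, N);

  arma::mat col(C * k * k, Ho * Wo);
  bool has_b = bias.size() == Cout;
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (R_xlen_t)C * H * W * n, C, H, W, k, stride, pad, Ho, Wo, col);
    arma::mat ym = Wm * col;
    if (has_b) ym.each_col() += arma::vec(&bias[0], Cout);
    std::copy(ym.memptr(), ym.memptr() + (R_xlen_t)Cout * Ho * Wo,
              &y[0] + (R_xlen_t)Cout * Ho * Wo * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Cout = wd[0], Cin = wd[1], k = wd[2];
  int Ho = yd[1], Wo = yd[2];
  int pad = (k - 1) / 2;

  arma::mat Wm = weight_matrix(w, Cout, Cin, k);
  arma::mat dWm(Cout, Cin * k * k, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;

  arma::mat col(C * k * k, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (R_xlen_t)C * H * W * n, C, H, W, k, stride, pad, Ho, Wo, col);
    arma::mat dym(const_cast<double*>(&dy[0]) + (R_xlen_t)Cout * Ho * Wo * n,
                  Cout, Ho * Wo, false, true);
    dWm += dym * col.t();
    db += arma::sum(dym, 1);
    if (need_dx) {
      arma::mat dcol = Wm.t() * dym;
      col2im_add(dcol, C, H, W, k, stride, pad, Ho, Wo,
                 &dx[0] + (R_xlen_t)C * H * W * n);
    }
  }

  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int kr = 0; kr < k; ++kr)
        for (int kc = 0; kc < k; ++kc)
          dw[co + Cout * (ci + Cin * (kr + k * kc))] =
            dWm(co, ci * k * k + kr * k + kc);

  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericVector w,
                             NumericVector bias, int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int Cw = wd[0], k = wd[1];
  if (Cw != C) stop("dwconv: channel mismatch");
  int pad = (k - 1) / 2;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;

  NumericVector y(C * Ho * Wo * N);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, N);
  bool has_b = bias.size() == C;

  for (int n = 0; n < N; ++n) {
    const double* xs = &x[0] + (R_xlen_t)C * H * W * n;
    double* ys = &y[0] + (R_xlen_t)C * Ho * Wo * n;
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy)
        for (int c = 0; c < C; ++c) {
          double acc = has_b ? bias[c] : 0.0;
          for (int kr = 0; kr < k; ++kr) {
            int iy = oy * stride - pad + kr;
            if (iy < 0 || iy >= H) continue;
            for (int kc = 0; kc < k; ++kc) {
              int ix = ox * stride - pad + kc;
              if (ix < 0 || ix >= W) continue;
              acc += w[c + C * (kr + k * kc)] * xs[c + C * (iy + H * ix)];
            }
          }
          ys[c + C * (oy + Ho * ox)] = acc;
        }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  int k = wd[1];
  int Ho = yd[1], Wo = yd[2];
  int pad = (k - 1) / 2;

  NumericVector dw(w.size()), db(C);
  dw.attr("dim") = wd;
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;

  for (int n = 0; n < N; ++n) {
    const double* xs = &x[0] + (R_xlen_t)C * H * W * n;
    const double* dys = &dy[0] + (R_xlen_t)C * Ho * Wo * n;
    double* dxs = need_dx ? &dx[0] + (R_xlen_t)C * H * W * n : nullptr;
    for (int ox = 0; ox < Wo; ++ox)
      for (int oy = 0; oy < Ho; ++oy)
        for (int c = 0; c < C; ++c) {
          double g = dys[c + C * (oy + Ho * ox)];
          if (g == 0.0) continue;
          db[c] += g;
          for (int kr = 0; kr < k; ++kr) {
            int iy = oy * stride - pad + kr;
            if (iy < 0 || iy >= H) continue;
            for (int kc = 0; kc < k; ++kc) {
              int ix = ox * stride - pad + kc;
              if (ix < 0 || ix >= W) continue;
              dw[c + C * (kr + k * kc)] += g * xs[c + C * (iy + H * ix)];
              if (need_dx) dxs[c + C * (iy + H * ix)] += g * w[c + C * (kr + k * kc)];
            }
          }
        }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Separable resize, triangle (bilinear) kernel; when downscaling the filter
// support is widened by the scale factor (antialias), as common raster
// libraries do. Weights are non-negative and normalized, so outputs stay
// within the input value range.
static void axis_weights(int n_in, int n_out,
                         std::vector<std::vector<double>>& wts,
                         std::vector<int>& first) {
  double scale = (double)n_in / n_out;
  double fscale = scale > 1.0 ? scale : 1.0;
  double radius = fscale;  // support of the triangle kernel, scaled
  wts.assign(n_out, {});
  first.assign(n_out, 0);
  for (int i = 0; i < n_out; ++i) {
    double center = (i + 0.5) * scale;
    int lo = (int)std::floor(center - radius + 0.5);
    int hi = (int)std::ceil(center + radius - 0.5);
    if (lo < 0) lo = 0;
    if (hi > n_in - 1) hi = n_in - 1;
    first[i] = lo;
    double tot = 0.0;
    std::vector<double> w(hi - lo + 1);
    for (int j = lo; j <= hi; ++j) {
      double t = std::fabs((j + 0.5 - center) / fscale);
      double v = t < 1.0 ? 1.0 - t : 0.0;
      w[j - lo] = v;
      tot += v;
    }
    if (tot <= 0.0) {  // degenerate: nearest neighbour fallback
      int j = (int)std::min<double>(n_in - 1.0, std::max(0.0, std::floor(center)));
      first[i] = j;
      w.assign(1, 1.0);
      tot = 1.0;
    }
    for (double& v : w) v /= tot;
    wts[i] = std::move(w);
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize(NumericVector img, int out_h, int out_w) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  if (out_h < 1 || out_w < 1) stop("resize: non-positive output size");

  std::vector<std::vector<double>> wh, ww;
  std::vector<int> fh, fw;
  axis_weights(H, out_h, wh, fh);
  axis_weights(W, out_w, ww, fw);

  // pass 1: rows (H -> out_h), pass 2: cols (W -> out_w)
  std::vector<double> tmp((R_xlen_t)out_h * W * C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < out_h; ++y) {
        double acc = 0.0;
        const std::vector<double>& w = wh[y];
        for (size_t j = 0; j < w.size(); ++j)
          acc += w[j] * img[(fh[y] + j) + H * (x + (R_xlen_t)W * c)];
        tmp[y + (R_xlen_t)out_h * (x + (R_xlen_t)W * c)] = acc;
      }

  NumericVector out((R_xlen_t)out_h * out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  for (int c = 0; c < C; ++c)
    for (int x = 0; x < out_w; ++x)
      for (int y = 0; y < out_h; ++y) {
        double acc = 0.0;
        const std::vector<double>& w = ww[x];
        for (size_t j = 0; j < w.size(); ++j)
          acc += w[j] * tmp[y + (R_xlen_t)out_h * ((fw[x] + j) + (R_xlen_t)W * c)];
        out[y + (R_xlen_t)out_h * (x + (R_xlen_t)out_w * c)] = acc;
      }
  return out;
}
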