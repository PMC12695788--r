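// Low-level numeric kernels for feature-map tensors.
//
// Feature maps are stored as dense R arrays with dim = c(C, H, W)
// (channel fastest-varying, column-major), weights as c(Cout, Cin/groups, kh, kw).
// Convolutions run as chunked im2col + BLAS gemm so peak memory stays bounded
// for 640x640 inputs; backward passes mirror the forward chunking.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill im2col block for output columns [j0, j1) of one group.
// K is (Cg*kh*kw) x (j1-j0). Column j corresponds to output site
// (ho, wo) with j = ho + Ho*wo. Row index r = ci + Cg*(p + kh*q).
static void im2col_block(const double* x, int C, int H, int W,
                         int cg0, int Cg, int kh, int kw,
                         int sh, int sw, int ph, int pw,
                         int Ho, int j0, int j1, arma::mat& K) {
  const int ncol = j1 - j0;
  K.zeros(static_cast<size_t>(Cg) * kh * kw, ncol);
  for (int j = j0; j < j1; ++j) {
    const int ho = j % Ho, wo = j / Ho;
    const int hi0 = ho * sh - ph, wi0 = wo * sw - pw;
    double* col = K.colptr(j - j0);
    for (int q = 0; q < kw; ++q) {
      const int wi = wi0 + q;
      if (wi < 0 || wi >= W) continue;
      for (int p = 0; p < kh; ++p) {
        const int hi = hi0 + p;
        if (hi < 0 || hi >= H) continue;
        const double* xptr = x + (cg0) + static_cast<size_t>(C) * (hi + static_cast<size_t>(H) * wi);
        double* kptr = col + static_cast<size_t>(Cg) * (p + kh * q);
        for (int ci = 0; ci < Cg; ++ci) kptr[ci] = xptr[ci];
      }
    }
  }
}

// Scatter-add the transpose operation of im2col (col2im) for one block.
static void col2im_block(double* dx, int C, int H, int W,
                         int cg0, int Cg, int kh, int kw,
                         int sh, int sw, int ph, int pw,
                         int Ho, int j0, int j1, const arma::mat& K) {
  for (int j = j0; j < j1; ++j) {
    const int ho = j % Ho, wo = j / Ho;
    const int hi0 = ho * sh - ph, wi0 = wo * sw - pw;
    const double* col = K.colptr(j - j0);
    for (int q = 0; q < kw; ++q) {
      const int wi = wi0 + q;
      if (wi < 0 || wi >= W) continue;
      for (int p = 0; p < kh; ++p) {
        const int hi = hi0 + p;
        if (hi < 0 || hi >= H) continue;
        double* xptr = dx + (cg0) + static_cast<size_t>(C) * (hi + static_cast<size_t>(H) * wi);
        const double* kptr = col + static_cast<size_t>(Cg) * (p + kh * q);
        for (int ci = 0; ci < Cg; ++ci) xptr[ci] += kptr[ci];
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv2d")]]
NumericVector cpp_conv2d(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         Nullable<NumericVector> bias,
                         int sh, int sw, int ph, int pw, int groups) {
  const int C = xd[0], H = xd[1], W = xd[2];
  const int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  if (C != Cg * groups) stop("conv2d: input channels (%d) != kernel channels (%d) * groups (%d)", C, Cg, groups);
  if (Cout % groups != 0) stop("conv2d: out channels not divisible by groups");
  const int Ho = out_dim(H, kh, sh, ph), Wo = out_dim(W, kw, sw, pw);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  const int Cog = Cout / groups;
  const size_t ncols = static_cast<size_t>(Ho) * Wo;

  NumericVector y(static_cast<size_t>(Cout) * ncols);
  y.attr("dim") = IntegerVector::create(Cout, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();

  // weight matrix per group: Cog x (Cg*kh*kw); weight layout o + Cout*(i + Cg*(p + kh*q))
  const size_t krows = static_cast<size_t>(Cg) * kh * kw;
  const int chunk = std::max(1, (int)std::min<size_t>(ncols, (1 << 22) / std::max<size_t>(krows, 1) + 1));
  arma::mat K;
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Cog, krows);
    for (size_t r = 0; r < krows; ++r)
      for (int o = 0; o < Cog; ++o)
        Wm(o, r) = w[(g * Cog + o) + static_cast<size_t>(Cout) * r];
    for (size_t j0 = 0; j0 < ncols; j0 += chunk) {
      const size_t j1 = std::min(ncols, j0 + chunk);
      im2col_block(xp, C, H, W, g * Cg, Cg, kh, kw, sh, sw, ph, pw, Ho, (int)j0, (int)j1, K);
      arma::mat Yb = Wm * K; // Cog x (j1-j0)
      for (size_t j = j0; j < j1; ++j) {
        double* ycol = yp + static_cast<size_t>(Cout) * j + g * Cog;
        const double* yb = Yb.colptr(j - j0);
        for (int o = 0; o < Cog; ++o) ycol[o] = yb[o];
      }
    }
  }
  if (bias.isNotNull()) {
    NumericVector b(bias);
    for (size_t j = 0; j < ncols; ++j) {
      double* ycol = yp + static_cast<size_t>(Cout) * j;
      for (int o = 0; o < Cout; ++o) ycol[o] += b[o];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_backward")]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xd,
                         NumericVector w, IntegerVector wd,
                         NumericVector dy,
                         int sh, int sw, int ph, int pw, int groups,
                         bool need_dx, bool need_dw, bool need_db) {
  const int C = xd[0], H = xd[1], W = xd[2];
  const int Cout = wd[0], Cg = wd[1], kh = wd[2], kw = wd[3];
  const int Ho = out_dim(H, kh, sh, ph), Wo = out_dim(W, kw, sw, pw);
  const int Cog = Cout / groups;
  const size_t ncols = static_cast<size_t>(Ho) * Wo;
  const size_t krows = static_cast<size_t>(Cg) * kh * kw;

  NumericVector dx(need_dx ? x.size() : 0);
  NumericVector dw(need_dw ? w.size() : 0);
  NumericVector db(need_db ? Cout : 0);
  if (need_dx) dx.attr("dim") = IntegerVector::create(C, H, W);
  if (need_dw) dw.attr("dim") = IntegerVector::create(Cout, Cg, kh, kw);

  const double* xp = x.begin();
  const double* dyp = dy.begin();
  const int chunk = std::max(1, (int)std::min<size_t>(ncols, (1 << 22) / std::max<size_t>(krows, 1) + 1));
  arma::mat K;

  for (int g = 0; g < groups; ++g) {
    arma::mat Wm(Cog, krows);
    for (size_t r = 0; r < krows; ++r)
      for (int o = 0; o < Cog; ++o)
        Wm(o, r) = w[(g * Cog + o) + static_cast<size_t>(Cout) * r];
    arma::mat dWm(Cog, krows, arma::fill::zeros);
    for (size_t j0 = 0; j0 < ncols; j0 += chunk) {
      const size_t j1 = std::min(ncols, j0 + chunk);
      arma::mat dYb(Cog, j1 - j0);
      for (size_t j = j0; j < j1; ++j) {
        const double* dcol = dyp + static_cast<size_t>(Cout) * j + g * Cog;
        double* dst = dYb.colptr(j - j0);
        for (int o = 0; o < Cog; ++o) dst[o] = dcol[o];
      }
      if (need_dw) {
        im2col_block(xp, C, H, W, g * Cg, Cg, kh, kw, sh, sw, ph, pw, Ho, (int)j0, (int)j1, K);
        dWm += dYb * K.t();
      }
      if (need_dx) {
        arma::mat dK = Wm.t() * dYb; // krows x ncols_block
        col2im_block(dx.begin(), C, H, W, g * Cg, Cg, kh, kw, sh, sw, ph, pw, Ho, (int)j0, (int)j1, dK);
      }
    }
    if (need_dw)
      for (size_t r = 0; r < krows; ++r)
        for (int o = 0; o < Cog; ++o)
          dw[(g * Cog + o) + static_cast<size_t>(Cout) * r] = dWm(o, r);
  }
  if (need_db) {
    for (size_t j = 0; j < ncols; ++j) {
      const double* dcol = dyp + static_cast<size_t>(Cout) * j;
      for (int o = 0; o < Cout; ++o) db[o] += dcol[o];
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_maxpool")]]
List cpp_maxpool(NumericVector x, IntegerVector xd, int k, int stride, int pad) {
  const int C = xd[0], H = xd[1], W = xd[2];
  const int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y(static_cast<size_t>(C) * Ho * Wo);
  IntegerVector arg(y.size()); // linear index into x of the max element
  y.attr("dim") = IntegerVector::create(C, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int c = 0; c < C; ++c) {
        double best = -std::numeric_limits<double>::infinity();
        int bidx = -1;
        for (int q = 0; q < k; ++q) {
          const int wi = wo * stride - pad + q;
          if (wi < 0 || wi >= W) continue;
          for (int p = 0; p < k; ++p) {
            const int hi = ho * stride - pad + p;
            if (hi < 0 || hi >= H) continue;
            const size_t idx = c + static_cast<size_t>(C) * (hi + static_cast<size_t>(H) * wi);
            if (xp[idx] > best) { best = xp[idx]; bidx = (int)idx; }
          }
        }
        const size_t oidx = c + static_cast<size_t>(C) * (ho + static_cast<size_t>(Ho) * wo);
        yp[oidx] = bidx >= 0 ? best : 0.0;
        arg[oidx] = bidx;
      }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export(name = ".cpp_maxpool_backward")]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector arg, IntegerVector xd) {
  NumericVector dx(static_cast<size_t>(xd[0]) * xd[1] * xd[2]);
  dx.attr("dim") = xd;
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    if (arg[i] >= 0) dx[arg[i]] += dy[i];
  return dx;
}

// Bilinear sampling with zero padding outside the valid grid.
// Coordinates are 0-based (px = column, py = row). x is (C,H,W);
// px,py have length M; output is (C,M). Weights follow
// max(0, 1-|px - floor(px)|) * max(0, 1-|py - floor(py)|) and its three
// companions, so out-of-bounds neighbours contribute zero.
// [[Rcpp::export(name = ".cpp_bilinear_sample")]]
NumericVector cpp_bilinear_sample(NumericVector x, IntegerVector xd,
                                  NumericVector px, NumericVector py) {
  const int C = xd[0], H = xd[1], W = xd[2];
  const R_xlen_t M = px.size();
  NumericVector y(static_cast<size_t>(C) * M);
  y.attr("dim") = IntegerVector::create(C, (int)M);
  const double* xp = x.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double cx = px[m], cy = py[m];
    const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy);
    const double fx = cx - x0, fy = cy - y0;
    const double wts[4] = { (1 - fx) * (1 - fy), fx * fy, (1 - fx) * fy, fx * (1 - fy) };
    const int xs[4] = { x0, x0 + 1, x0, x0 + 1 };
    const int ys[4] = { y0, y0 + 1, y0 + 1, y0 };
    double* ycol = y.begin() + static_cast<size_t>(C) * m;
    for (int t = 0; t < 4; ++t) {
      if (wts[t] == 0.0 || xs[t] < 0 || xs[t] >= W || ys[t] < 0 || ys[t] >= H) continue;
      const double* xcol = xp + static_cast<size_t>(C) * (ys[t] + static_cast<size_t>(H) * xs[t]);
      for (int c = 0; c < C; ++c) ycol[c] += wts[t] * xcol[c];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_bilinear_sample_backward")]]
List cpp_bilinear_sample_backward(NumericVector x, IntegerVector xd,
                                  NumericVector px, NumericVector py,
                                  NumericVector dy, bool need_dx, bool need_dp) {
  const int C = xd[0], H = xd[1], W = xd[2];
  const R_xlen_t M = px.size();
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;
  NumericVector dpx(need_dp ? M : 0), dpy(need_dp ? M : 0);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  for (R_xlen_t m = 0; m < M; ++m) {
    const double cx = px[m], cy = py[m];
    const int x0 = (int)std::floor(cx), y0 = (int)std::floor(cy);
    const double fx = cx - x0, fy = cy - y0;
    // weights and their derivatives w.r.t. (px, py)
    const double wts[4]  = { (1 - fx) * (1 - fy), fx * fy, (1 - fx) * fy, fx * (1 - fy) };
    const double dwx[4]  = { -(1 - fy), fy, -fy, (1 - fy) };
    const double dwy[4]  = { -(1 - fx), fx, (1 - fx), -fx };
    const int xs[4] = { x0, x0 + 1, x0, x0 + 1 };
    const int ys[4] = { y0, y0 + 1, y0 + 1, y0 };
    const double* dcol = dyp + static_cast<size_t>(C) * m;
    double gx = 0, gy = 0;
    for (int t = 0; t < 4; ++t) {
      if (xs[t] < 0 || xs[t] >= W || ys[t] < 0 || ys[t] >= H) continue;
      const size_t base = static_cast<size_t>(C) * (ys[t] + static_cast<size_t>(H) * xs[t]);
      double dot = 0;
      for (int c = 0; c < C; ++c) dot += dcol[c] * xp[base + c];
      gx += dwx[t] * dot;
      gy += dwy[t] * dot;
      if (need_dx && wts[t] != 0.0) {
        double* dxcol = dx.begin() + base;
        for (int c = 0; c < C; ++c) dxcol[c] += wts[t] * dcol[c];
      }
    }
    if (need_dp) { dpx[m] = gx; dpy[m] = gy; }
  }
  return List::create(_["dx"] = dx, _["dpx"] = dpx, _["dpy"] = dpy);
}
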