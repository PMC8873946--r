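// Low-level numeric kernels for the fully convolutional network and the
// detection post-processing filters. Layout convention throughout: an image
// or feature map is an H x W x C array (column-major, matching R), a
// convolution weight is a (kh, kw, Cin, Cout) array flattened column-major.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// symmetric (edge-duplicating) reflection of index i into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static arma::mat im2col(const arma::cube &x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::mat col(kh * kw * C, (size_t)H * W, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat &sl = x.slice(ch);
    for (int dc = 0; dc < kw; ++dc) {
      for (int dr = 0; dr < kh; ++dr) {
        const int krow = dr + kh * (dc + kw * ch);
        for (int c = 0; c < W; ++c) {
          const int ic = c + dc - pw;
          if (ic < 0 || ic >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int ir = r + dr - ph;
            if (ir < 0 || ir >= H) continue;
            col(krow, (size_t)r + (size_t)H * c) = sl(ir, ic);
          }
        }
      }
    }
  }
  return col;
}

static arma::cube col2im(const arma::mat &dcol, int H, int W, int C,
                         int kh, int kw) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    arma::mat &sl = dx.slice(ch);
    for (int dc = 0; dc < kw; ++dc) {
      for (int dr = 0; dr < kh; ++dr) {
        const int krow = dr + kh * (dc + kw * ch);
        for (int c = 0; c < W; ++c) {
          const int ic = c + dc - pw;
          if (ic < 0 || ic >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int ir = r + dr - ph;
            if (ir < 0 || ir >= H) continue;
            sl(ir, ic) += dcol(krow, (size_t)r + (size_t)H * c);
          }
        }
      }
    }
  }
  return dx;
}

// zero-padded "same" convolution, odd kernel sizes only
// [[Rcpp::export]]
arma::cube cpp_conv2d(const arma::cube &x, const arma::vec &w,
                      const arma::vec &b, int kh, int kw,
                      int cin, int cout) {
  const int H = x.n_rows, W = x.n_cols;
  const size_t N = (size_t)H * W;
  arma::mat wmat(const_cast<double *>(w.memptr()), kh * kw * cin, cout,
                 false, true);
  arma::mat col = im2col(x, kh, kw);
  arma::mat out = col.t() * wmat; // N x cout
  out.each_row() += b.t();
  arma::cube y(H, W, cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * N * cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(const arma::cube &x, const arma::vec &w,
                         const arma::cube &dout, int kh, int kw,
                         int cin, int cout) {
  const int H = x.n_rows, W = x.n_cols;
  const size_t N = (size_t)H * W;
  arma::mat wmat(const_cast<double *>(w.memptr()), kh * kw * cin, cout,
                 false, true);
  arma::mat dout_mat(const_cast<double *>(dout.memptr()), N, cout,
                     false, true);
  arma::mat col = im2col(x, kh, kw);
  arma::mat dw = col * dout_mat;              // K x cout
  arma::vec db = arma::sum(dout_mat, 0).t();  // cout
  arma::mat dcol = wmat * dout_mat.t();       // K x N
  arma::cube dx = col2im(dcol, H, W, cin, kh, kw);
  return List::create(_["dx"] = dx, _["dw"] = arma::vectorise(dw),
                      _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even
// [[Rcpp::export]]
List cpp_maxpool2(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::icube idx(Ho, Wo, C); // 0..3 = (dr, dc) = (0,0) (1,0) (0,1) (1,1)
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        double best = x(2 * r, 2 * c, ch);
        int bi = 0;
        const double v10 = x(2 * r + 1, 2 * c, ch);
        const double v01 = x(2 * r, 2 * c + 1, ch);
        const double v11 = x(2 * r + 1, 2 * c + 1, ch);
        if (v10 > best) { best = v10; bi = 1; }
        if (v01 > best) { best = v01; bi = 2; }
        if (v11 > best) { best = v11; bi = 3; }
        y(r, c, ch) = best;
        idx(r, c, ch) = bi;
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_backward(const arma::cube &dout,
                                 const arma::icube &idx) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  arma::cube dx(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    for (int c = 0; c < Wo; ++c) {
      for (int r = 0; r < Ho; ++r) {
        const int bi = idx(r, c, ch);
        const int dr = bi & 1, dc = bi >> 1;
        dx(2 * r + dr, 2 * c + dc, ch) += dout(r, c, ch);
      }
    }
  }
  return dx;
}

// bilinear x2 upsampling weights, align_corners = FALSE semantics
static void up2_weights(int n_in, std::vector<int> &lo, std::vector<int> &hi,
                        std::vector<double> &whi) {
  const int n_out = 2 * n_in;
  lo.resize(n_out); hi.resize(n_out); whi.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    if (src < 0) src = 0;
    if (src > n_in - 1) src = n_in - 1;
    int i0 = (int)std::floor(src);
    if (i0 > n_in - 2) i0 = n_in - 2;
    if (i0 < 0) i0 = 0;
    lo[i] = i0; hi[i] = i0 + 1; whi[i] = src - i0;
  }
}

// [[Rcpp::export]]
arma::cube cpp_upsample2(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  std::vector<int> rlo, rhi, clo, chi;
  std::vector<double> rw, cw;
  up2_weights(H, rlo, rhi, rw);
  up2_weights(W, clo, chi, cw);
  arma::cube y(2 * H, 2 * W, C);
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat &sl = x.slice(ch);
    arma::mat tmp(2 * H, W);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < 2 * H; ++r)
        tmp(r, c) = (1 - rw[r]) * sl(rlo[r], c) + rw[r] * sl(rhi[r], c);
    arma::mat &out = y.slice(ch);
    for (int c = 0; c < 2 * W; ++c)
      for (int r = 0; r < 2 * H; ++r)
        out(r, c) = (1 - cw[c]) * tmp(r, clo[c]) + cw[c] * tmp(r, chi[c]);
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_backward(const arma::cube &dout) {
  const int Ho = dout.n_rows, Wo = dout.n_cols, C = dout.n_slices;
  const int H = Ho / 2, W = Wo / 2;
  std::vector<int> rlo, rhi, clo, chi;
  std::vector<double> rw, cw;
  up2_weights(H, rlo, rhi, rw);
  up2_weights(W, clo, chi, cw);
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    arma::mat tmp(Ho, W, arma::fill::zeros);
    const arma::mat &d = dout.slice(ch);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        tmp(r, clo[c]) += (1 - cw[c]) * d(r, c);
        tmp(r, chi[c]) += cw[c] * d(r, c);
      }
    arma::mat &dsl = dx.slice(ch);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < Ho; ++r) {
        dsl(rlo[r], c) += (1 - rw[r]) * tmp(r, c);
        dsl(rhi[r], c) += rw[r] * tmp(r, c);
      }
  }
  return dx;
}

// 3x3 median filter with symmetric reflection at borders
// [[Rcpp::export]]
arma::mat cpp_median3(const arma::mat &x) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat y(H, W);
  double buf[9];
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr)
          buf[k++] = x(reflect_idx(r + dr, H), reflect_idx(c + dc, W));
      std::nth_element(buf, buf + 4, buf + 9);
      y(r, c) = buf[4];
    }
  }
  return y;
}

// separable Gaussian blur, radius ceil(3*sigma), symmetric reflection
// [[Rcpp::export]]
arma::mat cpp_gaussian_blur(const arma::mat &x, double sigma) {
  if (sigma <= 0) return x;
  const int H = x.n_rows, W = x.n_cols;
  const int R = std::max(1, (int)std::ceil(3.0 * sigma));
  arma::vec k(2 * R + 1);
  for (int i = -R; i <= R; ++i)
    k(i + R) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  k /= arma::accu(k);
  arma::mat tmp(H, W), y(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int d = -R; d <= R; ++d) s += k(d + R) * x(reflect_idx(r + d, H), c);
      tmp(r, c) = s;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int d = -R; d <= R; ++d) s += k(d + R) * tmp(r, reflect_idx(c + d, W));
      y(r, c) = s;
    }
  return y;
}

// grayscale dilation with a Euclidean disc structuring element;
// pixels outside the frame are treated as 0 (background)
// [[Rcpp::export]]
arma::mat cpp_grey_dilate_disc(const arma::mat &x, int radius) {
  const int H = x.n_rows, W = x.n_cols;
  if (radius <= 0) return x;
  std::vector<std::pair<int, int> > off;
  for (int dc = -radius; dc <= radius; ++dc)
    for (int dr = -radius; dr <= radius; ++dr)
      if (dr * dr + dc * dc <= radius * radius) off.push_back({dr, dc});
  arma::mat y(H, W, arma::fill::zeros);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double m = 0;
      for (size_t i = 0; i < off.size(); ++i) {
        const int rr = r + off[i].first, cc = c + off[i].second;
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (x(rr, cc) > m) m = x(rr, cc);
      }
      y(r, c) = m;
    }
  return y;
}
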