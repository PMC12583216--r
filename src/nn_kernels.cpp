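// Minimal convolutional-network kernels: im2col convolution (forward and
// backward), 2x2 max pooling and nearest-neighbour upsampling. Feature
// maps are H x W x C cubes; convolution weights are (k*k*Cin) x Cout
// matrices with column index ci*k*k + kc*k + kr (channel-major, then
// kernel column, then kernel row).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// valid output-row range [ho_lo, ho_hi) for an input of H rows
static inline void valid_range(int H, int k_off, int stride, int pad,
                               int Ho, int& lo, int& hi) {
  // need 0 <= ho*stride + k_off - pad < H
  int lo_num = pad - k_off;
  lo = lo_num <= 0 ? 0 : (lo_num + stride - 1) / stride;
  int hi_num = H - 1 + pad - k_off;
  hi = hi_num < 0 ? 0 : hi_num / stride + 1;
  if (hi > Ho) hi = Ho;
  if (lo > hi) lo = hi;
}

static void im2col(const cube& x, int k, int stride, int pad,
                   mat& out, int& Ho, int& Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  Ho = (H + 2 * pad - k) / stride + 1;
  Wo = (W + 2 * pad - k) / stride + 1;
  out.zeros(Ho * Wo, (size_t)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* xs = x.slice_memptr(c);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int colIdx = c * k * k + kc * k + kr;
        double* ocol = out.colptr(colIdx);
        int ho_lo, ho_hi;
        valid_range(H, kr, stride, pad, Ho, ho_lo, ho_hi);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kc - pad;
          if (wi < 0 || wi >= W) continue;
          const double* src = xs + (size_t)H * wi;
          double* dst = ocol + (size_t)Ho * wo;
          if (stride == 1) {
            memcpy(dst + ho_lo, src + ho_lo + kr - pad,
                   (ho_hi - ho_lo) * sizeof(double));
          } else {
            for (int ho = ho_lo; ho < ho_hi; ++ho) {
              dst[ho] = src[ho * stride + kr - pad];
            }
          }
        }
      }
    }
  }
}

static void col2im(const mat& cols, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, cube& dx) {
  dx.zeros(H, W, C);
  for (int c = 0; c < C; ++c) {
    double* ds = dx.slice_memptr(c);
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const int colIdx = c * k * k + kc * k + kr;
        const double* icol = cols.colptr(colIdx);
        int ho_lo, ho_hi;
        valid_range(H, kr, stride, pad, Ho, ho_lo, ho_hi);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride + kc - pad;
          if (wi < 0 || wi >= W) continue;
          double* dst = ds + (size_t)H * wi + kr - pad;
          const double* src = icol + (size_t)Ho * wo;
          for (int ho = ho_lo; ho < ho_hi; ++ho) {
            dst[ho * stride] += src[ho];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fw(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, int k, int stride, int pad) {
  int Ho, Wo;
  mat cols;
  im2col(x, k, stride, pad, cols, Ho, Wo);
  mat Y = cols * W;
  Y.each_row() += b.t();
  const int Cout = W.n_cols;
  cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    y.slice(co) = reshape(Y.col(co), Ho, Wo);
  }
  return y;
}

// forward that also returns the im2col matrix for reuse in backward
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_fw2(const arma::cube& x, const arma::mat& W,
                          const arma::vec& b, int k, int stride, int pad) {
  int Ho, Wo;
  mat cols;
  im2col(x, k, stride, pad, cols, Ho, Wo);
  mat Y = cols * W;
  Y.each_row() += b.t();
  const int Cout = W.n_cols;
  cube y(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    y.slice(co) = reshape(Y.col(co), Ho, Wo);
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("cols") = cols);
}

// backward from a cached im2col matrix (dims = input H, W, C)
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw2(const arma::mat& cols,
                          const arma::ivec& dims, const arma::mat& W,
                          const arma::cube& dy, int k, int stride,
                          int pad) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, Cout = dy.n_slices;
  mat dY(Ho * Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    dY.col(co) = vectorise(dy.slice(co));
  }
  mat dW = cols.t() * dY;
  vec db = sum(dY, 0).t();
  mat dcols = dY * W.t();
  cube dx;
  col2im(dcols, dims(0), dims(1), dims(2), k, stride, pad, Ho, Wo, dx);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bw(const arma::cube& x, const arma::mat& W,
                         const arma::cube& dy, int k, int stride, int pad) {
  int Ho, Wo;
  mat cols;
  im2col(x, k, stride, pad, cols, Ho, Wo);
  const int Cout = W.n_cols;
  mat dY(Ho * Wo, Cout);
  for (int co = 0; co < Cout; ++co) {
    dY.col(co) = vectorise(dy.slice(co));
  }
  mat dW = cols.t() * dY;
  vec db = sum(dY, 0).t();
  mat dcols = dY * W.t();
  cube dx;
  col2im(dcols, x.n_rows, x.n_cols, x.n_slices, k, stride, pad, Ho, Wo, dx);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cpp_maxpool2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  ucube idx(Ho, Wo, C);  // linear index into the H x W slice
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        int bi = 2 * ho, bj = 2 * wo;
        double best = xs(bi, bj);
        int br = bi, bc = bj;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            if (xs(bi + di, bj + dj) > best) {
              best = xs(bi + di, bj + dj);
              br = bi + di; bc = bj + dj;
            }
          }
        }
        y(ho, wo, c) = best;
        idx(ho, wo, c) = br + (size_t)H * bc;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bw(const arma::cube& dy, const arma::ucube& idx,
                           int H, int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& ds = dx.slice(c);
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        ds(idx(ho, wo, c)) += dy(ho, wo, c);
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        const double v = x(h, w, c);
        y(2 * h, 2 * w, c) = v;
        y(2 * h + 1, 2 * w, c) = v;
        y(2 * h, 2 * w + 1, c) = v;
        y(2 * h + 1, 2 * w + 1, c) = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        dx(h, w, c) = dy(2 * h, 2 * w, c) + dy(2 * h + 1, 2 * w, c) +
                      dy(2 * h, 2 * w + 1, c) + dy(2 * h + 1, 2 * w + 1, c);
      }
    }
  }
  return dx;
}
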