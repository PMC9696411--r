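// Core convolution primitives for the CPU network engine.
//
// Layout conventions (fixed across the package):
//   feature maps  : arma::cube H x W x C   (R array dim c(H, W, C))
//   conv weights  : arma::mat (k*k*Cin) x Cout, rows ordered so that for a
//                   receptive-field offset (di, dj) and input channel c the
//                   row index is c*k*k + dj*k + di (di fastest)
// im2col is built pixel-major -- an (Ho*Wo) x (k*k*Cin) matrix whose column
// r holds, for every output pixel, the input sample at kernel offset r --
// so each column fills in long contiguous runs (output pixel index
// jo*Ho + io, io fastest, matching the column-major map layout).
// Zero padding, square kernels, uniform stride.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col_t(const cube& x, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  mat cols((size_t)Ho * Wo, (size_t)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* col = cols.colptr((size_t)c * k * k + (size_t)dj * k + di);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jsrc = jo * stride + dj - pad;
          if (jsrc < 0 || jsrc >= W) continue;
          const double* src = xc + (size_t)jsrc * H;
          double* dst = col + (size_t)jo * Ho;
          // valid io range: 0 <= io*stride + di - pad < H
          int io0 = 0;
          if (di - pad < 0) io0 = (pad - di + stride - 1) / stride;
          int io1 = (H - 1 - di + pad) / stride;  // inclusive
          if (io1 > Ho - 1) io1 = Ho - 1;
          if (stride == 1) {
            for (int io = io0; io <= io1; ++io)
              dst[io] = src[io + di - pad];
          } else {
            for (int io = io0; io <= io1; ++io)
              dst[io] = src[io * stride + di - pad];
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_t_acc(const mat& cols, cube& dx, int k, int stride, int pad) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < C; ++c) {
    double* xc = dx.slice_memptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* col = cols.colptr((size_t)c * k * k + (size_t)dj * k + di);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jsrc = jo * stride + dj - pad;
          if (jsrc < 0 || jsrc >= W) continue;
          double* dst = xc + (size_t)jsrc * H;
          const double* src = col + (size_t)jo * Ho;
          int io0 = 0;
          if (di - pad < 0) io0 = (pad - di + stride - 1) / stride;
          int io1 = (H - 1 - di + pad) / stride;
          if (io1 > Ho - 1) io1 = Ho - 1;
          if (stride == 1) {
            for (int io = io0; io <= io1; ++io)
              dst[io + di - pad] += src[io];
          } else {
            for (int io = io0; io <= io1; ++io)
              dst[io * stride + di - pad] += src[io];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv_fwd_cpp(const arma::cube& x, const arma::mat& W,
                        const arma::vec& b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = W.n_cols;
  mat cols = im2col_t(x, k, stride, pad);
  mat y = cols * W;                 // (Ho*Wo) x Cout
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(),
              sizeof(double) * (size_t)Ho * Wo * Cout);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv_bwd_cpp(const arma::cube& x, const arma::mat& W,
                        const arma::cube& dy, int k, int stride, int pad) {
  const int Cout = W.n_cols;
  const size_t N = (size_t)dy.n_rows * dy.n_cols;
  mat dy_mat(const_cast<double*>(dy.memptr()), N, Cout, false, true);
  mat cols = im2col_t(x, k, stride, pad);
  mat dW = cols.t() * dy_mat;
  vec db = sum(dy_mat, 0).t();
  mat dcols = dy_mat * W.t();       // N x (k*k*Cin)
  cube dx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_t_acc(dcols, dx, k, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Forward pass that additionally hands back the im2col matrix as an
// external pointer, so the backward pass can skip rebuilding it.
// [[Rcpp::export]]
Rcpp::List conv_fwd_keep_cpp(const arma::cube& x, const arma::mat& W,
                             const arma::vec& b, int k, int stride, int pad) {
  const int Ho = out_size(x.n_rows, k, stride, pad);
  const int Wo = out_size(x.n_cols, k, stride, pad);
  const int Cout = W.n_cols;
  mat tmp = im2col_t(x, k, stride, pad);
  Rcpp::XPtr<mat> cols(new mat(std::move(tmp)), true);
  mat y = (*cols) * W;
  y.each_row() += b.t();
  cube out(Ho, Wo, Cout);
  std::memcpy(out.memptr(), y.memptr(),
              sizeof(double) * (size_t)Ho * Wo * Cout);
  return Rcpp::List::create(Rcpp::Named("y") = out,
                            Rcpp::Named("cols") = cols);
}

// Backward pass reusing a cached im2col matrix; x is only needed for its
// dimensions.
// [[Rcpp::export]]
Rcpp::List conv_bwd_cached_cpp(SEXP colsPtr, int H, int W_in, int Cin,
                               const arma::mat& W, const arma::cube& dy,
                               int k, int stride, int pad) {
  Rcpp::XPtr<mat> cols(colsPtr);
  const int Cout = W.n_cols;
  const size_t N = (size_t)dy.n_rows * dy.n_cols;
  mat dy_mat(const_cast<double*>(dy.memptr()), N, Cout, false, true);
  mat dW = cols->t() * dy_mat;
  vec db = sum(dy_mat, 0).t();
  mat dcols = dy_mat * W.t();
  cube dx(H, W_in, Cin, fill::zeros);
  col2im_t_acc(dcols, dx, k, stride, pad);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
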