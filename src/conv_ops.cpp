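// Low-level convolution kernels for the segmentation network.
//
// Activation tensors are R numeric arrays with dim (H, W, C, N), column-major,
// so the linear index of (h, w, c, n) is h + H*(w + W*(c + C*n)).
//
// Convolution weights are matrices of dim (C_out) x (C_in * kh * kw) with
// column index c*(kh*kw) + i*kw + j for input channel c and kernel tap (i, j).
// Transpose-convolution weights are matrices of dim (C_out * kh * kw) x (C_in)
// with row index (c_out*kh + a)*kw + b; kernel 2, stride 2 (non-overlapping).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (Ci*kh*kw) x (Ho*Wo) for sample n.
static void im2col(const double* x, int H, int W, int Ci, int n,
                   int kh, int kw, int stride, int pad,
                   int Ho, int Wo, arma::mat& cols) {
  const double* xs = x + (std::size_t)n * H * W * Ci;
  for (int c = 0; c < Ci; ++c) {
    const double* xc = xs + (std::size_t)c * H * W;
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        int row = c * kh * kw + i * kw + j;
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * stride - pad + j;
          double* dst = cols.memptr() + (std::size_t)(wo * Ho) * cols.n_rows + row;
          if (w < 0 || w >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[(std::size_t)ho * cols.n_rows] = 0.0;
            continue;
          }
          const double* xcw = xc + (std::size_t)w * H;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * stride - pad + i;
            dst[(std::size_t)ho * cols.n_rows] =
              (h >= 0 && h < H) ? xcw[h] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the columns back to the input layout (adjoint of im2col).
static void col2im(const arma::mat& cols, double* dx, int H, int W, int Ci,
                   int n, int kh, int kw, int stride, int pad,
                   int Ho, int Wo) {
  double* xs = dx + (std::size_t)n * H * W * Ci;
  for (int c = 0; c < Ci; ++c) {
    double* xc = xs + (std::size_t)c * H * W;
    for (int i = 0; i < kh; ++i) {
      for (int j = 0; j < kw; ++j) {
        int row = c * kh * kw + i * kw + j;
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * stride - pad + j;
          if (w < 0 || w >= W) continue;
          double* xcw = xc + (std::size_t)w * H;
          const double* src = cols.memptr() + (std::size_t)(wo * Ho) * cols.n_rows + row;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * stride - pad + i;
            if (h >= 0 && h < H) xcw[h] += src[(std::size_t)ho * cols.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericMatrix wmat,
                             NumericVector bias, int kh, int kw,
                             int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  int Co = wmat.nrow();
  int Ho = out_extent(H, kh, stride, pad);
  int Wo = out_extent(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("convolution output would be empty");
  if (wmat.ncol() != Ci * kh * kw)
    stop("weight matrix does not match input channels/kernel");
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Co * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat Wm(wmat.begin(), Co, wmat.ncol(), false);
  arma::mat cols(Ci * kh * kw, Ho * Wo);
  bool has_b = bias.size() > 0;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Ci, n, kh, kw, stride, pad, Ho, Wo, cols);
    arma::mat out = (Wm * cols).t();  // (Ho*Wo) x Co, memory matches layout
    if (has_b) out.each_row() += arma::rowvec(bias.begin(), Co, false);
    std::copy(out.memptr(), out.memptr() + (std::size_t)Ho * Wo * Co,
              y.begin() + (std::size_t)n * Ho * Wo * Co);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericMatrix wmat, NumericVector dy,
                    int kh, int kw, int stride, int pad,
                    bool need_dx, bool has_bias) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  IntegerVector dd = dy.attr("dim");
  int Ho = dd[0], Wo = dd[1], Co = dd[2];
  arma::mat Wm(wmat.begin(), Co, wmat.ncol(), false);
  arma::mat dW(Co, Ci * kh * kw, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Ci * N));
    std::fill(dx.begin(), dx.end(), 0.0);
    dx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  }
  arma::mat cols(Ci * kh * kw, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, Ci, n, kh, kw, stride, pad, Ho, Wo, cols);
    // dy slice for sample n is (Ho*Wo) x Co in memory
    arma::mat Dt(dy.begin() + (std::size_t)n * Ho * Wo * Co, Ho * Wo, Co, false);
    arma::mat Dy = Dt.t();             // Co x (Ho*Wo)
    dW += Dy * cols.t();
    if (has_bias) db += arma::sum(Dy, 1);
    if (need_dx) {
      arma::mat dcols = Wm.t() * Dy;   // (Ci*kh*kw) x (Ho*Wo)
      col2im(dcols, dx.begin(), H, W, Ci, n, kh, kw, stride, pad, Ho, Wo);
    }
  }
  return List::create(_["dx"] = need_dx ? (SEXP)dx : R_NilValue,
                      _["dW"] = wrap(dW), _["db"] = wrap(db));
}

// Transpose convolution, kernel 2 stride 2: each input pixel expands to a
// 2x2 output patch; patches do not overlap.
// [[Rcpp::export]]
NumericVector convt2x2_fwd_cpp(NumericVector x, NumericMatrix wtmat,
                               NumericVector bias) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  int Co = wtmat.nrow() / 4;
  if (wtmat.ncol() != Ci) stop("transpose-conv weight does not match input channels");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * Co * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  arma::mat Wt(wtmat.begin(), Co * 4, Ci, false);
  bool has_b = bias.size() > 0;
  for (int n = 0; n < N; ++n) {
    // gather sample n as (Ci) x (H*W): spatial-major memory is (H*W) x Ci
    arma::mat Xs(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * Ci,
                 H * W, Ci, false);
    arma::mat U = Wt * Xs.t();         // (Co*4) x (H*W)
    double* ys = y.begin() + (std::size_t)n * Ho * Wo * Co;
    for (int co = 0; co < Co; ++co) {
      double* yc = ys + (std::size_t)co * Ho * Wo;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          std::size_t col = (std::size_t)w * H + h;
          double b = has_b ? bias[co] : 0.0;
          for (int a = 0; a < 2; ++a) {
            for (int bb = 0; bb < 2; ++bb) {
              int row = (co * 2 + a) * 2 + bb;
              yc[(std::size_t)(2 * w + bb) * Ho + (2 * h + a)] =
                U(row, col) + b;
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List convt2x2_bwd_cpp(NumericVector x, NumericMatrix wtmat, NumericVector dy,
                      bool has_bias) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], Ci = d[2], N = d[3];
  int Co = wtmat.nrow() / 4;
  int Ho = 2 * H, Wo = 2 * W;
  arma::mat Wt(wtmat.begin(), Co * 4, Ci, false);
  arma::mat dWt(Co * 4, Ci, arma::fill::zeros);
  arma::vec db(Co, arma::fill::zeros);
  NumericVector dx(Rf_allocVector(REALSXP, (R_xlen_t)H * W * Ci * N));
  dx.attr("dim") = IntegerVector::create(H, W, Ci, N);
  arma::mat dU(Co * 4, H * W);
  for (int n = 0; n < N; ++n) {
    const double* dys = dy.begin() + (std::size_t)n * Ho * Wo * Co;
    for (int co = 0; co < Co; ++co) {
      const double* dyc = dys + (std::size_t)co * Ho * Wo;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          std::size_t col = (std::size_t)w * H + h;
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              dU((co * 2 + a) * 2 + bb, col) =
                dyc[(std::size_t)(2 * w + bb) * Ho + (2 * h + a)];
          if (has_bias)
            db[co] += dU((co * 2) * 2, col) + dU((co * 2) * 2 + 1, col) +
                      dU((co * 2 + 1) * 2, col) + dU((co * 2 + 1) * 2 + 1, col);
        }
      }
    }
    arma::mat Xs(const_cast<double*>(x.begin()) + (std::size_t)n * H * W * Ci,
                 H * W, Ci, false);
    dWt += dU * Xs;                    // (Co*4) x Ci
    arma::mat dXs = (Wt.t() * dU).t(); // (H*W) x Ci, matches layout
    std::copy(dXs.memptr(), dXs.memptr() + (std::size_t)H * W * Ci,
              dx.begin() + (std::size_t)n * H * W * Ci);
  }
  return List::create(_["dx"] = dx, _["dW"] = wrap(dWt), _["db"] = wrap(db));
}

// Max pooling with argmax cache (indices are 1-based linear indices into x).
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  int Ho = out_extent(H, k, stride, pad);
  int Wo = out_extent(W, k, stride, pad);
  NumericVector y(Rf_allocVector(REALSXP, (R_xlen_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(Rf_allocVector(INTSXP, (R_xlen_t)Ho * Wo * C * N));
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      std::size_t base = ((std::size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -INFINITY;
          std::size_t besti = 0;
          for (int j = 0; j < k; ++j) {
            int w = wo * stride - pad + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < k; ++i) {
              int h = ho * stride - pad + i;
              if (h < 0 || h >= H) continue;
              std::size_t idx = base + (std::size_t)w * H + h;
              if (xp[idx] > best) { best = xp[idx]; besti = idx; }
            }
          }
          // column-major (Ho,Wo,C,N): ho fastest — iterate ho inner, wo outer
          R_xlen_t oidx = ((R_xlen_t)n * C + c) * Ho * Wo + (R_xlen_t)wo * Ho + ho;
          y[oidx] = best;
          arg[oidx] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector argmax,
                              IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(Rf_allocVector(REALSXP, nx));
  std::fill(dx.begin(), dx.end(), 0.0);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}
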