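// im2col-based 2-D convolution and transposed convolution, forward and
// backward, for the desk-scale convolutional autoencoder.  Tensors cross the
// R boundary as column-major numeric arrays with dim (H, W, C, N); kernels as
// (k, k, Cin, Cout) for conv and (k, k, Cout, Cin) for transposed conv.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::List;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Gather: x (H x W x C slice view) -> cols (k*k*C x Hout*Wout).
static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Hout, int Wout, mat& cols) {
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int r = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          const double* xcol = xc + (size_t)wi * H;
          double* crow = cols.memptr() + (size_t)r + (size_t)(Hout) * (size_t)wo * cols.n_rows;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            crow[(size_t)ho * cols.n_rows] = xcol[hi];
          }
        }
      }
  }
}

// Scatter-add: cols (k*k*C x Hout*Wout) -> x (H x W x C), accumulating.
static void col2im_add(double* x, int H, int W, int C,
                       int k, int stride, int pad, int Hout, int Wout,
                       const mat& cols) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        int r = ki + k * kj + k * k * c;
        for (int wo = 0; wo < Wout; ++wo) {
          int wi = wo * stride - pad + kj;
          if (wi < 0 || wi >= W) continue;
          double* xcol = xc + (size_t)wi * H;
          const double* crow = cols.memptr() + (size_t)r + (size_t)(Hout) * (size_t)wo * cols.n_rows;
          for (int ho = 0; ho < Hout; ++ho) {
            int hi = ho * stride - pad + ki;
            if (hi < 0 || hi >= H) continue;
            xcol[hi] += crow[(size_t)ho * cols.n_rows];
          }
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Hout = out_size(H, k, stride, pad), Wout = out_size(W, k, stride, pad);
  mat Wm(w.begin(), k * k * Cin, Cout, false, true);
  rowvec bv(b.begin(), Cout);
  NumericVector y = alloc4(Hout, Wout, Cout, N);
  mat cols(k * k * Cin, Hout * Wout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, stride, pad, Hout, Wout, cols);
    mat ym = cols.t() * Wm;           // (Hout*Wout) x Cout
    ym.each_row() += bv;
    std::copy(ym.begin(), ym.end(), y.begin() + (size_t)n * Hout * Wout * Cout);
  }
  return y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Hout = gd[0], Wout = gd[1];
  mat Wm(w.begin(), k * k * Cin, Cout, false, true);
  NumericVector gx = alloc4(H, W, Cin, N);
  NumericVector gw = alloc4(k, k, Cin, Cout);
  NumericVector gb(Cout);
  mat gWm(gw.begin(), k * k * Cin, Cout, false, true);
  vec gbv(gb.begin(), Cout, false, true);
  mat cols(k * k * Cin, Hout * Wout);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, stride, pad, Hout, Wout, cols);
    mat gym((double*)gy.begin() + (size_t)n * Hout * Wout * Cout,
            Hout * Wout, Cout, false, true);
    gWm += cols * gym;
    gbv += sum(gym, 0).t();
    mat gcols = Wm * gym.t();         // (k*k*Cin) x (Hout*Wout)
    col2im_add(gx.begin() + (size_t)n * H * W * Cin, H, W, Cin,
               k, stride, pad, Hout, Wout, gcols);
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// Transposed conv: input (H, W, Cin, N), weights (k, k, Cout, Cin),
// output (Hout, Wout, Cout, N) with Hout = (H - 1) * stride - 2 * pad + k.
// [[Rcpp::export]]
NumericVector convt_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[2];
  int Hout = (H - 1) * stride - 2 * pad + k;
  int Wout = (W - 1) * stride - 2 * pad + k;
  mat Wm(w.begin(), k * k * Cout, Cin, false, true);
  NumericVector y = alloc4(Hout, Wout, Cout, N);
  for (int n = 0; n < N; ++n) {
    mat xm((double*)x.begin() + (size_t)n * H * W * Cin, H * W, Cin, false, true);
    mat cols = Wm * xm.t();           // (k*k*Cout) x (H*W)
    col2im_add(y.begin() + (size_t)n * Hout * Wout * Cout, Hout, Wout, Cout,
               k, stride, pad, H, W, cols);
  }
  // bias
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < Cout; ++c) {
      double* yp = y.begin() + ((size_t)n * Cout + c) * Hout * Wout;
      for (int i = 0; i < Hout * Wout; ++i) yp[i] += b[c];
    }
  return y;
}

// [[Rcpp::export]]
List convt_bwd_cpp(NumericVector x, NumericVector w, NumericVector gy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), gd = gy.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[2];
  int Hout = gd[0], Wout = gd[1];
  mat Wm(w.begin(), k * k * Cout, Cin, false, true);
  NumericVector gx = alloc4(H, W, Cin, N);
  NumericVector gw = alloc4(k, k, Cout, Cin);
  NumericVector gb(Cout);
  mat gWm(gw.begin(), k * k * Cout, Cin, false, true);
  mat gcols(k * k * Cout, H * W);
  for (int n = 0; n < N; ++n) {
    im2col(gy.begin() + (size_t)n * Hout * Wout * Cout, Hout, Wout, Cout,
           k, stride, pad, H, W, gcols);
    mat xm((double*)x.begin() + (size_t)n * H * W * Cin, H * W, Cin, false, true);
    mat gxm = gcols.t() * Wm;         // (H*W) x Cin
    std::copy(gxm.begin(), gxm.end(), gx.begin() + (size_t)n * H * W * Cin);
    gWm += gcols * xm;
    for (int c = 0; c < Cout; ++c) {
      const double* gp = gy.begin() + ((size_t)n * Cout + c) * Hout * Wout;
      double s = 0;
      for (int i = 0; i < Hout * Wout; ++i) s += gp[i];
      gb[c] += s;
    }
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}
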