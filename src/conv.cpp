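// Hot kernels of the conv-net layer stack: im2col 3x3 convolution forward
// and backward. Everything else (pooling, upsampling, warping) stays in
// vectorized R; only these two dominate training time.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: H x W x Cin cube; W: (9*Cin) x Cout; b: Cout.
// Column layout of X2: offset-major blocks of Cin channels, offsets in
// column-major order over the 3x3 window (ki fastest), matching the R
// reference implementation.
// [[Rcpp::export(name = ".conv3ForwardC")]]
List conv3ForwardC(const arma::cube& x, const arma::mat& W,
                   const arma::vec& b) {
  const arma::uword H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const arma::uword N = H * Wd;
  arma::mat X2(N, 9 * Cin);
  arma::uword k = 0;
  for (int kj = 0; kj < 3; ++kj) {
    for (int ki = 0; ki < 3; ++ki) {
      for (arma::uword c = 0; c < Cin; ++c) {
        double* dst = X2.colptr(k * Cin + c);
        const arma::mat& plane = x.slice(c);
        for (arma::uword j = 0; j < Wd; ++j) {
          const int sj = (int)j + kj - 1;
          double* dcol = dst + j * H;
          if (sj < 0 || sj >= (int)Wd) {
            std::fill(dcol, dcol + H, 0.0);
            continue;
          }
          const double* src = plane.colptr(sj);
          const int di = ki - 1;
          for (arma::uword i = 0; i < H; ++i) {
            const int si = (int)i + di;
            dcol[i] = (si < 0 || si >= (int)H) ? 0.0 : src[si];
          }
        }
      }
      ++k;
    }
  }
  arma::mat Y = X2 * W;
  Y.each_row() += b.t();
  arma::cube y(Y.memptr(), H, Wd, W.n_cols);
  return List::create(_["y"] = y, _["X2"] = X2);
}

// [[Rcpp::export(name = ".conv3BackwardC")]]
List conv3BackwardC(const arma::mat& dY, const arma::mat& X2,
                    const arma::mat& W, int H, int Wd, int Cin) {
  arma::mat dW = X2.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dX2 = dY * W.t();
  arma::cube dx(H, Wd, Cin, arma::fill::zeros);
  arma::uword k = 0;
  for (int kj = 0; kj < 3; ++kj) {
    for (int ki = 0; ki < 3; ++ki) {
      for (int c = 0; c < Cin; ++c) {
        const double* src = dX2.colptr(k * Cin + c);
        arma::mat& plane = dx.slice(c);
        for (int j = 0; j < Wd; ++j) {
          const int sj = j + kj - 1;
          if (sj < 0 || sj >= Wd) continue;
          double* dcol = plane.colptr(sj);
          const double* scol = src + (arma::uword)j * H;
          const int di = ki - 1;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i) dcol[i + di] += scol[i];
        }
      }
      ++k;
    }
  }
  return List::create(_["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()),
                      _["dx"] = dx);
}
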