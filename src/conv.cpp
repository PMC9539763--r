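// 2D convolution primitives for the translation networks.
// Layout conventions (column-major, matching R):
//   activations: arma::cube H x W x C
//   conv weights: matrix (k*k*Cin) x Cout, rows ordered kernel-row fastest,
//     then kernel-col, then input channel (i.e. flatten of a (k,k,Cin) block)
//   transposed-conv weights: matrix (k*k*Cout) x Cin (the mirror conv's
//     weights; convT forward == gradient of that conv w.r.t. its input)
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(k * k * C, (size_t)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < k; ++b) {       // kernel col
      for (int a = 0; a < k; ++a) {     // kernel row
        const int row = a + k * b + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride - pad + b;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wi = i * stride - pad + a;
            if (wi < 0 || wi >= H) continue;
            cols(row, (size_t)i + (size_t)Ho * j) = x(wi, wj, c);
          }
        }
      }
    }
  }
  return cols;
}

static arma::cube col2im(const arma::mat& cols, int H, int W, int C, int k,
                         int stride, int pad, int Ho, int Wo) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int row = a + k * b + k * k * c;
        for (int j = 0; j < Wo; ++j) {
          const int wj = j * stride - pad + b;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Ho; ++i) {
            const int wi = i * stride - pad + a;
            if (wi < 0 || wi >= H) continue;
            x(wi, wj, c) += cols(row, (size_t)i + (size_t)Ho * j);
          }
        }
      }
    }
  }
  return x;
}

static inline int convOut(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, int k, int stride, int pad) {
  const int Ho = convOut(x.n_rows, k, stride, pad);
  const int Wo = convOut(x.n_cols, k, stride, pad);
  const int Cout = w.n_cols;
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat y = w.t() * cols;          // Cout x (Ho*Wo)
  y.each_col() += b;
  arma::cube out(Ho, Wo, Cout);
  for (int o = 0; o < Cout; ++o)
    out.slice(o) = arma::reshape(y.row(o), Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& w,
                  const arma::cube& gy, int k, int stride, int pad) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Cout = gy.n_slices;
  arma::mat gymat(Cout, (size_t)Ho * Wo);
  for (int o = 0; o < Cout; ++o)
    gymat.row(o) = arma::vectorise(gy.slice(o)).t();
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat gw = cols * gymat.t();               // (kkCin) x Cout
  arma::vec gb = arma::sum(gymat, 1);
  arma::mat gcols = w * gymat;                   // (kkCin) x (Ho*Wo)
  arma::cube gx = col2im(gcols, x.n_rows, x.n_cols, x.n_slices, k, stride,
                         pad, Ho, Wo);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed conv: x has Cin slices, w is (k*k*Cout) x Cin, output Ho x Wo x
// Cout with Ho = (H-1)*stride - 2*pad + k.
// [[Rcpp::export]]
arma::cube cpp_convt_fwd(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (W - 1) * stride - 2 * pad + k;
  const int Cout = w.n_rows / (k * k);
  arma::mat xmat(Cin, (size_t)H * W);
  for (int c = 0; c < Cin; ++c)
    xmat.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat cols = w * xmat;                     // (kkCout) x (H*W)
  arma::cube out = col2im(cols, Ho, Wo, Cout, k, stride, pad, H, W);
  for (int o = 0; o < Cout; ++o) out.slice(o) += b(o);
  return out;
}

// [[Rcpp::export]]
List cpp_convt_bwd(const arma::cube& x, const arma::mat& w,
                   const arma::cube& gy, int k, int stride, int pad) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gy.n_slices;
  arma::mat xmat(Cin, (size_t)H * W);
  for (int c = 0; c < Cin; ++c)
    xmat.row(c) = arma::vectorise(x.slice(c)).t();
  arma::mat gycols = im2col(gy, k, stride, pad, H, W); // (kkCout) x (H*W)
  arma::mat gxmat = w.t() * gycols;                    // Cin x (H*W)
  arma::cube gx(H, W, Cin);
  for (int c = 0; c < Cin; ++c)
    gx.slice(c) = arma::reshape(gxmat.row(c), H, W);
  arma::mat gw = gycols * xmat.t();                    // (kkCout) x Cin
  arma::vec gb(Cout);
  for (int o = 0; o < Cout; ++o) gb(o) = arma::accu(gy.slice(o));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
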