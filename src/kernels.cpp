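// Low-level numeric kernels: stride-1 "same" 2-D convolution (forward and
// backward, via im2col + GEMM) and 8-connectivity component labeling.
// Tensors are R arrays (H, W, C), column-major, matching arma::cube layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// cols: (H*W) x (k*k*Cin); column index dh + k*dw + k*k*c; row index h + H*w.
static arma::mat im2col(const arma::cube& x, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * W, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = dh + k * dw + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - dh);
          const int h1 = std::min(H, H + pad - dh);
          for (int h = h0; h < h1; ++h) {
            cols(h + H * w, col) = x(h + dh - pad, iw, c);
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add transpose of im2col.
static arma::cube col2im(const arma::mat& cols, const int H, const int W,
                         const int C, const int k, const int pad) {
  arma::cube x(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = dh + k * dw + k * k * c;
        for (int w = 0; w < W; ++w) {
          const int iw = w + dw - pad;
          if (iw < 0 || iw >= W) continue;
          const int h0 = std::max(0, pad - dh);
          const int h1 = std::min(H, H + pad - dh);
          for (int h = h0; h < h1; ++h) {
            x(h + dh - pad, iw, c) += cols(h + H * w, col);
          }
        }
      }
    }
  }
  return x;
}

// x: (H, W, Cin); w: (k*k*Cin) x Cout; b: length Cout. Returns (H, W, Cout)
// plus, when keep_cols, the im2col matrix for reuse in the backward pass.
// [[Rcpp::export(name = ".conv2d_fwd")]]
List conv2d_fwd(const arma::cube& x, const arma::mat& w,
                const arma::vec& b, const int k, const int pad,
                const bool keep_cols = false) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat cols = im2col(x, k, pad);
  arma::mat y = cols * w;                   // (H*W) x Cout
  y.each_row() += b.t();
  arma::cube yc(y.memptr(), H, W, Cout);
  if (keep_cols) return List::create(_["y"] = yc, _["cols"] = cols);
  return List::create(_["y"] = yc);
}

// Gradients for conv2d_fwd given the cached im2col matrix.
// dy: (H, W, Cout). Returns dx, gw, gb.
// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::mat& cols, const arma::mat& w, const arma::cube& dy,
                const int Cin, const int k, const int pad) {
  const int H = dy.n_rows, W = dy.n_cols;
  const int Cout = dy.n_slices;
  const arma::mat dym(const_cast<double*>(dy.memptr()), H * W, Cout, false);
  arma::mat gw = cols.t() * dym;
  arma::vec gb = arma::sum(dym, 0).t();
  arma::mat dcols = dym * w.t();
  arma::cube dx = col2im(dcols, H, W, Cin, k, pad);
  return List::create(_["dx"] = dx, _["gw"] = gw, _["gb"] = gb);
}

// Standalone im2col for a backward pass without a cached forward matrix.
// [[Rcpp::export(name = ".im2col")]]
arma::mat im2col_export(const arma::cube& x, const int k, const int pad) {
  return im2col(x, k, pad);
}

// Label 8-connected foreground components, scan order, labels from 1.
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(const LogicalMatrix& fg) {
  const int H = fg.nrow(), W = fg.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int cur = 0;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (!fg(h, w) || lab(h, w)) continue;
      ++cur;
      lab(h, w) = cur;
      stack.push_back(h + H * w);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int ph = p % H, pw = p / H;
        for (int dw = -1; dw <= 1; ++dw) {
          for (int dh = -1; dh <= 1; ++dh) {
            const int nh = ph + dh, nw = pw + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (fg(nh, nw) && !lab(nh, nw)) {
              lab(nh, nw) = cur;
              stack.push_back(nh + H * nw);
            }
          }
        }
      }
    }
  }
  return lab;
}
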