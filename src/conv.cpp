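// Minibatch 2D convolution / max-pooling kernels for the CNN classifiers.
// Layout: inputs are (H*W*C, B) matrices, each column one sample stored as an
// H x W x C array in column-major order. Convolutions are 3x3 (kh x kw),
// stride 1, zero "same" padding; implemented as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, mat& cols, uword rowOffset) {
  // cols rows: spatial positions (H*W), columns: kh*kw*C patch entries
  int pr = kh / 2, pc = kw / 2;
  uword col = 0;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - pc;
          double* dst = cols.colptr(col) + rowOffset + (uword)j * H;
          if (sj < 0 || sj >= W) {
            std::memset(dst, 0, sizeof(double) * H);
          } else {
            const double* src = x + ((uword)c * W + sj) * H;
            for (int i = 0; i < H; ++i) {
              int si = i + di - pr;
              dst[i] = (si < 0 || si >= H) ? 0.0 : src[si];
            }
          }
        }
        ++col;
      }
    }
  }
}

// [[Rcpp::export(name = ".convForward")]]
arma::mat convForward(const arma::mat& input, const arma::mat& weights,
                      const arma::vec& bias, int H, int W, int C,
                      int kh, int kw) {
  int B = input.n_cols;
  int F = weights.n_cols;           // weights: (kh*kw*C) x F
  uword HW = (uword)H * W;
  mat cols((uword)B * HW, (uword)kh * kw * C);
  for (int b = 0; b < B; ++b)
    im2col_one(input.colptr(b), H, W, C, kh, kw, cols, (uword)b * HW);
  mat out = cols * weights;          // (B*HW) x F
  out.each_row() += bias.t();
  // reshape to (H*W*F) x B
  mat res(HW * F, B);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      res.submat((uword)f * HW, b, (uword)(f + 1) * HW - 1, b) =
        out.submat((uword)b * HW, f, (uword)(b + 1) * HW - 1, f);
  return res;
}

// [[Rcpp::export(name = ".convBackward")]]
Rcpp::List convBackward(const arma::mat& input, const arma::mat& weights,
                        const arma::mat& gradOut, int H, int W, int C,
                        int kh, int kw) {
  int B = input.n_cols;
  int F = weights.n_cols;
  uword HW = (uword)H * W;
  int pr = kh / 2, pc = kw / 2;

  mat cols((uword)B * HW, (uword)kh * kw * C);
  for (int b = 0; b < B; ++b)
    im2col_one(input.colptr(b), H, W, C, kh, kw, cols, (uword)b * HW);

  // gradOut: (H*W*F) x B -> (B*HW) x F
  mat gOut((uword)B * HW, F);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      gOut.submat((uword)b * HW, f, (uword)(b + 1) * HW - 1, f) =
        gradOut.submat((uword)f * HW, b, (uword)(f + 1) * HW - 1, b);

  mat gW = cols.t() * gOut;                       // (kh*kw*C) x F
  vec gB = sum(gOut, 0).t();
  mat gCols = gOut * weights.t();                 // (B*HW) x (kh*kw*C)

  // col2im: scatter-add patch gradients back onto the input
  mat gIn(HW * C, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* gx = gIn.colptr(b);
    uword col = 0;
    for (int c = 0; c < C; ++c) {
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di) {
          const double* src = gCols.colptr(col) + (uword)b * HW;
          for (int j = 0; j < W; ++j) {
            int sj = j + dj - pc;
            if (sj < 0 || sj >= W) continue;
            double* dst = gx + ((uword)c * W + sj) * H;
            for (int i = 0; i < H; ++i) {
              int si = i + di - pr;
              if (si >= 0 && si < H) dst[si] += src[(uword)j * H + i];
            }
          }
          ++col;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gradInput") = gIn,
                            Rcpp::Named("gradWeights") = gW,
                            Rcpp::Named("gradBias") = gB);
}

// [[Rcpp::export(name = ".maxPoolForward")]]
Rcpp::List maxPoolForward(const arma::mat& input, int H, int W, int C,
                          int ph, int pw) {
  int B = input.n_cols;
  int Ho = H / ph, Wo = W / pw;
  uword HWo = (uword)Ho * Wo;
  mat out(HWo * C, B);
  umat amax(HWo * C, B);
  for (int b = 0; b < B; ++b) {
    const double* x = input.colptr(b);
    double* o = out.colptr(b);
    uword* a = amax.colptr(b);
    for (int c = 0; c < C; ++c) {
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          double best = -datum::inf;
          uword besti = 0;
          for (int dj = 0; dj < pw; ++dj) {
            for (int di = 0; di < ph; ++di) {
              uword idx = ((uword)c * W + (uword)jo * pw + dj) * H +
                          (uword)io * ph + di;
              if (x[idx] > best) { best = x[idx]; besti = idx; }
            }
          }
          uword oidx = ((uword)c * Wo + jo) * Ho + io;
          o[oidx] = best;
          a[oidx] = besti;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("output") = out,
                            Rcpp::Named("argmax") = amax);
}

// [[Rcpp::export(name = ".maxPoolBackward")]]
arma::mat maxPoolBackward(const arma::mat& gradOut, const arma::umat& amax,
                          int H, int W, int C) {
  int B = gradOut.n_cols;
  mat gIn((uword)H * W * C, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* g = gIn.colptr(b);
    const double* go = gradOut.colptr(b);
    const uword* a = amax.colptr(b);
    for (uword i = 0; i < gradOut.n_rows; ++i) g[a[i]] += go[i];
  }
  return gIn;
}
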