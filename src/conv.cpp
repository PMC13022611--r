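// Low-level kernels for the patch CNN: 3x3 same-padding convolution and
// 2x2/stride-2 max pooling, forward and backward. Arrays are column-major
// [H, W, C, B] as produced by R's array(); im2col + GEMM does the heavy
// lifting so single-threaded BLAS sets the speed.
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fill K (9*C x H*W) with the 3x3 neighbourhood of every pixel of one image,
// zero outside the border (same padding).
static void im2col3(const double* x, int H, int W, int C, arma::mat& K) {
  K.zeros();
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + HW * c;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int r = (di + 1) + 3 * (dj + 1) + 9 * c;
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = xc + (size_t)H * (j + dj);
          for (int i = i0; i < i1; ++i)
            K(r, i + (size_t)H * j) = src[i + di];
        }
      }
    }
  }
}

static arma::mat weight_mat(const NumericVector& w, int C, int F) {
  // w layout [3,3,C,F] -> F x 9C with row index f, col (di + 3*dj + 9*c)
  arma::mat Wm(F, 9 * C);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          Wm(f, di + 3 * dj + 9 * c) = w[di + 3 * (dj + 3 * (c + (size_t)C * f))];
  return Wm;
}

// [[Rcpp::export]]
NumericVector conv3x3_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int H, int W, int C, int B, int F) {
  arma::mat Wm = weight_mat(w, C, F);
  arma::vec bv(b.begin(), F);
  const size_t HW = (size_t)H * W;
  NumericVector y(HW * F * B);
  arma::mat K(9 * C, HW);
  for (int im = 0; im < B; ++im) {
    im2col3(x.begin() + HW * C * im, H, W, C, K);
    arma::mat Y = Wm * K; // F x HW
    Y.each_col() += bv;
    double* yo = y.begin() + HW * F * im;
    for (int f = 0; f < F; ++f) {
      const double* row = Y.memptr(); // column-major F x HW
      for (size_t p = 0; p < HW; ++p) yo[p + HW * f] = row[f + (size_t)F * p];
    }
  }
  y.attr("dim") = IntegerVector::create(H, W, F, B);
  return y;
}

// [[Rcpp::export]]
List conv3x3_bwd(NumericVector x, NumericVector w, NumericVector dy,
                 int H, int W, int C, int B, int F) {
  arma::mat Wm = weight_mat(w, C, F);
  arma::mat dWm(F, 9 * C, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  const size_t HW = (size_t)H * W;
  NumericVector dx(HW * C * B);
  arma::mat K(9 * C, HW), dY(F, HW);
  for (int im = 0; im < B; ++im) {
    im2col3(x.begin() + HW * C * im, H, W, C, K);
    const double* dyo = dy.begin() + HW * F * im;
    for (int f = 0; f < F; ++f)
      for (size_t p = 0; p < HW; ++p) dY(f, p) = dyo[p + HW * f];
    dWm += dY * K.t();
    db += arma::sum(dY, 1);
    arma::mat dK = Wm.t() * dY; // 9C x HW
    double* dxo = dx.begin() + HW * C * im;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxo + HW * c;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          const int r = (di + 1) + 3 * (dj + 1) + 9 * c;
          const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int j = j0; j < j1; ++j)
            for (int i = i0; i < i1; ++i)
              dxc[(i + di) + (size_t)H * (j + dj)] += dK(r, i + (size_t)H * j);
        }
      }
    }
  }
  NumericVector dwv(9 * (size_t)C * F);
  for (int f = 0; f < F; ++f)
    for (int c = 0; c < C; ++c)
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          dwv[di + 3 * (dj + 3 * (c + (size_t)C * f))] = dWm(f, di + 3 * dj + 9 * c);
  dwv.attr("dim") = IntegerVector::create(3, 3, C, F);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x, int H, int W, int C, int B) {
  const int Ho = H / 2, Wo = W / 2;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector y(HWo * C * B);
  IntegerVector idx(HWo * C * B); // 0-based flat index into x
  for (int im = 0; im < B; ++im) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + HW * (c + (size_t)C * im);
      double* yc = y.begin() + HWo * (c + (size_t)C * im);
      int* ic = idx.begin() + HWo * (c + (size_t)C * im);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          size_t p00 = (size_t)(2 * i) + (size_t)H * (2 * j);
          size_t best = p00;
          double v = xc[p00];
          const size_t cand[3] = {p00 + 1, p00 + (size_t)H, p00 + (size_t)H + 1};
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > v) { v = xc[cand[t]]; best = cand[t]; }
          yc[i + (size_t)Ho * j] = v;
          ic[i + (size_t)Ho * j] = (int)(best + HW * (c + (size_t)C * im));
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, int n_in) {
  NumericVector dx(n_in);
  const R_xlen_t n = dy.size();
  for (R_xlen_t t = 0; t < n; ++t) dx[idx[t]] += dy[t];
  return dx;
}
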