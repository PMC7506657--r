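// Convolution and pooling kernels for the compact CNN classifier.
// Layout: activation batches are R arrays dim(H, W, C, N) (column-major);
// 3x3 conv weights are dim(3, 3, Cin, Cout), stride 1, zero padding 1.
// im2col row ordering is ki + 3*kj + 9*c, matching the column-major
// flattening of the weight array, so the weight matrix is a plain view.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, arma::mat& col) {
  const int P = H * W;
  col.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int r = ki + 3 * kj + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - 1;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - 1;
            if (ii < 0 || ii >= H) continue;
            col(r, i + H * j) = xc[ii + H * jj];
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& colT, double* dx, int H, int W,
                       int C) {
  // colT is P x K (transposed column matrix of gradients)
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (std::size_t)H * W * c;
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const int r = ki + 3 * kj + 9 * c;
        for (int j = 0; j < W; ++j) {
          const int jj = j + kj - 1;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + ki - 1;
            if (ii < 0 || ii >= H) continue;
            dxc[ii + H * jj] += colT(i + H * j, r);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv_forward(NumericVector x, NumericVector w,
                           NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  const int K = 9 * Cin, P = H * W;
  NumericVector y((R_xlen_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat col(K, P);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)P * C * n, H, W, C, col);
    arma::mat yt = col.t() * Wm;  // P x Cout
    for (int o = 0; o < Cout; ++o) yt.col(o) += b[o];
    std::copy(yt.begin(), yt.end(),
              y.begin() + (std::size_t)P * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List conv_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int K = 9 * C, P = H * W;
  NumericVector dx(x.size()), dw(w.size()), db(Cout);
  dx.attr("dim") = xd;
  dw.attr("dim") = wd;
  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat dWm(dw.begin(), K, Cout, false, true);
  arma::mat col(K, P);
  arma::vec dbv(db.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (std::size_t)P * C * n;
    arma::mat dyt(const_cast<double*>(dy.begin()) +
                      (std::size_t)P * Cout * n,
                  P, Cout, false, true);
    im2col(xn, H, W, C, col);
    dWm += col * dyt;                       // K x Cout
    dbv += arma::sum(dyt, 0).t();
    arma::mat dcolT = dyt * Wm.t();         // P x K
    col2im_acc(dcolT, dx.begin() + (std::size_t)P * C * n, H, W, C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("pooling input side must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(y.size());
  arg.attr("dim") = y.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t xoff = (std::size_t)H * W * (c + (std::size_t)C * n);
      const std::size_t yoff =
          (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -1e300;
          int besti = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              const int idx = (2 * i + di) + H * (2 * j + dj);
              const double v = xp[xoff + idx];
              if (v > best) { best = v; besti = idx; }
            }
          }
          yp[yoff + i + Ho * j] = best;
          ap[yoff + i + Ho * j] = (int)xoff + besti;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_backward(IntegerVector argmax, NumericVector dy,
                               IntegerVector xdim) {
  std::size_t total = 1;
  for (int k = 0; k < xdim.size(); ++k) total *= (std::size_t)xdim[k];
  NumericVector dx(total);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k) dxp[argmax[k]] += dy[k];
  return dx;
}
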