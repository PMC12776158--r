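// Low-level neural-network tensor operations.
//
// Feature maps are H x W x C arma::cube objects (R: 3-D arrays, dims
// c(H, W, C)). Convolutions are stride-1, zero-padded, same-size, odd
// square kernels. Weights for a k x k conv from Cin to Cout channels are
// stored as a (k*k*Cin) x Cout matrix whose row index runs fastest over
// the kernel row offset, then kernel column offset, then input channel
// (i.e. r = ci*k*k + dj*k + di, column-major within the kernel window,
// matching im2col below). Biases are length-Cout vectors.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static mat im2col(const cube& input, const int k) {
  const int H = input.n_rows, W = input.n_cols, C = input.n_slices;
  const int r = (k - 1) / 2;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& sl = input.slice(c);
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int row = c * k * k + (dj + r) * k + (di + r);
        // source pixel (i+di, j+dj) feeds output pixel (i, j)
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          const double* src = sl.colptr(j + dj) + (i0 + di);
          double* dst = cols.colptr(j * H + i0) + row;
          for (int i = i0; i < i1; ++i) {
            *dst = *src;
            ++src;
            dst += k * k * C;
          }
        }
      }
    }
  }
  return cols;
}

// scatter-add of a (k*k*C) x (H*W) column matrix back onto an H x W x C cube
static cube col2im(const mat& cols, const int H, const int W, const int C,
                   const int k) {
  const int r = (k - 1) / 2;
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& sl = out.slice(c);
    for (int dj = -r; dj <= r; ++dj) {
      for (int di = -r; di <= r; ++di) {
        const int row = c * k * k + (dj + r) * k + (di + r);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        for (int j = j0; j < j1; ++j) {
          double* dst = sl.colptr(j + dj) + (i0 + di);
          const double* src = cols.colptr(j * H + i0) + row;
          for (int i = i0; i < i1; ++i) {
            *dst += *src;
            ++dst;
            src += k * k * C;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& input, const arma::mat& weights,
                      const arma::vec& bias, const int k) {
  const int H = input.n_rows, W = input.n_cols;
  const int Cout = weights.n_cols;
  mat cols = im2col(input, k);             // (k*k*Cin) x (H*W)
  mat out = weights.t() * cols;            // Cout x (H*W)
  out.each_col() += bias;
  cube res(H, W, Cout);
  for (int c = 0; c < Cout; ++c) {
    res.slice(c) = reshape(out.row(c), H, W);
  }
  return res;
}

// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& input, const arma::mat& weights,
                      const arma::cube& grad_out, const int k,
                      const bool want_dx) {
  const int H = input.n_rows, W = input.n_cols, Cin = input.n_slices;
  const int Cout = grad_out.n_slices;
  mat g(Cout, H * W);
  for (int c = 0; c < Cout; ++c) {
    g.row(c) = vectorise(grad_out.slice(c)).t();
  }
  mat cols = im2col(input, k);
  mat dW = cols * g.t();                   // (k*k*Cin) x Cout
  vec db = sum(g, 1);
  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
  if (want_dx) {
    mat dcols = weights * g;               // (k*k*Cin) x (H*W)
    res["dX"] = col2im(dcols, H, W, Cin, k);
  }
  return res;
}

// 2x2 max-pool, stride 2; H and W must be even.
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& input) {
  const int H = input.n_rows, W = input.n_cols, C = input.n_slices;
  const int h = H / 2, w = W / 2;
  cube out(h, w, C);
  ucube argmax(h, w, C);                   // linear index into the slice
  for (int c = 0; c < C; ++c) {
    const mat& sl = input.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        double best = sl(2 * i, 2 * j);
        uword bi = 2 * i, bj = 2 * j;
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double v = sl(2 * i + di, 2 * j + dj);
            if (v > best) {
              best = v;
              bi = 2 * i + di;
              bj = 2 * j + dj;
            }
          }
        }
        out(i, j, c) = best;
        argmax(i, j, c) = bj * H + bi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("argmax") = argmax);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const arma::cube& grad_out, const arma::ucube& argmax,
                        const int H, const int W) {
  const int h = grad_out.n_rows, w = grad_out.n_cols, C = grad_out.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& sl = dx.slice(c);
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        sl(argmax(i, j, c)) += grad_out(i, j, c);
      }
    }
  }
  return dx;
}

// 2x nearest-neighbour up-sample.
// [[Rcpp::export]]
arma::cube upsample2_fwd(const arma::cube& input) {
  const int H = input.n_rows, W = input.n_cols, C = input.n_slices;
  cube out(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = input(i, j, c);
        out(2 * i, 2 * j, c) = v;
        out(2 * i + 1, 2 * j, c) = v;
        out(2 * i, 2 * j + 1, c) = v;
        out(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube upsample2_bwd(const arma::cube& grad_out) {
  const int H = grad_out.n_rows / 2, W = grad_out.n_cols / 2,
            C = grad_out.n_slices;
  cube dx(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        dx(i, j, c) = grad_out(2 * i, 2 * j, c) +
                      grad_out(2 * i + 1, 2 * j, c) +
                      grad_out(2 * i, 2 * j + 1, c) +
                      grad_out(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return dx;
}

// f x f average pool, stride f; H and W must be divisible by f.
// [[Rcpp::export]]
arma::cube avgpool_fwd(const arma::cube& input, const int f) {
  const int H = input.n_rows, W = input.n_cols, C = input.n_slices;
  const int h = H / f, w = W / f;
  cube out(h, w, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        out(i, j, c) =
            accu(input.slice(c).submat(i * f, j * f, (i + 1) * f - 1,
                                       (j + 1) * f - 1)) /
            (f * f);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube avgpool_bwd(const arma::cube& grad_out, const int f) {
  const int h = grad_out.n_rows, w = grad_out.n_cols, C = grad_out.n_slices;
  cube dx(h * f, w * f, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < w; ++j) {
      for (int i = 0; i < h; ++i) {
        dx.slice(c)
            .submat(i * f, j * f, (i + 1) * f - 1, (j + 1) * f - 1)
            .fill(grad_out(i, j, c) / (f * f));
      }
    }
  }
  return dx;
}
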