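// Low-level kernels for the small encoder-decoder CNNs and the patch labeller.
// Tensors are H x W x C arma::cubes (column-major, matching R arrays).
// Convolution uses im2col with "same" zero padding; dilation supported for
// atrous branches. Weight matrices are (k*k*Cin) x Cout with row index
// (ci*k + ki)*k + kj, pixel rows ordered r + c*H (R column-major).

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = (k - 1) / 2;
  arma::mat col(H * (arma::uword)W, (arma::uword)k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& sl = x.slice(ci);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int dr = dil * (ki - half), dc = dil * (kj - half);
        const arma::uword cc = (arma::uword)(ci * k + ki) * k + kj;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int sr = r + dr;
            if (sr < 0 || sr >= H) continue;
            col(r + (arma::uword)c * H, cc) = sl(sr, sc);
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& w,
                        const arma::vec& b, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat y = im2col(x, k, dil) * w;
  y.each_row() += b.t();
  arma::cube out(H, W, Cout);
  std::memcpy(out.memptr(), y.memptr(), sizeof(double) * y.n_elem);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& w,
                  const arma::cube& gy, int k, int dil) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int half = (k - 1) / 2;
  const arma::mat gym(const_cast<double*>(gy.memptr()), (arma::uword)H * W,
                      gy.n_slices, false, true);
  arma::mat col = im2col(x, k, dil);
  arma::mat dw = col.t() * gym;
  arma::vec db = arma::sum(gym, 0).t();
  arma::mat dcol = gym * w.t();
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    arma::mat& sl = dx.slice(ci);
    for (int ki = 0; ki < k; ++ki) {
      for (int kj = 0; kj < k; ++kj) {
        const int dr = dil * (ki - half), dc = dil * (kj - half);
        const arma::uword cc = (arma::uword)(ci * k + ki) * k + kj;
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          for (int r = 0; r < H; ++r) {
            const int sr = r + dr;
            if (sr < 0 || sr >= H) continue;
            sl(sr, sc) += dcol(r + (arma::uword)c * H, cc);
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. H and W must be even (checked in R).
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int h = H / 2, w = W / 2;
  arma::cube y(h, w, C);
  arma::ucube idx(h, w, C);
  for (int ci = 0; ci < C; ++ci) {
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        double best = -arma::datum::inf;
        arma::uword bi = 0;
        for (int dc = 0; dc < 2; ++dc) {
          for (int dr = 0; dr < 2; ++dr) {
            const int rr = 2 * r + dr, cc = 2 * c + dc;
            const double v = x(rr, cc, ci);
            if (v > best) {
              best = v;
              bi = (arma::uword)ci * H * W + (arma::uword)cc * H + rr;
            }
          }
        }
        y(r, c, ci) = best;
        idx(r, c, ci) = bi;
      }
    }
  }
  return List::create(_["y"] = y,
                      _["idx"] = NumericVector(idx.begin(), idx.end()));
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(int H, int W, int C, const NumericVector& idx,
                           const arma::cube& gy) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  const double* g = gy.memptr();
  for (arma::uword i = 0; i < gy.n_elem; ++i)
    dx((arma::uword)idx[i]) += g[i];
  return dx;
}

// nearest-neighbour x2 upsampling
// [[Rcpp::export]]
arma::cube cpp_upsample_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < 2 * W; ++c)
      for (int r = 0; r < 2 * H; ++r)
        y(r, c, ci) = x(r / 2, c / 2, ci);
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_bwd(const arma::cube& gy) {
  const int H = gy.n_rows / 2, W = gy.n_cols / 2, C = gy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci)
    for (int c = 0; c < 2 * W; ++c)
      for (int r = 0; r < 2 * H; ++r)
        dx(r / 2, c / 2, ci) += gy(r, c, ci);
  return dx;
}

// Connected components of mask == target under 4- or 8-connectivity (BFS).
// Returns 0 where mask != target, 1..n component labels elsewhere.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int target,
                                   int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) != target || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int i = 0; i < nn; ++i) {
          const int rr = p.first + dr8[i], cc = p.second + dc8[i];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != target || lab(rr, cc) != 0) continue;
          lab(rr, cc) = next;
          q.push(std::make_pair(rr, cc));
        }
      }
    }
  }
  return lab;
}
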