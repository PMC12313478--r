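// Compiled kernels for the autodiff engine.
//
// Feature maps are stored column-major with dims (C, H, W, N): channel
// fastest, batch slowest.  Token stacks are plain (N*L, d) matrices with the
// L rows of sample n contiguous (rows n*L .. n*L+L-1).

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int conv_out(int H, int k, int pad, int stride) {
  return (H + 2 * pad - k) / stride + 1;
}

// im2col: patches matrix (C*k*k, Ho*Wo*N); row index = c + C*(kh + k*kw),
// column index = oh + Ho*(ow + Wo*n).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int H, int W, int N,
                         int k, int pad, int stride) {
  const int Ho = conv_out(H, k, pad, stride);
  const int Wo = conv_out(W, k, pad, stride);
  NumericMatrix out(C * k * k, Ho * Wo * N);
  const double* px = x.begin();
  double* po = out.begin();
  const int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double* col = po + (std::size_t)nrow * (oh + (std::size_t)Ho * (ow + (std::size_t)Wo * n));
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride - pad + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride - pad + kh;
            double* dst = col + C * (kh + k * kw);
            if (h < 0 || h >= H || w < 0 || w >= W) {
              for (int c = 0; c < C; ++c) dst[c] = 0.0;
            } else {
              const double* src = px + (std::size_t)C * (h + (std::size_t)H * (w + (std::size_t)W * n));
              for (int c = 0; c < C; ++c) dst[c] = src[c];
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int C, int H, int W, int N,
                         int k, int pad, int stride) {
  const int Ho = conv_out(H, k, pad, stride);
  const int Wo = conv_out(W, k, pad, stride);
  NumericVector dx((std::size_t)C * H * W * N);
  double* pdx = dx.begin();
  const double* pc = cols.begin();
  const int nrow = C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const double* col = pc + (std::size_t)nrow * (oh + (std::size_t)Ho * (ow + (std::size_t)Wo * n));
        for (int kw = 0; kw < k; ++kw) {
          const int w = ow * stride - pad + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = oh * stride - pad + kh;
            if (h < 0 || h >= H) continue;
            const double* src = col + C * (kh + k * kw);
            double* dst = pdx + (std::size_t)C * (h + (std::size_t)H * (w + (std::size_t)W * n));
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  return dx;
}

// Max pooling with argmax bookkeeping (1-based linear indices into x).
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int C, int H, int W, int N,
                 int k, int pad, int stride) {
  const int Ho = conv_out(H, k, pad, stride);
  const int Wo = conv_out(W, k, pad, stride);
  NumericVector out((std::size_t)C * Ho * Wo * N);
  IntegerVector idx((std::size_t)C * Ho * Wo * N);
  const double* px = x.begin();
  double* po = out.begin();
  int* pi = idx.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          std::size_t besti = 0;
          for (int kw = 0; kw < k; ++kw) {
            const int w = ow * stride - pad + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = oh * stride - pad + kh;
              if (h < 0 || h >= H) continue;
              std::size_t ii = c + (std::size_t)C * (h + (std::size_t)H * (w + (std::size_t)W * n));
              if (px[ii] > best) { best = px[ii]; besti = ii; }
            }
          }
          std::size_t oi = c + (std::size_t)C * (oh + (std::size_t)Ho * (ow + (std::size_t)Wo * n));
          po[oi] = best;
          pi[oi] = (int)(besti + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector g, IntegerVector idx, int size) {
  NumericVector dx(size);
  double* pdx = dx.begin();
  const double* pg = g.begin();
  const int* pi = idx.begin();
  const R_xlen_t M = g.size();
  for (R_xlen_t i = 0; i < M; ++i) pdx[pi[i] - 1] += pg[i];
  return dx;
}

// Average p x p patches of a (C,h,w,N) map into tokens (N*L, C); token
// l = gh + Gh*gw within each sample, Gh = h/p.
// [[Rcpp::export]]
NumericMatrix cpp_patchify(NumericVector x, int C, int H, int W, int N, int p) {
  const int Gh = H / p, Gw = W / p, L = Gh * Gw;
  NumericMatrix out(N * L, C);
  const double* px = x.begin();
  const double inv = 1.0 / (p * p);
  for (int n = 0; n < N; ++n) {
    for (int gw = 0; gw < Gw; ++gw) {
      for (int gh = 0; gh < Gh; ++gh) {
        const int row = n * L + gh + Gh * gw;
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int pw = 0; pw < p; ++pw) {
            const int w = gw * p + pw;
            for (int ph = 0; ph < p; ++ph) {
              const int h = gh * p + ph;
              s += px[c + (std::size_t)C * (h + (std::size_t)H * (w + (std::size_t)W * n))];
            }
          }
          out(row, c) = s * inv;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_patchify_bwd(NumericMatrix g, int C, int H, int W, int N, int p) {
  const int Gh = H / p, Gw = W / p, L = Gh * Gw;
  NumericVector dx((std::size_t)C * H * W * N);
  double* pdx = dx.begin();
  const double inv = 1.0 / (p * p);
  for (int n = 0; n < N; ++n) {
    for (int gw = 0; gw < Gw; ++gw) {
      for (int gh = 0; gh < Gh; ++gh) {
        const int row = n * L + gh + Gh * gw;
        for (int c = 0; c < C; ++c) {
          const double v = g(row, c) * inv;
          for (int pw = 0; pw < p; ++pw) {
            const int w = gw * p + pw;
            for (int ph = 0; ph < p; ++ph) {
              const int h = gh * p + ph;
              pdx[c + (std::size_t)C * (h + (std::size_t)H * (w + (std::size_t)W * n))] += v;
            }
          }
        }
      }
    }
  }
  return dx;
}

// Nearest-neighbour expansion of tokens back to a (C,h,w,N) map.
// [[Rcpp::export]]
NumericVector cpp_unpatchify(NumericMatrix tok, int C, int H, int W, int N, int p) {
  const int Gh = H / p, Gw = W / p, L = Gh * Gw;
  NumericVector x((std::size_t)C * H * W * N);
  double* px = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int gw = 0; gw < Gw; ++gw) {
      for (int gh = 0; gh < Gh; ++gh) {
        const int row = n * L + gh + Gh * gw;
        for (int c = 0; c < C; ++c) {
          const double v = tok(row, c);
          for (int pw = 0; pw < p; ++pw) {
            const int w = gw * p + pw;
            for (int ph = 0; ph < p; ++ph) {
              const int h = gh * p + ph;
              px[c + (std::size_t)C * (h + (std::size_t)H * (w + (std::size_t)W * n))] = v;
            }
          }
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
NumericMatrix cpp_unpatchify_bwd(NumericVector g, int C, int H, int W, int N, int p) {
  const int Gh = H / p, Gw = W / p, L = Gh * Gw;
  NumericMatrix dtok(N * L, C);
  const double* pg = g.begin();
  for (int n = 0; n < N; ++n) {
    for (int gw = 0; gw < Gw; ++gw) {
      for (int gh = 0; gh < Gh; ++gh) {
        const int row = n * L + gh + Gh * gw;
        for (int c = 0; c < C; ++c) {
          double s = 0.0;
          for (int pw = 0; pw < p; ++pw) {
            const int w = gw * p + pw;
            for (int ph = 0; ph < p; ++ph) {
              const int h = gh * p + ph;
              s += pg[c + (std::size_t)C * (h + (std::size_t)H * (w + (std::size_t)W * n))];
            }
          }
          dtok(row, c) += s;
        }
      }
    }
  }
  return dtok;
}

static arma::mat softmax_rows(const arma::mat& S) {
  arma::vec m = arma::max(S, 1);
  arma::mat A = arma::exp(S.each_col() - m);
  arma::vec z = arma::sum(A, 1);
  A.each_col() /= z;
  return A;
}

// Multi-head scaled-dot-product self-attention over per-sample blocks of L
// rows.  Q, K, V: (N*L, d) with d = nh * dh; head h owns columns
// h*dh .. (h+1)*dh-1.  `mask` (length N*L, 0/1) removes key positions from
// every softmax (pad masking); an all-zero block falls back to uniform
// weights, which only affects masked rows.
// [[Rcpp::export]]
arma::mat cpp_attn_fwd(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, int L, int nh,
                       const arma::vec& mask) {
  const int d = Q.n_cols, dh = d / nh;
  const int N = Q.n_rows / L;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat out(Q.n_rows, d, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const arma::uword r0 = (arma::uword)n * L, r1 = r0 + L - 1;
    arma::rowvec bias = (1.0 - mask.subvec(r0, r1).t()) * (-1e30);
    for (int h = 0; h < nh; ++h) {
      const arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      arma::mat Qh = Q.submat(r0, c0, r1, c1);
      arma::mat Kh = K.submat(r0, c0, r1, c1);
      arma::mat Vh = V.submat(r0, c0, r1, c1);
      arma::mat S = scale * (Qh * Kh.t());
      S.each_row() += bias;
      arma::mat A = softmax_rows(S);
      out.submat(r0, c0, r1, c1) = A * Vh;
    }
  }
  return out;
}

// Backward pass; the attention matrix is recomputed per block to keep peak
// memory at one L x L matrix.
// [[Rcpp::export]]
List cpp_attn_bwd(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                  int L, int nh, const arma::vec& mask, const arma::mat& G) {
  const int d = Q.n_cols, dh = d / nh;
  const int N = Q.n_rows / L;
  const double scale = 1.0 / std::sqrt((double)dh);
  arma::mat dQ(arma::size(Q), arma::fill::zeros);
  arma::mat dK(arma::size(K), arma::fill::zeros);
  arma::mat dV(arma::size(V), arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const arma::uword r0 = (arma::uword)n * L, r1 = r0 + L - 1;
    arma::rowvec bias = (1.0 - mask.subvec(r0, r1).t()) * (-1e30);
    for (int h = 0; h < nh; ++h) {
      const arma::uword c0 = (arma::uword)h * dh, c1 = c0 + dh - 1;
      arma::mat Qh = Q.submat(r0, c0, r1, c1);
      arma::mat Kh = K.submat(r0, c0, r1, c1);
      arma::mat Vh = V.submat(r0, c0, r1, c1);
      arma::mat Gh = G.submat(r0, c0, r1, c1);
      arma::mat S = scale * (Qh * Kh.t());
      S.each_row() += bias;
      arma::mat A = softmax_rows(S);
      dV.submat(r0, c0, r1, c1) = A.t() * Gh;
      arma::mat dA = Gh * Vh.t();
      arma::vec rs = arma::sum(dA % A, 1);
      arma::mat dS = A % (dA.each_col() - rs);
      dQ.submat(r0, c0, r1, c1) = scale * (dS * Kh);
      dK.submat(r0, c0, r1, c1) = scale * (dS.t() * Qh);
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}
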