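#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Activation layout used throughout the network code: a matrix with one
// column per channel and rows enumerating spatial positions within each
// sample, position fastest (row = i + ih*j + ih*iw*n for sample n).
// Convolutions are lowered to matrix products: im2col_mat_cpp builds the
// patch matrix (rows = output positions x samples, columns = (ki, kj, c)
// with ki fastest), which is multiplied with a (kh*kw*C, Cout) weight
// matrix in R via BLAS.

// [[Rcpp::export]]
NumericMatrix im2col_mat_cpp(NumericMatrix M, int ih, int iw, int N,
                             int kh, int kw) {
  const int C = M.ncol();
  const int oh = ih - kh + 1, ow = iw - kw + 1;
  const int np = oh * ow;
  const R_xlen_t plane = (R_xlen_t)ih * iw;
  NumericMatrix out((R_xlen_t)np * N, kh * kw * C);
  const double* mp = M.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    const double* mcol = mp + (R_xlen_t)c * ih * iw * N;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        double* ocol = op + (R_xlen_t)col * np * N;
        for (int n = 0; n < N; ++n) {
          const double* base = mcol + (R_xlen_t)n * plane + ki +
                               (R_xlen_t)kj * ih;
          double* orow = ocol + (R_xlen_t)n * np;
          for (int j = 0; j < ow; ++j) {
            const double* src = base + (R_xlen_t)j * ih;
            double* dst = orow + (R_xlen_t)j * oh;
            for (int i = 0; i < oh; ++i) dst[i] = src[i];
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add inverse of im2col_mat_cpp (backward pass of the lowering).

// [[Rcpp::export]]
NumericMatrix col2im_mat_cpp(NumericMatrix cols, int ih, int iw, int N,
                             int kh, int kw, int C) {
  const int oh = ih - kh + 1, ow = iw - kw + 1;
  const int np = oh * ow;
  const R_xlen_t plane = (R_xlen_t)ih * iw;
  NumericMatrix out((R_xlen_t)ih * iw * N, C);
  double* op = out.begin();
  const double* cp = cols.begin();
  for (int c = 0; c < C; ++c) {
    double* mcol = op + (R_xlen_t)c * ih * iw * N;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int col = ki + kh * (kj + kw * c);
        const double* ccol = cp + (R_xlen_t)col * np * N;
        for (int n = 0; n < N; ++n) {
          double* base = mcol + (R_xlen_t)n * plane + ki + (R_xlen_t)kj * ih;
          const double* crow = ccol + (R_xlen_t)n * np;
          for (int j = 0; j < ow; ++j) {
            double* dst = base + (R_xlen_t)j * ih;
            const double* src = crow + (R_xlen_t)j * oh;
            for (int i = 0; i < oh; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  return out;
}

// 2x2/stride-2 max pooling on the channel-column layout; trailing odd
// row/column dropped. idx holds 1-based linear indices into the input
// matrix for the backward scatter.

// [[Rcpp::export]]
List maxpool2_mat_cpp(NumericMatrix M, int ih, int iw, int N) {
  const int C = M.ncol();
  const int oh = ih / 2, ow = iw / 2;
  const R_xlen_t np_in = (R_xlen_t)ih * iw, np_out = (R_xlen_t)oh * ow;
  NumericMatrix y(np_out * N, C);
  IntegerVector idx(np_out * N * C);
  const double* mp = M.begin();
  double* yp = y.begin();
  int* ip = idx.begin();
  for (int c = 0; c < C; ++c) {
    const R_xlen_t coff = (R_xlen_t)c * np_in * N;
    R_xlen_t o = (R_xlen_t)c * np_out * N;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t base = coff + (R_xlen_t)n * np_in;
      for (int j = 0; j < ow; ++j) {
        for (int i = 0; i < oh; ++i) {
          R_xlen_t p00 = base + (R_xlen_t)(2 * j) * ih + 2 * i;
          R_xlen_t best = p00;
          double v = mp[p00];
          if (mp[p00 + 1] > v) { v = mp[p00 + 1]; best = p00 + 1; }
          if (mp[p00 + ih] > v) { v = mp[p00 + ih]; best = p00 + ih; }
          if (mp[p00 + ih + 1] > v) { v = mp[p00 + ih + 1];
                                      best = p00 + ih + 1; }
          yp[o] = v;
          ip[o] = (int)(best + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool2_mat_back_cpp(NumericMatrix dy, IntegerVector idx,
                                    double nrow_in) {
  const int C = dy.ncol();
  NumericMatrix dx((R_xlen_t)nrow_in, C);
  double* dp = dx.begin();
  const double* gp = dy.begin();
  const int* ip = idx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t k = 0; k < n; ++k) dp[ip[k] - 1] += gp[k];
  return dx;
}

// Fused batch-norm + ReLU forward over the channel columns. In training
// mode batch statistics are used and running statistics updated in place;
// in inference mode the running statistics are used and xhat/inv_std are
// empty.

// [[Rcpp::export]]
List bnrelu_fwd_cpp(NumericMatrix z, NumericVector gamma, NumericVector beta,
                    NumericVector run_mu, NumericVector run_var,
                    bool training, double momentum, double eps) {
  const int C = z.ncol();
  const R_xlen_t m = z.nrow();
  NumericMatrix out(m, C);
  NumericMatrix xhat(training ? m : 0, training ? C : 0);
  NumericVector inv_std(C), mu_out(C), var_out(C);
  NumericVector new_mu = clone(run_mu), new_var = clone(run_var);
  for (int c = 0; c < C; ++c) {
    const double* zc = z.begin() + (R_xlen_t)c * m;
    double* oc = out.begin() + (R_xlen_t)c * m;
    double mu, var;
    if (training) {
      double s = 0;
      for (R_xlen_t i = 0; i < m; ++i) s += zc[i];
      mu = s / m;
      double sv = 0;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double d = zc[i] - mu;
        sv += d * d;
      }
      var = sv / m;
      new_mu[c] = (1 - momentum) * run_mu[c] + momentum * mu;
      new_var[c] = (1 - momentum) * run_var[c] + momentum * var;
    } else {
      mu = run_mu[c];
      var = run_var[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    inv_std[c] = is;
    const double g = gamma[c], b = beta[c];
    if (training) {
      double* xc = xhat.begin() + (R_xlen_t)c * m;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double xh = (zc[i] - mu) * is;
        xc[i] = xh;
        const double v = g * xh + b;
        oc[i] = v > 0 ? v : 0;
      }
    } else {
      for (R_xlen_t i = 0; i < m; ++i) {
        const double v = g * (zc[i] - mu) * is + b;
        oc[i] = v > 0 ? v : 0;
      }
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["inv_std"] = inv_std, _["run_mu"] = new_mu,
                      _["run_var"] = new_var);
}

// Fused ReLU + batch-norm backward: masks the incoming gradient with the
// post-activation (out > 0), then applies the batch-norm backward formula
// per channel.

// [[Rcpp::export]]
List bnrelu_bwd_cpp(NumericMatrix dout, NumericMatrix out,
                    NumericMatrix xhat, NumericVector inv_std,
                    NumericVector gamma) {
  const int C = dout.ncol();
  const R_xlen_t m = dout.nrow();
  NumericMatrix dz(m, C);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dc = dout.begin() + (R_xlen_t)c * m;
    const double* oc = out.begin() + (R_xlen_t)c * m;
    const double* xc = xhat.begin() + (R_xlen_t)c * m;
    double* zc = dz.begin() + (R_xlen_t)c * m;
    double sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double d = oc[i] > 0 ? dc[i] : 0;
      zc[i] = d;          // temporarily the masked gradient
      sg += d * xc[i];
      sb += d;
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    const double g = gamma[c], is = inv_std[c];
    const double mb = sb / m, mg = sg / m;
    for (R_xlen_t i = 0; i < m; ++i)
      zc[i] = g * is * (zc[i] - mb - xc[i] * mg);
  }
  return List::create(_["dz"] = dz, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// Per-sample flattening between the conv stack and the fully connected
// layers: (np*N x C) channel-column layout -> (N x np*C) feature rows,
// feature index f = p + np*c.

// [[Rcpp::export]]
NumericMatrix flatten_rows_cpp(NumericMatrix Y, int N) {
  const int C = Y.ncol();
  const R_xlen_t np = Y.nrow() / N;
  NumericMatrix out(N, np * C);
  const double* yp = Y.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      const double* src = yp + ((R_xlen_t)c * N + n) * np;
      for (R_xlen_t p = 0; p < np; ++p)
        op[(R_xlen_t)(c * np + p) * N + n] = src[p];
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix unflatten_rows_cpp(NumericMatrix X, int np) {
  const int N = X.nrow();
  const int C = X.ncol() / np;
  NumericMatrix out((R_xlen_t)np * N, C);
  const double* xp = X.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n) {
      double* dst = op + ((R_xlen_t)c * N + n) * np;
      for (R_xlen_t p = 0; p < np; ++p)
        dst[p] = xp[(R_xlen_t)(c * np + p) * N + n];
    }
  return out;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// The conv lowering allocates multi-hundred-MB scratch matrices every
// minibatch; with glibc's default mmap threshold each one is mapped and
// unmapped, dominating wall time with page faults. Raising the thresholds
// lets the heap reuse those blocks. No-op on non-glibc platforms.

// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}
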