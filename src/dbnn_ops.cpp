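// Low-level numerical kernels for the dual-branch CNN.
//
// Batch layout convention (shared with the R side):
//   a feature map batch is a (H*W*N x C) matrix ("pixel-major"); sample n
//   occupies rows [n*H*W, (n+1)*H*W); pixels within a sample are
//   column-major (row index fastest), i.e. pixel (r, c) of sample n sits at
//   matrix row n*H*W + c*H + r (all zero-based). Channels are columns.
//
// Convolution weights are (Cin*9 x Cout) matrices; matrix row
// k*Cin + ci with k = 3*(dc+1) + (dr+1) holds the tap applied to input
// channel ci at spatial offset (dr, dc). With this layout a padded 3x3
// convolution is nine shifted GEMMs: the spatial shift (dr, dc) is a row
// offset of dc*H + dr in the flattened batch, valid everywhere except at
// image borders (and sample boundaries), which are patched by a small
// gathered correction. The R helpers convWeightMatrix()/convWeightArray()
// map this to/from the natural array(dim = c(3, 3, Cin, Cout)).
//
// Kernels take and return Rcpp matrices (R-owned memory, no copies) and
// drive BLAS dgemm directly with leading-dimension offsets.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

#ifndef FCONE
#define FCONE
#endif

static inline void blas_gemm(bool tA, bool tB, int m, int n, int k,
                             double alpha, const double* A, int lda,
                             const double* B, int ldb, double beta,
                             double* C, int ldc) {
  const char* ta = tA ? "T" : "N";
  const char* tb = tB ? "T" : "N";
  F77_CALL(dgemm)(ta, tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// 0-based rows of the flattened batch whose 3x3 neighbour at offset
// (dr, dc) falls outside the image (those rows get no contribution from
// this tap, but the shifted GEMM adds a spurious one, removed afterwards).
// Only rows within the clipped GEMM range [lo, hi] are returned.
static std::vector<int> invalid_rows(int H, int W, int N, int dr, int dc,
                                     int lo, int hi) {
  std::vector<int> bad;
  if (dr == 0 && dc == 0) return bad;
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    if (dc != 0) {
      const int c = (dc == 1) ? W - 1 : 0;
      for (int r = 0; r < H; ++r) {
        const int p = n * HW + c * H + r;
        if (p >= lo && p <= hi) bad.push_back(p);
      }
    }
    if (dr != 0) {
      const int r = (dr == 1) ? H - 1 : 0;
      const int c0 = (dc == -1) ? 1 : 0;
      const int c1 = (dc == 1) ? W - 1 : W;
      for (int c = c0; c < c1; ++c) {
        const int p = n * HW + c * H + r;
        if (p >= lo && p <= hi) bad.push_back(p);
      }
    }
  }
  return bad;
}

// [[Rcpp::export(name = ".conv3x3Forward")]]
NumericMatrix conv3x3_forward(const NumericMatrix& X, int H, int W, int N,
                              const NumericMatrix& Wt,
                              const NumericVector& b) {
  const int M = H * W * N;
  const int Cin = X.ncol(), Cout = Wt.ncol();
  if (X.nrow() != M) stop("input batch has wrong number of rows");
  if (Wt.nrow() != Cin * 9) stop("weights do not match input channels");
  NumericMatrix Y(M, Cout);
  double* yp = REAL(Y);
  for (int j = 0; j < Cout; ++j) std::fill(yp + (size_t)j * M,
                                           yp + (size_t)(j + 1) * M, b[j]);
  const double* xp = REAL(X);
  const double* wp = REAL(Wt);
  const int ldw = 9 * Cin;
  std::vector<double> gbuf, cbuf;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = 3 * (dc + 1) + (dr + 1);
      const double* Wk = wp + k * Cin;
      const int off = dc * H + dr;
      const int lo = std::max(0, -off);
      const int hi = M - 1 - std::max(0, off);
      if (lo > hi) continue;
      blas_gemm(false, false, hi - lo + 1, Cout, Cin, 1.0, xp + lo + off, M,
                Wk, ldw, 1.0, yp + lo, M);
      const std::vector<int> bad = invalid_rows(H, W, N, dr, dc, lo, hi);
      if (!bad.empty()) {
        const int nb = (int)bad.size();
        gbuf.assign((size_t)nb * Cin, 0.0);
        for (int ci = 0; ci < Cin; ++ci) {
          const double* col = xp + (size_t)ci * M + off;
          for (int i = 0; i < nb; ++i) gbuf[(size_t)ci * nb + i] = col[bad[i]];
        }
        cbuf.assign((size_t)nb * Cout, 0.0);
        blas_gemm(false, false, nb, Cout, Cin, 1.0, gbuf.data(), nb,
                  Wk, ldw, 0.0, cbuf.data(), nb);
        for (int j = 0; j < Cout; ++j) {
          double* col = yp + (size_t)j * M;
          const double* cc = cbuf.data() + (size_t)j * nb;
          for (int i = 0; i < nb; ++i) col[bad[i]] -= cc[i];
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv3x3Backward")]]
List conv3x3_backward(const NumericMatrix& dY, const NumericMatrix& X,
                      int H, int W, int N, const NumericMatrix& Wt,
                      bool needInputGrad = true) {
  const int M = H * W * N;
  const int Cin = X.ncol(), Cout = Wt.ncol();
  NumericMatrix dW(9 * Cin, Cout);
  NumericMatrix dX(needInputGrad ? M : 1, needInputGrad ? Cin : 1);
  NumericVector db(Cout);
  const double* dyp = REAL(dY);
  const double* xp = REAL(X);
  const double* wp = REAL(Wt);
  double* dwp = REAL(dW);
  double* dxp = REAL(dX);
  for (int j = 0; j < Cout; ++j) {
    const double* col = dyp + (size_t)j * M;
    double s = 0;
    for (int i = 0; i < M; ++i) s += col[i];
    db[j] = s;
  }
  const int ldw = 9 * Cin;
  std::vector<double> gxbuf, gybuf, cbuf;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = 3 * (dc + 1) + (dr + 1);
      const double* Wk = wp + k * Cin;
      const int off = dc * H + dr;
      const int lo = std::max(0, -off);
      const int hi = M - 1 - std::max(0, off);
      if (lo > hi) continue;
      const int Mv = hi - lo + 1;
      // dWk = X_shifted^T dY (k-th row block of dW)
      blas_gemm(true, false, Cin, Cout, Mv, 1.0, xp + lo + off, M,
                dyp + lo, M, 0.0, dwp + k * Cin, ldw);
      if (needInputGrad) {
        // dX_shifted += dY Wk^T
        blas_gemm(false, true, Mv, Cin, Cout, 1.0, dyp + lo, M, Wk, ldw,
                  1.0, dxp + lo + off, M);
      }
      const std::vector<int> bad = invalid_rows(H, W, N, dr, dc, lo, hi);
      if (!bad.empty()) {
        const int nb = (int)bad.size();
        gxbuf.assign((size_t)nb * Cin, 0.0);
        for (int ci = 0; ci < Cin; ++ci) {
          const double* col = xp + (size_t)ci * M + off;
          for (int i = 0; i < nb; ++i)
            gxbuf[(size_t)ci * nb + i] = col[bad[i]];
        }
        gybuf.assign((size_t)nb * Cout, 0.0);
        for (int j = 0; j < Cout; ++j) {
          const double* col = dyp + (size_t)j * M;
          for (int i = 0; i < nb; ++i)
            gybuf[(size_t)j * nb + i] = col[bad[i]];
        }
        blas_gemm(true, false, Cin, Cout, nb, -1.0, gxbuf.data(), nb,
                  gybuf.data(), nb, 1.0, dwp + k * Cin, ldw);
        if (needInputGrad) {
          cbuf.assign((size_t)nb * Cin, 0.0);
          blas_gemm(false, true, nb, Cin, Cout, 1.0, gybuf.data(), nb,
                    Wk, ldw, 0.0, cbuf.data(), nb);
          for (int ci = 0; ci < Cin; ++ci) {
            double* col = dxp + (size_t)ci * M + off;
            const double* cc = cbuf.data() + (size_t)ci * nb;
            for (int i = 0; i < nb; ++i) col[bad[i]] -= cc[i];
          }
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".bnStats")]]
List bn_stats(const NumericMatrix& S) {
  const int M = S.nrow(), C = S.ncol();
  NumericVector mu(C), v(C);
  const double* sp = REAL(S);
  for (int j = 0; j < C; ++j) {
    const double* col = sp + (size_t)j * M;
    double s1 = 0, s2 = 0;
    for (int i = 0; i < M; ++i) { s1 += col[i]; s2 += col[i] * col[i]; }
    const double m = s1 / M;
    mu[j] = m;
    const double vv = s2 / M - m * m;
    v[j] = vv > 0 ? vv : 0.0;
  }
  return List::create(_["mean"] = mu, _["var"] = v);
}

// batch-norm + ReLU, fused: act = max(0, gamma * xhat + beta)
// [[Rcpp::export(name = ".bnReluForward")]]
List bn_relu_forward(const NumericMatrix& S, const NumericVector& mean,
                     const NumericVector& invstd, const NumericVector& gamma,
                     const NumericVector& beta) {
  const int M = S.nrow(), C = S.ncol();
  NumericMatrix xhat(M, C), act(M, C);
  const double* sp = REAL(S);
  double* xp = REAL(xhat);
  double* ap = REAL(act);
  for (int j = 0; j < C; ++j) {
    const double mu = mean[j], is = invstd[j], g = gamma[j], bb = beta[j];
    const double* sc = sp + (size_t)j * M;
    double* xc = xp + (size_t)j * M;
    double* ac = ap + (size_t)j * M;
    for (int i = 0; i < M; ++i) {
      const double xh = (sc[i] - mu) * is;
      xc[i] = xh;
      const double y = g * xh + bb;
      ac[i] = y > 0 ? y : 0.0;
    }
  }
  return List::create(_["xhat"] = xhat, _["act"] = act);
}

// backward through ReLU + batch norm; train = TRUE propagates through the
// batch statistics, train = FALSE treats mean/var as constants
// [[Rcpp::export(name = ".bnReluBackward")]]
List bn_relu_backward(const NumericMatrix& dOut, const NumericMatrix& act,
                      const NumericMatrix& xhat, const NumericVector& invstd,
                      const NumericVector& gamma, bool train) {
  const int M = dOut.nrow(), C = dOut.ncol();
  NumericMatrix dS(M, C);
  NumericVector dgamma(C), dbeta(C);
  const double* dp = REAL(dOut);
  const double* ap = REAL(act);
  const double* xp = REAL(xhat);
  double* op = REAL(dS);
  for (int j = 0; j < C; ++j) {
    const double* dc = dp + (size_t)j * M;
    const double* ac = ap + (size_t)j * M;
    const double* xc = xp + (size_t)j * M;
    double* oc = op + (size_t)j * M;
    double s1 = 0, s2 = 0;
    for (int i = 0; i < M; ++i) {
      const double dy = ac[i] > 0 ? dc[i] : 0.0;
      oc[i] = dy;  // temporarily holds dY
      s1 += dy;
      s2 += dy * xc[i];
    }
    dgamma[j] = s2;
    dbeta[j] = s1;
    const double g = gamma[j], is = invstd[j];
    if (train) {
      const double m1 = s1 / M, m2 = s2 / M;
      for (int i = 0; i < M; ++i) oc[i] = is * g * (oc[i] - m1 - xc[i] * m2);
    } else {
      for (int i = 0; i < M; ++i) oc[i] *= is * g;
    }
  }
  return List::create(_["dS"] = dS, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".maxpool2Forward")]]
List maxpool2_forward(const NumericMatrix& X, int H, int W, int N) {
  if (H % 2 != 0 || W % 2 != 0) stop("maxpool requires even spatial dims");
  const int C = X.ncol(), HW = H * W;
  const int H2 = H / 2, W2 = W / 2, HW2 = H2 * W2;
  NumericMatrix Y(HW2 * N, C);
  IntegerMatrix arg(HW2 * N, C);  // global source row index
  const double* xall = REAL(X);
  double* yall = REAL(Y);
  int* aall = INTEGER(arg);
  const size_t Mi = (size_t)HW * N, Mo = (size_t)HW2 * N;
  for (int j = 0; j < C; ++j) {
    const double* xp = xall + Mi * j;
    double* yp = yall + Mo * j;
    int* ag = aall + Mo * j;
    for (int n = 0; n < N; ++n) {
      for (int oc = 0; oc < W2; ++oc) {
        for (int orr = 0; orr < H2; ++orr) {
          const int out = n * HW2 + oc * H2 + orr;
          const int s00 = n * HW + (2 * oc) * H + 2 * orr;
          const int cand[4] = {s00, s00 + 1, s00 + H, s00 + H + 1};
          double best = xp[cand[0]];
          int bi = cand[0];
          for (int q = 1; q < 4; ++q) {
            if (xp[cand[q]] > best) { best = xp[cand[q]]; bi = cand[q]; }
          }
          yp[out] = best;
          ag[out] = bi;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool2Backward")]]
NumericMatrix maxpool2_backward(const NumericMatrix& dY,
                                const IntegerMatrix& arg, int H, int W,
                                int N) {
  const int C = dY.ncol();
  const int M2 = dY.nrow();
  NumericMatrix dX(H * W * N, C);
  const double* dall = REAL(dY);
  const int* aall = INTEGER(arg);
  double* xall = REAL(dX);
  const size_t Mi = (size_t)H * W * N;
  for (int j = 0; j < C; ++j) {
    const double* dp = dall + (size_t)M2 * j;
    const int* ag = aall + (size_t)M2 * j;
    double* xp = xall + Mi * j;
    for (int i = 0; i < M2; ++i) xp[ag[i]] += dp[i];
  }
  return dX;
}

// [[Rcpp::export(name = ".medianFilterCpp")]]
NumericMatrix median_filter(const NumericMatrix& img, int k) {
  if (k < 3 || k % 2 == 0) stop("kernel must be an odd integer >= 3");
  const int H = img.nrow(), W = img.ncol();
  const int h = k / 2, kk = k * k;
  NumericMatrix out(H, W);
  std::vector<double> buf(kk);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int m = 0;
      for (int dc = -h; dc <= h; ++dc) {
        int sc = c + dc;
        // half-sample symmetric reflection: [c b a | a b c]
        if (sc < 0) sc = -sc - 1;
        if (sc >= W) sc = 2 * W - sc - 1;
        for (int dr = -h; dr <= h; ++dr) {
          int sr = r + dr;
          if (sr < 0) sr = -sr - 1;
          if (sr >= H) sr = 2 * H - sr - 1;
          buf[m++] = img(sr, sc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + kk / 2, buf.end());
      out(r, c) = buf[kk / 2];
    }
  }
  return out;
}
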