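#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <cstring>
using namespace Rcpp;

#ifndef FCONE
#define FCONE
#endif

// 1-D convolution (stride 1, symmetric zero padding) over channels-last
// (N, T, C) arrays as K shifted GEMMs on pointer-offset subblocks of the
// (N*T, C) column-major view -- no patch-matrix materialization.
// W is (K*C, F), rows channel-fastest within tap; b length F.
// [[Rcpp::export]]
NumericVector conv1d_sg_fwd(NumericVector x, NumericMatrix W,
                            NumericVector b, int K, int pad) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], T = d[1], C = d[2];
  const int Tout = T + 2 * pad - K + 1;
  const int Fd = W.ncol();
  NumericVector y(no_init((R_xlen_t)N * Tout * Fd));
  y.attr("dim") = IntegerVector::create(N, Tout, Fd);
  double* yp = REAL(y);
  for (int f = 0; f < Fd; ++f) {
    std::fill(yp + (R_xlen_t)f * N * Tout, yp + (R_xlen_t)(f + 1) * N * Tout,
              b[f]);
  }
  const double* xp = REAL(x);
  const double* wp = REAL(W);
  const double one = 1.0;
  const int ldx = N * T, ldw = K * C, ldy = N * Tout;
  for (int k = 0; k < K; ++k) {
    const int tlo = std::max(0, pad - k);
    const int thi = std::min(Tout - 1, T - 1 + pad - k);
    if (thi < tlo) continue;
    const int M = (thi - tlo + 1) * N;
    const double* A = xp + (R_xlen_t)(tlo + k - pad) * N;
    const double* B = wp + (R_xlen_t)k * C;
    double* Cp = yp + (R_xlen_t)tlo * N;
    F77_CALL(dgemm)("N", "N", &M, &Fd, &C, &one, A, &ldx, B, &ldw, &one,
                    Cp, &ldy FCONE FCONE);
  }
  return y;
}

// backward: dx (beta-1 accumulated shifted GEMMs with W transposed) and
// dW (per-tap crossprods of input and output-gradient subblocks)
// [[Rcpp::export]]
List conv1d_sg_bwd(NumericVector dy, NumericVector x, NumericMatrix W,
                   int K, int pad) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], T = d[1], C = d[2];
  const int Tout = T + 2 * pad - K + 1;
  const int Fd = W.ncol();
  NumericVector dx((R_xlen_t)N * T * C);  // zero-initialized
  dx.attr("dim") = IntegerVector::create(N, T, C);
  NumericMatrix dW((R_xlen_t)K * C, (R_xlen_t)Fd);
  const double* gp = REAL(dy);
  const double* xp = REAL(x);
  const double* wp = REAL(W);
  double* dxp = REAL(dx);
  double* dwp = REAL(dW);
  const double one = 1.0, zero = 0.0;
  const int ldx = N * T, ldw = K * C, ldy = N * Tout;
  for (int k = 0; k < K; ++k) {
    const int tlo = std::max(0, pad - k);
    const int thi = std::min(Tout - 1, T - 1 + pad - k);
    if (thi < tlo) continue;
    const int M = (thi - tlo + 1) * N;
    const double* G = gp + (R_xlen_t)tlo * N;
    const double* X = xp + (R_xlen_t)(tlo + k - pad) * N;
    double* DX = dxp + (R_xlen_t)(tlo + k - pad) * N;
    double* DW = dwp + (R_xlen_t)k * C;
    // dx_sub += dy_sub %*% t(W_k)
    F77_CALL(dgemm)("N", "T", &M, &C, &Fd, &one, G, &ldy,
                    wp + (R_xlen_t)k * C, &ldw, &one, DX, &ldx FCONE FCONE);
    // dW_k = t(x_sub) %*% dy_sub
    F77_CALL(dgemm)("T", "N", &C, &Fd, &M, &one, X, &ldx, G, &ldy, &zero,
                    DW, &ldw FCONE FCONE);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// max pooling over (N, T, C), returning pooled values and winning tap index
// (1-based) for the backward pass
// [[Rcpp::export]]
List maxpool1d_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int N = d[0], T = d[1], C = d[2];
  const int Tp = T + 2 * pad;
  const int Tout = (Tp - k) / stride + 1;
  NumericVector y(no_init((R_xlen_t)N * Tout * C));
  IntegerVector arg(no_init((R_xlen_t)N * Tout * C));
  y.attr("dim") = IntegerVector::create(N, Tout, C);
  arg.attr("dim") = IntegerVector::create(N, Tout, C);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ap = INTEGER(arg);
  for (int c = 0; c < C; ++c) {
    const double* src = xp + (R_xlen_t)c * N * T;
    for (int tau = 0; tau < Tout; ++tau) {
      double* yd = yp + (R_xlen_t)c * N * Tout + (R_xlen_t)tau * N;
      int* ad = ap + (R_xlen_t)c * N * Tout + (R_xlen_t)tau * N;
      for (int n = 0; n < N; ++n) {
        double best = R_NegInf;
        int bj = 1;
        for (int j = 0; j < k; ++j) {
          const int t = tau * stride + j - pad;
          if (t < 0 || t >= T) continue;
          const double v = src[(R_xlen_t)t * N + n];
          if (v > best) { best = v; bj = j + 1; }
        }
        yd[n] = best;
        ad[n] = bj;
      }
    }
  }
  return List::create(_["y"] = y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool1d_bwd(NumericVector dy, IntegerVector arg, int N,
                            int T, int C, int k, int stride, int pad) {
  const int Tp = T + 2 * pad;
  const int Tout = (Tp - k) / stride + 1;
  NumericVector dx((R_xlen_t)N * T * C);
  dx.attr("dim") = IntegerVector::create(N, T, C);
  double* dp = REAL(dx);
  const double* gp = REAL(dy);
  const int* ap = INTEGER(arg);
  for (int c = 0; c < C; ++c) {
    double* dst = dp + (R_xlen_t)c * N * T;
    for (int tau = 0; tau < Tout; ++tau) {
      const double* g2 = gp + (R_xlen_t)c * N * Tout + (R_xlen_t)tau * N;
      const int* a2 = ap + (R_xlen_t)c * N * Tout + (R_xlen_t)tau * N;
      for (int n = 0; n < N; ++n) {
        const int t = tau * stride + (a2[n] - 1) - pad;
        if (t >= 0 && t < T) dst[(R_xlen_t)t * N + n] += g2[n];
      }
    }
  }
  return dx;
}

static inline double sigm_(double v) { return 1.0 / (1.0 + std::exp(-v)); }

// LSTM sequence forward. XWb: (N, T, 4H) input projections x W + b (gate
// columns [input | forget | cell | output]); U: (H, 4H) recurrent weights.
// Returns hidden/cell sequences and post-activation gates.
// [[Rcpp::export]]
List lstm_seq_fwd(NumericVector XWb, NumericMatrix U, int N, int T, int H) {
  NumericVector Z = clone(XWb);
  NumericVector Hs(no_init((R_xlen_t)N * T * H));
  NumericVector Cs(no_init((R_xlen_t)N * T * H));
  Hs.attr("dim") = IntegerVector::create(N, T, H);
  Cs.attr("dim") = IntegerVector::create(N, T, H);
  double* zp = REAL(Z);
  double* hp = REAL(Hs);
  double* cp = REAL(Cs);
  const double* up = REAL(U);
  const int ldz = N * T, H4 = 4 * H, ldh = N;
  const double one = 1.0;
  std::vector<double> hprev((R_xlen_t)N * H, 0.0);
  std::vector<double> cprev((R_xlen_t)N * H, 0.0);
  for (int t = 0; t < T; ++t) {
    double* zt = zp + (R_xlen_t)t * N;  // (N x 4H) subblock, LDA = N*T
    if (t > 0) {
      F77_CALL(dgemm)("N", "N", &N, &H4, &H, &one, hprev.data(), &ldh, up,
                      &H, &one, zt, &ldz FCONE FCONE);
    }
    for (int j = 0; j < H; ++j) {
      double* zi = zt + (R_xlen_t)j * ldz;
      double* zf = zt + (R_xlen_t)(H + j) * ldz;
      double* zg = zt + (R_xlen_t)(2 * H + j) * ldz;
      double* zo = zt + (R_xlen_t)(3 * H + j) * ldz;
      double* ct = cp + (R_xlen_t)t * N + (R_xlen_t)j * ldz;
      double* ht = hp + (R_xlen_t)t * N + (R_xlen_t)j * ldz;
      double* cpv = cprev.data() + (R_xlen_t)j * N;
      double* hpv = hprev.data() + (R_xlen_t)j * N;
      for (int n = 0; n < N; ++n) {
        const double gi = sigm_(zi[n]);
        const double gf = sigm_(zf[n]);
        const double gg = std::tanh(zg[n]);
        const double go = sigm_(zo[n]);
        const double cc = gf * cpv[n] + gi * gg;
        zi[n] = gi; zf[n] = gf; zg[n] = gg; zo[n] = go;
        ct[n] = cc;
        const double hh = go * std::tanh(cc);
        ht[n] = hh;
        cpv[n] = cc;
        hpv[n] = hh;
      }
    }
  }
  return List::create(_["h"] = Hs, _["c"] = Cs, _["g"] = Z);
}

// LSTM backpropagation through time. dHs: gradient wrt the full hidden
// sequence; G/Cs/Hs: forward outputs. Returns gradients wrt the input
// projections plus accumulated dU, db.
// [[Rcpp::export]]
List lstm_seq_bwd(NumericVector dHs, NumericVector G, NumericVector Cs,
                  NumericVector Hs, NumericMatrix U, int N, int T, int H) {
  const int H4 = 4 * H, ldz = N * T;
  NumericVector dXW(no_init((R_xlen_t)N * T * H4));
  dXW.attr("dim") = IntegerVector::create(N, T, H4);
  NumericMatrix dU(H, H4);
  NumericVector db(H4);
  const double* dhs = REAL(dHs);
  const double* gp = REAL(G);
  const double* cs = REAL(Cs);
  const double* hs = REAL(Hs);
  const double* up = REAL(U);
  double* dxw = REAL(dXW);
  double* dup = REAL(dU);
  double* dbp = REAL(db);
  const double one = 1.0, zero = 0.0;
  std::vector<double> dhc((R_xlen_t)N * H, 0.0);   // recurrent dh carry
  std::vector<double> dcc((R_xlen_t)N * H, 0.0);   // cell-state carry
  std::vector<double> dz((R_xlen_t)N * H4);
  for (int t = T - 1; t >= 0; --t) {
    const double* gt = gp + (R_xlen_t)t * N;
    const double* ct = cs + (R_xlen_t)t * N;
    const double* cprev = (t > 0) ? cs + (R_xlen_t)(t - 1) * N : nullptr;
    for (int j = 0; j < H; ++j) {
      const double* gi = gt + (R_xlen_t)j * ldz;
      const double* gf = gt + (R_xlen_t)(H + j) * ldz;
      const double* gg = gt + (R_xlen_t)(2 * H + j) * ldz;
      const double* go = gt + (R_xlen_t)(3 * H + j) * ldz;
      const double* cc = ct + (R_xlen_t)j * ldz;
      const double* cpv = cprev ? cprev + (R_xlen_t)j * ldz : nullptr;
      const double* dseq = dhs + (R_xlen_t)t * N + (R_xlen_t)j * ldz;
      double* dhj = dhc.data() + (R_xlen_t)j * N;
      double* dcj = dcc.data() + (R_xlen_t)j * N;
      double* dzi = dz.data() + (R_xlen_t)j * N;
      double* dzf = dz.data() + (R_xlen_t)(H + j) * N;
      double* dzg = dz.data() + (R_xlen_t)(2 * H + j) * N;
      double* dzo = dz.data() + (R_xlen_t)(3 * H + j) * N;
      for (int n = 0; n < N; ++n) {
        const double dh = dseq[n] + dhj[n];
        const double tc = std::tanh(cc[n]);
        const double dc = dcj[n] + dh * go[n] * (1.0 - tc * tc);
        const double cp_ = cpv ? cpv[n] : 0.0;
        dzi[n] = dc * gg[n] * gi[n] * (1.0 - gi[n]);
        dzf[n] = dc * cp_ * gf[n] * (1.0 - gf[n]);
        dzg[n] = dc * gi[n] * (1.0 - gg[n] * gg[n]);
        dzo[n] = dh * tc * go[n] * (1.0 - go[n]);
        dcj[n] = dc * gf[n];
      }
    }
    // write dz into the (N, T, 4H) output at step t
    for (int j = 0; j < H4; ++j) {
      std::memcpy(dxw + (R_xlen_t)t * N + (R_xlen_t)j * ldz,
                  dz.data() + (R_xlen_t)j * N, N * sizeof(double));
    }
    // dh carry for step t-1: dz %*% t(U)
    F77_CALL(dgemm)("N", "T", &N, &H, &H4, &one, dz.data(), &N, up, &H,
                    &zero, dhc.data(), &N FCONE FCONE);
    // dU += t(h_prev) %*% dz
    if (t > 0) {
      F77_CALL(dgemm)("T", "N", &H, &H4, &N, &one,
                      hs + (R_xlen_t)(t - 1) * N, &ldz, dz.data(), &N, &one,
                      dup, &H FCONE FCONE);
    }
    for (int j = 0; j < H4; ++j) {
      const double* c = dz.data() + (R_xlen_t)j * N;
      double acc = 0.0;
      for (int n = 0; n < N; ++n) acc += c[n];
      dbp[j] += acc;
    }
  }
  return List::create(_["dXW"] = dXW, _["dU"] = dU, _["db"] = db);
}
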