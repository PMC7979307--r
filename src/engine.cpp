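// Compact volumetric conv-net engine: forward, backward, Grad-CAM taps.
//
// Activations are stored one column per sample, channel-fastest:
//   element index = c + C * (x + X*(y + Y*z)).
// 2D networks are handled uniformly as 3D with z-extent 1 and kernel depth 1.
// All heavy arithmetic is float32 through im2col + sgemm (Armadillo/BLAS).

#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
// Activation and im2col buffers run to tens of MB and are reallocated every
// call; keep glibc from handing them straight back to the kernel so repeated
// steps reuse warm pages instead of faulting fresh ones.
static const int g_mallopt_done = []() {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  return 0;
}();
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static const int K_CONV = 1, K_BN = 2, K_POOL = 3, K_FLAT = 4,
                 K_DENSE = 5, K_DROP = 6, K_GAP = 7;
static const float BN_EPS = 1e-5f;

struct Layer {
  int kind, in_c, out_c, kx, kz, s, sz, plo, phi, plo_z, phi_z, act;
  int ix, iy, iz, ox, oy, oz;
  long to, tl, so, sl;   // theta/state offsets (0-based) and lengths
  float drop;
  long fin()  const { return (long)in_c  * ix * iy * iz; }
  long fout() const { return (long)out_c * ox * oy * oz; }
  long pos_out() const { return (long)ox * oy * oz; }
  long krows() const { return (long)in_c * kx * kx * kz; }
};

static std::vector<Layer> parse_desc(const IntegerMatrix& desc,
                                     const NumericVector& drop_rates) {
  std::vector<Layer> L(desc.nrow());
  for (int i = 0; i < desc.nrow(); ++i) {
    Layer& l = L[i];
    l.kind = desc(i, 0);  l.in_c = desc(i, 1);  l.out_c = desc(i, 2);
    l.kx = desc(i, 3);    l.kz = desc(i, 4);
    l.s = desc(i, 5);     l.sz = desc(i, 6);
    l.plo = desc(i, 7);   l.phi = desc(i, 8);
    l.plo_z = desc(i, 9); l.phi_z = desc(i, 10);
    l.act = desc(i, 11);
    l.ix = desc(i, 12); l.iy = desc(i, 13); l.iz = desc(i, 14);
    l.ox = desc(i, 15); l.oy = desc(i, 16); l.oz = desc(i, 17);
    l.to = desc(i, 18); l.tl = desc(i, 19);
    l.so = desc(i, 20); l.sl = desc(i, 21);
    l.drop = (float)drop_rates[i];
  }
  return L;
}

// Unpack input patches of one sample into columns (rows indexed c-fastest,
// then dx, dy, dz to match the weight matrix layout). Out-of-volume taps
// (same padding) read zero.
static void im2col(const float* x, const Layer& L, float* col) {
  const int C = L.in_c, IX = L.ix, IY = L.iy, IZ = L.iz;
  const int KX = L.kx, KY = L.kx, KZ = L.kz;
  const long R = L.krows();
  long p = 0;
  for (int oz = 0; oz < L.oz; ++oz)
    for (int oy = 0; oy < L.oy; ++oy)
      for (int ox = 0; ox < L.ox; ++ox, ++p) {
        float* cp = col + p * R;
        const int bx = ox * L.s - L.plo, by = oy * L.s - L.plo,
                  bz = oz * L.sz - L.plo_z;
        // clamp the tap ranges once per window; zero-fill the padded taps
        const int dx0 = bx < 0 ? -bx : 0, dx1 = std::min(KX, IX - bx);
        const int dy0 = by < 0 ? -by : 0, dy1 = std::min(KY, IY - by);
        const int dz0 = bz < 0 ? -bz : 0, dz1 = std::min(KZ, IZ - bz);
        if (dx0 > 0 || dx1 < KX || dy0 > 0 || dy1 < KY || dz0 > 0 || dz1 < KZ)
          std::memset(cp, 0, sizeof(float) * R);
        const float* base = x + (long)C * (bx + (long)IX * (by + (long)IY * bz));
        for (int dz = dz0; dz < dz1; ++dz) {
          const float* pz = base + (long)C * IX * IY * dz;
          float* cz = cp + (long)C * KX * KY * dz;
          for (int dy = dy0; dy < dy1; ++dy) {
            const float* py = pz + (long)C * IX * dy;
            float* cy = cz + (long)C * KX * dy;
            if (C == 1) {
              for (int dx = dx0; dx < dx1; ++dx) cy[dx] = py[dx];
            } else {
              std::memcpy(cy + (long)C * dx0, py + (long)C * dx0,
                          sizeof(float) * C * (dx1 - dx0));
            }
          }
        }
      }
}

// Adjoint of im2col: scatter-add column gradients back onto the input grid.
static void col2im(const float* col, const Layer& L, float* dx) {
  const int C = L.in_c, IX = L.ix, IY = L.iy, IZ = L.iz;
  const int KX = L.kx, KY = L.kx, KZ = L.kz;
  const long R = L.krows();
  long p = 0;
  for (int oz = 0; oz < L.oz; ++oz)
    for (int oy = 0; oy < L.oy; ++oy)
      for (int ox = 0; ox < L.ox; ++ox, ++p) {
        const float* cp = col + p * R;
        const int bx = ox * L.s - L.plo, by = oy * L.s - L.plo,
                  bz = oz * L.sz - L.plo_z;
        const int dx0 = bx < 0 ? -bx : 0, dx1 = std::min(KX, IX - bx);
        const int dy0 = by < 0 ? -by : 0, dy1 = std::min(KY, IY - by);
        const int dz0 = bz < 0 ? -bz : 0, dz1 = std::min(KZ, IZ - bz);
        float* base = dx + (long)C * (bx + (long)IX * (by + (long)IY * bz));
        for (int dz = dz0; dz < dz1; ++dz) {
          float* pz = base + (long)C * IX * IY * dz;
          const float* cz = cp + (long)C * KX * KY * dz;
          for (int dy = dy0; dy < dy1; ++dy) {
            float* py = pz + (long)C * IX * dy;
            const float* cy = cz + (long)C * KX * dy;
            const long n = (long)C * (dx1 - dx0);
            float* dst = py + (long)C * dx0;
            const float* src = cy + (long)C * dx0;
            for (long k = 0; k < n; ++k) dst[k] += src[k];
          }
        }
      }
}

struct Caches {
  std::vector<fmat> act;                 // act[0] = input, act[l+1] = layer l output
  std::vector<fmat> bn_xhat;             // per BN layer (indexed by layer)
  std::vector<fvec> bn_invstd;
  std::vector<arma::umat> pool_idx;      // argmax linear index within sample column
  std::vector<fmat> drop_mask;
  std::vector<fmat> conv_col;            // cached im2col columns (training only)
  bool keep_cols = false;
};

// Forward pass over all layers. training=true uses batch BN statistics
// (recorded into batch_mu/batch_var), applies dropout; training=false uses
// running statistics and no dropout.
static void net_forward(const std::vector<Layer>& Ls, const fvec& theta,
                        const fvec& state, const fmat& X, bool training,
                        int dropout_seed, Caches& C,
                        std::vector<fvec>* batch_mu, std::vector<fvec>* batch_var) {
  const int B = X.n_cols;
  const int nL = Ls.size();
  C.act.assign(nL + 1, fmat());
  C.bn_xhat.assign(nL, fmat());
  C.bn_invstd.assign(nL, fvec());
  C.pool_idx.assign(nL, arma::umat());
  C.drop_mask.assign(nL, fmat());
  C.conv_col.assign(nL, fmat());
  if (batch_mu) { batch_mu->assign(nL, fvec()); batch_var->assign(nL, fvec()); }
  C.act[0] = X;

  for (int li = 0; li < nL; ++li) {
    const Layer& L = Ls[li];
    const fmat& A = C.act[li];
    fmat& O = C.act[li + 1];

    switch (L.kind) {
    case K_CONV: {
      const long R = L.krows(), P = L.pos_out();
      O.set_size(L.fout(), B);
      const fmat W(const_cast<float*>(theta.memptr() + L.to), L.out_c, R, false, true);
      const fvec b(const_cast<float*>(theta.memptr() + L.to + (long)L.out_c * R),
                   L.out_c, false, true);
      // during training keep the unpacked columns so backward can reuse them;
      // the (R x P*B) column block and the (out_c*P x B) output share the
      // same memory layout, so the whole batch is one GEMM
      fmat scratch;
      fmat& CB = C.keep_cols ? C.conv_col[li] : scratch;
      CB.set_size(R, C.keep_cols ? P * B : P);
      if (C.keep_cols) {
        for (int s = 0; s < B; ++s) im2col(A.colptr(s), L, CB.colptr((long)s * P));
        fmat Yall(O.memptr(), L.out_c, P * (long)B, false, true);
        Yall = W * CB;
        Yall.each_col() += b;
      } else {
        for (int s = 0; s < B; ++s) {
          im2col(A.colptr(s), L, CB.colptr(0));
          fmat Y(O.colptr(s), L.out_c, P, false, true);
          Y = W * CB;
          Y.each_col() += b;
        }
      }
      if (L.act) O.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      break;
    }
    case K_BN: {
      const int Cc = L.out_c;
      const long P = L.pos_out();
      const long N = P * (long)B;
      const fvec g(const_cast<float*>(theta.memptr() + L.to), Cc, false, true);
      const fvec be(const_cast<float*>(theta.memptr() + L.to + Cc), Cc, false, true);
      fvec mu(Cc), var(Cc);
      if (training) {
        mu.zeros(); var.zeros();
        for (int s = 0; s < B; ++s) {
          const float* a = A.colptr(s);
          for (long p = 0; p < P; ++p)
            for (int c = 0; c < Cc; ++c) mu[c] += a[c + (long)Cc * p];
        }
        mu /= (float)N;
        for (int s = 0; s < B; ++s) {
          const float* a = A.colptr(s);
          for (long p = 0; p < P; ++p)
            for (int c = 0; c < Cc; ++c) {
              const float d = a[c + (long)Cc * p] - mu[c];
              var[c] += d * d;
            }
        }
        var /= (float)N;
        if (batch_mu) { (*batch_mu)[li] = mu; (*batch_var)[li] = var; }
      } else {
        mu = fvec(const_cast<float*>(state.memptr() + L.so), Cc);
        var = fvec(const_cast<float*>(state.memptr() + L.so + Cc), Cc);
      }
      fvec inv = 1.0f / arma::sqrt(var + BN_EPS);
      C.bn_invstd[li] = inv;
      O.set_size(A.n_rows, B);
      if (training) C.bn_xhat[li].set_size(A.n_rows, B);
      for (int s = 0; s < B; ++s) {
        const float* a = A.colptr(s);
        float* o = O.colptr(s);
        float* xh = training ? C.bn_xhat[li].colptr(s) : nullptr;
        for (long p = 0; p < P; ++p)
          for (int c = 0; c < Cc; ++c) {
            const long k = c + (long)Cc * p;
            const float v = (a[k] - mu[c]) * inv[c];
            if (xh) xh[k] = v;
            o[k] = g[c] * v + be[c];
          }
      }
      break;
    }
    case K_POOL: {
      const int Cc = L.in_c;
      O.set_size(L.fout(), B);
      C.pool_idx[li].set_size(L.fout(), B);
      for (int s = 0; s < B; ++s) {
        const float* a = C.act[li].colptr(s);
        float* o = O.colptr(s);
        arma::uword* ip = C.pool_idx[li].colptr(s);
        long q = 0;
        for (int oz = 0; oz < L.oz; ++oz)
          for (int oy = 0; oy < L.oy; ++oy)
            for (int ox = 0; ox < L.ox; ++ox)
              for (int c = 0; c < Cc; ++c, ++q) {
                float best = -std::numeric_limits<float>::infinity();
                long bidx = -1;
                for (int dz = 0; dz < L.kz; ++dz) {
                  const int zz = oz * L.sz + dz;
                  if (zz >= L.iz) continue;
                  for (int dy = 0; dy < L.kx; ++dy) {
                    const int yy = oy * L.s + dy;
                    if (yy >= L.iy) continue;
                    for (int dx = 0; dx < L.kx; ++dx) {
                      const int xx = ox * L.s + dx;
                      if (xx >= L.ix) continue;
                      const long k = c + (long)Cc * (xx + (long)L.ix * (yy + (long)L.iy * zz));
                      if (a[k] > best) { best = a[k]; bidx = k; }
                    }
                  }
                }
                o[q] = best;
                ip[q] = (arma::uword)bidx;
              }
      }
      break;
    }
    case K_GAP: {
      const int Cc = L.in_c;
      const long P = (long)L.ix * L.iy * L.iz;
      O.set_size(Cc, B);
      for (int s = 0; s < B; ++s) {
        const float* a = C.act[li].colptr(s);
        float* o = O.colptr(s);
        for (int c = 0; c < Cc; ++c) o[c] = 0.0f;
        for (long p = 0; p < P; ++p)
          for (int c = 0; c < Cc; ++c) o[c] += a[c + (long)Cc * p];
        for (int c = 0; c < Cc; ++c) o[c] /= (float)P;
      }
      break;
    }
    case K_FLAT:
      O = A;
      break;
    case K_DENSE: {
      const fmat W(const_cast<float*>(theta.memptr() + L.to), L.out_c, L.in_c, false, true);
      const fvec b(const_cast<float*>(theta.memptr() + L.to + (long)L.out_c * L.in_c),
                   L.out_c, false, true);
      O = W * A;
      O.each_col() += b;
      if (L.act) O.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      break;
    }
    case K_DROP: {
      if (training && L.drop > 0.0f) {
        std::mt19937 rng((unsigned)(dropout_seed + 1000003L * (li + 1)));
        std::uniform_real_distribution<float> U(0.0f, 1.0f);
        const float keep = 1.0f - L.drop;
        fmat& M = C.drop_mask[li];
        M.set_size(A.n_rows, B);
        for (arma::uword k = 0; k < M.n_elem; ++k)
          M[k] = (U(rng) < keep) ? 1.0f / keep : 0.0f;
        O = A % M;
      } else {
        O = A;
      }
      break;
    }
    default:
      stop("unknown layer kind %d", L.kind);
    }
  }
}

// Backward pass from dTop = d(objective)/d(final output). Accumulates
// parameter gradients into grad (when accumulate_grads) and stops early once
// the gradient at layer stop_at's *output* is available (stop_at is a 0-based
// layer index, or -1 to run to the input). Returns the gradient at the
// stopping activation.
static fmat net_backward(const std::vector<Layer>& Ls, const fvec& theta,
                         const Caches& C, fmat dTop, bool training,
                         fvec* grad, int stop_at,
                         const std::vector<fvec>* batch_var_unused = nullptr) {
  const int nL = Ls.size();
  const int B = dTop.n_cols;
  fmat dO = std::move(dTop);
  for (int li = nL - 1; li >= 0; --li) {
    if (li == stop_at) return dO;   // dO is gradient w.r.t. act[li+1]
    const Layer& L = Ls[li];
    const fmat& A = C.act[li];
    const fmat& O = C.act[li + 1];
    fmat dA;
    switch (L.kind) {
    case K_CONV: {
      if (L.act) {
        const float* o = O.memptr();
        float* d = dO.memptr();
        const arma::uword n = dO.n_elem;
        for (arma::uword k = 0; k < n; ++k) if (o[k] <= 0.0f) d[k] = 0.0f;
      }
      const long R = L.krows(), P = L.pos_out();
      const fmat W(const_cast<float*>(theta.memptr() + L.to), L.out_c, R, false, true);
      const bool need_dx = li > 0;   // input gradient of the first layer is unused
      if (need_dx) dA.zeros(L.fin(), B);
      fmat col(R, P), dcol(R, P);
      fmat dWt(R, L.out_c, arma::fill::zeros);   // transposed accumulator: faster GEMM shape
      fvec db(L.out_c, arma::fill::zeros);
      const fmat Wt = W.t();
      const bool cached = C.keep_cols && C.conv_col[li].n_elem > 0;
      if (cached && grad) {
        // whole-batch GEMMs over the cached column block
        const fmat dYall(const_cast<float*>(dO.memptr()), L.out_c, P * (long)B,
                         false, true);
        dWt = C.conv_col[li] * dYall.t();
        db = arma::sum(dYall, 1);
        if (need_dx) {
          for (int s = 0; s < B; ++s) {
            const fmat dY(const_cast<float*>(dO.colptr(s)), L.out_c, P, false, true);
            dcol = Wt * dY;
            col2im(dcol.memptr(), L, dA.colptr(s));
          }
        }
      } else {
        for (int s = 0; s < B; ++s) {
          const fmat dY(const_cast<float*>(dO.colptr(s)), L.out_c, P, false, true);
          if (grad) {
            const float* colp;
            if (cached) {
              colp = C.conv_col[li].colptr((long)s * P);
            } else {
              im2col(A.colptr(s), L, col.memptr());
              colp = col.memptr();
            }
            const fmat colv(const_cast<float*>(colp), R, P, false, true);
            dWt += colv * dY.t();
            db += arma::sum(dY, 1);
          }
          if (need_dx) {
            dcol = Wt * dY;
            col2im(dcol.memptr(), L, dA.colptr(s));
          }
        }
      }
      if (grad) {
        float* g = grad->memptr() + L.to;
        const long nw = (long)L.out_c * R;
        for (int oc = 0; oc < L.out_c; ++oc)
          for (long r = 0; r < R; ++r) g[oc + L.out_c * r] += dWt(r, oc);
        for (int k = 0; k < L.out_c; ++k) g[nw + k] += db[k];
      }
      break;
    }
    case K_BN: {
      const int Cc = L.out_c;
      const long P = L.pos_out();
      const long N = P * (long)B;
      const fvec g(const_cast<float*>(theta.memptr() + L.to), Cc, false, true);
      const fvec& inv = C.bn_invstd[li];
      dA.set_size(A.n_rows, B);
      if (training) {
        const fmat& xh = C.bn_xhat[li];
        fvec sdy(Cc, arma::fill::zeros), sdyx(Cc, arma::fill::zeros);
        fvec dg(Cc, arma::fill::zeros), dbe(Cc, arma::fill::zeros);
        for (int s = 0; s < B; ++s) {
          const float* d = dO.colptr(s);
          const float* x = xh.colptr(s);
          for (long p = 0; p < P; ++p)
            for (int c = 0; c < Cc; ++c) {
              const long k = c + (long)Cc * p;
              sdy[c] += d[k];
              sdyx[c] += d[k] * x[k];
            }
        }
        dg = sdyx; dbe = sdy;
        for (int s = 0; s < B; ++s) {
          const float* d = dO.colptr(s);
          const float* x = xh.colptr(s);
          float* o = dA.colptr(s);
          for (long p = 0; p < P; ++p)
            for (int c = 0; c < Cc; ++c) {
              const long k = c + (long)Cc * p;
              o[k] = g[c] * inv[c] *
                     (d[k] - sdy[c] / (float)N - x[k] * sdyx[c] / (float)N);
            }
        }
        if (grad) {
          float* gp = grad->memptr() + L.to;
          for (int c = 0; c < Cc; ++c) { gp[c] += dg[c]; gp[Cc + c] += dbe[c]; }
        }
      } else {
        for (int s = 0; s < B; ++s) {
          const float* d = dO.colptr(s);
          float* o = dA.colptr(s);
          for (long p = 0; p < P; ++p)
            for (int c = 0; c < Cc; ++c) {
              const long k = c + (long)Cc * p;
              o[k] = d[k] * g[c] * inv[c];
            }
        }
      }
      break;
    }
    case K_POOL: {
      dA.zeros(L.fin(), B);
      for (int s = 0; s < B; ++s) {
        const float* d = dO.colptr(s);
        const arma::uword* ip = C.pool_idx[li].colptr(s);
        float* o = dA.colptr(s);
        for (long q = 0; q < (long)L.fout(); ++q) o[ip[q]] += d[q];
      }
      break;
    }
    case K_GAP: {
      const int Cc = L.in_c;
      const long P = (long)L.ix * L.iy * L.iz;
      dA.set_size(L.fin(), B);
      for (int s = 0; s < B; ++s) {
        const float* d = dO.colptr(s);
        float* o = dA.colptr(s);
        for (long p = 0; p < P; ++p)
          for (int c = 0; c < Cc; ++c) o[c + (long)Cc * p] = d[c] / (float)P;
      }
      break;
    }
    case K_FLAT:
      dA = std::move(dO);
      break;
    case K_DENSE: {
      if (L.act) {
        const float* o = O.memptr();
        float* d = dO.memptr();
        for (arma::uword k = 0; k < dO.n_elem; ++k) if (o[k] <= 0.0f) d[k] = 0.0f;
      }
      const fmat W(const_cast<float*>(theta.memptr() + L.to), L.out_c, L.in_c, false, true);
      if (grad) {
        fmat dW = dO * A.t();
        fvec db = arma::sum(dO, 1);
        float* gp = grad->memptr() + L.to;
        const long nw = (long)L.out_c * L.in_c;
        for (long k = 0; k < nw; ++k) gp[k] += dW[k];
        for (int k = 0; k < L.out_c; ++k) gp[nw + k] += db[k];
      }
      dA = W.t() * dO;
      break;
    }
    case K_DROP: {
      if (training && L.drop > 0.0f) dA = dO % C.drop_mask[li];
      else dA = std::move(dO);
      break;
    }
    }
    dO = std::move(dA);
  }
  return dO;
}

static fvec as_fvec(const NumericVector& v) {
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static fmat as_fmat(const NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (R_xlen_t i = 0; i < (R_xlen_t)m.nrow() * m.ncol(); ++i) out[i] = (float)m[i];
  return out;
}

// Forward pass in inference mode; returns pre-softmax scores (classes x batch).
// [[Rcpp::export]]
NumericMatrix cpp_forward(IntegerMatrix desc, NumericVector drop_rates,
                          NumericVector theta, NumericVector state,
                          NumericMatrix X) {
  std::vector<Layer> Ls = parse_desc(desc, drop_rates);
  fvec th = as_fvec(theta), st = as_fvec(state);
  fmat Xf = as_fmat(X);
  Caches C;
  net_forward(Ls, th, st, Xf, false, 0, C, nullptr, nullptr);
  const fmat& S = C.act.back();
  NumericMatrix out(S.n_rows, S.n_cols);
  for (arma::uword i = 0; i < S.n_elem; ++i) out[i] = S[i];
  return out;
}

// One training step: forward (batch BN stats, dropout), softmax cross-entropy
// loss, full backward. Returns loss, scores, parameter gradient, and the
// updated running-statistics vector.
// [[Rcpp::export]]
List cpp_train_step(IntegerMatrix desc, NumericVector drop_rates,
                    NumericVector theta, NumericVector state,
                    NumericMatrix X, IntegerVector y,
                    double bn_momentum, int dropout_seed) {
  std::vector<Layer> Ls = parse_desc(desc, drop_rates);
  fvec th = as_fvec(theta), st = as_fvec(state);
  fmat Xf = as_fmat(X);
  const int B = Xf.n_cols;
  Caches C;
  C.keep_cols = true;
  std::vector<fvec> bmu, bvar;
  net_forward(Ls, th, st, Xf, true, dropout_seed, C, &bmu, &bvar);
  const fmat& S = C.act.back();
  const int nc = S.n_rows;

  // stable softmax + mean cross-entropy
  fmat P(nc, B);
  double loss = 0.0;
  for (int s = 0; s < B; ++s) {
    float m = S.col(s).max();
    double den = 0.0;
    for (int c = 0; c < nc; ++c) den += std::exp((double)(S(c, s) - m));
    for (int c = 0; c < nc; ++c) P(c, s) = (float)(std::exp((double)(S(c, s) - m)) / den);
    loss += -std::log(std::max((double)P(y[s], s), 1e-30));
  }
  loss /= B;

  fmat dS = P;
  for (int s = 0; s < B; ++s) dS(y[s], s) -= 1.0f;
  dS /= (float)B;

  fvec grad(th.n_elem, arma::fill::zeros);
  net_backward(Ls, th, C, dS, true, &grad, -1);

  // running-statistics update (biased batch variance, exponential average)
  for (size_t li = 0; li < Ls.size(); ++li) {
    const Layer& L = Ls[li];
    if (L.kind != K_BN) continue;
    for (int c = 0; c < L.out_c; ++c) {
      st[L.so + c] = (float)(bn_momentum * st[L.so + c] + (1 - bn_momentum) * bmu[li][c]);
      st[L.so + L.out_c + c] =
          (float)(bn_momentum * st[L.so + L.out_c + c] + (1 - bn_momentum) * bvar[li][c]);
    }
  }

  NumericVector gout(grad.n_elem), stout(st.n_elem);
  for (arma::uword i = 0; i < grad.n_elem; ++i) gout[i] = grad[i];
  for (arma::uword i = 0; i < st.n_elem; ++i) stout[i] = st[i];
  NumericMatrix sout(S.n_rows, S.n_cols);
  for (arma::uword i = 0; i < S.n_elem; ++i) sout[i] = S[i];
  return List::create(_["loss"] = loss, _["scores"] = sout,
                      _["grad"] = gout, _["state"] = stout);
}

// Grad-CAM tap: inference-mode forward on a single volume, then backward of
// the selected pre-softmax class score down to the output of target_layer
// (1-based). Returns that layer's activations and d(score)/d(activations),
// both with dim (channels, x, y, z).
// [[Rcpp::export]]
List cpp_gradcam(IntegerMatrix desc, NumericVector drop_rates,
                 NumericVector theta, NumericVector state,
                 NumericVector x, int class_index0, int target_layer1) {
  std::vector<Layer> Ls = parse_desc(desc, drop_rates);
  fvec th = as_fvec(theta), st = as_fvec(state);
  fmat Xf(x.size(), 1);
  for (R_xlen_t i = 0; i < x.size(); ++i) Xf(i, 0) = (float)x[i];
  Caches C;
  net_forward(Ls, th, st, Xf, false, 0, C, nullptr, nullptr);
  const fmat& S = C.act.back();
  if (class_index0 < 0 || class_index0 >= (int)S.n_rows)
    stop("class index out of range");
  const int ti = target_layer1 - 1;
  if (ti < 0 || ti >= (int)Ls.size()) stop("target layer out of range");

  fmat dTop(S.n_rows, 1, arma::fill::zeros);
  dTop(class_index0, 0) = 1.0f;
  fmat dA = net_backward(Ls, th, C, dTop, false, nullptr, ti);

  const Layer& L = Ls[ti];
  NumericVector A(L.fout()), G(L.fout());
  const fmat& Af = C.act[ti + 1];
  for (long k = 0; k < (long)L.fout(); ++k) { A[k] = Af(k, 0); G[k] = dA(k, 0); }
  IntegerVector dm = IntegerVector::create(L.out_c, L.ox, L.oy, L.oz);
  A.attr("dim") = dm;
  G.attr("dim") = dm;
  NumericVector scores(S.n_rows);
  for (arma::uword i = 0; i < S.n_rows; ++i) scores[i] = S(i, 0);
  return List::create(_["activations"] = A, _["gradients"] = G,
                      _["scores"] = scores);
}
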