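// Convolutional encoder stack: forward and backward passes.
//
// Architecture (fixed topology, sizes set by the R-side encoder_spec):
//   layer 1   : 3x3 conv (pad 1, stride 1) + ELU
//   layers 2+ : 3x3 conv (pad 1, stride 1) + ELU + 2x2 max-pool (floor)
//   head      : global average pool over the spatial grid -> h (length = last width)
//
// The whole batch is processed in one matrix per layer: feature maps are
// (M*F*T) x C matrices whose row block i*F*T .. (i+1)*F*T - 1 is sample i,
// with rows indexed f + F*t (column-major over the F x T grid).  im2col
// patch columns are indexed q = ki + 3*kj + 9*cin, matching the memory
// order of the R weight arrays dim(3, 3, in, out), so a weight array maps
// onto a (9*in) x out matrix by a straight copy and each convolution is a
// single GEMM over the batch.
//
// Caches for the backward pass live on the C++ heap behind an XPtr so a
// training step pays no R <-> C++ copy for intermediate activations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::uword;

static inline double elu1(double x) { return x > 0.0 ? x : std::expm1(x); }
// derivative of ELU in terms of the pre-activation
static inline double elu1_grad(double x) { return x > 0.0 ? 1.0 : std::exp(x); }

struct LayerCache {
  mat P;              // im2col patches, (M*F*T) x (9*Cin)
  mat Ypre;           // pre-activation, (M*F*T) x Cout
  arma::umat poolidx; // (M*Fp*Tp) x Cout, argmax row in the pre-pool map
  uword F, T, Cin, Cout, Fp, Tp;
  bool pooled;
};

struct BatchCache {
  std::vector<LayerCache> L;
  uword M, d;
};

// zero-padded 3x3 im2col of a batched map X ((M*F*T) x Cin) into
// P ((M*F*T) x (9*Cin))
static void im2col3(const mat& X, uword M, uword F, uword T, mat& P) {
  const uword Cin = X.n_cols, FT = F * T;
  P.zeros(M * FT, 9 * Cin);
  for (uword c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (uword kj = 0; kj < 3; ++kj) {
      for (uword ki = 0; ki < 3; ++ki) {
        const uword q = 9 * c + 3 * kj + ki;
        double* pc = P.colptr(q);
        // output (f, t) reads input (f + ki - 1, t + kj - 1)
        const long df = (long)ki - 1, dt = (long)kj - 1;
        const uword f0 = (df < 0) ? 1 : 0;           // first valid output f
        const uword f1 = (df > 0) ? F - 1 : F;       // one past last valid
        if (f1 <= f0) continue;
        for (uword i = 0; i < M; ++i) {
          const uword base = i * FT;
          for (uword t = 0; t < T; ++t) {
            const long ti = (long)t + dt;
            if (ti < 0 || ti >= (long)T) continue;
            const double* src = xc + base + (uword)ti * F + (f0 + df);
            double* dst = pc + base + t * F + f0;
            std::copy(src, src + (f1 - f0), dst);
          }
        }
      }
    }
  }
}

// transpose of im2col3: accumulate dP back onto the input grid
static void col2im3(const mat& dP, uword M, uword F, uword T, uword Cin,
                    mat& dX) {
  const uword FT = F * T;
  dX.zeros(M * FT, Cin);
  for (uword c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    for (uword kj = 0; kj < 3; ++kj) {
      for (uword ki = 0; ki < 3; ++ki) {
        const uword q = 9 * c + 3 * kj + ki;
        const double* pc = dP.colptr(q);
        const long df = (long)ki - 1, dt = (long)kj - 1;
        const uword f0 = (df < 0) ? 1 : 0;
        const uword f1 = (df > 0) ? F - 1 : F;
        if (f1 <= f0) continue;
        for (uword i = 0; i < M; ++i) {
          const uword base = i * FT;
          for (uword t = 0; t < T; ++t) {
            const long ti = (long)t + dt;
            if (ti < 0 || ti >= (long)T) continue;
            double* dst = xc + base + (uword)ti * F + (f0 + df);
            const double* src = pc + base + t * F + f0;
            for (uword k = 0; k < f1 - f0; ++k) dst[k] += src[k];
          }
        }
      }
    }
  }
}

static void pool2x2(const mat& A, uword M, uword F, uword T, mat& out,
                    arma::umat& idx, uword& Fp, uword& Tp) {
  Fp = F / 2; Tp = T / 2;
  const uword C = A.n_cols, FT = F * T, FTp = Fp * Tp;
  out.set_size(M * FTp, C);
  idx.set_size(M * FTp, C);
  for (uword c = 0; c < C; ++c) {
    const double* a = A.colptr(c);
    double* o = out.colptr(c);
    arma::uword* ix = idx.colptr(c);
    for (uword i = 0; i < M; ++i) {
      const uword bi = i * FT, bo = i * FTp;
      for (uword tp = 0; tp < Tp; ++tp) {
        for (uword fp = 0; fp < Fp; ++fp) {
          const uword base = bi + (2 * tp) * F + 2 * fp;
          uword best = base;
          double v = a[base];
          const uword cand[3] = { base + 1, base + F, base + F + 1 };
          for (int k = 0; k < 3; ++k)
            if (a[cand[k]] > v) { v = a[cand[k]]; best = cand[k]; }
          o[bo + tp * Fp + fp] = v;
          ix[bo + tp * Fp + fp] = best;
        }
      }
    }
  }
}

static void weights_to_mats(const List& weights, const List& biases,
                            std::vector<mat>& W, std::vector<arma::rowvec>& b) {
  const int L = weights.size();
  W.resize(L); b.resize(L);
  for (int l = 0; l < L; ++l) {
    NumericVector w = weights[l];
    IntegerVector dm = w.attr("dim");
    if (dm.size() != 4 || dm[0] != 3 || dm[1] != 3)
      stop("conv weight %d must be a 3 x 3 x in x out array", l + 1);
    const uword cin = dm[2], cout = dm[3];
    W[l] = mat(w.begin(), 9 * cin, cout); // copies
    NumericVector bb = biases[l];
    if ((uword)bb.size() != cout)
      stop("conv bias %d has length %d, expected %d", l + 1, (int)bb.size(),
           (int)cout);
    b[l] = arma::rowvec(bb.begin(), cout);
  }
}

// [[Rcpp::export]]
List cnn_forward_cpp(NumericVector x, List weights, List biases,
                     bool want_cache) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("spectrogram batch must be a 4-d array (F, T, C, M)");
  const uword F0 = dm[0], T0 = dm[1], C0 = dm[2], M = dm[3];
  std::vector<mat> W;
  std::vector<arma::rowvec> b;
  weights_to_mats(weights, biases, W, b);
  const int L = W.size();
  if (W[0].n_rows != 9 * C0)
    stop("first conv layer expects %d input channels, got %d",
         (int)(W[0].n_rows / 9), (int)C0);
  const uword d = W[L - 1].n_cols, FT0 = F0 * T0;

  // reorder the (F, T, C, M) array into the batched (M*F*T) x C layout
  mat X(M * FT0, C0);
  for (uword c = 0; c < C0; ++c) {
    double* dst = X.colptr(c);
    for (uword i = 0; i < M; ++i)
      std::copy(x.begin() + (i * C0 + c) * FT0,
                x.begin() + (i * C0 + c + 1) * FT0, dst + i * FT0);
  }

  BatchCache* cache = want_cache ? new BatchCache() : nullptr;
  if (cache) { cache->L.resize(L); cache->M = M; cache->d = d; }

  mat P, A, pooled;
  arma::umat pidx;
  uword F = F0, T = T0;
  for (int l = 0; l < L; ++l) {
    const uword Cin = W[l].n_rows / 9, Cout = W[l].n_cols;
    if (X.n_cols != Cin) stop("layer %d: channel mismatch", l + 1);
    im2col3(X, M, F, T, P);
    mat Ypre = P * W[l];
    Ypre.each_row() += b[l];
    A.set_size(Ypre.n_rows, Ypre.n_cols);
    {
      const double* yp = Ypre.memptr();
      double* ap = A.memptr();
      const uword n = Ypre.n_elem;
      for (uword k = 0; k < n; ++k) ap[k] = elu1(yp[k]);
    }
    LayerCache* lc = cache ? &cache->L[l] : nullptr;
    if (lc) { lc->P = std::move(P); lc->Ypre = std::move(Ypre);
              lc->F = F; lc->T = T; lc->Cin = Cin; lc->Cout = Cout;
              lc->pooled = (l >= 1); }
    if (l >= 1) {
      uword Fp, Tp;
      pool2x2(A, M, F, T, pooled, pidx, Fp, Tp);
      if (lc) { lc->poolidx = pidx; lc->Fp = Fp; lc->Tp = Tp; }
      X = std::move(pooled); F = Fp; T = Tp;
    } else {
      X = std::move(A);
    }
  }

  // global average pool per sample
  const uword FTl = F * T;
  mat H(M, d);
  for (uword c = 0; c < d; ++c) {
    const double* xc = X.colptr(c);
    for (uword i = 0; i < M; ++i) {
      double s = 0;
      for (uword k = 0; k < FTl; ++k) s += xc[i * FTl + k];
      H(i, c) = s / (double)FTl;
    }
  }

  List out = List::create(Named("h") = wrap(H));
  if (cache) {
    XPtr<BatchCache> ptr(cache, true);
    out["cache"] = ptr;
  } else {
    out["cache"] = R_NilValue;
  }
  return out;
}

// [[Rcpp::export]]
List cnn_backward_cpp(SEXP cacheptr, List weights, List biases,
                      NumericMatrix dH) {
  XPtr<BatchCache> cache(cacheptr);
  std::vector<mat> W;
  std::vector<arma::rowvec> b;
  weights_to_mats(weights, biases, W, b);
  const int L = W.size();
  const uword M = cache->M, d = cache->d;
  if ((uword)dH.nrow() != M || (uword)dH.ncol() != d)
    stop("dH must be %d x %d", (int)M, (int)d);

  std::vector<mat> gW(L);
  std::vector<arma::rowvec> gb(L);

  // through the global average pool
  const LayerCache& last = cache->L[L - 1];
  const uword FTl = (last.pooled ? last.Fp * last.Tp : last.F * last.T);
  mat dX(M * FTl, d);
  for (uword c = 0; c < d; ++c) {
    double* xc = dX.colptr(c);
    for (uword i = 0; i < M; ++i) {
      const double g = dH(i, c) / (double)FTl;
      for (uword k = 0; k < FTl; ++k) xc[i * FTl + k] = g;
    }
  }

  mat dA, dP;
  for (int l = L - 1; l >= 0; --l) {
    const LayerCache& lc = cache->L[l];
    if (lc.pooled) {
      // un-pool: scatter onto argmax positions
      dA.zeros(M * lc.F * lc.T, lc.Cout);
      for (uword c = 0; c < lc.Cout; ++c) {
        double* dst = dA.colptr(c);
        const double* src = dX.colptr(c);
        const arma::uword* id = lc.poolidx.colptr(c);
        const uword n = lc.poolidx.n_rows;
        for (uword k = 0; k < n; ++k) dst[id[k]] += src[k];
      }
    } else {
      dA = std::move(dX);
    }
    // through ELU
    {
      double* da = dA.memptr();
      const double* yp = lc.Ypre.memptr();
      const uword n = dA.n_elem;
      for (uword k = 0; k < n; ++k) da[k] *= elu1_grad(yp[k]);
    }
    gW[l] = lc.P.t() * dA;
    gb[l] = arma::sum(dA, 0);
    if (l > 0) {
      dP = dA * W[l].t();
      col2im3(dP, M, lc.F, lc.T, lc.Cin, dX);
    }
  }

  List gws(L), gbs(L);
  for (int l = 0; l < L; ++l) {
    const uword cin = W[l].n_rows / 9, cout = W[l].n_cols;
    NumericVector gw(gW[l].memptr(), gW[l].memptr() + gW[l].n_elem);
    gw.attr("dim") = IntegerVector::create(3, 3, cin, cout);
    gws[l] = gw;
    gbs[l] = NumericVector(gb[l].memptr(), gb[l].memptr() + cout);
  }
  return List::create(Named("dw") = gws, Named("db") = gbs);
}
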