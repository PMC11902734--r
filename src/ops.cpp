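// Numeric kernels for the segmentation network.
//
// Feature maps live on the C++ side as single-precision matrices wrapped in
// external pointers ("ft" handles): an FT holds values as a (C, H*W*N)
// column-major matrix, so the channel vector of each pixel is contiguous
// and a feature map batch (C, H, W, N) flattens naturally. R orchestrates
// the graph through handles; doubles cross the boundary only at the input,
// the head outputs, and parameter vectors.
//
// Conventions:
//   conv weight : matrix (Cout, Cin*k*k), column index c + Cin*(dh + k*dw)
//                 for kernel offset (dh, dw), 0-based
//   depthwise   : matrix (C, k*k), column index dh + k*dw
//   activations : 0 linear, 1 SiLU, 2 ReLU, 3 sigmoid
// Binary masks at the R level are H x W matrices indexed [y, x].

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <cmath>
#include <vector>
#ifdef __GLIBC__
#include <malloc.h>
#endif

// Keep large scratch buffers (im2col matrices, activation caches) on the
// process heap instead of returning them to the OS after every free; the
// buffers are reallocated at the same sizes every forward/backward pass.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
#endif
}

using namespace Rcpp;
typedef arma::fmat fmat;
typedef arma::fvec fvec;

struct FT {
  fmat v;  // C x (H*W*N)
  int C, H, W, N;
};
typedef XPtr<FT> FTP;

static SEXP wrap_ft(FT* t) { return FTP(t, true); }
static FT* get_ft(SEXP p) { return FTP(p).get(); }

// [[Rcpp::export]]
SEXP cpp_ft_new(NumericVector x, IntegerVector d) {
  FT* t = new FT;
  t->C = d[0]; t->H = d[1]; t->W = d[2]; t->N = d[3];
  t->v.set_size(t->C, (arma::uword)t->H * t->W * t->N);
  const double* p = x.begin();
  float* q = t->v.memptr();
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return wrap_ft(t);
}

// [[Rcpp::export]]
NumericVector cpp_ft_get(SEXP p) {
  FT* t = get_ft(p);
  NumericVector out(t->v.n_elem);
  const float* q = t->v.memptr();
  for (R_xlen_t i = 0; i < (R_xlen_t)t->v.n_elem; ++i) out[i] = q[i];
  out.attr("dim") = IntegerVector::create(t->C, t->H, t->W, t->N);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_ft_dim(SEXP p) {
  FT* t = get_ft(p);
  return IntegerVector::create(t->C, t->H, t->W, t->N);
}

static fmat to_fmat(const NumericVector& x, int nr, int nc) {
  fmat out(nr, nc);
  const double* p = x.begin();
  float* q = out.memptr();
  R_xlen_t n = (R_xlen_t)nr * nc;
  for (R_xlen_t i = 0; i < n; ++i) q[i] = (float)p[i];
  return out;
}

static NumericVector to_num(const fmat& m) {
  NumericVector out(m.n_elem);
  const float* p = m.memptr();
  for (R_xlen_t i = 0; i < (R_xlen_t)m.n_elem; ++i) out[i] = p[i];
  return out;
}

static inline int out_size(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// ---- im2col / col2im -------------------------------------------------------

// Patch-matrix columns for output pixels [l0, l0 + nt) written into a
// preallocated scratch tile; tiles keep the working set in cache instead
// of materializing the full (C*k*k) x (Ho*Wo*N) matrix.
static void im2col_tile(const fmat& x, int C, int H, int W,
                        int k, int s, int p, int Ho, int Wo,
                        R_xlen_t l0, int nt, fmat& colt) {
  colt.zeros();
  const float* xp = x.memptr();
  float* cp = colt.memptr();
  const R_xlen_t rows = (R_xlen_t)C * k * k;
  for (int t = 0; t < nt; ++t) {
    R_xlen_t l = l0 + t;
    int ho = (int)(l % Ho);
    R_xlen_t rest = l / Ho;
    int wo = (int)(rest % Wo);
    int n = (int)(rest / Wo);
    const float* xn = xp + (R_xlen_t)C * H * W * n;
    float* dst0 = cp + rows * t;
    for (int dw = 0; dw < k; ++dw) {
      int wi = wo * s - p + dw;
      if (wi < 0 || wi >= W) continue;
      for (int dh = 0; dh < k; ++dh) {
        int hi = ho * s - p + dh;
        if (hi < 0 || hi >= H) continue;
        std::copy(xn + (R_xlen_t)C * (hi + (R_xlen_t)H * wi),
                  xn + (R_xlen_t)C * (hi + (R_xlen_t)H * wi) + C,
                  dst0 + (R_xlen_t)C * (dh + k * dw));
      }
    }
  }
}

static void col2im_tile_add(const fmat& colt, int C, int H, int W,
                            int k, int s, int p, int Ho, int Wo,
                            R_xlen_t l0, int nt, fmat& gx) {
  const float* cp = colt.memptr();
  float* xp = gx.memptr();
  const R_xlen_t rows = (R_xlen_t)C * k * k;
  for (int t = 0; t < nt; ++t) {
    R_xlen_t l = l0 + t;
    int ho = (int)(l % Ho);
    R_xlen_t rest = l / Ho;
    int wo = (int)(rest % Wo);
    int n = (int)(rest / Wo);
    float* xn = xp + (R_xlen_t)C * H * W * n;
    const float* src0 = cp + rows * t;
    for (int dw = 0; dw < k; ++dw) {
      int wi = wo * s - p + dw;
      if (wi < 0 || wi >= W) continue;
      for (int dh = 0; dh < k; ++dh) {
        int hi = ho * s - p + dh;
        if (hi < 0 || hi >= H) continue;
        float* dst = xn + (R_xlen_t)C * (hi + (R_xlen_t)H * wi);
        const float* src = src0 + (R_xlen_t)C * (dh + k * dw);
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
}

// Tile width in columns: big enough for efficient GEMM even when the
// patch matrix has many rows (large kernels), small enough to keep the
// scratch near cache.
static int conv_tile_cols(R_xlen_t rows) {
  R_xlen_t budget = (R_xlen_t)1 << 19;  // floats (~2 MB)
  int t = (int)std::max((R_xlen_t)512, budget / std::max(rows, (R_xlen_t)1));
  return std::min(t, 8192);
}

static void conv_fwd_tiled(const fmat& x, const fmat& wm, fmat& y,
                           int C, int H, int W, int N,
                           int k, int s, int p, int Ho, int Wo) {
  R_xlen_t rows = (R_xlen_t)C * k * k;
  R_xlen_t L = (R_xlen_t)Ho * Wo * N;
  int tile = conv_tile_cols(rows);
  fmat colt(rows, tile);
  for (R_xlen_t l0 = 0; l0 < L; l0 += tile) {
    int nt = (int)std::min((R_xlen_t)tile, L - l0);
    im2col_tile(x, C, H, W, k, s, p, Ho, Wo, l0, nt, colt);
    y.cols(l0, l0 + nt - 1) = wm * colt.head_cols(nt);
  }
}

static void conv_bwd_tiled(const fmat& x, const fmat& wm, const fmat& g,
                           fmat& gw, fmat& gx,
                           int C, int H, int W, int N,
                           int k, int s, int p, int Ho, int Wo,
                           bool want_gx) {
  R_xlen_t rows = (R_xlen_t)C * k * k;
  R_xlen_t L = (R_xlen_t)Ho * Wo * N;
  int tile = conv_tile_cols(rows);
  fmat colt(rows, tile), gcolt;
  for (R_xlen_t l0 = 0; l0 < L; l0 += tile) {
    int nt = (int)std::min((R_xlen_t)tile, L - l0);
    im2col_tile(x, C, H, W, k, s, p, Ho, Wo, l0, nt, colt);
    gw += g.cols(l0, l0 + nt - 1) * colt.head_cols(nt).t();
    if (want_gx) {
      gcolt = wm.t() * g.cols(l0, l0 + nt - 1);
      col2im_tile_add(gcolt, C, H, W, k, s, p, Ho, Wo, l0, nt, gx);
    }
  }
}

// ---- fused conv + batch norm + activation ---------------------------------

struct CbsCache {
  fmat xhat;    // normalized pre-affine map (empty without bn)
  fmat pre;     // pre-activation map (empty for linear)
  fvec invstd;
};

// Logistic with the exponential argument clamped: expf overflows above
// ~88.7 and the overflowed reciprocal is not reliable under vectorization.
static inline float sigmoidf_safe(float x) {
  if (x < -80.0f) x = -80.0f;
  else if (x > 80.0f) x = 80.0f;
  return 1.0f / (1.0f + std::exp(-x));
}

static void act_apply(fmat& y, int act) {
  float* p = y.memptr();
  R_xlen_t n = y.n_elem;
  switch (act) {
  case 1: for (R_xlen_t i = 0; i < n; ++i) p[i] *= sigmoidf_safe(p[i]);
    break;
  case 2: for (R_xlen_t i = 0; i < n; ++i) p[i] = p[i] > 0 ? p[i] : 0; break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) p[i] = sigmoidf_safe(p[i]);
    break;
  default: break;
  }
}

static void act_bwd_inplace(fmat& g, const fmat& pre, int act) {
  float* gp = g.memptr();
  const float* zp = pre.memptr();
  R_xlen_t n = g.n_elem;
  switch (act) {
  case 1: for (R_xlen_t i = 0; i < n; ++i) {
      float s = sigmoidf_safe(zp[i]);
      gp[i] *= s * (1.0f + zp[i] * (1.0f - s)); } break;
  case 2: for (R_xlen_t i = 0; i < n; ++i) if (zp[i] <= 0) gp[i] = 0; break;
  case 3: for (R_xlen_t i = 0; i < n; ++i) {
      float s = sigmoidf_safe(zp[i]);
      gp[i] *= s * (1.0f - s); } break;
  default: break;
  }
}

// Normalize z in place (training statistics), returning xhat/invstd in the
// cache and the updated running moments. One accumulation pass (sum and
// sum of squares) plus one write pass.
static void bn_train(fmat& z, CbsCache* cc, NumericVector gamma,
                     NumericVector beta, std::vector<double>& rmean,
                     std::vector<double>& rvar, double eps, double mom) {
  int C = z.n_rows;
  R_xlen_t L = z.n_cols;
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  {
    const float* p = z.memptr();
    for (R_xlen_t l = 0; l < L; ++l) {
      const float* pc = p + (R_xlen_t)C * l;
      for (int c = 0; c < C; ++c) {
        s1[c] += pc[c];
        s2[c] += (double)pc[c] * pc[c];
      }
    }
  }
  fvec mean(C), ga(C), be(C);
  cc->invstd.set_size(C);
  for (int c = 0; c < C; ++c) {
    double m = s1[c] / L;
    double v = s2[c] / L - m * m;
    if (v < 0) v = 0;
    mean[c] = (float)m;
    cc->invstd[c] = (float)(1.0 / std::sqrt(v + eps));
    rmean[c] = (1 - mom) * rmean[c] + mom * m;
    double ub = L > 1 ? v * L / (L - 1) : v;
    rvar[c] = (1 - mom) * rvar[c] + mom * ub;
    ga[c] = (float)gamma[c];
    be[c] = (float)beta[c];
  }
  cc->xhat.set_size(C, L);
  float* hp = cc->xhat.memptr();
  float* zp = z.memptr();
  for (R_xlen_t l = 0; l < L; ++l) {
    float* zc = zp + (R_xlen_t)C * l;
    float* hc = hp + (R_xlen_t)C * l;
    for (int c = 0; c < C; ++c) {
      float h = (zc[c] - mean[c]) * cc->invstd[c];
      hc[c] = h;
      zc[c] = ga[c] * h + be[c];
    }
  }
}

static void bn_eval(fmat& z, NumericVector gamma, NumericVector beta,
                    NumericVector rmean, NumericVector rvar, double eps) {
  int C = z.n_rows;
  R_xlen_t L = z.n_cols;
  fvec sc(C), sh(C);
  for (int c = 0; c < C; ++c) {
    sc[c] = (float)(gamma[c] / std::sqrt(rvar[c] + eps));
    sh[c] = (float)(beta[c] - gamma[c] * rmean[c] / std::sqrt(rvar[c] + eps));
  }
  float* zp = z.memptr();
  for (R_xlen_t l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) {
      R_xlen_t i = (R_xlen_t)C * l + c;
      zp[i] = sc[c] * zp[i] + sh[c];
    }
}

// [[Rcpp::export]]
List cpp_cbs_fwd(SEXP xp, NumericVector w, NumericVector bias, bool has_bias,
                 int cout, int k, int s, int p, bool has_bn,
                 NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar,
                 double eps, double momentum, int act, bool training) {
  FT* x = get_ft(xp);
  int Ho = out_size(x->H, k, s, p), Wo = out_size(x->W, k, s, p);
  fmat wm = to_fmat(w, cout, (R_xlen_t)x->C * k * k);
  bool direct = (k == 1 && s == 1 && p == 0);
  FT* y = new FT;
  y->C = cout; y->H = Ho; y->W = Wo; y->N = x->N;
  CbsCache* cc = training ? new CbsCache : NULL;
  if (direct) {
    y->v = wm * x->v;
  } else {
    y->v.set_size(cout, (R_xlen_t)Ho * Wo * x->N);
    conv_fwd_tiled(x->v, wm, y->v, x->C, x->H, x->W, x->N, k, s, p,
                   Ho, Wo);
  }
  if (has_bias) {
    fvec b(cout);
    for (int c = 0; c < cout; ++c) b[c] = (float)bias[c];
    y->v.each_col() += b;
  }
  List out;
  if (has_bn) {
    if (training) {
      std::vector<double> rm(rmean.begin(), rmean.end());
      std::vector<double> rv(rvar.begin(), rvar.end());
      bn_train(y->v, cc, gamma, beta, rm, rv, eps, momentum);
      out["rmean"] = NumericVector(rm.begin(), rm.end());
      out["rvar"] = NumericVector(rv.begin(), rv.end());
    } else {
      bn_eval(y->v, gamma, beta, rmean, rvar, eps);
    }
  }
  if (training && act != 0) cc->pre = y->v;
  act_apply(y->v, act);
  out["y"] = wrap_ft(y);
  if (training)
    out["cache"] = XPtr<CbsCache>(cc, true);
  else if (cc) delete cc;
  return out;
}

// [[Rcpp::export]]
List cpp_cbs_bwd(SEXP xp, SEXP cachep, SEXP gyp, NumericVector w,
                 bool has_bias, int cout, int k, int s, int p, bool has_bn,
                 NumericVector gamma, int act, bool want_gx) {
  FT* x = get_ft(xp);
  XPtr<CbsCache> cc(cachep);
  FT* gy = get_ft(gyp);
  int Ho = gy->H, Wo = gy->W;
  List out;
  fmat g;
  if (has_bn) {
    // fused: activation backward + batch-norm sums in one pass, then the
    // normalization update in a second pass
    int C = gy->v.n_rows;
    R_xlen_t L = gy->v.n_cols;
    g.set_size(C, L);
    std::vector<double> sg(C, 0.0), sgh(C, 0.0);
    {
      const float* gp = gy->v.memptr();
      const float* zp = (act != 0) ? cc->pre.memptr() : NULL;
      const float* hp = cc->xhat.memptr();
      float* go = g.memptr();
      for (R_xlen_t l = 0; l < L; ++l) {
        R_xlen_t off = (R_xlen_t)C * l;
        for (int c = 0; c < C; ++c) {
          R_xlen_t i = off + c;
          float v = gp[i];
          if (act == 1) {
            float s = sigmoidf_safe(zp[i]);
            v *= s * (1.0f + zp[i] * (1.0f - s));
          } else if (act == 2) {
            if (zp[i] <= 0) v = 0;
          } else if (act == 3) {
            float s = sigmoidf_safe(zp[i]);
            v *= s * (1.0f - s);
          }
          go[i] = v;
          sg[c] += v;
          sgh[c] += (double)v * hp[i];
        }
      }
    }
    NumericVector ggamma(C), gbeta(C);
    for (int c = 0; c < C; ++c) { ggamma[c] = sgh[c]; gbeta[c] = sg[c]; }
    fvec sc(C); fvec m1(C); fvec m2(C);
    for (int c = 0; c < C; ++c) {
      sc[c] = (float)gamma[c] * cc->invstd[c];
      m1[c] = (float)(sg[c] / L);
      m2[c] = (float)(sgh[c] / L);
    }
    {
      float* gm = g.memptr();
      const float* hp = cc->xhat.memptr();
      for (R_xlen_t l = 0; l < L; ++l) {
        R_xlen_t off = (R_xlen_t)C * l;
        for (int c = 0; c < C; ++c) {
          R_xlen_t i = off + c;
          gm[i] = sc[c] * (gm[i] - m1[c] - hp[i] * m2[c]);
        }
      }
    }
    out["ggamma"] = ggamma;
    out["gbeta"] = gbeta;
  } else {
    g = gy->v;
    if (act != 0) act_bwd_inplace(g, cc->pre, act);
  }
  if (has_bias) {
    fvec gb = arma::sum(g, 1);
    out["gb"] = to_num(fmat(gb));
  }
  fmat wm = to_fmat(w, cout, (R_xlen_t)x->C * k * k);
  bool direct = (k == 1 && s == 1 && p == 0);
  FT* gx = new FT;
  gx->C = x->C; gx->H = x->H; gx->W = x->W; gx->N = x->N;
  if (direct) {
    out["gw"] = to_num(g * x->v.t());
    if (want_gx) gx->v = wm.t() * g;
    else gx->v.zeros(x->C, 1);
  } else {
    gx->v.zeros(x->C,
                want_gx ? (R_xlen_t)x->H * x->W * x->N : (R_xlen_t)1);
    fmat gw(cout, (R_xlen_t)x->C * k * k, arma::fill::zeros);
    conv_bwd_tiled(x->v, wm, g, gw, gx->v, x->C, x->H, x->W, x->N,
                   k, s, p, Ho, Wo, want_gx);
    out["gw"] = to_num(gw);
  }
  out["gx"] = wrap_ft(gx);
  return out;
}

// ---- fused depthwise conv + batch norm + activation -----------------------

static void dw_fwd_core(const FT* x, const fmat& wm, fmat& y,
                        int k, int s, int p, int Ho, int Wo) {
  int C = x->C, H = x->H, W = x->W, N = x->N;
  y.zeros(C, (R_xlen_t)Ho * Wo * N);
  const float* xp = x->v.memptr();
  const float* wf = wm.memptr();
  float* yp = y.memptr();
  for (int n = 0; n < N; ++n) {
    const float* xn = xp + (R_xlen_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        float* yq = yp + (R_xlen_t)C *
          (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int dw = 0; dw < k; ++dw) {
          int wi = wo * s - p + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int hi = ho * s - p + dh;
            if (hi < 0 || hi >= H) continue;
            const float* xq = xn + (R_xlen_t)C * (hi + (R_xlen_t)H * wi);
            const float* wq = wf + (R_xlen_t)C * (dh + k * dw);
            for (int c = 0; c < C; ++c) yq[c] += xq[c] * wq[c];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_dbs_fwd(SEXP xp, NumericVector w, int k, int s, int p, bool has_bn,
                 NumericVector gamma, NumericVector beta,
                 NumericVector rmean, NumericVector rvar,
                 double eps, double momentum, int act, bool training) {
  FT* x = get_ft(xp);
  int Ho = out_size(x->H, k, s, p), Wo = out_size(x->W, k, s, p);
  fmat wm = to_fmat(w, x->C, (R_xlen_t)k * k);
  FT* y = new FT;
  y->C = x->C; y->H = Ho; y->W = Wo; y->N = x->N;
  dw_fwd_core(x, wm, y->v, k, s, p, Ho, Wo);
  CbsCache* cc = training ? new CbsCache : NULL;
  List out;
  if (has_bn) {
    if (training) {
      std::vector<double> rm(rmean.begin(), rmean.end());
      std::vector<double> rv(rvar.begin(), rvar.end());
      bn_train(y->v, cc, gamma, beta, rm, rv, eps, momentum);
      out["rmean"] = NumericVector(rm.begin(), rm.end());
      out["rvar"] = NumericVector(rv.begin(), rv.end());
    } else {
      bn_eval(y->v, gamma, beta, rmean, rvar, eps);
    }
  }
  if (training && act != 0) cc->pre = y->v;
  act_apply(y->v, act);
  out["y"] = wrap_ft(y);
  if (training)
    out["cache"] = XPtr<CbsCache>(cc, true);
  else if (cc) delete cc;
  return out;
}

// [[Rcpp::export]]
List cpp_dbs_bwd(SEXP xp, SEXP cachep, SEXP gyp, NumericVector w,
                 int k, int s, int p, bool has_bn, NumericVector gamma,
                 int act) {
  FT* x = get_ft(xp);
  XPtr<CbsCache> cc(cachep);
  FT* gy = get_ft(gyp);
  int C = x->C, H = x->H, W = x->W, N = x->N;
  int Ho = gy->H, Wo = gy->W;
  fmat g = gy->v;
  if (act != 0) act_bwd_inplace(g, cc->pre, act);
  List out;
  if (has_bn) {
    R_xlen_t L = g.n_cols;
    std::vector<double> sg(C, 0.0), sgh(C, 0.0);
    const float* gp = g.memptr();
    const float* hp = cc->xhat.memptr();
    for (R_xlen_t l = 0; l < L; ++l)
      for (int c = 0; c < C; ++c) {
        R_xlen_t i = (R_xlen_t)C * l + c;
        sg[c] += gp[i]; sgh[c] += gp[i] * hp[i];
      }
    NumericVector ggamma(C), gbeta(C);
    for (int c = 0; c < C; ++c) { ggamma[c] = sgh[c]; gbeta[c] = sg[c]; }
    float* gm = g.memptr();
    for (R_xlen_t l = 0; l < L; ++l)
      for (int c = 0; c < C; ++c) {
        R_xlen_t i = (R_xlen_t)C * l + c;
        gm[i] = (float)gamma[c] * cc->invstd[c] *
          (gm[i] - (float)(sg[c] / L) - hp[i] * (float)(sgh[c] / L));
      }
    out["ggamma"] = ggamma;
    out["gbeta"] = gbeta;
  }
  fmat wm = to_fmat(w, C, (R_xlen_t)k * k);
  FT* gx = new FT;
  gx->C = C; gx->H = H; gx->W = W; gx->N = N;
  gx->v.zeros(C, (R_xlen_t)H * W * N);
  fmat gw(C, (R_xlen_t)k * k, arma::fill::zeros);
  const float* xv = x->v.memptr();
  const float* gp = g.memptr();
  float* gxp = gx->v.memptr();
  float* gwp = gw.memptr();
  const float* wp = wm.memptr();
  for (int n = 0; n < N; ++n) {
    const float* xn = xv + (R_xlen_t)C * H * W * n;
    float* gxn = gxp + (R_xlen_t)C * H * W * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const float* gq = gp + (R_xlen_t)C *
          (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int dw = 0; dw < k; ++dw) {
          int wi = wo * s - p + dw;
          if (wi < 0 || wi >= W) continue;
          for (int dh = 0; dh < k; ++dh) {
            int hi = ho * s - p + dh;
            if (hi < 0 || hi >= H) continue;
            const float* xq = xn + (R_xlen_t)C * (hi + (R_xlen_t)H * wi);
            float* gxq = gxn + (R_xlen_t)C * (hi + (R_xlen_t)H * wi);
            const float* wq = wp + (R_xlen_t)C * (dh + k * dw);
            float* gwq = gwp + (R_xlen_t)C * (dh + k * dw);
            for (int c = 0; c < C; ++c) {
              gxq[c] += gq[c] * wq[c];
              gwq[c] += gq[c] * xq[c];
            }
          }
        }
      }
    }
  }
  out["gw"] = to_num(gw);
  out["gx"] = wrap_ft(gx);
  return out;
}

// ---- pooling, upsampling, glue --------------------------------------------

// Max pooling, stride 1, same padding; cache holds flat argmax indices.
// [[Rcpp::export]]
List cpp_maxpool_fwd(SEXP xp, int k, bool training) {
  FT* x = get_ft(xp);
  int C = x->C, H = x->H, W = x->W, N = x->N;
  int p = (k - 1) / 2;
  FT* y = new FT;
  y->C = C; y->H = H; y->W = W; y->N = N;
  y->v.set_size(C, (R_xlen_t)H * W * N);
  IntegerVector amax(training ? x->v.n_elem : 0);
  const float* xv = x->v.memptr();
  float* yv = y->v.memptr();
  for (int n = 0; n < N; ++n) {
    R_xlen_t base = (R_xlen_t)C * H * W * n;
    for (int w0 = 0; w0 < W; ++w0) {
      for (int h0 = 0; h0 < H; ++h0) {
        for (int c = 0; c < C; ++c) {
          float best = -INFINITY; R_xlen_t bi = 0;
          for (int dw = 0; dw < k; ++dw) {
            int wi = w0 - p + dw;
            if (wi < 0 || wi >= W) continue;
            for (int dh = 0; dh < k; ++dh) {
              int hi = h0 - p + dh;
              if (hi < 0 || hi >= H) continue;
              R_xlen_t idx = base + c + (R_xlen_t)C * (hi + (R_xlen_t)H * wi);
              if (xv[idx] > best) { best = xv[idx]; bi = idx; }
            }
          }
          R_xlen_t o = base + c + (R_xlen_t)C * (h0 + (R_xlen_t)H * w0);
          yv[o] = best;
          if (training) amax[o] = (int)bi;
        }
      }
    }
  }
  return List::create(_["y"] = wrap_ft(y), _["amax"] = amax);
}

// [[Rcpp::export]]
SEXP cpp_maxpool_bwd(SEXP gyp, IntegerVector amax) {
  FT* gy = get_ft(gyp);
  FT* gx = new FT;
  gx->C = gy->C; gx->H = gy->H; gx->W = gy->W; gx->N = gy->N;
  gx->v.zeros(gy->C, gy->v.n_cols);
  const float* gp = gy->v.memptr();
  float* xp = gx->v.memptr();
  for (R_xlen_t i = 0; i < (R_xlen_t)gy->v.n_elem; ++i)
    xp[amax[i]] += gp[i];
  return wrap_ft(gx);
}

// [[Rcpp::export]]
SEXP cpp_upsample2_fwd(SEXP xp) {
  FT* x = get_ft(xp);
  int C = x->C, H = x->H, W = x->W, N = x->N;
  FT* y = new FT;
  y->C = C; y->H = 2 * H; y->W = 2 * W; y->N = N;
  y->v.set_size(C, (R_xlen_t)4 * H * W * N);
  const float* xv = x->v.memptr();
  float* yv = y->v.memptr();
  int Ho = 2 * H, Wo = 2 * W;
  for (int n = 0; n < N; ++n)
    for (int w0 = 0; w0 < Wo; ++w0)
      for (int h0 = 0; h0 < Ho; ++h0) {
        const float* src = xv + (R_xlen_t)C *
          ((h0 / 2) + (R_xlen_t)H * ((w0 / 2) + (R_xlen_t)W * n));
        float* dst = yv + (R_xlen_t)C *
          (h0 + (R_xlen_t)Ho * (w0 + (R_xlen_t)Wo * n));
        std::copy(src, src + C, dst);
      }
  return wrap_ft(y);
}

// [[Rcpp::export]]
SEXP cpp_upsample2_bwd(SEXP gyp) {
  FT* gy = get_ft(gyp);
  int C = gy->C, Ho = gy->H, Wo = gy->W, N = gy->N;
  int H = Ho / 2, W = Wo / 2;
  FT* gx = new FT;
  gx->C = C; gx->H = H; gx->W = W; gx->N = N;
  gx->v.zeros(C, (R_xlen_t)H * W * N);
  const float* gp = gy->v.memptr();
  float* xp = gx->v.memptr();
  for (int n = 0; n < N; ++n)
    for (int w0 = 0; w0 < Wo; ++w0)
      for (int h0 = 0; h0 < Ho; ++h0) {
        const float* src = gp + (R_xlen_t)C *
          (h0 + (R_xlen_t)Ho * (w0 + (R_xlen_t)Wo * n));
        float* dst = xp + (R_xlen_t)C *
          ((h0 / 2) + (R_xlen_t)H * ((w0 / 2) + (R_xlen_t)W * n));
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  return wrap_ft(gx);
}

// [[Rcpp::export]]
SEXP cpp_ft_cat(List parts) {
  int np = parts.size();
  std::vector<FT*> ts(np);
  int Ctot = 0;
  for (int i = 0; i < np; ++i) { ts[i] = get_ft(parts[i]); Ctot += ts[i]->C; }
  FT* y = new FT;
  y->C = Ctot; y->H = ts[0]->H; y->W = ts[0]->W; y->N = ts[0]->N;
  R_xlen_t L = ts[0]->v.n_cols;
  y->v.set_size(Ctot, L);
  float* yp = y->v.memptr();
  for (R_xlen_t l = 0; l < L; ++l) {
    float* dst = yp + (R_xlen_t)Ctot * l;
    for (int i = 0; i < np; ++i) {
      const float* src = ts[i]->v.memptr() + (R_xlen_t)ts[i]->C * l;
      std::copy(src, src + ts[i]->C, dst);
      dst += ts[i]->C;
    }
  }
  return wrap_ft(y);
}

// [[Rcpp::export]]
List cpp_ft_split(SEXP xp, IntegerVector sizes) {
  FT* x = get_ft(xp);
  R_xlen_t L = x->v.n_cols;
  List out(sizes.size());
  int off = 0;
  for (int i = 0; i < sizes.size(); ++i) {
    FT* y = new FT;
    y->C = sizes[i]; y->H = x->H; y->W = x->W; y->N = x->N;
    y->v.set_size(sizes[i], L);
    for (R_xlen_t l = 0; l < L; ++l)
      std::copy(x->v.memptr() + (R_xlen_t)x->C * l + off,
                x->v.memptr() + (R_xlen_t)x->C * l + off + sizes[i],
                y->v.memptr() + (R_xlen_t)sizes[i] * l);
    off += sizes[i];
    out[i] = wrap_ft(y);
  }
  return out;
}

// [[Rcpp::export]]
SEXP cpp_ft_add(SEXP ap, SEXP bp) {
  FT* a = get_ft(ap); FT* b = get_ft(bp);
  FT* y = new FT;
  y->C = a->C; y->H = a->H; y->W = a->W; y->N = a->N;
  y->v = a->v + b->v;
  return wrap_ft(y);
}

// [[Rcpp::export]]
SEXP cpp_ft_mul(SEXP ap, SEXP bp) {
  FT* a = get_ft(ap); FT* b = get_ft(bp);
  FT* y = new FT;
  y->C = a->C; y->H = a->H; y->W = a->W; y->N = a->N;
  y->v = a->v % b->v;
  return wrap_ft(y);
}

// Global average pool: C x N matrix of per-channel means.
// [[Rcpp::export]]
NumericMatrix cpp_ft_gap(SEXP xp) {
  FT* x = get_ft(xp);
  R_xlen_t hw = (R_xlen_t)x->H * x->W;
  NumericMatrix out(x->C, x->N);
  const float* p = x->v.memptr();
  for (int n = 0; n < x->N; ++n) {
    std::vector<double> acc(x->C, 0.0);
    const float* pn = p + (R_xlen_t)x->C * hw * n;
    for (R_xlen_t l = 0; l < hw; ++l)
      for (int c = 0; c < x->C; ++c) acc[c] += pn[(R_xlen_t)x->C * l + c];
    for (int c = 0; c < x->C; ++c) out(c, n) = acc[c] / hw;
  }
  return out;
}

// y = x scaled per channel by s (C x N).
// [[Rcpp::export]]
SEXP cpp_ft_scale_channels(SEXP xp, NumericMatrix s) {
  FT* x = get_ft(xp);
  FT* y = new FT;
  y->C = x->C; y->H = x->H; y->W = x->W; y->N = x->N;
  y->v.set_size(x->C, x->v.n_cols);
  R_xlen_t hw = (R_xlen_t)x->H * x->W;
  const float* p = x->v.memptr();
  float* q = y->v.memptr();
  for (int n = 0; n < x->N; ++n) {
    fvec sc(x->C);
    for (int c = 0; c < x->C; ++c) sc[c] = (float)s(c, n);
    const float* pn = p + (R_xlen_t)x->C * hw * n;
    float* qn = q + (R_xlen_t)x->C * hw * n;
    for (R_xlen_t l = 0; l < hw; ++l)
      for (int c = 0; c < x->C; ++c)
        qn[(R_xlen_t)x->C * l + c] = pn[(R_xlen_t)x->C * l + c] * sc[c];
  }
  return wrap_ft(y);
}

// Per-(channel, image) inner product of two maps: sum over H, W of a*b.
// [[Rcpp::export]]
NumericMatrix cpp_ft_dot_channels(SEXP ap, SEXP bp) {
  FT* a = get_ft(ap); FT* b = get_ft(bp);
  R_xlen_t hw = (R_xlen_t)a->H * a->W;
  NumericMatrix out(a->C, a->N);
  const float* pa = a->v.memptr();
  const float* pb = b->v.memptr();
  for (int n = 0; n < a->N; ++n) {
    std::vector<double> acc(a->C, 0.0);
    const float* an = pa + (R_xlen_t)a->C * hw * n;
    const float* bn = pb + (R_xlen_t)a->C * hw * n;
    for (R_xlen_t l = 0; l < hw; ++l)
      for (int c = 0; c < a->C; ++c)
        acc[c] += (double)an[(R_xlen_t)a->C * l + c] *
          bn[(R_xlen_t)a->C * l + c];
    for (int c = 0; c < a->C; ++c) out(c, n) = acc[c];
  }
  return out;
}

// y = x + broadcast of v (C x N) over H, W.
// [[Rcpp::export]]
SEXP cpp_ft_add_channels(SEXP xp, NumericMatrix v) {
  FT* x = get_ft(xp);
  FT* y = new FT;
  y->C = x->C; y->H = x->H; y->W = x->W; y->N = x->N;
  y->v = x->v;
  R_xlen_t hw = (R_xlen_t)x->H * x->W;
  float* q = y->v.memptr();
  for (int n = 0; n < x->N; ++n) {
    fvec vc(x->C);
    for (int c = 0; c < x->C; ++c) vc[c] = (float)v(c, n);
    float* qn = q + (R_xlen_t)x->C * hw * n;
    for (R_xlen_t l = 0; l < hw; ++l)
      for (int c = 0; c < x->C; ++c) qn[(R_xlen_t)x->C * l + c] += vc[c];
  }
  return wrap_ft(y);
}

// ---- general-purpose raster kernels (double precision, R arrays) ----------

// Bilinear resize with half-pixel sample centers, edge clamped;
// x is (C, H, W, N).
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(NumericVector x, IntegerVector xd,
                                  int Ho, int Wo) {
  int C = xd[0], H = xd[1], W = xd[2], N = xd[3];
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int n = 0; n < N; ++n) {
    for (int w0 = 0; w0 < Wo; ++w0) {
      double ws = (w0 + 0.5) * sw - 0.5;
      int w1 = (int)std::floor(ws);
      double fw = ws - w1;
      int w1c = std::min(std::max(w1, 0), W - 1);
      int w2c = std::min(std::max(w1 + 1, 0), W - 1);
      for (int h0 = 0; h0 < Ho; ++h0) {
        double hs = (h0 + 0.5) * sh - 0.5;
        int h1 = (int)std::floor(hs);
        double fh = hs - h1;
        int h1c = std::min(std::max(h1, 0), H - 1);
        int h2c = std::min(std::max(h1 + 1, 0), H - 1);
        double* dst = y.begin() +
          (R_xlen_t)C * (h0 + (R_xlen_t)Ho * (w0 + (R_xlen_t)Wo * n));
        const double* base = x.begin() + (R_xlen_t)C * H * W * n;
        const double* p11 = base + (R_xlen_t)C * (h1c + (R_xlen_t)H * w1c);
        const double* p21 = base + (R_xlen_t)C * (h2c + (R_xlen_t)H * w1c);
        const double* p12 = base + (R_xlen_t)C * (h1c + (R_xlen_t)H * w2c);
        const double* p22 = base + (R_xlen_t)C * (h2c + (R_xlen_t)H * w2c);
        for (int c = 0; c < C; ++c) {
          double a = p11[c] * (1 - fh) + p21[c] * fh;
          double b = p12[c] * (1 - fh) + p22[c] * fh;
          dst[c] = a * (1 - fw) + b * fw;
        }
      }
    }
  }
  return y;
}

// Even-odd polygon rasterization sampled at pixel centers (x+0.5, y+0.5).
// px, py in pixel coordinates; returns H x W integer mask [y, x], 1 inside.
// [[Rcpp::export]]
IntegerVector cpp_polygon_fill(NumericVector px, NumericVector py,
                               int height, int width) {
  IntegerVector mask((R_xlen_t)height * width);
  int nv = px.size();
  if (nv < 3) return mask;
  std::vector<double> xs;
  for (int y = 0; y < height; ++y) {
    double cy = y + 0.5;
    xs.clear();
    for (int i = 0; i < nv; ++i) {
      int j = (i + 1) % nv;
      double y1 = py[i], y2 = py[j];
      if ((y1 > cy) == (y2 > cy)) continue;
      double t = (cy - y1) / (y2 - y1);
      xs.push_back(px[i] + t * (px[j] - px[i]));
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    size_t m = xs.size();
    for (int x = 0; x < width; ++x) {
      double cx = x + 0.5;
      size_t lo = std::upper_bound(xs.begin(), xs.end(), cx) - xs.begin();
      if ((m - lo) % 2 == 1) mask[(R_xlen_t)y + (R_xlen_t)height * x] = 1;
    }
  }
  return mask;
}
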