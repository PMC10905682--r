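// Low-level 3D CNN kernels: conv3d (3x3x3, pad 1) via im2col + gemm,
// a fused head convolution exploiting spatially-constant prior planes,
// factor-k max pooling, and a fused batch gather + flip for
// augmentation.  Tensors are R arrays with dim (C, D, H, W, N) --
// channel fastest, batch slowest.  Compute is single precision; the R
// interface is double.  Forward passes can return an opaque cache of
// the im2col matrices that the matching backward pass reuses.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int out_len(int din, int stride) {
  // kernel 3, pad 1: floor((din + 2 - 3)/stride) + 1
  return (din - 1) / stride + 1;
}

// Border-class code per output index along one axis:
// bit 1 = low tap (d=0) out of bounds, bit 2 = high tap (d=2) out.
static inline int axis_class(int io, int stride, int din) {
  int lo = stride * io - 1;
  int cls = 0;
  if (lo < 0) cls += 1;
  if (lo + 2 >= din) cls += 2;
  return cls;
}

static inline bool tap_valid(int cls, int d) {
  if ((cls & 1) && d == 0) return false;
  if ((cls & 2) && d == 2) return false;
  return true;
}

struct ConvCache {
  int C, D, H, W, N, stride;
  std::vector<float> P;   // N blocks of (V x K) column-major
  size_t block = 0;       // V*K
};

// im2col for one sample into the float block `p` (V x K column-major),
// K = C*27.  Inner loops write each column contiguously.
static void im2col(const float* xf, int C, int D, int H, int W,
                   int stride, float* p) {
  const int Do = out_len(D, stride), Ho = out_len(H, stride), Wo = out_len(W, stride);
  const size_t V = (size_t)Do * Ho * Wo;
  for (int dk = 0; dk < 3; ++dk)
  for (int dj = 0; dj < 3; ++dj)
  for (int di = 0; di < 3; ++di) {
    const int off = di + 3 * (dj + 3 * dk);
    // valid output range along the first axis for this tap
    int io_lo = 0, io_hi = Do - 1;
    while (io_lo < Do && stride * io_lo + di - 1 < 0) ++io_lo;
    while (io_hi >= 0 && stride * io_hi + di - 1 >= D) --io_hi;
    for (int c = 0; c < C; ++c) {
      float* col = p + V * (size_t)(c + C * off);
      for (int ko = 0; ko < Wo; ++ko) {
        const int kin = stride * ko + dk - 1;
        if (kin < 0 || kin >= W) {
          std::fill(col + (size_t)Do * Ho * ko, col + (size_t)Do * Ho * (ko + 1), 0.0f);
          continue;
        }
        for (int jo = 0; jo < Ho; ++jo) {
          const int jin = stride * jo + dj - 1;
          float* dst = col + (size_t)Do * (jo + (size_t)Ho * ko);
          if (jin < 0 || jin >= H) {
            std::fill(dst, dst + Do, 0.0f);
            continue;
          }
          for (int io = 0; io < io_lo; ++io) dst[io] = 0.0f;
          const float* src = xf + c + (size_t)C * ((stride * io_lo + di - 1)
                               + (size_t)D * (jin + (size_t)H * kin));
          const int xstep = C * stride;
          for (int io = io_lo; io <= io_hi; ++io)
            dst[io] = src[(size_t)xstep * (io - io_lo)];
          for (int io = io_hi + 1; io < Do; ++io) dst[io] = 0.0f;
        }
      }
    }
  }
}

static void col2im_add(const arma::fmat& Gp, int C, int D, int H, int W,
                       int stride, float* gxf) {
  const int Do = out_len(D, stride), Ho = out_len(H, stride), Wo = out_len(W, stride);
  for (int dk = 0; dk < 3; ++dk)
  for (int dj = 0; dj < 3; ++dj)
  for (int di = 0; di < 3; ++di) {
    const int off = di + 3 * (dj + 3 * dk);
    for (int ko = 0; ko < Wo; ++ko) {
      const int kin = stride * ko + dk - 1;
      if (kin < 0 || kin >= W) continue;
      for (int jo = 0; jo < Ho; ++jo) {
        const int jin = stride * jo + dj - 1;
        if (jin < 0 || jin >= H) continue;
        for (int io = 0; io < Do; ++io) {
          const int iin = stride * io + di - 1;
          if (iin < 0 || iin >= D) continue;
          const int v = io + Do * (jo + Ho * ko);
          float* dst = gxf + (size_t)C * (iin + (size_t)D * (jin + (size_t)H * kin));
          for (int c = 0; c < C; ++c) dst[c] += Gp(v, c + C * off);
        }
      }
    }
  }
}

static std::vector<int> tensor_dims(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 5) stop("expected a 5-d (C, D, H, W, N) array");
  return std::vector<int>(d.begin(), d.end());
}

static XPtr<ConvCache> make_cache(int C, int D, int H, int W, int N, int stride) {
  ConvCache* cc = new ConvCache();
  cc->C = C; cc->D = D; cc->H = H; cc->W = W; cc->N = N; cc->stride = stride;
  const int Do = out_len(D, stride), Ho = out_len(H, stride), Wo = out_len(W, stride);
  cc->block = (size_t)Do * Ho * Wo * 27 * C;
  cc->P.resize(cc->block * N);
  return XPtr<ConvCache>(cc, true);
}

// [[Rcpp::export]]
List cpp_conv3d_fwd(NumericVector x, NumericMatrix w, NumericVector b,
                    int stride, bool want_cache) {
  std::vector<int> dm = tensor_dims(x);
  const int C = dm[0], D = dm[1], H = dm[2], W = dm[3], N = dm[4];
  const int K = 27 * C, Cout = w.nrow();
  if (w.ncol() != K) stop("weight shape mismatch");
  const int Do = out_len(D, stride), Ho = out_len(H, stride), Wo = out_len(W, stride);
  const int V = Do * Ho * Wo, S = C * D * H * W;

  arma::fmat Wt(K, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < K; ++k) Wt(k, o) = (float)w(o, k);

  NumericVector y(Cout * (R_xlen_t)V * N);
  y.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo, N);

  XPtr<ConvCache> cache(static_cast<ConvCache*>(nullptr), false);
  std::vector<float> pbuf;
  if (want_cache) cache = make_cache(C, D, H, W, N, stride);
  else pbuf.resize((size_t)V * K);
  std::vector<float> xf(S);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (R_xlen_t)S * n;
    for (int i = 0; i < S; ++i) xf[i] = (float)xs[i];
    float* pblk = want_cache ? cache->P.data() + cache->block * n : pbuf.data();
    im2col(xf.data(), C, D, H, W, stride, pblk);
    arma::fmat P(pblk, V, K, false, true);
    arma::fmat Y = P * Wt;
    double* ys = y.begin() + (R_xlen_t)Cout * V * n;
    for (int o = 0; o < Cout; ++o) {
      const float* yc = Y.colptr(o);
      const double bo = b[o];
      for (int v = 0; v < V; ++v) ys[o + (size_t)Cout * v] = (double)yc[v] + bo;
    }
  }
  if (want_cache) return List::create(_["y"] = y, _["cache"] = cache);
  return List::create(_["y"] = y);
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericMatrix w, NumericVector gy,
                    int stride, bool need_gx, SEXP cache_sexp) {
  std::vector<int> dm = tensor_dims(x);
  const int C = dm[0], D = dm[1], H = dm[2], W = dm[3], N = dm[4];
  const int K = 27 * C, Cout = w.nrow();
  const int Do = out_len(D, stride), Ho = out_len(H, stride), Wo = out_len(W, stride);
  const int V = Do * Ho * Wo, S = C * D * H * W;

  ConvCache* cache = nullptr;
  if (cache_sexp != R_NilValue) {
    XPtr<ConvCache> cp(cache_sexp);
    if (cp->C != C || cp->D != D || cp->N != N || cp->stride != stride)
      stop("conv cache does not match input");
    cache = cp.get();
  }

  arma::fmat Wf(Cout, K);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < K; ++k) Wf(o, k) = (float)w(o, k);

  arma::fmat gWt(K, Cout, arma::fill::zeros);
  arma::fvec gb(Cout, arma::fill::zeros);
  NumericVector gx;
  if (need_gx) {
    gx = NumericVector(x.size());
    gx.attr("dim") = x.attr("dim");
  }

  std::vector<float> xf, gxf(need_gx ? S : 0), pown;
  if (!cache) { xf.resize(S); pown.resize((size_t)V * K); }
  arma::fmat Gy(V, Cout);
  for (int n = 0; n < N; ++n) {
    const double* gys = gy.begin() + (R_xlen_t)Cout * V * n;
    for (int o = 0; o < Cout; ++o) {
      float* gc = Gy.colptr(o);
      for (int v = 0; v < V; ++v) gc[v] = (float)gys[o + (size_t)Cout * v];
    }
    float* pblk;
    if (cache) {
      pblk = cache->P.data() + cache->block * n;
    } else {
      const double* xs = x.begin() + (R_xlen_t)S * n;
      for (int i = 0; i < S; ++i) xf[i] = (float)xs[i];
      im2col(xf.data(), C, D, H, W, stride, pown.data());
      pblk = pown.data();
    }
    arma::fmat P(pblk, V, K, false, true);
    gWt += P.t() * Gy;
    gb += arma::sum(Gy, 0).t();
    if (need_gx) {
      arma::fmat Gp = Gy * Wf;  // (V x K)
      std::fill(gxf.begin(), gxf.end(), 0.0f);
      col2im_add(Gp, C, D, H, W, stride, gxf.data());
      double* gxs = gx.begin() + (R_xlen_t)S * n;
      for (int i = 0; i < S; ++i) gxs[i] = (double)gxf[i];
    }
  }

  NumericMatrix gw(Cout, K);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < K; ++k) gw(o, k) = (double)gWt(k, o);
  NumericVector gbv(Cout);
  for (int o = 0; o < Cout; ++o) gbv[o] = (double)gb(o);

  if (need_gx) return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gbv);
  return List::create(_["gw"] = gw, _["gb"] = gbv);
}

// Fused head convolution: image channels convolved normally; prior
// channels are spatially constant so their contribution at an output
// voxel depends only on the voxel's border class -- a partial sum of
// the kernel taps that fall inside the volume.
// ximg: (Ci, D, H, W, N); priors: (F x N) matrix of plane values.
// wimg: (Cout x 27*Ci); wpri: (Cout x 27*F).
// [[Rcpp::export]]
List cpp_head_fwd(NumericVector ximg, NumericMatrix priors,
                  NumericMatrix wimg, NumericMatrix wpri,
                  NumericVector b, int stride, bool want_cache) {
  std::vector<int> dm = tensor_dims(ximg);
  const int Ci = dm[0], D = dm[1], H = dm[2], W = dm[3], N = dm[4];
  const int Ki = 27 * Ci, Cout = wimg.nrow();
  const int F = priors.nrow();
  if (wpri.nrow() != Cout || wpri.ncol() != 27 * F) stop("prior weight shape mismatch");
  const int Do = out_len(D, stride), Ho = out_len(H, stride), Wo = out_len(W, stride);
  const int V = Do * Ho * Wo, S = Ci * D * H * W;

  arma::fmat Wt(Ki, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < Ki; ++k) Wt(k, o) = (float)wimg(o, k);

  // S27[cls] (Cout x F): partial tap sums of the prior kernels per class.
  std::vector<arma::fmat> S27(27);
  for (int ca = 0; ca < 3; ++ca)
  for (int cb = 0; cb < 3; ++cb)
  for (int cc = 0; cc < 3; ++cc) {
    const int cls = ca + 3 * (cb + 3 * cc);
    arma::fmat Sm(Cout, F, arma::fill::zeros);
    for (int dk = 0; dk < 3; ++dk)
    for (int dj = 0; dj < 3; ++dj)
    for (int di = 0; di < 3; ++di) {
      if (!tap_valid(ca, di) || !tap_valid(cb, dj) || !tap_valid(cc, dk)) continue;
      const int off = di + 3 * (dj + 3 * dk);
      for (int o = 0; o < Cout; ++o)
        for (int f = 0; f < F; ++f) Sm(o, f) += (float)wpri(o, f + F * off);
    }
    S27[cls] = Sm;
  }

  std::vector<int> vcls(V);
  for (int ko = 0; ko < Wo; ++ko) {
    const int cc = axis_class(ko, stride, W);
    for (int jo = 0; jo < Ho; ++jo) {
      const int cb = axis_class(jo, stride, H);
      for (int io = 0; io < Do; ++io)
        vcls[io + Do * (jo + Ho * ko)] = axis_class(io, stride, D) + 3 * (cb + 3 * cc);
    }
  }

  NumericVector y(Cout * (R_xlen_t)V * N);
  y.attr("dim") = IntegerVector::create(Cout, Do, Ho, Wo, N);

  XPtr<ConvCache> cache(static_cast<ConvCache*>(nullptr), false);
  std::vector<float> pbuf;
  if (want_cache) cache = make_cache(Ci, D, H, W, N, stride);
  else pbuf.resize((size_t)V * Ki);
  std::vector<float> xf(S);
  arma::fvec vf(F);
  for (int n = 0; n < N; ++n) {
    const double* xs = ximg.begin() + (R_xlen_t)S * n;
    for (int i = 0; i < S; ++i) xf[i] = (float)xs[i];
    float* pblk = want_cache ? cache->P.data() + cache->block * n : pbuf.data();
    im2col(xf.data(), Ci, D, H, W, stride, pblk);
    arma::fmat P(pblk, V, Ki, false, true);
    arma::fmat Y = P * Wt;  // (V x Cout)
    for (int f = 0; f < F; ++f) vf(f) = (float)priors(f, n);
    arma::fmat corr(Cout, 27);
    for (int cls = 0; cls < 27; ++cls) corr.col(cls) = S27[cls] * vf;
    double* ys = y.begin() + (R_xlen_t)Cout * V * n;
    for (int o = 0; o < Cout; ++o) {
      const float* yc = Y.colptr(o);
      const float* cr = corr.memptr() + o;   // corr(o, cls) at cr[Cout*cls]
      const double bo = b[o];
      for (int v = 0; v < V; ++v)
        ys[o + (size_t)Cout * v] =
          (double)(yc[v] + cr[(size_t)Cout * vcls[v]]) + bo;
    }
  }
  if (want_cache) return List::create(_["y"] = y, _["cache"] = cache);
  return List::create(_["y"] = y);
}

// Backward of the fused head; the gradient wrt the input volumes is not
// needed (the head is the first layer), only parameter gradients.
// [[Rcpp::export]]
List cpp_head_bwd(NumericVector ximg, NumericMatrix priors,
                  NumericVector gy, int stride, int cout, SEXP cache_sexp) {
  std::vector<int> dm = tensor_dims(ximg);
  const int Ci = dm[0], D = dm[1], H = dm[2], W = dm[3], N = dm[4];
  const int Ki = 27 * Ci, Cout = cout, F = priors.nrow();
  const int Do = out_len(D, stride), Ho = out_len(H, stride), Wo = out_len(W, stride);
  const int V = Do * Ho * Wo, S = Ci * D * H * W;

  ConvCache* cache = nullptr;
  if (cache_sexp != R_NilValue) {
    XPtr<ConvCache> cp(cache_sexp);
    if (cp->C != Ci || cp->D != D || cp->N != N || cp->stride != stride)
      stop("conv cache does not match input");
    cache = cp.get();
  }

  std::vector<int> vcls(V);
  for (int ko = 0; ko < Wo; ++ko) {
    const int cc = axis_class(ko, stride, W);
    for (int jo = 0; jo < Ho; ++jo) {
      const int cb = axis_class(jo, stride, H);
      for (int io = 0; io < Do; ++io)
        vcls[io + Do * (jo + Ho * ko)] = axis_class(io, stride, D) + 3 * (cb + 3 * cc);
    }
  }

  arma::fmat gWt(Ki, Cout, arma::fill::zeros);
  arma::fmat gWp(Cout, 27 * F, arma::fill::zeros);
  arma::fvec gb(Cout, arma::fill::zeros);

  std::vector<float> xf, pown;
  if (!cache) { xf.resize(S); pown.resize((size_t)V * Ki); }
  arma::fmat Gy(V, Cout);
  arma::fvec vf(F);
  for (int n = 0; n < N; ++n) {
    const double* gys = gy.begin() + (R_xlen_t)Cout * V * n;
    for (int o = 0; o < Cout; ++o) {
      float* gc = Gy.colptr(o);
      for (int v = 0; v < V; ++v) gc[v] = (float)gys[o + (size_t)Cout * v];
    }
    float* pblk;
    if (cache) {
      pblk = cache->P.data() + cache->block * n;
    } else {
      const double* xs = ximg.begin() + (R_xlen_t)S * n;
      for (int i = 0; i < S; ++i) xf[i] = (float)xs[i];
      im2col(xf.data(), Ci, D, H, W, stride, pown.data());
      pblk = pown.data();
    }
    arma::fmat P(pblk, V, Ki, false, true);
    gWt += P.t() * Gy;
    gb += arma::sum(Gy, 0).t();

    // per-class column sums of Gy
    arma::fmat Gcls(Cout, 27, arma::fill::zeros);
    for (int v = 0; v < V; ++v) {
      float* gc = Gcls.colptr(vcls[v]);
      for (int o = 0; o < Cout; ++o) gc[o] += Gy(v, o);
    }
    // T(o, off) = sum over classes where tap off is valid
    arma::fmat T(Cout, 27, arma::fill::zeros);
    for (int ca = 0; ca < 3; ++ca)
    for (int cb = 0; cb < 3; ++cb)
    for (int cc2 = 0; cc2 < 3; ++cc2) {
      const int cls = ca + 3 * (cb + 3 * cc2);
      for (int dk = 0; dk < 3; ++dk)
      for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        if (!tap_valid(ca, di) || !tap_valid(cb, dj) || !tap_valid(cc2, dk)) continue;
        const int off = di + 3 * (dj + 3 * dk);
        for (int o = 0; o < Cout; ++o) T(o, off) += Gcls(o, cls);
      }
    }
    for (int f = 0; f < F; ++f) vf(f) = (float)priors(f, n);
    for (int off = 0; off < 27; ++off)
      for (int f = 0; f < F; ++f)
        for (int o = 0; o < Cout; ++o) gWp(o, f + F * off) += T(o, off) * vf(f);
  }

  NumericMatrix gwimg(Cout, Ki), gwpri(Cout, 27 * F);
  for (int o = 0; o < Cout; ++o) {
    for (int k = 0; k < Ki; ++k) gwimg(o, k) = (double)gWt(k, o);
    for (int k = 0; k < 27 * F; ++k) gwpri(o, k) = (double)gWp(o, k);
  }
  NumericVector gbv(Cout);
  for (int o = 0; o < Cout; ++o) gbv[o] = (double)gb(o);
  return List::create(_["gw_img"] = gwimg, _["gw_pri"] = gwpri, _["gb"] = gbv);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int factor) {
  std::vector<int> dm = tensor_dims(x);
  const int C = dm[0], D = dm[1], H = dm[2], W = dm[3], N = dm[4];
  if (D % factor || H % factor || W % factor) stop("spatial dims not divisible by pool factor");
  const int Do = D / factor, Ho = H / factor, Wo = W / factor;
  const R_xlen_t Vout = (R_xlen_t)Do * Ho * Wo;

  NumericVector y(C * Vout * N);
  IntegerVector idx(C * Vout * N);  // linear index into x of the max
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo, N);

  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff = (R_xlen_t)C * D * H * W * n;
    const R_xlen_t yoff = (R_xlen_t)C * Vout * n;
    for (int ko = 0; ko < Wo; ++ko)
    for (int jo = 0; jo < Ho; ++jo)
    for (int io = 0; io < Do; ++io) {
      const R_xlen_t vo = io + (R_xlen_t)Do * (jo + Ho * ko);
      for (int c = 0; c < C; ++c) {
        double best = R_NegInf; R_xlen_t bi = -1;
        for (int dk = 0; dk < factor; ++dk)
        for (int dj = 0; dj < factor; ++dj)
        for (int di = 0; di < factor; ++di) {
          const int i = factor * io + di, j = factor * jo + dj, k = factor * ko + dk;
          const R_xlen_t xi = xoff + c + (R_xlen_t)C * (i + D * (j + (R_xlen_t)H * k));
          const double v = x[xi];
          if (v > best) { best = v; bi = xi; }
        }
        y[yoff + c + C * vo] = best;
        idx[yoff + c + C * vo] = (int)bi;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  R_xlen_t S = 1;
  for (int i = 0; i < xdim.size(); ++i) S *= xdim[i];
  NumericVector gx(S);
  gx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// Gather a mini-batch from the case axis and apply per-sample axis
// flips in one pass.  x: (C, D, H, W, N); idx: 1-based case indices;
// flips: (nb x 3) logical.
// [[Rcpp::export]]
NumericVector cpp_gather_flip(NumericVector x, IntegerVector idx,
                              LogicalMatrix flips) {
  std::vector<int> dm = tensor_dims(x);
  const int C = dm[0], D = dm[1], H = dm[2], W = dm[3];
  const int nb = idx.size();
  const R_xlen_t S = (R_xlen_t)C * D * H * W;
  NumericVector y(S * nb);
  y.attr("dim") = IntegerVector::create(C, D, H, W, nb);
  for (int b = 0; b < nb; ++b) {
    const double* src = x.begin() + S * (idx[b] - 1);
    double* dst = y.begin() + S * b;
    const bool f1 = flips(b, 0), f2 = flips(b, 1), f3 = flips(b, 2);
    if (!f1 && !f2 && !f3) { std::copy(src, src + S, dst); continue; }
    for (int k = 0; k < W; ++k) {
      const int ks = f3 ? W - 1 - k : k;
      for (int j = 0; j < H; ++j) {
        const int js = f2 ? H - 1 - j : j;
        for (int i = 0; i < D; ++i) {
          const int is = f1 ? D - 1 - i : i;
          const double* s = src + (size_t)C * (is + (size_t)D * (js + (size_t)H * ks));
          double* d = dst + (size_t)C * (i + (size_t)D * (j + (size_t)H * k));
          std::copy(s, s + C, d);
        }
      }
    }
  }
  return y;
}
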