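// Batched 1-D convolution primitives for the conv-net engine.
// Layout: signals are (channels, length, batch) cubes; weights are
// (out_channels, in_channels * kernel) matrices with column index
// t * C + c (kernel-major blocks of contiguous channels). Internally
// single precision: one im2col copy feeding a single sgemm per layer call.

#include <RcppArmadillo.h>
#include <cstring>
#if defined(__GLIBC__)
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

// Large tensors are allocated and freed on every layer call; with glibc's
// default mmap threshold each one costs an mmap/munmap plus page faults.
// Raising the thresholds keeps those buffers on the heap for reuse.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#if defined(__GLIBC__)
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
}

using namespace arma;

static fcube as_f(const cube &x) { return conv_to<fcube>::from(x); }
static fmat as_f(const mat &x) { return conv_to<fmat>::from(x); }
static fvec as_f(const vec &x) { return conv_to<fvec>::from(x); }

// Reusable float workspaces. Layer calls repeat with identical shapes every
// training step; growing-once buffers avoid a 30+ MB mmap/munmap (and the
// page-fault zeroing that comes with it) on every call. R is single-threaded
// through this interface.
static std::vector<float> ws_x, ws_m, ws_y, ws_dy, ws_dm;

// forward-pass im2col matrices cached per layer name: the backward pass for
// a layer always follows its most recent forward with identical shapes, so
// the copy (and the double-to-float conversion of x) need not be redone.
#include <unordered_map>
static std::unordered_map<std::string, fmat> g_mcache;

static float *ws(std::vector<float> &v, size_t n) {
  if (v.size() < n) v.resize(n);
  return v.data();
}

static void d2f(const double *src, float *dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
}

// im2col over the whole batch into `out`: columns indexed (n * Lout + j);
// each column holds k channel-contiguous blocks copied from the slice.
static void im2col(const float *xf, int C, int L, int N, int k, int stride,
                   int pad, int Lout, float *out) {
  const size_t ck = (size_t)C * k;
  std::memset(out, 0, ck * (size_t)Lout * N * sizeof(float));
  for (int n = 0; n < N; ++n) {
    const float *xs = xf + (size_t)n * C * L;
    for (int j = 0; j < Lout; ++j) {
      float *mcol = out + ((size_t)n * Lout + j) * ck;
      const int src0 = j * stride - pad;
      for (int t = 0; t < k; ++t) {
        const int src = src0 + t;
        if (src < 0 || src >= L) continue;
        std::memcpy(mcol + (size_t)t * C, xs + (size_t)src * C,
                    C * sizeof(float));
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv1d_fw(const Rcpp::NumericVector &x,
                                  const arma::mat &w, const arma::vec &b,
                                  int k, int stride, int pad,
                                  const std::string &cache_key = "") {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int C = xd[0], L = xd[1], N = xd[2];
  const int Cout = w.n_rows;
  const int Lout = (L + 2 * pad - k) / stride + 1;
  const size_t nel_x = (size_t)C * L * N;
  const size_t cols = (size_t)Lout * N;
  float *xf = ws(ws_x, nel_x);
  d2f(x.begin(), xf, nel_x);
  float *mp;
  if (!cache_key.empty()) {
    fmat &Mc = g_mcache[cache_key];
    Mc.set_size(C * k, cols);
    mp = Mc.memptr();
  } else {
    mp = ws(ws_m, (size_t)C * k * cols);
  }
  im2col(xf, C, L, N, k, stride, pad, Lout, mp);
  fmat Mv(mp, C * k, cols, false, true);
  float *yp = ws(ws_y, (size_t)Cout * cols);
  fmat Yv(yp, Cout, cols, false, true);
  Yv = as_f(w) * Mv;
  Yv.each_col() += as_f(b);
  const size_t nel = (size_t)Cout * cols;
  Rcpp::NumericVector res(nel);
  double *rp = res.begin();
  for (size_t i = 0; i < nel; ++i) rp[i] = yp[i];  // same layout as out cube
  res.attr("dim") = Rcpp::IntegerVector::create(Cout, Lout, N);
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv1d_bw(const Rcpp::NumericVector &x, const arma::mat &w,
                         const Rcpp::NumericVector &dy, int k, int stride,
                         int pad, const std::string &cache_key = "") {
  Rcpp::IntegerVector xd = x.attr("dim");
  Rcpp::IntegerVector dd = dy.attr("dim");
  const int C = xd[0], L = xd[1], N = xd[2];
  const int Cout = dd[0], Lout = dd[1];
  const size_t cols = (size_t)Lout * N;
  const size_t nel_x = (size_t)C * L * N;
  float *mp;
  auto hit = cache_key.empty() ? g_mcache.end() : g_mcache.find(cache_key);
  if (hit != g_mcache.end() && hit->second.n_rows == (size_t)(C * k) &&
      hit->second.n_cols == cols) {
    mp = hit->second.memptr();
  } else {
    float *xf = ws(ws_x, nel_x);
    d2f(x.begin(), xf, nel_x);
    mp = ws(ws_m, (size_t)C * k * cols);
    im2col(xf, C, L, N, k, stride, pad, Lout, mp);
  }
  fmat Mv(mp, C * k, cols, false, true);
  float *dyp = ws(ws_dy, (size_t)Cout * cols);
  d2f(dy.begin(), dyp, (size_t)Cout * cols);   // identical layouts
  fmat dYv(dyp, Cout, cols, false, true);
  fmat dW = dYv * Mv.t();
  fvec db = sum(dYv, 1);
  float *dmp = ws(ws_dm, (size_t)C * k * cols);
  fmat dMv(dmp, C * k, cols, false, true);
  dMv = as_f(w).t() * dYv;
  Rcpp::NumericVector dx(nel_x);               // zero-initialized
  double *dxp = dx.begin();
  for (int n = 0; n < N; ++n) {
    double *dxs = dxp + (size_t)n * C * L;
    for (int j = 0; j < Lout; ++j) {
      const float *mcol = dmp + ((size_t)n * Lout + j) * C * k;
      const int src0 = j * stride - pad;
      for (int t = 0; t < k; ++t) {
        const int src = src0 + t;
        if (src < 0 || src >= L) continue;
        double *dst = dxs + (size_t)src * C;
        const float *blk = mcol + (size_t)t * C;
        for (int c = 0; c < C; ++c) dst[c] += blk[c];
      }
    }
  }
  dx.attr("dim") = Rcpp::IntegerVector::create(C, L, N);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = conv_to<mat>::from(dW),
                            Rcpp::Named("db") = conv_to<vec>::from(db));
}

// PReLU forward/backward as single C++ passes (per-channel alpha), avoiding
// a cascade of full-size temporaries in R.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_prelu_fw(const Rcpp::NumericVector &x,
                                 const Rcpp::NumericVector &a) {
  Rcpp::IntegerVector d = x.attr("dim");
  const int C = d[0];
  const size_t n = x.size();
  Rcpp::NumericVector y(n);
  const double *xp = x.begin();
  const double *ap = a.begin();
  double *yp = y.begin();
  int c = 0;
  for (size_t i = 0; i < n; ++i) {
    const double v = xp[i];
    yp[i] = v > 0 ? v : ap[c] * v;
    if (++c == C) c = 0;
  }
  y.attr("dim") = d;
  return y;
}

// [[Rcpp::export]]
Rcpp::List cpp_prelu_bw(const Rcpp::NumericVector &x,
                        const Rcpp::NumericVector &a,
                        const Rcpp::NumericVector &grad) {
  Rcpp::IntegerVector d = x.attr("dim");
  const int C = d[0];
  const size_t n = x.size();
  Rcpp::NumericVector dx(n);
  Rcpp::NumericVector da(C);
  const double *xp = x.begin();
  const double *ap = a.begin();
  const double *gp = grad.begin();
  double *dxp = dx.begin();
  double *dap = da.begin();
  int c = 0;
  for (size_t i = 0; i < n; ++i) {
    const double v = xp[i];
    if (v > 0) {
      dxp[i] = gp[i];
    } else {
      dxp[i] = ap[c] * gp[i];
      dap[c] += gp[i] * v;
    }
    if (++c == C) c = 0;
  }
  dx.attr("dim") = d;
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("da") = da);
}

// Transposed convolution, kernel 2 / stride 2 (non-overlapping up-sampling).
// w is (2*Cout, Cin) with row index t * Cout + c, so the gemm result
// (2*Cout, L) read column-major is already the (Cout, 2L) output slice.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_upconv2_fw(const Rcpp::NumericVector &x,
                                   const arma::mat &w, const arma::vec &b) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int Cin = xd[0], L = xd[1], N = xd[2];
  const int Cout = w.n_rows / 2;
  fmat wf = as_f(w);
  fvec bf = as_f(b);
  fvec b2 = join_cols(bf, bf);
  const size_t nel_x = (size_t)Cin * L * N;
  float *xf = ws(ws_x, nel_x);
  d2f(x.begin(), xf, nel_x);
  Rcpp::NumericVector res((size_t)Cout * 2 * L * N);
  double *rp = res.begin();
  for (int n = 0; n < N; ++n) {
    fmat xs(xf + (size_t)n * Cin * L, Cin, L, false, true);
    fmat Y2 = wf * xs;                        // (2*Cout, L)
    Y2.each_col() += b2;
    const float *yp = Y2.memptr();
    double *dst = rp + (size_t)n * Cout * 2 * L;
    for (size_t i = 0; i < (size_t)Cout * 2 * L; ++i) dst[i] = yp[i];
  }
  res.attr("dim") = Rcpp::IntegerVector::create(Cout, 2 * L, N);
  return res;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv2_bw(const Rcpp::NumericVector &x, const arma::mat &w,
                          const Rcpp::NumericVector &dy) {
  Rcpp::IntegerVector xd = x.attr("dim");
  const int Cin = xd[0], L = xd[1], N = xd[2];
  const int Cout = w.n_rows / 2;
  fmat wf = as_f(w);
  const size_t nel_x = (size_t)Cin * L * N;
  float *xfp = ws(ws_x, nel_x);
  d2f(x.begin(), xfp, nel_x);
  Rcpp::NumericVector dx((size_t)Cin * L * N);
  double *dxp = dx.begin();
  fmat dW(2 * Cout, Cin, fill::zeros);
  fvec db(2 * Cout, fill::zeros);
  for (int n = 0; n < N; ++n) {
    // reinterpret the (Cout, 2L) gradient slice as (2*Cout, L)
    fmat dY2(2 * Cout, L);
    {
      float *dp = dY2.memptr();
      const double *sp = dy.begin() + (size_t)n * 2 * Cout * L;
      for (size_t i = 0; i < (size_t)2 * Cout * L; ++i) dp[i] = (float)sp[i];
    }
    fmat dxn = wf.t() * dY2;
    double *dxs = dxp + (size_t)n * Cin * L;
    const float *dp = dxn.memptr();
    for (size_t i = 0; i < (size_t)Cin * L; ++i) dxs[i] = dp[i];
    fmat xs(xfp + (size_t)n * Cin * L, Cin, L, false, true);
    dW += dY2 * xs.t();
    db += sum(dY2, 1);
  }
  dx.attr("dim") = Rcpp::IntegerVector::create(Cin, L, N);
  vec dbv = conv_to<vec>::from(db.subvec(0, Cout - 1) +
                               db.subvec(Cout, 2 * Cout - 1));
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = conv_to<mat>::from(dW),
                            Rcpp::Named("db") = dbv);
}
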