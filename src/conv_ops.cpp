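#include <Rcpp.h>
using namespace Rcpp;

// Activations are column-major arrays with dim (L, C, n): time position
// (fastest), channel, batch sample. im2col lowers a valid 1-D convolution to
// one GEMM: row (i-1)*L_out + t of the output holds the k-tap window starting
// at t for every channel of sample i.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int L, int C, int n, int k) {
  const int L_out = L - k + 1;
  NumericMatrix M(n * L_out, k * C);
  const double *xp = x.begin();
  double *mp = M.begin();
  const R_xlen_t nrow = (R_xlen_t)n * L_out;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      double *col = mp + ((R_xlen_t)(c * k + j)) * nrow;
      for (int i = 0; i < n; ++i) {
        const double *src = xp + (R_xlen_t)i * L * C + (R_xlen_t)c * L + j;
        double *dst = col + (R_xlen_t)i * L_out;
        memcpy(dst, src, sizeof(double) * L_out);
      }
    }
  }
  return M;
}

// Scatter-add transpose of im2col: accumulates gradient windows back onto the
// (L, C, n) input layout.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dM, int L, int C, int n, int k) {
  const int L_out = L - k + 1;
  NumericVector dx((R_xlen_t)L * C * n);
  const double *mp = dM.begin();
  double *xp = dx.begin();
  const R_xlen_t nrow = (R_xlen_t)n * L_out;
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < k; ++j) {
      const double *col = mp + ((R_xlen_t)(c * k + j)) * nrow;
      for (int i = 0; i < n; ++i) {
        double *dst = xp + (R_xlen_t)i * L * C + (R_xlen_t)c * L + j;
        const double *src = col + (R_xlen_t)i * L_out;
        for (int t = 0; t < L_out; ++t) dst[t] += src[t];
      }
    }
  }
  return dx;
}

// Reshape the GEMM output ((n*L_out) x F, t fastest within sample) into the
// activation layout (L_out, F, n), adding the bias per filter.
// [[Rcpp::export]]
NumericVector gemm_to_act_cpp(NumericMatrix Y, NumericVector b, int L_out,
                              int F, int n) {
  NumericVector out((R_xlen_t)L_out * F * n);
  const double *yp = Y.begin();
  double *op = out.begin();
  for (int f = 0; f < F; ++f) {
    const double *ycol = yp + (R_xlen_t)f * n * L_out;
    const double bf = b[f];
    for (int i = 0; i < n; ++i) {
      const double *src = ycol + (R_xlen_t)i * L_out;
      double *dst = op + (R_xlen_t)i * L_out * F + (R_xlen_t)f * L_out;
      for (int t = 0; t < L_out; ++t) dst[t] = src[t] + bf;
    }
  }
  return out;
}

// Inverse of gemm_to_act (no bias): (L_out, F, n) array -> (n*L_out) x F.
// [[Rcpp::export]]
NumericMatrix act_to_gemm_cpp(NumericVector a, int L_out, int F, int n) {
  NumericMatrix Y((R_xlen_t)n * L_out, F);
  const double *ap = a.begin();
  double *yp = Y.begin();
  for (int f = 0; f < F; ++f) {
    double *ycol = yp + (R_xlen_t)f * n * L_out;
    for (int i = 0; i < n; ++i) {
      const double *src = ap + (R_xlen_t)i * L_out * F + (R_xlen_t)f * L_out;
      double *dst = ycol + (R_xlen_t)i * L_out;
      memcpy(dst, src, sizeof(double) * L_out);
    }
  }
  return Y;
}

// Non-overlapping max pooling along the time axis with argmax bookkeeping.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int L, int C, int n, int p) {
  const int L2 = L / p;
  NumericVector out((R_xlen_t)L2 * C * n);
  IntegerVector arg((R_xlen_t)L2 * C * n);
  const double *xp = x.begin();
  double *op = out.begin();
  int *ag = arg.begin();
  const R_xlen_t slices = (R_xlen_t)C * n;
  for (R_xlen_t s = 0; s < slices; ++s) {
    const double *src = xp + s * L;
    double *dst = op + s * L2;
    int *adst = ag + s * L2;
    for (int t = 0; t < L2; ++t) {
      const double *w = src + (R_xlen_t)t * p;
      double best = w[0];
      int bi = 0;
      for (int r = 1; r < p; ++r) {
        if (w[r] > best) { best = w[r]; bi = r; }
      }
      dst[t] = best;
      adst[t] = t * p + bi;  // offset within the slice
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dout, IntegerVector arg, int L,
                              int C, int n, int p) {
  const int L2 = L / p;
  NumericVector dx((R_xlen_t)L * C * n);
  const double *dp = dout.begin();
  const int *ag = arg.begin();
  double *xp = dx.begin();
  const R_xlen_t slices = (R_xlen_t)C * n;
  for (R_xlen_t s = 0; s < slices; ++s) {
    const double *src = dp + s * L2;
    const int *asrc = ag + s * L2;
    double *dst = xp + s * L;
    for (int t = 0; t < L2; ++t) dst[asrc[t]] += src[t];
  }
  return dx;
}
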