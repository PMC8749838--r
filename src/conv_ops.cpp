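#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix (im2col) layout shared by the forward and backward kernels:
//   row index  r = c*k*k + kx*k + ky          (ky fastest)
//   col index  j = n*oh*ow + ox*oh + oy       (oy fastest)
// so that matrix(out, c(Cout, oh, ow, N)) in R has the natural ordering.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim"); // H, W, C, N
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int nr = k * k * C;
  NumericMatrix out(nr, oh * ow * N);
  const double *px = x.begin();
  double *po = out.begin();
  for (int n = 0; n < N; ++n) {
    const double *pn = px + (R_xlen_t)n * C * W * H;
    for (int ox = 0; ox < ow; ++ox)
      for (int oy = 0; oy < oh; ++oy) {
        double *pcol = po + (R_xlen_t)(n * (R_xlen_t)oh * ow + ox * oh + oy) * nr;
        for (int c = 0; c < C; ++c) {
          const double *pc = pn + (R_xlen_t)c * W * H;
          for (int kx = 0; kx < k; ++kx) {
            const int ix = ox * stride - pad + kx;
            double *pr = pcol + c * k * k + kx * k;
            if (ix < 0 || ix >= W) {
              for (int ky = 0; ky < k; ++ky) pr[ky] = 0.0;
              continue;
            }
            const double *psrc = pc + (R_xlen_t)ix * H;
            const int iy0 = oy * stride - pad;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = iy0 + ky;
              pr[ky] = (iy >= 0 && iy < H) ? psrc[iy] : 0.0;
            }
          }
        }
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int oh = (H + 2 * pad - k) / stride + 1;
  const int ow = (W + 2 * pad - k) / stride + 1;
  const int nr = k * k * C;
  NumericVector x((R_xlen_t)H * W * C * N);
  x.attr("dim") = IntegerVector::create(H, W, C, N);
  double *px = x.begin();
  const double *po = cols.begin();
  for (int n = 0; n < N; ++n) {
    double *pn = px + (R_xlen_t)n * C * W * H;
    for (int ox = 0; ox < ow; ++ox)
      for (int oy = 0; oy < oh; ++oy) {
        const double *pcol = po + (R_xlen_t)(n * (R_xlen_t)oh * ow + ox * oh + oy) * nr;
        for (int c = 0; c < C; ++c) {
          double *pc = pn + (R_xlen_t)c * W * H;
          for (int kx = 0; kx < k; ++kx) {
            const int ix = ox * stride - pad + kx;
            if (ix < 0 || ix >= W) continue;
            double *pdst = pc + (R_xlen_t)ix * H;
            const double *pr = pcol + c * k * k + kx * k;
            const int iy0 = oy * stride - pad;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = iy0 + ky;
              if (iy >= 0 && iy < H) pdst[iy] += pr[ky];
            }
          }
        }
      }
  }
  return x;
}

// Local Shannon entropy (bits, 256 gray levels) over a disk neighbourhood.
// Neighbours falling outside the image are ignored (shrinking window),
// matching the usual rank-filter convention.
// [[Rcpp::export]]
NumericMatrix disk_entropy_cpp(IntegerMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<int> dy, dx;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dy.push_back(a); dx.push_back(b); }
  const int m = dy.size();
  NumericMatrix out(H, W);
  std::vector<int> hist(256);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      std::fill(hist.begin(), hist.end(), 0);
      int tot = 0;
      for (int t = 0; t < m; ++t) {
        const int ii = i + dy[t], jj = j + dx[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
        int v = img(ii, jj);
        if (v < 0) v = 0; else if (v > 255) v = 255;
        ++hist[v];
        ++tot;
      }
      double hsum = 0.0;
      for (int v = 0; v < 256; ++v)
        if (hist[v] > 0) {
          const double p = (double)hist[v] / tot;
          hsum -= p * std::log2(p);
        }
      out(i, j) = hsum;
    }
  return out;
}
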