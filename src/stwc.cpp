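#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sliding-window lagged Pearson correlation between two equal-length
// segments.  For each window center t (0-based indices in `centers`) and
// each lag d in [-max_lag, max_lag], correlates x[t-half .. t+half] with
// y[t+d-half .. t+d+half].  Windows are guaranteed in-range by the caller.
// Zero-variance windows yield NA (never +/-Inf).
//
// Segments are mean-centered before prefix-summing, which keeps the
// cancellation error of the prefix-sum form near 1e-13 on the short
// (<= few thousand sample) epochs this is used on; per-window first and
// second moments are precomputed once per window start.
// [[Rcpp::export]]
NumericMatrix stwc_kernel(NumericVector x, NumericVector y,
                          int half_win, int max_lag,
                          IntegerVector centers) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  const int L = 2 * half_win + 1;
  const int nlag = 2 * max_lag + 1;
  const int nt = centers.size();
  NumericMatrix out(nt, nlag);
  if (n < L) stop("segment shorter than the window");

  std::vector<double> xc(n), yc(n);
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  for (int i = 0; i < n; ++i) { xc[i] = x[i] - mx; yc[i] = y[i] - my; }

  // prefix sums of centered series and their squares
  std::vector<double> px(n + 1, 0.0), pxx(n + 1, 0.0),
                      py(n + 1, 0.0), pyy(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    px[i + 1]  = px[i]  + xc[i];
    pxx[i + 1] = pxx[i] + xc[i] * xc[i];
    py[i + 1]  = py[i]  + yc[i];
    pyy[i + 1] = pyy[i] + yc[i] * yc[i];
  }

  // per-window-start sums and centered sum of squares
  const int nstart = n - L + 1;
  std::vector<double> sx(nstart), vx(nstart), sy(nstart), vy(nstart);
  for (int a = 0; a < nstart; ++a) {
    sx[a] = px[a + L] - px[a];
    vx[a] = (pxx[a + L] - pxx[a]) - sx[a] * sx[a] / L;
    sy[a] = py[a + L] - py[a];
    vy[a] = (pyy[a + L] - pyy[a]) - sy[a] * sy[a] / L;
  }

  std::vector<double> pxy(n + 1, 0.0);
  for (int ld = 0; ld < nlag; ++ld) {
    const int d = ld - max_lag;
    const int i0 = std::max(0, -d), i1 = std::min(n, n - d);
    std::fill(pxy.begin(), pxy.end(), 0.0);
    for (int i = i0; i < i1; ++i)
      pxy[i + 1] = pxy[i] + xc[i] * yc[i + d];

    for (int it = 0; it < nt; ++it) {
      const int t = centers[it];
      const int a = t - half_win;          // x window start
      const int b = a + d;                 // y window start
      if (a < 0 || a >= nstart || b < 0 || b >= nstart) {
        out(it, ld) = NA_REAL;
        continue;
      }
      const double vxa = vx[a], vyb = vy[b];
      if (vxa <= 0.0 || vyb <= 0.0) {
        out(it, ld) = NA_REAL;
        continue;
      }
      const double sxy = pxy[a + L] - pxy[a];
      double r = (sxy - sx[a] * sy[b] / L) / std::sqrt(vxa * vyb);
      if (r > 1.0) r = 1.0;
      if (r < -1.0) r = -1.0;
      out(it, ld) = r;
    }
  }
  return out;
}

// Trial-averaged STWC map: runs the single-trial kernel over the columns
// of two epoch matrices and averages entrywise, ignoring NA entries.
// [[Rcpp::export]]
NumericMatrix stwc_avg_kernel(NumericMatrix xs, NumericMatrix ys,
                              int half_win, int max_lag,
                              IntegerVector centers) {
  const int ntr = xs.ncol();
  if (ys.ncol() != ntr) stop("trial counts differ");
  const int nt = centers.size();
  const int nlag = 2 * max_lag + 1;
  NumericMatrix acc(nt, nlag);
  IntegerMatrix cnt(nt, nlag);
  for (int j = 0; j < ntr; ++j) {
    NumericMatrix m = stwc_kernel(xs(_, j), ys(_, j), half_win, max_lag,
                                  centers);
    for (int c = 0; c < nlag; ++c) {
      for (int r = 0; r < nt; ++r) {
        const double v = m(r, c);
        if (!NumericMatrix::is_na(v)) { acc(r, c) += v; cnt(r, c) += 1; }
      }
    }
  }
  for (int c = 0; c < nlag; ++c) {
    for (int r = 0; r < nt; ++r) {
      acc(r, c) = cnt(r, c) > 0 ? acc(r, c) / cnt(r, c) : NA_REAL;
    }
  }
  return acc;
}
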