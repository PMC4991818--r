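#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

static inline std::complex<double> cplx(const Rcomplex &z) {
  return std::complex<double>(z.r, z.i);
}

// Bi-phase locking value map.  e1, e2, e3 are unit phasors exp(i*phi)
// stored as [freq, time, trial] arrays (freq fastest).  e1 holds the f1
// rows at the source, e2 the f2 rows at the source, e3 the f1+f2 rows at
// the target, aligned so that row (i1, i2) of the grid pairs with sum row
// sum_index(i1, i2) = i1 + i2 (0-based) in e3.  Returns |mean over trials
// of e1*e2*e3| as an [nf1, nf2, nt] array.
// [[Rcpp::export]]
NumericVector bplv_map_kernel(ComplexVector e1, ComplexVector e2,
                              ComplexVector e3,
                              int nf1, int nf2, int nf3,
                              int nt, int ntr) {
  NumericVector out((R_xlen_t)nf1 * nf2 * nt);
  out.attr("dim") = IntegerVector::create(nf1, nf2, nt);
  const Rcomplex *p1 = COMPLEX(e1), *p2 = COMPLEX(e2), *p3 = COMPLEX(e3);
  for (int i2 = 0; i2 < nf2; ++i2) {
    for (int i1 = 0; i1 < nf1; ++i1) {
      const int i3 = i1 + i2;           // index of f1+f2 in the sum axis
      if (i3 >= nf3) stop("sum-frequency index out of range");
      for (int t = 0; t < nt; ++t) {
        std::complex<double> acc(0.0, 0.0);
        for (int j = 0; j < ntr; ++j) {
          const R_xlen_t o1 = (R_xlen_t)i1 + (R_xlen_t)nf1 * (t + (R_xlen_t)nt * j);
          const R_xlen_t o2 = (R_xlen_t)i2 + (R_xlen_t)nf2 * (t + (R_xlen_t)nt * j);
          const R_xlen_t o3 = (R_xlen_t)i3 + (R_xlen_t)nf3 * (t + (R_xlen_t)nt * j);
          acc += cplx(p1[o1]) * cplx(p2[o2]) * cplx(p3[o3]);
        }
        out[(R_xlen_t)i1 + (R_xlen_t)nf1 * (i2 + (R_xlen_t)nf2 * t)] =
          std::abs(acc) / ntr;
      }
    }
  }
  return out;
}

// Time-integrated bPLV grid with the target's trial order circularly
// shifted by `offset` (0 = observed pairing).  Arrays as above, restricted
// to the integration window; returns the [nf1, nf2] grid of time-means.
// [[Rcpp::export]]
NumericMatrix bplv_integrated_kernel(ComplexVector e1, ComplexVector e2,
                                     ComplexVector e3,
                                     int nf1, int nf2, int nf3,
                                     int nt, int ntr, int offset) {
  NumericMatrix out(nf1, nf2);
  const Rcomplex *p1 = COMPLEX(e1), *p2 = COMPLEX(e2), *p3 = COMPLEX(e3);
  for (int i2 = 0; i2 < nf2; ++i2) {
    for (int i1 = 0; i1 < nf1; ++i1) {
      const int i3 = i1 + i2;
      if (i3 >= nf3) stop("sum-frequency index out of range");
      double tsum = 0.0;
      for (int t = 0; t < nt; ++t) {
        std::complex<double> acc(0.0, 0.0);
        for (int j = 0; j < ntr; ++j) {
          const int js = (j + offset) % ntr;
          const R_xlen_t o1 = (R_xlen_t)i1 + (R_xlen_t)nf1 * (t + (R_xlen_t)nt * j);
          const R_xlen_t o2 = (R_xlen_t)i2 + (R_xlen_t)nf2 * (t + (R_xlen_t)nt * j);
          const R_xlen_t o3 = (R_xlen_t)i3 + (R_xlen_t)nf3 * (t + (R_xlen_t)nt * js);
          acc += cplx(p1[o1]) * cplx(p2[o2]) * cplx(p3[o3]);
        }
        tsum += std::abs(acc) / ntr;
      }
      out(i1, i2) = tsum / nt;
    }
  }
  return out;
}

// All circular-shift surrogates in one pass, with trial-major contiguous
// buffers so the inner time loop streams memory.  Returns the observed
// (offset 0) integrated grid and, for each nonzero offset, the maximum of
// its integrated grid.
// [[Rcpp::export]]
List bplv_offsets_kernel(ComplexVector e1, ComplexVector e2,
                         ComplexVector e3,
                         int nf1, int nf2, int nf3, int nt, int ntr) {
  typedef std::complex<double> cd;
  const Rcomplex *p1 = COMPLEX(e1), *p2 = COMPLEX(e2), *p3 = COMPLEX(e3);
  // repack as [freq][trial][time] (time contiguous)
  const R_xlen_t block = (R_xlen_t)ntr * nt;
  std::vector<cd> c1((R_xlen_t)nf1 * block), c2((R_xlen_t)nf2 * block),
                  c3((R_xlen_t)nf3 * block);
  for (int j = 0; j < ntr; ++j) {
    for (int t = 0; t < nt; ++t) {
      for (int f = 0; f < nf1; ++f)
        c1[(R_xlen_t)f * block + (R_xlen_t)j * nt + t] =
          cplx(p1[(R_xlen_t)f + (R_xlen_t)nf1 * (t + (R_xlen_t)nt * j)]);
      for (int f = 0; f < nf2; ++f)
        c2[(R_xlen_t)f * block + (R_xlen_t)j * nt + t] =
          cplx(p2[(R_xlen_t)f + (R_xlen_t)nf2 * (t + (R_xlen_t)nt * j)]);
      for (int f = 0; f < nf3; ++f)
        c3[(R_xlen_t)f * block + (R_xlen_t)j * nt + t] =
          cplx(p3[(R_xlen_t)f + (R_xlen_t)nf3 * (t + (R_xlen_t)nt * j)]);
    }
  }
  NumericMatrix observed(nf1, nf2);
  NumericVector offset_max(ntr > 1 ? ntr - 1 : 0);
  std::fill(offset_max.begin(), offset_max.end(), 0.0);
  std::vector<cd> s12((R_xlen_t)ntr * nt), acc(nt);
  for (int i2 = 0; i2 < nf2; ++i2) {
    for (int i1 = 0; i1 < nf1; ++i1) {
      const int i3 = i1 + i2;
      if (i3 >= nf3) stop("sum-frequency index out of range");
      const cd *a = &c1[(R_xlen_t)i1 * block];
      const cd *b = &c2[(R_xlen_t)i2 * block];
      const cd *z = &c3[(R_xlen_t)i3 * block];
      for (R_xlen_t k = 0; k < (R_xlen_t)ntr * nt; ++k) s12[k] = a[k] * b[k];
      for (int o = 0; o < ntr; ++o) {
        std::fill(acc.begin(), acc.end(), cd(0.0, 0.0));
        for (int j = 0; j < ntr; ++j) {
          const cd *sj = &s12[(R_xlen_t)j * nt];
          const cd *zj = &z[(R_xlen_t)((j + o) % ntr) * nt];
          for (int t = 0; t < nt; ++t) acc[t] += sj[t] * zj[t];
        }
        double tsum = 0.0;
        for (int t = 0; t < nt; ++t) tsum += std::abs(acc[t]);
        const double val = tsum / ((double)nt * ntr);
        if (o == 0) {
          observed(i1, i2) = val;
        } else if (val > offset_max[o - 1]) {
          offset_max[o - 1] = val;
        }
      }
    }
  }
  return List::create(Named("observed") = observed,
                      Named("offset_max") = offset_max);
}
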