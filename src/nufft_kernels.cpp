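#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Zeroth-order modified Bessel function of the first kind.
// Abramowitz & Stegun 9.8.1 / 9.8.2 polynomial approximations
// (relative error ~1e-7, well below the gridding kernel's aliasing error).
static inline double bessel_i0(double x) {
  double ax = std::fabs(x);
  if (ax < 3.75) {
    double t = x / 3.75;
    t *= t;
    return 1.0 + t * (3.5156229 + t * (3.0899424 + t * (1.2067492 +
               t * (0.2659732 + t * (0.0360768 + t * 0.0045813)))));
  }
  double t = 3.75 / ax;
  return (std::exp(ax) / std::sqrt(ax)) *
         (0.39894228 + t * (0.01328592 + t * (0.00225319 + t * (-0.00157565 +
          t * (0.00916281 + t * (-0.02057706 + t * (0.02635537 +
          t * (-0.01647633 + t * 0.00392377))))))));
}

// Kaiser-Bessel interpolation kernel on [-W/2, W/2].
static inline double kb_weight(double u, double halfW, double beta) {
  double t = u / halfW;
  double s = 1.0 - t * t;
  if (s <= 0.0) return (s > -1e-12) ? 1.0 : 0.0;
  return bessel_i0(beta * std::sqrt(s));
}

// Precompute, for every sample and axis, the W kernel weights and the
// wrapped linear-offset contributions. Returned as a list so the R-side
// plan can cache it across repeated transforms.
// [[Rcpp::export]]
List kb_table_cpp(const NumericMatrix& coords, const IntegerVector& dims,
                  int W, double beta) {
  const int n = coords.nrow(), d = coords.ncol();
  std::vector<long> stride(d);
  stride[0] = 1;
  for (int a = 1; a < d; ++a) stride[a] = stride[a - 1] * dims[a - 1];
  const double halfW = W / 2.0;
  NumericMatrix wts(n, d * W);
  IntegerMatrix offs(n, d * W);
  for (int i = 0; i < n; ++i) {
    for (int a = 0; a < d; ++a) {
      double c = coords(i, a);
      int j0 = (int)std::ceil(c - halfW);
      for (int t = 0; t < W; ++t) {
        wts(i, a * W + t) = kb_weight(c - (double)(j0 + t), halfW, beta);
        int j = (j0 + t) % dims[a];
        if (j < 0) j += dims[a];
        offs(i, a * W + t) = (int)((long)j * stride[a]);
      }
    }
  }
  return List::create(_["wts"] = wts, _["offs"] = offs);
}

// Spread non-uniform samples onto the periodic grid (adjoint of
// interpolation), using a precomputed kernel table.
// [[Rcpp::export]]
ComplexVector kb_spread_tab_cpp(const ComplexVector& y,
                                const NumericMatrix& wts,
                                const IntegerMatrix& offs,
                                const IntegerVector& dims, int W, int d) {
  long total = 1;
  for (int a = 0; a < d; ++a) total *= dims[a];
  const int n = wts.nrow();
  std::vector<std::complex<double> > grid((size_t)total,
                                          std::complex<double>(0.0, 0.0));
  const double* wp = REAL(wts);
  const int* op = INTEGER(offs);
  const long nrow = n;
  for (int i = 0; i < n; ++i) {
    std::complex<double> yi(y[i].r, y[i].i);
    const double* w0 = wp + i;          // column-major: stride nrow
    const int* o0 = op + i;
    if (d == 1) {
      for (int t = 0; t < W; ++t)
        grid[o0[t * nrow]] += w0[t * nrow] * yi;
    } else if (d == 2) {
      for (int t2 = 0; t2 < W; ++t2) {
        double w2 = w0[(W + t2) * nrow];
        long off2 = o0[(W + t2) * nrow];
        std::complex<double> y2 = w2 * yi;
        for (int t1 = 0; t1 < W; ++t1)
          grid[off2 + o0[t1 * nrow]] += w0[t1 * nrow] * y2;
      }
    } else {
      for (int t3 = 0; t3 < W; ++t3) {
        double w3 = w0[(2 * W + t3) * nrow];
        long off3 = o0[(2 * W + t3) * nrow];
        for (int t2 = 0; t2 < W; ++t2) {
          std::complex<double> y23 = (w3 * w0[(W + t2) * nrow]) * yi;
          long off23 = off3 + o0[(W + t2) * nrow];
          for (int t1 = 0; t1 < W; ++t1)
            grid[off23 + o0[t1 * nrow]] += w0[t1 * nrow] * y23;
        }
      }
    }
  }
  ComplexVector out((R_xlen_t)total);
  Rcomplex* outp = COMPLEX(out);
  for (long k = 0; k < total; ++k) {
    outp[k].r = grid[(size_t)k].real();
    outp[k].i = grid[(size_t)k].imag();
  }
  return out;
}

// Interpolate the periodic grid at the tabulated sample positions.
// [[Rcpp::export]]
ComplexVector kb_interp_tab_cpp(const ComplexVector& grid,
                                const NumericMatrix& wts,
                                const IntegerMatrix& offs,
                                const IntegerVector& dims, int W, int d) {
  const int n = wts.nrow();
  const double* wp = REAL(wts);
  const int* op = INTEGER(offs);
  const Rcomplex* gp = COMPLEX(grid);
  const long nrow = n;
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* w0 = wp + i;
    const int* o0 = op + i;
    double ar = 0.0, ai = 0.0;
    if (d == 1) {
      for (int t = 0; t < W; ++t) {
        double w = w0[t * nrow];
        const Rcomplex& g = gp[o0[t * nrow]];
        ar += w * g.r;
        ai += w * g.i;
      }
    } else if (d == 2) {
      for (int t2 = 0; t2 < W; ++t2) {
        double w2 = w0[(W + t2) * nrow];
        long off2 = o0[(W + t2) * nrow];
        double br = 0.0, bi = 0.0;
        for (int t1 = 0; t1 < W; ++t1) {
          double w = w0[t1 * nrow];
          const Rcomplex& g = gp[off2 + o0[t1 * nrow]];
          br += w * g.r;
          bi += w * g.i;
        }
        ar += w2 * br;
        ai += w2 * bi;
      }
    } else {
      for (int t3 = 0; t3 < W; ++t3) {
        double w3 = w0[(2 * W + t3) * nrow];
        long off3 = o0[(2 * W + t3) * nrow];
        double cr = 0.0, ci = 0.0;
        for (int t2 = 0; t2 < W; ++t2) {
          double w2 = w0[(W + t2) * nrow];
          long off23 = off3 + o0[(W + t2) * nrow];
          double br = 0.0, bi = 0.0;
          for (int t1 = 0; t1 < W; ++t1) {
            double w = w0[t1 * nrow];
            const Rcomplex& g = gp[off23 + o0[t1 * nrow]];
            br += w * g.r;
            bi += w * g.i;
          }
          cr += w2 * br;
          ci += w2 * bi;
        }
        ar += w3 * cr;
        ai += w3 * ci;
      }
    }
    out[i].r = ar;
    out[i].i = ai;
  }
  return out;
}
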