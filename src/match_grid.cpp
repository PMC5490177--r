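#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Exhaustive normalized template search over integer shifts and a small set
// of pre-rotated templates.
//
// region:   square matrix of side 2*(search+half)+1, [row = y, col = x],
//           query intensities sampled around the mapped key point.
// templates: (2*half+1)^2 x n_theta matrix, columns are range-normalized
//           template patches flattened column-major ([row = y, col = x]).
// The candidate patch for shift (cx, cy) is the window whose centre sits at
// offset (-cx, -cy) from the region centre; it is range-normalized to
// [0, 255] per window (constant windows normalize to all zeros).
// Returns c(score, cx, cy, theta_index(1-based)) for the minimum Euclidean
// norm; ties broken lexicographically by (theta, cx, cy) via strict '<' in
// ascending loop order.
// [[Rcpp::export]]
NumericVector match_grid_cpp(NumericMatrix region, NumericMatrix templates,
                             int half, int search) {
  const int side = 2 * half + 1;
  const int npix = side * side;
  const int rside = region.nrow();
  const int nshift = 2 * search + 1;
  const int ntheta = templates.ncol();
  if (region.ncol() != rside || rside != side + 2 * search)
    stop("region size inconsistent with half/search");
  if (templates.nrow() != npix) stop("template size mismatch");

  const double *reg = region.begin();
  // cache per-window min and max (windows indexed by (cx, cy))
  std::vector<double> wmin((size_t)nshift * nshift), wmax((size_t)nshift * nshift);
  for (int icx = 0; icx < nshift; ++icx) {
    for (int icy = 0; icy < nshift; ++icy) {
      // cx = icx - search; window top-left col = search - cx = 2*search - icx
      const int col0 = 2 * search - icx;
      const int row0 = 2 * search - icy;
      double mn = DBL_MAX, mx = -DBL_MAX;
      for (int c = 0; c < side; ++c) {
        const double *colp = reg + (size_t)(col0 + c) * rside + row0;
        for (int r = 0; r < side; ++r) {
          const double v = colp[r];
          if (v < mn) mn = v;
          if (v > mx) mx = v;
        }
      }
      wmin[(size_t)icx * nshift + icy] = mn;
      wmax[(size_t)icx * nshift + icy] = mx;
    }
  }

  double best = DBL_MAX;
  int best_cx = 0, best_cy = 0, best_th = 0;
  for (int th = 0; th < ntheta; ++th) {
    const double *tmpl = templates.begin() + (size_t)th * npix;
    for (int icx = 0; icx < nshift; ++icx) {
      for (int icy = 0; icy < nshift; ++icy) {
        const int col0 = 2 * search - icx;
        const int row0 = 2 * search - icy;
        const double mn = wmin[(size_t)icx * nshift + icy];
        const double mx = wmax[(size_t)icx * nshift + icy];
        const double a = (mx - mn > 1e-12) ? 255.0 / (mx - mn) : 0.0;
        double ss = 0.0;
        int p = 0;
        for (int c = 0; c < side; ++c) {
          const double *colp = reg + (size_t)(col0 + c) * rside + row0;
          for (int r = 0; r < side; ++r, ++p) {
            const double q = a * (colp[r] - mn);
            const double d = q - tmpl[p];
            ss += d * d;
          }
        }
        if (ss < best) {
          best = ss;
          best_cx = icx - search;
          best_cy = icy - search;
          best_th = th;
        }
      }
    }
  }
  return NumericVector::create(std::sqrt(best), (double)best_cx,
                               (double)best_cy, (double)(best_th + 1));
}
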