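#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam pixel-driven projector pair. Forward projection splats each
// pixel onto the two nearest detector bins with linear weights; back
// projection is its exact adjoint (bilinear gather along the detector axis).
// Image convention: row 0 = top, x = (col - cx) * ps rightward,
// y = (cy - row) * ps upward, coordinates in mm from the image centre.
// Detector coordinate of a pixel at view angle theta: t = x cos(theta) +
// y sin(theta). The ps^2/ds factor makes a sinogram entry approximate the
// line integral (value * mm) of the image along the ray.

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& img,
                                  const NumericVector& angles,
                                  int n_det, double ds, double ps) {
  const int nr = img.nrow(), nc = img.ncol(), na = angles.size();
  NumericMatrix sino(na, n_det);
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0,
               cd = (n_det - 1) / 2.0, scale = ps * ps / ds;
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int c = 0; c < nc; ++c) {
      const double xc = (c - cx) * ps * ca;
      for (int r = 0; r < nr; ++r) {
        const double v = img(r, c);
        if (v == 0.0) continue;
        const double t = xc + (cy - r) * ps * sa;
        const double u = t / ds + cd;
        const int i0 = (int)std::floor(u);
        const double w = u - i0;
        if (i0 >= 0 && i0 < n_det) sino(a, i0) += v * (1.0 - w) * scale;
        if (i0 + 1 >= 0 && i0 + 1 < n_det) sino(a, i0 + 1) += v * w * scale;
      }
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(const NumericMatrix& sino,
                               const NumericVector& angles,
                               int nr, int nc, double ds, double ps) {
  const int na = angles.size(), n_det = sino.ncol();
  NumericMatrix img(nr, nc);
  const double cx = (nc - 1) / 2.0, cy = (nr - 1) / 2.0,
               cd = (n_det - 1) / 2.0, scale = ps * ps / ds;
  for (int a = 0; a < na; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    for (int c = 0; c < nc; ++c) {
      const double xc = (c - cx) * ps * ca;
      for (int r = 0; r < nr; ++r) {
        const double t = xc + (cy - r) * ps * sa;
        const double u = t / ds + cd;
        const int i0 = (int)std::floor(u);
        const double w = u - i0;
        double v = 0.0;
        if (i0 >= 0 && i0 < n_det) v += sino(a, i0) * (1.0 - w);
        if (i0 + 1 >= 0 && i0 + 1 < n_det) v += sino(a, i0 + 1) * w;
        img(r, c) += v * scale;
      }
    }
  }
  return img;
}
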