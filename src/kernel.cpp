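#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trapezoidal z-aperture at isocenter: FWHM = bw, one-sided ramps of width pen.
static inline double aperture(double z, double half_umbra, double half_base,
                              double pen) {
  double az = std::fabs(z);
  if (az <= half_umbra) return 1.0;
  if (az >= half_base) return 0.0;
  return (half_base - az) / pen;
}

// Accumulate entrance exposure on the unwrapped cylinder.
//
// Rows index z (row centre z = z_min + (i + 0.5) * px), columns index the
// unwrapped circumference u (u = u_min + (j + 0.5) * px, angle phi = u / R).
// The source moves on a helix: gantry angle theta = 2*pi*tau, beam centre
// z_s = z_start + feed * tau, tau in rotations. A plate point is exposed when
// it is the beam-entrance point of the cylinder (cos(theta - phi) > R / fid),
// weighted by inverse-square distance, incidence obliquity (cosine to the
// surface normal, floored at 0) and a Gaussian in fan angle standing in for
// the in-plane beam-shaping fluence profile. The dynamic z-collimator clamps
// the aperture edges (in absolute isocenter z) against the planned range
// boundaries 0 and d at scan start/end.
//
// [[Rcpp::export]]
NumericMatrix cpp_accumulate_exposure(
    int nrow, int ncol, double px, double z_min, double u_min,
    double fid, double plate_radius,
    double bw, double pen, double fan_sigma_deg,
    double feed, double scan_d, double z_start, double z_end,
    double step_deg, bool active, double ramp_rotations) {

  NumericMatrix img(nrow, ncol);
  const double R = plate_radius;
  const double half_umbra = (bw - pen) / 2.0;
  const double half_base  = (bw + pen) / 2.0;
  const double hb = half_base;
  const double two_pi = 2.0 * M_PI;
  const double cos_min = R / fid;             // entrance condition
  const bool finite_fan = std::isfinite(fan_sigma_deg);
  const double sig = fan_sigma_deg * M_PI / 180.0;
  const double gcut = finite_fan ? 4.0 * sig : M_PI;
  const double lag = std::min(1.0, ramp_rotations / 0.5);

  const double total_rot = (z_end - z_start) / feed;
  const int nsteps = std::max(1, (int)std::ceil(total_rot * 360.0 / step_deg));
  const double dtau = total_rot / nsteps;

  for (int k = 0; k < nsteps; ++k) {
    const double tau = (k + 0.5) * dtau;
    const double theta = two_pi * (tau - std::floor(tau));
    const double z_s = z_start + feed * tau;

    // collimator edges in absolute isocenter z
    double lo, hi;
    if (active) {
      lo = std::max(z_s - hb, lag * std::min(z_s, 0.0));
      hi = std::min(z_s + hb, scan_d + lag * std::max(z_s - scan_d, 0.0));
    } else {
      lo = z_s - hb;
      hi = z_s + hb;
    }
    if (hi <= lo) continue;

    for (int j = 0; j < ncol; ++j) {
      const double phi = (u_min + (j + 0.5) * px) / R;
      const double dphi = theta - phi;
      const double delta = dphi - two_pi * std::round(dphi / two_pi);
      const double cd = std::cos(delta);
      if (cd <= cos_min) continue;
      const double rho2 = fid * fid + R * R - 2.0 * fid * R * cd;
      const double rho = std::sqrt(rho2);
      const double cpsi = (fid * cd - R) / rho;     // incidence cosine
      if (cpsi <= 0.0) continue;
      double wfan = 1.0;
      if (finite_fan) {
        const double gamma = std::asin(R * std::fabs(std::sin(delta)) / rho);
        if (gamma > gcut) continue;
        wfan = std::exp(-0.5 * gamma * gamma / (sig * sig));
      }
      const double w = cpsi / rho2 * wfan * dtau;
      const double s = fid / rho;                   // iso-z per plate-z
      const double hbp = half_base / s;             // half base on the plate
      int i0 = (int)std::ceil((z_s - hbp - z_min) / px - 0.5);
      int i1 = (int)std::floor((z_s + hbp - z_min) / px - 0.5);
      if (i0 < 0) i0 = 0;
      if (i1 > nrow - 1) i1 = nrow - 1;
      double *col = &img(0, j);
      for (int i = i0; i <= i1; ++i) {
        const double zoff = (z_min + (i + 0.5) * px - z_s) * s;
        const double zi = z_s + zoff;               // absolute iso z of the ray
        if (zi < lo || zi > hi) continue;
        const double a = aperture(zoff, half_umbra, half_base, pen);
        if (a > 0.0) col[i] += w * a;
      }
    }
  }
  return img;
}
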