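#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Freely rotating chain: unit bonds, fixed angle theta between successive
// bond vectors, uniform azimuth.  First bead at the origin, first bond along
// +z.  Returns an n_beads x 3 coordinate matrix.
// [[Rcpp::export]]
NumericMatrix cpp_generate_frc(int n_beads, double theta) {
  NumericMatrix xyz(n_beads, 3);
  double b[3] = {0.0, 0.0, 1.0};
  xyz(1, 2) = 1.0;
  double ct = std::cos(theta), st = std::sin(theta);
  for (int i = 2; i < n_beads; ++i) {
    // orthonormal frame (u, v) perpendicular to b
    double a[3] = {1.0, 0.0, 0.0};
    if (std::fabs(b[0]) > 0.9) { a[0] = 0.0; a[1] = 1.0; }
    double u[3] = {b[1] * a[2] - b[2] * a[1],
                   b[2] * a[0] - b[0] * a[2],
                   b[0] * a[1] - b[1] * a[0]};
    double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    for (int d = 0; d < 3; ++d) u[d] /= un;
    double v[3] = {b[1] * u[2] - b[2] * u[1],
                   b[2] * u[0] - b[0] * u[2],
                   b[0] * u[1] - b[1] * u[0]};
    double phi = 2.0 * M_PI * unif_rand();
    double cp = std::cos(phi), sp = std::sin(phi);
    double nb[3];
    for (int d = 0; d < 3; ++d) nb[d] = ct * b[d] + st * (cp * u[d] + sp * v[d]);
    for (int d = 0; d < 3; ++d) {
      xyz(i, d) = xyz(i - 1, d) + nb[d];
      b[d] = nb[d];
    }
  }
  return xyz;
}

namespace {

// pair force magnitude dE/dr for LJ (kind 0) or soft-core LJ (kind 1)
inline double pair_dEdr(double r, int kind, double eps, double sigma,
                        double cutoff, double V0, double eta1, double eta2,
                        double rm) {
  if (r >= cutoff) return 0.0;
  if (kind == 1 && r < rm) {
    double u = std::pow(r / rm, eta1);
    double base = 1.0 - u;
    if (base <= 0.0) return 0.0;
    return -V0 * eta2 * std::pow(base, eta2 - 1.0) * eta1 * u / r;
  }
  double sr6 = std::pow(sigma / r, 6.0);
  return 4.0 * eps * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
}

}  // namespace

// Langevin dynamics of a harmonic-spring bead chain with LJ or soft-core LJ
// non-bonded interactions, integrated with velocity Verlet; friction and
// thermal kicks enter the force (BBK scheme).  Coordinates evolve in place
// for n_steps of size dt; returns the final coordinates.
// [[Rcpp::export]]
NumericMatrix cpp_langevin(NumericMatrix coords, double kspring, double eps,
                           double sigma, double cutoff, int pair_kind,
                           double V0, double eta1, double eta2, double rm,
                           double kBT, double gamma_fric, double mass,
                           double dt, int n_steps) {
  int n = coords.nrow();
  NumericMatrix x = clone(coords);
  std::vector<double> vel(3 * n, 0.0), F(3 * n, 0.0), Fn(3 * n, 0.0);
  if (kBT > 0.0) {
    double sd = std::sqrt(kBT / mass);
    for (int i = 0; i < 3 * n; ++i) vel[i] = sd * norm_rand();
  }
  double noise_sd = (kBT > 0.0) ? std::sqrt(2.0 * gamma_fric * kBT / dt) : 0.0;
  double cut2 = cutoff * cutoff;

  auto forces = [&](std::vector<double> &out) {
    std::fill(out.begin(), out.end(), 0.0);
    // springs between consecutive beads, rest length sigma
    for (int i = 0; i < n - 1; ++i) {
      double d[3], r2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        d[c] = x(i + 1, c) - x(i, c);
        r2 += d[c] * d[c];
      }
      double r = std::sqrt(r2);
      if (r < 1e-9) r = 1e-9;
      double fmag = kspring * (r - sigma);  // -dE/dr along -d/r on bead i+1
      for (int c = 0; c < 3; ++c) {
        double f = fmag * d[c] / r;
        out[3 * i + c] += f;
        out[3 * (i + 1) + c] -= f;
      }
    }
    // non-bonded pairs |i-j| >= 2
    for (int i = 0; i < n - 2; ++i) {
      for (int j = i + 2; j < n; ++j) {
        double d[3], r2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          d[c] = x(j, c) - x(i, c);
          r2 += d[c] * d[c];
        }
        if (r2 >= cut2) continue;
        double r = std::sqrt(r2);
        if (r < 1e-9) r = 1e-9;
        double dEdr = pair_dEdr(r, pair_kind, eps, sigma, cutoff, V0, eta1,
                                eta2, rm);
        if (!std::isfinite(dEdr) || std::fabs(dEdr) > 1e14)
          stop("pair force overflow (bead overlap with a hard potential)");
        for (int c = 0; c < 3; ++c) {
          double f = -dEdr * d[c] / r;  // force on bead j
          out[3 * j + c] += f;
          out[3 * i + c] -= f;
        }
      }
    }
    // friction and thermal noise
    for (int i = 0; i < 3 * n; ++i) {
      out[i] -= gamma_fric * vel[i];
      if (noise_sd > 0.0) out[i] += noise_sd * norm_rand();
    }
  };

  forces(F);
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c) {
        x(i, c) += vel[3 * i + c] * dt + 0.5 * F[3 * i + c] / mass * dt * dt;
      }
    // half-step velocity so the friction in the new force uses v(t+dt/2)
    for (int i = 0; i < 3 * n; ++i) vel[i] += 0.5 * F[i] / mass * dt;
    forces(Fn);
    for (int i = 0; i < 3 * n; ++i) vel[i] += 0.5 * Fn[i] / mass * dt;
    std::swap(F, Fn);
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return x;
}
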