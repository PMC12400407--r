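#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
using namespace Rcpp;

// Internal units follow the GROMACS/Martini convention: nm, ps, amu (g/mol),
// kJ/mol.  kB in kJ/(mol K); pressure conversion kJ/(mol nm^3) -> bar.
static const double KB = 0.0083144621;
static const double PRESFAC = 16.6054;

namespace {

struct RNG {
  std::mt19937_64 eng;
  bool has_cache = false;
  double cache = 0.0;
  explicit RNG(uint64_t seed) : eng(seed) {}
  double unif() {
    // 53-bit uniform in (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {
    // Box-Muller: stdlib-independent, reproducible across compilers.
    if (has_cache) { has_cache = false; return cache; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    cache = r * std::sin(a);
    has_cache = true;
    return r * std::cos(a);
  }
};

inline double min_image(double d, double L) { return d - L * std::round(d / L); }

} // namespace

// Soft-sphere mixture integrator: BAOAB Langevin (or velocity Verlet when the
// thermostat is off), pair potential = harmonic repulsive core + quartic
// attractive well, cut at rcut with continuous force:
//   U(r) = a_rep (1 - r/sigma)^2 - eps_ij            r <  sigma
//   U(r) = -eps_ij (1 - x^2)^2, x = (r-sigma)/(rcut-sigma)   sigma <= r < rcut
// Optional external cosine acceleration a_x(z) = A cos(2 pi z / Lz); in that
// case the thermostat acts on peculiar velocities (streaming mode subtracted)
// so friction does not damp the perturbed flow.
// [[Rcpp::export]]
List run_langevin_cpp(NumericMatrix x0, NumericMatrix v0, IntegerVector sp,
                      NumericVector mass_sp, NumericMatrix eps, double sigma,
                      double a_rep, double rcut, NumericVector box0, double dt,
                      int n_steps, int sample_every, double temperature,
                      double gamma, bool thermostat, bool barostat,
                      double pressure0, double tau_p, double compressibility,
                      double cosine_accel, double seed) {
  const int n = x0.nrow();
  double L[3] = {box0[0], box0[1], box0[2]};
  std::vector<double> x(3 * n), xu(3 * n), v(3 * n), f(3 * n), m(n), isq(n);
  for (int i = 0; i < n; ++i) {
    m[i] = mass_sp[sp[i]];
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = x0(i, k);
      xu[3 * i + k] = x0(i, k);
      v[3 * i + k] = v0(i, k);
    }
  }
  RNG rng((uint64_t)seed);

  const double rc2 = rcut * rcut, wr = rcut - sigma;
  double pe = 0.0, virial = 0.0;

  auto forces = [&]() {
    pe = 0.0;
    virial = 0.0;
    std::fill(f.begin(), f.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d[3], r2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          d[k] = min_image(x[3 * i + k] - x[3 * j + k], L[k]);
          r2 += d[k] * d[k];
        }
        if (r2 >= rc2 || r2 <= 0.0) continue;
        double r = std::sqrt(r2), e = eps(sp[i], sp[j]), fr;
        if (r < sigma) {
          double q = 1.0 - r / sigma;
          pe += a_rep * q * q - e;
          fr = 2.0 * a_rep * q / sigma; // repulsive, -dU/dr
        } else {
          double xx = (r - sigma) / wr, om = 1.0 - xx * xx;
          pe += -e * om * om;
          fr = -4.0 * e * xx * om / wr;
        }
        virial += fr * r;
        for (int k = 0; k < 3; ++k) {
          double fk = fr * d[k] / r;
          f[3 * i + k] += fk;
          f[3 * j + k] -= fk;
        }
      }
    if (cosine_accel != 0.0) {
      double kz = 2.0 * M_PI / L[2];
      for (int i = 0; i < n; ++i)
        f[3 * i + 0] += m[i] * cosine_accel * std::cos(kz * x[3 * i + 2]);
    }
  };

  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) ke += 0.5 * m[i] * v[3 * i + k] * v[3 * i + k];
    return ke;
  };

  auto cosine_amplitude = [&]() {
    double kz = 2.0 * M_PI / L[2], num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      double c = std::cos(kz * x[3 * i + 2]);
      num += m[i] * v[3 * i + 0] * c;
      den += m[i] * c * c;
    }
    return den > 0.0 ? num / den : 0.0;
  };

  const double c1 = thermostat ? std::exp(-gamma * dt) : 1.0;
  const double c2 = thermostat ? std::sqrt(1.0 - c1 * c1) : 0.0;
  for (int i = 0; i < n; ++i) isq[i] = std::sqrt(KB * temperature / m[i]);

  const int n_frames = n_steps / sample_every + 1;
  NumericVector xw_out(n * 3 * n_frames), xu_out(n * 3 * n_frames),
      v_out(n * 3 * n_frames), times(n_frames), ke_s(n_frames), pe_s(n_frames),
      vol_s(n_frames), amp_s(n_frames), box_out(3 * n_frames);

  auto sample = [&](int frame, double t) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double xw = x[3 * i + k];
        xw -= L[k] * std::floor(xw / L[k]);
        xw_out[i + n * k + (size_t)n * 3 * frame] = xw;
        xu_out[i + n * k + (size_t)n * 3 * frame] = xu[3 * i + k];
        v_out[i + n * k + (size_t)n * 3 * frame] = v[3 * i + k];
      }
    times[frame] = t;
    ke_s[frame] = kinetic();
    pe_s[frame] = pe;
    vol_s[frame] = L[0] * L[1] * L[2];
    amp_s[frame] = cosine_amplitude();
    for (int k = 0; k < 3; ++k) box_out[k + 3 * frame] = L[k];
  };

  forces();
  sample(0, 0.0);
  const double half = 0.5 * dt;
  int frame = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] += half * f[3 * i + k] / m[i];
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double dx = half * v[3 * i + k];
        if (std::fabs(dx) > 0.5 * L[k])
          stop("integration blew up: displacement exceeds half the box in one step");
        x[3 * i + k] += dx;
        xu[3 * i + k] += dx;
      }
    if (thermostat) {
      if (cosine_accel != 0.0) {
        double V = cosine_amplitude(), kz = 2.0 * M_PI / L[2];
        for (int i = 0; i < n; ++i) {
          double u = V * std::cos(kz * x[3 * i + 2]);
          double p = v[3 * i + 0] - u;
          v[3 * i + 0] = u + c1 * p + c2 * isq[i] * rng.gauss();
          for (int k = 1; k < 3; ++k)
            v[3 * i + k] = c1 * v[3 * i + k] + c2 * isq[i] * rng.gauss();
        }
      } else {
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < 3; ++k)
            v[3 * i + k] = c1 * v[3 * i + k] + c2 * isq[i] * rng.gauss();
      }
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double dx = half * v[3 * i + k];
        x[3 * i + k] += dx;
        xu[3 * i + k] += dx;
      }
    forces();
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] += half * f[3 * i + k] / m[i];
    if (barostat) {
      double vol = L[0] * L[1] * L[2];
      double p_int = (2.0 * kinetic() / 3.0 + virial / 3.0) / vol * PRESFAC;
      double mu3 = 1.0 - (dt / tau_p) * compressibility * (pressure0 - p_int);
      double mu = std::cbrt(std::max(0.5, std::min(1.5, mu3)));
      for (int k = 0; k < 3; ++k) L[k] *= mu;
      for (int i = 0; i < 3 * n; ++i) {
        x[i] *= mu;
        xu[i] *= mu;
      }
      forces(); // box changed; keep force/energy consistent
    }
    if (step % sample_every == 0 && frame < n_frames) {
      sample(frame, step * dt);
      ++frame;
    }
  }

  xw_out.attr("dim") = IntegerVector::create(n, 3, n_frames);
  xu_out.attr("dim") = IntegerVector::create(n, 3, n_frames);
  v_out.attr("dim") = IntegerVector::create(n, 3, n_frames);
  box_out.attr("dim") = IntegerVector::create(3, n_frames);
  return List::create(_["coords"] = xw_out, _["unwrapped"] = xu_out,
                      _["velocities"] = v_out, _["times"] = times,
                      _["kinetic"] = ke_s, _["potential"] = pe_s,
                      _["volume"] = vol_s, _["cosine_amp"] = amp_s,
                      _["box"] = box_out);
}
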