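#include <Rcpp.h>
#include <cmath>
#include <vector>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
using namespace Rcpp;

// The exponential tail of the gradient underflows to subnormal doubles over
// most of a long domain, and subnormal arithmetic is ~100x slower on x86.
// Flush-to-zero mode removes that penalty; values this small are far below
// any physically meaningful amount. RAII so the caller's FP state is restored.
struct FlushDenormals {
#ifdef __SSE2__
  unsigned int old_csr;
  FlushDenormals() : old_csr(_mm_getcsr()) {
    _mm_setcsr(old_csr | 0x8040);  // FTZ | DAZ
  }
  ~FlushDenormals() { _mm_setcsr(old_csr); }
#endif
};

// Forward-Euler integration of the two-state free/bound ligand model
//   du/dt = D d2u/dx2 - a(x) u + b v + g(x)
//   dv/dt = a(x) u - (b + c) v
// on a uniform grid with no-flux (Neumann) boundaries implemented by
// ghost-node mirroring, so the boundary Laplacian is 2*(u[1]-u[0])/dx^2.
// Snapshots of (u, v) are recorded every `record_every` steps, including
// the initial state. Stability (D*dt/dx^2 < 1/2) is checked by the caller.
// [[Rcpp::export]]
List euler_integrate_cpp(NumericVector u0, NumericVector v0,
                         NumericVector a, NumericVector g,
                         double D, double b, double c,
                         double dx, double dt,
                         int n_steps, int record_every) {
  const int n = u0.size();
  if (a.size() != n || g.size() != n || v0.size() != n)
    stop("field lengths must match the grid");
  if (n < 3) stop("grid must have at least 3 nodes");
  if (record_every < 1) stop("record_every must be >= 1");

  FlushDenormals ftz;
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> un(n), vn(n);

  const double alpha = D * dt / (dx * dx);
  const double bc = b + c;

  const int n_rec = n_steps / record_every + 1;
  NumericMatrix U(n_rec, n), V(n_rec, n);
  NumericVector times(n_rec);

  for (int i = 0; i < n; ++i) { U(0, i) = u[i]; V(0, i) = v[i]; }
  times[0] = 0.0;
  int r = 1;

  for (int s = 1; s <= n_steps; ++s) {
    un[0] = u[0] + 2.0 * alpha * (u[1] - u[0])
            + dt * (-a[0] * u[0] + b * v[0] + g[0]);
    vn[0] = v[0] + dt * (a[0] * u[0] - bc * v[0]);
    for (int i = 1; i < n - 1; ++i) {
      const double ui = u[i], vi = v[i];
      un[i] = ui + alpha * (u[i - 1] - 2.0 * ui + u[i + 1])
              + dt * (-a[i] * ui + b * vi + g[i]);
      vn[i] = vi + dt * (a[i] * ui - bc * vi);
    }
    un[n - 1] = u[n - 1] + 2.0 * alpha * (u[n - 2] - u[n - 1])
                + dt * (-a[n - 1] * u[n - 1] + b * v[n - 1] + g[n - 1]);
    vn[n - 1] = v[n - 1] + dt * (a[n - 1] * u[n - 1] - bc * v[n - 1]);
    u.swap(un);
    v.swap(vn);

    if (s % record_every == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(u[i]) || !std::isfinite(v[i]))
          stop("non-finite field values at t = %g s: integration unstable",
               s * dt);
        U(r, i) = u[i];
        V(r, i) = v[i];
      }
      times[r] = s * dt;
      ++r;
    }
  }

  return List::create(_["times"] = times, _["U"] = U, _["V"] = V);
}

// Brownian-dynamics photon trace through a 3-D Gaussian detection volume.
// Particles random-walk in a periodic box (edges bx, by, bz, centred on the
// detection volume); per-frame expected counts are
//   sum_i brightness * dt * exp(-2 (x^2+y^2)/w0^2 - 2 z^2/z0^2)
// for emissive particles, with Poisson photon noise. Optional triplet
// blinking is a two-state telegraph process with equilibrium dark fraction
// T_trip and relaxation time tau_trip. Uses the R RNG, so the trace is
// reproducible from set.seed().
// [[Rcpp::export]]
IntegerVector brownian_trace_cpp(NumericVector D_particle,
                                 double bx, double by, double bz,
                                 double w0, double z0,
                                 double brightness, double dt, int n_steps,
                                 double T_trip, double tau_trip) {
  const int np = D_particle.size();
  if (np < 1) stop("need at least one particle");

  std::vector<double> x(np), y(np), z(np), sigma(np);
  std::vector<int> dark(np, 0);
  for (int i = 0; i < np; ++i) {
    x[i] = R::runif(-bx / 2.0, bx / 2.0);
    y[i] = R::runif(-by / 2.0, by / 2.0);
    z[i] = R::runif(-bz / 2.0, bz / 2.0);
    sigma[i] = std::sqrt(2.0 * D_particle[i] * dt);
  }

  double p_to_dark = 0.0, p_to_bright = 0.0;
  const bool blink = (T_trip > 0.0 && tau_trip > 0.0);
  if (blink) {
    // telegraph rates: k_dark = T/tau, k_bright = (1-T)/tau
    p_to_dark = 1.0 - std::exp(-(T_trip / tau_trip) * dt);
    p_to_bright = 1.0 - std::exp(-((1.0 - T_trip) / tau_trip) * dt);
    for (int i = 0; i < np; ++i)
      dark[i] = (R::unif_rand() < T_trip) ? 1 : 0;
  }

  const double inv_w2 = 2.0 / (w0 * w0);
  const double inv_z2 = 2.0 / (z0 * z0);
  const double amp = brightness * dt;
  IntegerVector counts(n_steps);

  for (int s = 0; s < n_steps; ++s) {
    double lambda = 0.0;
    for (int i = 0; i < np; ++i) {
      if (sigma[i] > 0.0) {
        x[i] += R::norm_rand() * sigma[i];
        y[i] += R::norm_rand() * sigma[i];
        z[i] += R::norm_rand() * sigma[i];
        // periodic wrap (displacements are << box edge)
        if (x[i] > bx / 2.0) x[i] -= bx; else if (x[i] < -bx / 2.0) x[i] += bx;
        if (y[i] > by / 2.0) y[i] -= by; else if (y[i] < -by / 2.0) y[i] += by;
        if (z[i] > bz / 2.0) z[i] -= bz; else if (z[i] < -bz / 2.0) z[i] += bz;
      }
      if (blink) {
        if (dark[i]) {
          if (R::unif_rand() < p_to_bright) dark[i] = 0;
        } else {
          if (R::unif_rand() < p_to_dark) dark[i] = 1;
        }
        if (dark[i]) continue;
      }
      lambda += amp * std::exp(-(x[i] * x[i] + y[i] * y[i]) * inv_w2
                               - z[i] * z[i] * inv_z2);
    }
    counts[s] = (int) R::rpois(lambda);
  }
  return counts;
}
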