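#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Brownian-dynamics photon-trace core for confocal FCS/FCCS simulation.
//
// Particles of each species perform free diffusion (Gaussian steps of
// variance 2*D*dt per axis) inside a box with periodic re-entry, weighted
// by a 3D Gaussian detection profile exp(-2(x^2+y^2)/r0^2 - 2 z^2/zr^2).
// Optional triplet blinking is a two-state telegraph process with dark
// fraction T and correlation time tau_t. Per-bin photon counts are Poisson
// around the deterministic molecular rate; the red channel additionally
// receives a fraction crosstalk_q of the green *molecular* rate.
//
// Randomness comes from an explicitly seeded mt19937_64 so traces are
// reproducible from the config seed alone, independent of R's RNG state.

// [[Rcpp::export]]
List sim_fcs_cpp(IntegerVector n_box, NumericVector D,
                 NumericVector eps_g, NumericVector eps_r,
                 NumericVector trip_T, NumericVector trip_tau,
                 double r0, double zr,
                 double hx, double hy, double hz,
                 double dt, int nbins,
                 double crosstalk_q, double bg_g, double bg_r,
                 double seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> norm(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  using pois_t = std::poisson_distribution<int>;
  pois_t pois;

  const int ns = n_box.size();
  int ntot = 0;
  for (int i = 0; i < ns; ++i) ntot += n_box[i];

  std::vector<double> x(ntot), y(ntot), z(ntot), sig(ntot), eg(ntot), er(ntot);
  std::vector<double> p_dark(ntot), p_bright(ntot);
  std::vector<char> dark(ntot, 0), blinks(ntot, 0);

  int p = 0;
  for (int i = 0; i < ns; ++i) {
    const double s = std::sqrt(2.0 * D[i] * dt);
    // telegraph rates: k_dark = T/tau_t, k_bright = (1-T)/tau_t
    const bool bl = trip_T[i] > 0.0;
    const double pd = bl ? -std::expm1(-(trip_T[i] / trip_tau[i]) * dt) : 0.0;
    const double pb = bl ? -std::expm1(-((1.0 - trip_T[i]) / trip_tau[i]) * dt) : 0.0;
    for (int k = 0; k < n_box[i]; ++k, ++p) {
      x[p] = (2.0 * unif(rng) - 1.0) * hx;
      y[p] = (2.0 * unif(rng) - 1.0) * hy;
      z[p] = (2.0 * unif(rng) - 1.0) * hz;
      sig[p] = s;
      eg[p] = eps_g[i];
      er[p] = eps_r[i];
      blinks[p] = bl ? 1 : 0;
      p_dark[p] = pd;
      p_bright[p] = pb;
      if (bl) dark[p] = (unif(rng) < trip_T[i]) ? 1 : 0;  // equilibrium start
    }
  }

  NumericVector out_g(nbins), out_r(nbins);
  const double ir2 = 2.0 / (r0 * r0), iz2 = 2.0 / (zr * zr);
  const double wx = 2.0 * hx, wy = 2.0 * hy, wz = 2.0 * hz;

  for (int t = 0; t < nbins; ++t) {
    double rate_g = 0.0, rate_r = 0.0;
    for (int q = 0; q < ntot; ++q) {
      double xx = x[q] + sig[q] * norm(rng);
      double yy = y[q] + sig[q] * norm(rng);
      double zz = z[q] + sig[q] * norm(rng);
      if (xx > hx) xx -= wx; else if (xx < -hx) xx += wx;
      if (yy > hy) yy -= wy; else if (yy < -hy) yy += wy;
      if (zz > hz) zz -= wz; else if (zz < -hz) zz += wz;
      x[q] = xx; y[q] = yy; z[q] = zz;
      if (blinks[q]) {
        const double u = unif(rng);
        if (dark[q]) { if (u < p_bright[q]) dark[q] = 0; }
        else         { if (u < p_dark[q])   dark[q] = 1; }
        if (dark[q]) continue;
      }
      const double w = std::exp(-(xx * xx + yy * yy) * ir2 - zz * zz * iz2);
      rate_g += eg[q] * w;
      rate_r += er[q] * w;
    }
    const double lg = rate_g + bg_g;
    const double lr = rate_r + crosstalk_q * rate_g + bg_r;
    out_g[t] = lg > 0.0 ? pois(rng, pois_t::param_type(lg)) : 0.0;
    out_r[t] = lr > 0.0 ? pois(rng, pois_t::param_type(lr)) : 0.0;
  }

  return List::create(_["green"] = out_g, _["red"] = out_r);
}
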