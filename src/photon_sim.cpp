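#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "rng.h"

using namespace Rcpp;

// One emission pathway of a species: Poisson rate (at beam centre, counts/s)
// into a fixed detection channel and excitation gate.
struct Pathway {
  double rate;
  int channel; // 0 = D, 1 = A
  int gate;    // 0 = Dex, 1 = Aex
};

// Brownian photon-stream simulator. Point emitters diffuse in a periodic box;
// the detection weight is a 3D Gaussian W = exp(-2(x^2+y^2)/w0^2 - 2z^2/z0^2).
// Photon emission uses per-pathway exponential clocks driven by the
// accumulated intensity integral, so no per-step Poisson draw is needed;
// photon times are jittered uniformly within their generating step.
//
// species: matrix with columns (class, stoichiometry, conc, D, eps, efret)
//          class: 0 donor-only, 1 acceptor-only, 2 dual-labelled
// [[Rcpp::export(name = ".simulate_photons_cpp")]]
List simulate_photons_cpp(NumericMatrix species, double w0, double z0,
                          double leak, double direct, double bg_rate,
                          double duration, double dt, NumericVector box,
                          double seed, Nullable<NumericMatrix> positions0) {
  FbRng rng((uint64_t)seed);

  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
  const double iw2 = 2.0 / (w0 * w0), iz2 = 2.0 / (z0 * z0);

  // particle bookkeeping
  std::vector<double> px, py, pz, sigma;
  std::vector<int> path_start, path_len;
  std::vector<Pathway> paths;
  std::vector<int> species_of;

  const int ns = species.nrow();
  IntegerVector n_per_species(ns);
  for (int s = 0; s < ns; ++s) {
    const int cls = (int)species(s, 0);
    const double stoich = species(s, 1), conc = species(s, 2);
    const double D = species(s, 3), eps = species(s, 4), ef = species(s, 5);
    const double E = stoich * eps; // peak rate of the particle
    int p0 = (int)paths.size();
    if (cls == 0) { // donor-only: leak fraction lands in the acceptor channel
      paths.push_back({E * (1.0 - leak), 0, 0});
      if (leak > 0) paths.push_back({E * leak, 1, 0});
    } else if (cls == 1) { // acceptor-only: direct excitation under Dex
      paths.push_back({E, 1, 1});
      if (direct > 0) paths.push_back({E * direct, 1, 0});
    } else { // dual: FRET split under Dex, acceptor emits under Aex
      const double dDex = (1.0 - ef) * (1.0 - leak);
      const double aDex = (1.0 - ef) * leak + ef + direct;
      if (dDex > 0) paths.push_back({E * dDex, 0, 0});
      if (aDex > 0) paths.push_back({E * aDex, 1, 0});
      paths.push_back({E, 1, 1});
    }
    const int plen = (int)paths.size() - p0;
    // stochastic rounding keeps the expected particle number exact even for
    // species whose mean count in the box is fractional
    const double xn = conc * Lx * Ly * Lz;
    long n = (long)std::floor(xn);
    if (rng.unif() < xn - n) ++n;
    n_per_species[s] = (int)n;
    const double sg = std::sqrt(2.0 * D * dt);
    for (long i = 0; i < n; ++i) {
      px.push_back((rng.unif() - 0.5) * Lx);
      py.push_back((rng.unif() - 0.5) * Ly);
      pz.push_back((rng.unif() - 0.5) * Lz);
      sigma.push_back(sg);
      path_start.push_back(p0);
      path_len.push_back(plen);
      species_of.push_back(s);
    }
  }

  // optional fixed initial positions (validation hook), recycled over particles
  if (positions0.isNotNull()) {
    NumericMatrix P(positions0);
    for (size_t i = 0; i < px.size(); ++i) {
      int r = (int)(i % P.nrow());
      px[i] = P(r, 0);
      py[i] = P(r, 1);
      pz[i] = P(r, 2);
    }
  }

  const size_t np = px.size();
  // per particle-pathway exponential clocks
  std::vector<double> acc, target;
  std::vector<int> clock_path;
  std::vector<int> clock_of_particle(np + 1, 0);
  for (size_t i = 0; i < np; ++i) {
    clock_of_particle[i] = (int)acc.size();
    for (int p = 0; p < path_len[i]; ++p) {
      acc.push_back(0.0);
      target.push_back(rng.exp1());
      clock_path.push_back(path_start[i] + p);
    }
  }
  clock_of_particle[np] = (int)acc.size();

  std::vector<double> t_out;
  std::vector<int> ch_out, gate_out;

  const long nsteps = (long)std::floor(duration / dt + 1e-9);
  const double rem = duration - nsteps * dt;
  const double qmax = 12.0; // skipped region contributes < 3e-5 of total emission

  for (long step = 0; step <= nsteps; ++step) {
    const double step_dt = (step < nsteps) ? dt : rem;
    if (step_dt <= 0) break;
    const double t0 = step * dt;
    for (size_t i = 0; i < np; ++i) {
      double x = px[i] + sigma[i] * rng.normal();
      double y = py[i] + sigma[i] * rng.normal();
      double z = pz[i] + sigma[i] * rng.normal();
      if (x > hx) x -= Lx; else if (x < -hx) x += Lx;
      if (y > hy) y -= Ly; else if (y < -hy) y += Ly;
      if (z > hz) z -= Lz; else if (z < -hz) z += Lz;
      px[i] = x; py[i] = y; pz[i] = z;
      const double q = (x * x + y * y) * iw2 + z * z * iz2;
      if (q > qmax) continue;
      const double W = std::exp(-q);
      const int c0 = clock_of_particle[i], c1 = clock_of_particle[i + 1];
      for (int c = c0; c < c1; ++c) {
        acc[c] += paths[clock_path[c]].rate * W * step_dt;
        while (acc[c] >= target[c]) {
          t_out.push_back(t0 + rng.unif() * step_dt);
          ch_out.push_back(paths[clock_path[c]].channel);
          gate_out.push_back(paths[clock_path[c]].gate);
          target[c] += rng.exp1();
        }
      }
    }
  }

  // uncorrelated background, per channel; gates split evenly (the background
  // is not synchronized with either laser)
  if (bg_rate > 0 && duration > 0) {
    for (int c = 0; c < 2; ++c) {
      int nb = rng.poisson(bg_rate * duration);
      for (int i = 0; i < nb; ++i) {
        t_out.push_back(rng.unif() * duration);
        ch_out.push_back(c);
        gate_out.push_back((int)(rng.next_u64() & 1ULL));
      }
    }
  }

  // sort by arrival time
  const size_t n = t_out.size();
  std::vector<size_t> ord(n);
  for (size_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return t_out[a] < t_out[b]; });
  NumericVector times(n);
  IntegerVector channel(n), gate(n);
  for (size_t i = 0; i < n; ++i) {
    times[i] = t_out[ord[i]];
    channel[i] = ch_out[ord[i]];
    gate[i] = gate_out[ord[i]];
  }

  return List::create(_["times"] = times, _["channel"] = channel,
                      _["gate"] = gate, _["n_particles"] = n_per_species);
}

// Test hooks for the internal generator.
// [[Rcpp::export(name = ".rng_normal_cpp")]]
NumericVector rng_normal_cpp(int n, double seed) {
  FbRng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.normal();
  return out;
}

// [[Rcpp::export(name = ".rng_unif_cpp")]]
NumericVector rng_unif_cpp(int n, double seed) {
  FbRng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.unif();
  return out;
}
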