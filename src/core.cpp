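// Compiled core: periodic energy terms, Metropolis / BAOAB samplers,
// batched frame re-evaluation, Widom test-particle insertion.
// Energies are reduced (k_B T) throughout; beta = 1.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

enum TermType { SITE_RESTRAINT = 0, LJ_PAIR = 1, HARMONIC_BOND = 2, SOFTCORE_PAIR = 3 };

struct Term {
  int type;
  double coeff;
  // site_restraint
  double k;
  std::vector<double> ref; // natoms x 3, column-major
  int exclude;             // 0-based fixed atom, -1 none
  // lj / softcore
  double eps, sigma, cutoff, lambda, alpha;
  std::vector<int> A, B;          // 0-based member indices
  std::vector<uint8_t> inA, inB;  // masks over all atoms
  bool cross;                     // true: A-B pairs; false: all pairs within A
  // bonds
  std::vector<int> b1, b2;
  std::vector<double> kb, r0;
};

static inline double min_image(double d, double L) {
  return d - L * std::nearbyint(d / L);
}

static std::vector<Term> parse_terms(const List& terms, int natoms) {
  std::vector<Term> out;
  for (int t = 0; t < terms.size(); ++t) {
    List tl = terms[t];
    Term tm;
    std::string ty = as<std::string>(tl["type"]);
    tm.coeff = tl.containsElementNamed("coeff") ? as<double>(tl["coeff"]) : 1.0;
    if (ty == "site_restraint") {
      tm.type = SITE_RESTRAINT;
      tm.k = as<double>(tl["k"]);
      NumericMatrix ref = tl["ref"];
      if (ref.nrow() != natoms || ref.ncol() != 3)
        stop("site_restraint reference dimensions do not match configuration");
      tm.ref.assign(ref.begin(), ref.end());
      tm.exclude = tl.containsElementNamed("exclude") ? as<int>(tl["exclude"]) - 1 : -1;
    } else if (ty == "lj_pair" || ty == "softcore_pair") {
      tm.type = (ty == "lj_pair") ? LJ_PAIR : SOFTCORE_PAIR;
      tm.eps = as<double>(tl["eps"]);
      tm.sigma = as<double>(tl["sigma"]);
      tm.cutoff = as<double>(tl["cutoff"]);
      tm.lambda = tl.containsElementNamed("lambda") ? as<double>(tl["lambda"]) : 1.0;
      tm.alpha = tl.containsElementNamed("alpha") ? as<double>(tl["alpha"]) : 0.5;
      IntegerVector A = tl["A"];
      for (int i = 0; i < A.size(); ++i) tm.A.push_back(A[i] - 1);
      tm.cross = false;
      if (tl.containsElementNamed("B")) {
        IntegerVector B = tl["B"];
        if (B.size() > 0) {
          tm.cross = true;
          for (int i = 0; i < B.size(); ++i) tm.B.push_back(B[i] - 1);
        }
      }
      tm.inA.assign(natoms, 0);
      tm.inB.assign(natoms, 0);
      for (int i : tm.A) {
        if (i < 0 || i >= natoms) stop("pair term index out of range");
        tm.inA[i] = 1;
      }
      for (int i : tm.B) {
        if (i < 0 || i >= natoms) stop("pair term index out of range");
        tm.inB[i] = 1;
      }
    } else if (ty == "harmonic_bond") {
      tm.type = HARMONIC_BOND;
      IntegerMatrix bonds = tl["bonds"];
      NumericVector kb = tl["kb"], r0 = tl["r0"];
      for (int i = 0; i < bonds.nrow(); ++i) {
        tm.b1.push_back(bonds(i, 0) - 1);
        tm.b2.push_back(bonds(i, 1) - 1);
        tm.kb.push_back(kb[i]);
        tm.r0.push_back(r0[i]);
      }
    } else {
      stop("unknown energy term type: %s", ty.c_str());
    }
    out.push_back(tm);
  }
  return out;
}

static inline double lj_u(double r2, double eps, double sigma) {
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  return 4.0 * eps * (s6 * s6 - s6);
}

// Beutler-style soft core, finite at r -> 0 for lambda < 1.
static inline double sc_u(double r2, double eps, double sigma, double lambda, double alpha) {
  double s2 = r2 / (sigma * sigma);
  double s6 = s2 * s2 * s2;
  double D = alpha * (1.0 - lambda) * (1.0 - lambda) + s6;
  return 4.0 * eps * lambda * (1.0 / (D * D) - 1.0 / D);
}

static double pair_sum(const Term& tm, const double* x, int n, const double* box, int only) {
  // only >= 0: restrict to pairs involving that atom
  double e = 0.0;
  double rc2 = tm.cutoff * tm.cutoff;
  auto pe = [&](int i, int j) {
    double dx = min_image(x[i] - x[j], box[0]);
    double dy = min_image(x[i + n] - x[j + n], box[1]);
    double dz = min_image(x[i + 2 * n] - x[j + 2 * n], box[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return 0.0;
    if (tm.type == LJ_PAIR) return lj_u(r2, tm.eps, tm.sigma);
    return sc_u(r2, tm.eps, tm.sigma, tm.lambda, tm.alpha);
  };
  if (!tm.cross) {
    if (only >= 0) {
      if (!tm.inA[only]) return 0.0;
      for (int j : tm.A)
        if (j != only) e += pe(only, j);
    } else {
      for (size_t a = 0; a < tm.A.size(); ++a)
        for (size_t b = a + 1; b < tm.A.size(); ++b) e += pe(tm.A[a], tm.A[b]);
    }
  } else {
    if (only >= 0) {
      if (tm.inA[only])
        for (int j : tm.B) e += pe(only, j);
      else if (tm.inB[only])
        for (int j : tm.A) e += pe(only, j);
    } else {
      for (int i : tm.A)
        for (int j : tm.B) e += pe(i, j);
    }
  }
  return e;
}

static double term_energy(const Term& tm, const double* x, int n, const double* box, int only) {
  switch (tm.type) {
    case SITE_RESTRAINT: {
      double e = 0.0;
      if (only >= 0) {
        if (only == tm.exclude) return 0.0;
        double dx = x[only] - tm.ref[only];
        double dy = x[only + n] - tm.ref[only + n];
        double dz = x[only + 2 * n] - tm.ref[only + 2 * n];
        return 0.5 * tm.k * (dx * dx + dy * dy + dz * dz);
      }
      for (int i = 0; i < n; ++i) {
        if (i == tm.exclude) continue;
        double dx = x[i] - tm.ref[i];
        double dy = x[i + n] - tm.ref[i + n];
        double dz = x[i + 2 * n] - tm.ref[i + 2 * n];
        e += 0.5 * tm.k * (dx * dx + dy * dy + dz * dz);
      }
      return e;
    }
    case LJ_PAIR:
    case SOFTCORE_PAIR:
      return pair_sum(tm, x, n, box, only);
    case HARMONIC_BOND: {
      double e = 0.0;
      for (size_t b = 0; b < tm.b1.size(); ++b) {
        int i = tm.b1[b], j = tm.b2[b];
        if (only >= 0 && i != only && j != only) continue;
        double dx = min_image(x[i] - x[j], box[0]);
        double dy = min_image(x[i + n] - x[j + n], box[1]);
        double dz = min_image(x[i + 2 * n] - x[j + 2 * n], box[2]);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double d = r - tm.r0[b];
        e += 0.5 * tm.kb[b] * d * d;
      }
      return e;
    }
  }
  return 0.0;
}

static void term_force(const Term& tm, const double* x, int n, const double* box, double* f) {
  // accumulates coeff-weighted forces (-dU/dx) into f (natoms x 3, column-major)
  double c = tm.coeff;
  if (c == 0.0) return;
  switch (tm.type) {
    case SITE_RESTRAINT: {
      for (int i = 0; i < n; ++i) {
        if (i == tm.exclude) continue;
        f[i] -= c * tm.k * (x[i] - tm.ref[i]);
        f[i + n] -= c * tm.k * (x[i + n] - tm.ref[i + n]);
        f[i + 2 * n] -= c * tm.k * (x[i + 2 * n] - tm.ref[i + 2 * n]);
      }
      return;
    }
    case HARMONIC_BOND: {
      for (size_t b = 0; b < tm.b1.size(); ++b) {
        int i = tm.b1[b], j = tm.b2[b];
        double dx = min_image(x[i] - x[j], box[0]);
        double dy = min_image(x[i + n] - x[j + n], box[1]);
        double dz = min_image(x[i + 2 * n] - x[j + 2 * n], box[2]);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < 1e-12) continue;
        double g = c * tm.kb[b] * (r - tm.r0[b]) / r;
        f[i] -= g * dx; f[j] += g * dx;
        f[i + n] -= g * dy; f[j + n] += g * dy;
        f[i + 2 * n] -= g * dz; f[j + 2 * n] += g * dz;
      }
      return;
    }
    case LJ_PAIR:
    case SOFTCORE_PAIR: {
      double rc2 = tm.cutoff * tm.cutoff;
      double s2i = 1.0 / (tm.sigma * tm.sigma);
      auto add = [&](int i, int j) {
        double dx = min_image(x[i] - x[j], box[0]);
        double dy = min_image(x[i + n] - x[j + n], box[1]);
        double dz = min_image(x[i + 2 * n] - x[j + 2 * n], box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2 || r2 < 1e-14) return;
        double g; // dU/d(r2)
        if (tm.type == LJ_PAIR) {
          double s2 = tm.sigma * tm.sigma / r2;
          double s6 = s2 * s2 * s2;
          // dU/dr2 = 4 eps (-6 s12 + 3 s6) / r2  with s12=s6^2
          g = 4.0 * tm.eps * (-6.0 * s6 * s6 + 3.0 * s6) / r2;
        } else {
          double s6 = (r2 * s2i) * (r2 * s2i) * (r2 * s2i);
          double D = tm.alpha * (1.0 - tm.lambda) * (1.0 - tm.lambda) + s6;
          double dUds6 = 4.0 * tm.eps * tm.lambda * (-2.0 / (D * D * D) + 1.0 / (D * D));
          double ds6dr2 = 3.0 * (r2 * s2i) * (r2 * s2i) * s2i;
          g = dUds6 * ds6dr2;
        }
        double h = -2.0 * c * g;
        f[i] += h * dx; f[j] -= h * dx;
        f[i + n] += h * dy; f[j + n] -= h * dy;
        f[i + 2 * n] += h * dz; f[j + 2 * n] -= h * dz;
      };
      if (!tm.cross) {
        for (size_t a = 0; a < tm.A.size(); ++a)
          for (size_t b = a + 1; b < tm.A.size(); ++b) add(tm.A[a], tm.A[b]);
      } else {
        for (int i : tm.A)
          for (int j : tm.B) add(i, j);
      }
      return;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_term_energies(NumericMatrix coords, List terms, NumericVector box) {
  int n = coords.nrow();
  std::vector<Term> tms = parse_terms(terms, n);
  NumericVector out(tms.size());
  for (size_t t = 0; t < tms.size(); ++t)
    out[t] = term_energy(tms[t], coords.begin(), n, box.begin(), -1);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_term_energies_frames(NumericVector frames, List terms, NumericVector box) {
  IntegerVector dim = frames.attr("dim");
  if (dim.size() != 3 || dim[1] != 3) stop("frames must be a natoms x 3 x nframes array");
  int n = dim[0], nf = dim[2];
  std::vector<Term> tms = parse_terms(terms, n);
  NumericMatrix out(nf, tms.size());
  const double* base = frames.begin();
  for (int fidx = 0; fidx < nf; ++fidx) {
    const double* x = base + (size_t)fidx * 3 * n;
    for (size_t t = 0; t < tms.size(); ++t)
      out(fidx, t) = term_energy(tms[t], x, n, box.begin(), -1);
  }
  return out;
}

static double total_energy(const std::vector<Term>& tms, const double* x, int n,
                           const double* box, int only) {
  double e = 0.0;
  for (const Term& tm : tms)
    if (tm.coeff != 0.0) e += tm.coeff * term_energy(tm, x, n, box, only);
  return e;
}

// [[Rcpp::export]]
List cpp_mc_sample(NumericMatrix coords0, List terms, NumericVector box, int fixed,
                   int n_sweeps, int n_equil, double step0, bool tune, int save_every,
                   double seed) {
  int n = coords0.nrow();
  std::vector<Term> tms = parse_terms(terms, n);
  std::vector<double> x(coords0.begin(), coords0.end());
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  int fx = fixed - 1; // -1 when fixed == 0 (no fixed atom)
  double step = step0;
  double minbox = std::min(box[0], std::min(box[1], box[2]));

  long acc = 0, att = 0, acc_tot = 0, att_tot = 0;
  int n_save = 0;
  for (int s = n_equil; s < n_sweeps; s += save_every) ++n_save;
  NumericVector frames((size_t)n * 3 * n_save);
  frames.attr("dim") = IntegerVector::create(n, 3, n_save);
  NumericVector energies(n_save);
  int isave = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      if (i == fx) continue;
      double old[3] = {x[i], x[i + n], x[i + 2 * n]};
      double e0 = total_energy(tms, x.data(), n, box.begin(), i);
      x[i] = old[0] + step * (2.0 * U(rng) - 1.0);
      x[i + n] = old[1] + step * (2.0 * U(rng) - 1.0);
      x[i + 2 * n] = old[2] + step * (2.0 * U(rng) - 1.0);
      double e1 = total_energy(tms, x.data(), n, box.begin(), i);
      double dE = e1 - e0;
      ++att;
      if (dE <= 0.0 || U(rng) < std::exp(-dE)) {
        ++acc;
      } else {
        x[i] = old[0]; x[i + n] = old[1]; x[i + 2 * n] = old[2];
      }
    }
    if (tune && sweep < n_equil && att >= 25L * n) {
      double rate = (double)acc / (double)att;
      if (rate < 0.30) step *= 0.85;
      else if (rate > 0.50) step *= 1.15;
      if (step > 0.45 * minbox) step = 0.45 * minbox;
      acc = 0; att = 0;
    }
    if (sweep == n_equil - 1) { acc = 0; att = 0; } // production statistics only
    if (sweep >= n_equil) { acc_tot = acc; att_tot = att; }
    if (sweep >= n_equil && (sweep - n_equil) % save_every == 0) {
      std::copy(x.begin(), x.end(), frames.begin() + (size_t)isave * 3 * n);
      energies[isave] = total_energy(tms, x.data(), n, box.begin(), -1);
      ++isave;
    }
  }
  double rate = att_tot > 0 ? (double)acc_tot / (double)att_tot : NA_REAL;
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["acceptance"] = rate, _["step"] = step);
}

// [[Rcpp::export]]
List cpp_baoab(NumericMatrix coords0, List terms, NumericVector box, int fixed,
               int n_steps, int n_equil, double dt, double gamma, int save_every,
               double seed) {
  int n = coords0.nrow();
  std::vector<Term> tms = parse_terms(terms, n);
  std::vector<double> x(coords0.begin(), coords0.end());
  std::vector<double> v(3 * n, 0.0), f(3 * n, 0.0);
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> N01(0.0, 1.0);
  int fx = fixed - 1;
  double c1 = std::exp(-gamma * dt), c2 = std::sqrt(1.0 - c1 * c1); // m = 1, beta = 1

  auto forces = [&]() {
    std::fill(f.begin(), f.end(), 0.0);
    for (const Term& tm : tms) term_force(tm, x.data(), n, box.begin(), f.data());
    if (fx >= 0) { f[fx] = 0.0; f[fx + n] = 0.0; f[fx + 2 * n] = 0.0; }
  };
  forces();
  for (int d = 0; d < 3 * n; ++d) v[d] = N01(rng); // Maxwell-Boltzmann start
  if (fx >= 0) { v[fx] = 0.0; v[fx + n] = 0.0; v[fx + 2 * n] = 0.0; }

  int n_save = 0;
  for (int s = n_equil; s < n_steps; s += save_every) ++n_save;
  NumericVector frames((size_t)n * 3 * n_save);
  frames.attr("dim") = IntegerVector::create(n, 3, n_save);
  NumericVector energies(n_save);
  int isave = 0;

  for (int step = 0; step < n_steps; ++step) {
    for (int d = 0; d < 3 * n; ++d) v[d] += 0.5 * dt * f[d];
    for (int d = 0; d < 3 * n; ++d) x[d] += 0.5 * dt * v[d];
    for (int d = 0; d < 3 * n; ++d) v[d] = c1 * v[d] + c2 * N01(rng);
    if (fx >= 0) { v[fx] = 0.0; v[fx + n] = 0.0; v[fx + 2 * n] = 0.0; }
    for (int d = 0; d < 3 * n; ++d) x[d] += 0.5 * dt * v[d];
    if (fx >= 0) { x[fx] = coords0(fx, 0); x[fx + n] = coords0(fx, 1); x[fx + 2 * n] = coords0(fx, 2); }
    forces();
    for (int d = 0; d < 3 * n; ++d) v[d] += 0.5 * dt * f[d];
    if (fx >= 0) { v[fx] = 0.0; v[fx + n] = 0.0; v[fx + 2 * n] = 0.0; }
    if (step >= n_equil && (step - n_equil) % save_every == 0) {
      std::copy(x.begin(), x.end(), frames.begin() + (size_t)isave * 3 * n);
      energies[isave] = total_energy(tms, x.data(), n, box.begin(), -1);
      ++isave;
    }
  }
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["acceptance"] = NA_REAL, _["step"] = dt);
}

// [[Rcpp::export]]
NumericVector cpp_widom(NumericVector frames, NumericVector box, IntegerVector solvent,
                        double eps, double sigma, double cutoff, int n_insertions,
                        double seed) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericVector dU(n_insertions);
  double rc2 = cutoff * cutoff;
  for (int ins = 0; ins < n_insertions; ++ins) {
    const double* x = frames.begin() + (size_t)(ins % nf) * 3 * n;
    double px = box[0] * U(rng), py = box[1] * U(rng), pz = box[2] * U(rng);
    double e = 0.0;
    for (int a = 0; a < solvent.size(); ++a) {
      int j = solvent[a] - 1;
      double dx = min_image(px - x[j], box[0]);
      double dy = min_image(py - x[j + n], box[1]);
      double dz = min_image(pz - x[j + 2 * n], box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rc2) e += lj_u(r2, eps, sigma);
    }
    dU[ins] = e;
  }
  return dU;
}
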