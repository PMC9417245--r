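// Metropolis Monte Carlo pulling engine on a C-alpha structure-based
// (Go-type) energy model. Energies are in kT; lengths in nm. One MC
// sweep = one attempted move per mobile bead; the virtual-spring target
// distance advances by v nm per sweep.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Pair {
  int type;      // 0 repulsion, 1 bond, 2 contact, -1 none (self)
  double p1;     // bond r0 / contact sigma / unused
  double p2;     // contact eps
  bool inter;    // inter-chain contact
};

inline double dist3(const std::vector<double>& x, int i, int j) {
  double dx = x[3 * i] - x[3 * j];
  double dy = x[3 * i + 1] - x[3 * j + 1];
  double dz = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

inline double pair_energy(const Pair& p, double r, double bond_k,
                          double rep_radius, double rep_eps) {
  switch (p.type) {
  case 1: {
    double d = r - p.p1;
    return 0.5 * bond_k * d * d;
  }
  case 2: {
    double u = p.p1 / r;
    double u2 = u * u;
    double u10 = u2 * u2 * u2 * u2 * u2;
    return p.p2 * (5.0 * u10 * u2 - 6.0 * u10);
  }
  case 0: {
    double u = rep_radius / r;
    double u2 = u * u;
    double u6 = u2 * u2 * u2;
    return rep_eps * u6 * u6;
  }
  default:
    return 0.0;
  }
}

} // namespace

// [[Rcpp::export]]
List mcp_run_cpp(NumericMatrix coords0, IntegerVector chain,
                 IntegerMatrix bonds, NumericVector bond_r0, double bond_k,
                 IntegerMatrix contacts, NumericVector contact_sigma,
                 NumericVector contact_eps, LogicalVector contact_inter,
                 double rep_radius, double rep_eps,
                 int anchor_a, int anchor_b, LogicalVector frozen,
                 double k_spring, double L0, double v_nm_sweep,
                 int max_sweeps, int record_stride, int dwell,
                 double sigma0, bool tune, double crank_frac,
                 double crank_max_angle, double break_factor) {
  const int n = coords0.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords0(i, d);

  // pair lookup table
  std::vector<Pair> ptab(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      ptab[i * n + j] = {i == j ? -1 : 0, 0.0, 0.0, false};
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
    ptab[i * n + j] = ptab[j * n + i] = {1, bond_r0[b], 0.0, false};
  }
  const int nc = contacts.nrow();
  std::vector<int> ci(nc), cj(nc);
  for (int c = 0; c < nc; ++c) {
    int i = contacts(c, 0) - 1, j = contacts(c, 1) - 1;
    ci[c] = i; cj[c] = j;
    ptab[i * n + j] = ptab[j * n + i] =
      {2, contact_sigma[c], contact_eps[c], (bool)contact_inter[c]};
  }
  bool has_inter = false;
  for (int c = 0; c < nc; ++c) if (contact_inter[c]) has_inter = true;

  std::vector<int> mobile;
  for (int i = 0; i < n; ++i) if (!frozen[i]) mobile.push_back(i);
  const int nmob = (int)mobile.size();
  if (nmob == 0) stop("all beads frozen");
  const int ia = anchor_a - 1, ib = anchor_b - 1;

  // crankshaft candidates: mobile beads with same-chain neighbors i-1, i+1
  std::vector<int> crank;
  for (int k = 0; k < nmob; ++k) {
    int i = mobile[k];
    if (i > 0 && i < n - 1 && chain[i - 1] == chain[i] &&
        chain[i + 1] == chain[i])
      crank.push_back(i);
  }

  auto local_energy = [&](int i) {
    double e = 0.0;
    for (int j = 0; j < n; ++j) {
      const Pair& p = ptab[i * n + j];
      if (p.type < 0) continue;
      e += pair_energy(p, dist3(x, i, j), bond_k, rep_radius, rep_eps);
    }
    return e;
  };
  auto spring_energy = [&](double target) {
    double L = dist3(x, ia, ib);
    double d = L - target;
    return 0.5 * k_spring * d * d;
  };

  double sigma = sigma0;
  long acc = 0, att = 0;

  auto attempt_move = [&](double target) {
    bool do_crank = !crank.empty() && unif_rand() < crank_frac;
    int i;
    double oldpos[3];
    double e_old, e_new;
    bool spring_i;
    if (do_crank) {
      i = crank[(int)(unif_rand() * crank.size())];
      spring_i = (i == ia || i == ib);
      e_old = local_energy(i) + (spring_i ? spring_energy(target) : 0.0);
      for (int d = 0; d < 3; ++d) oldpos[d] = x[3 * i + d];
      // rotate bead i about the axis through its chain neighbors
      double ax = x[3 * (i + 1)] - x[3 * (i - 1)];
      double ay = x[3 * (i + 1) + 1] - x[3 * (i - 1) + 1];
      double az = x[3 * (i + 1) + 2] - x[3 * (i - 1) + 2];
      double an = std::sqrt(ax * ax + ay * ay + az * az);
      if (an < 1e-12) return;
      ax /= an; ay /= an; az /= an;
      double th = (2.0 * unif_rand() - 1.0) * crank_max_angle;
      double c = std::cos(th), s = std::sin(th);
      double px = oldpos[0] - x[3 * (i - 1)];
      double py = oldpos[1] - x[3 * (i - 1) + 1];
      double pz = oldpos[2] - x[3 * (i - 1) + 2];
      double dot = px * ax + py * ay + pz * az;
      double rx = px * c + (ay * pz - az * py) * s + ax * dot * (1 - c);
      double ry = py * c + (az * px - ax * pz) * s + ay * dot * (1 - c);
      double rz = pz * c + (ax * py - ay * px) * s + az * dot * (1 - c);
      x[3 * i] = x[3 * (i - 1)] + rx;
      x[3 * i + 1] = x[3 * (i - 1) + 1] + ry;
      x[3 * i + 2] = x[3 * (i - 1) + 2] + rz;
    } else {
      i = mobile[(int)(unif_rand() * nmob)];
      spring_i = (i == ia || i == ib);
      e_old = local_energy(i) + (spring_i ? spring_energy(target) : 0.0);
      for (int d = 0; d < 3; ++d) {
        oldpos[d] = x[3 * i + d];
        x[3 * i + d] += norm_rand() * sigma;
      }
    }
    e_new = local_energy(i) + (spring_i ? spring_energy(target) : 0.0);
    ++att;
    double dE = e_new - e_old;
    if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
      ++acc;
    } else {
      for (int d = 0; d < 3; ++d) x[3 * i + d] = oldpos[d];
    }
  };

  // sigma auto-tuning at fixed target (t = 0)
  if (tune) {
    for (int block = 0; block < 10; ++block) {
      acc = 0; att = 0;
      for (int s = 0; s < 50; ++s)
        for (int m = 0; m < nmob; ++m) attempt_move(L0);
      double rate = att ? (double)acc / att : 0.0;
      if (rate > 0.45) sigma *= 1.2;
      else if (rate < 0.35) sigma /= 1.2;
      if (sigma < 1e-4) sigma = 1e-4;
      if (sigma > 0.5) sigma = 0.5;
    }
  }

  acc = 0; att = 0;
  const int cap = max_sweeps / record_stride + 2;
  NumericMatrix trace(cap, 4); // sweep, L, force (kT/nm), inter contacts
  int nrec = 0;
  double best_absF = -1.0, best_F = 0.0, best_L = L0;
  int best_sweep = 0, zero_run = 0;
  bool ruptured = false;
  int sweeps_done = 0;

  for (int s = 1; s <= max_sweeps; ++s) {
    double target = L0 + v_nm_sweep * (s - 1);
    for (int m = 0; m < nmob; ++m) attempt_move(target);
    double L = dist3(x, ia, ib);
    double F = k_spring * (L - target);
    int ninter = 0;
    for (int c = 0; c < nc; ++c) {
      if (!contact_inter[c]) continue;
      if (dist3(x, ci[c], cj[c]) <= break_factor * contact_sigma[c]) ++ninter;
    }
    if (std::fabs(F) > best_absF && (!has_inter || zero_run == 0)) {
      best_absF = std::fabs(F); best_F = F; best_L = L; best_sweep = s;
    }
    if (has_inter) {
      if (ninter == 0) ++zero_run; else zero_run = 0;
    }
    if (s % record_stride == 0 || s == 1) {
      trace(nrec, 0) = s; trace(nrec, 1) = L;
      trace(nrec, 2) = F; trace(nrec, 3) = ninter;
      ++nrec;
    }
    sweeps_done = s;
    if (has_inter && zero_run >= dwell) { ruptured = true; break; }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_coords(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) out_coords(i, d) = x[3 * i + d];

  return List::create(
    _["trace"] = trace(Range(0, nrec - 1), _),
    _["ruptured"] = ruptured,
    _["rupture_force_kT_nm"] = best_absF,
    _["rupture_force_signed"] = best_F,
    _["rupture_L"] = best_L,
    _["rupture_sweep"] = best_sweep,
    _["sweeps_done"] = sweeps_done,
    _["sigma_final"] = sigma,
    _["acceptance"] = att ? (double)acc / att : NA_REAL,
    _["coords"] = out_coords);
}
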