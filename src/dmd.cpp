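// Event-driven discrete molecular dynamics over step potentials.
//
// Pair interactions are piecewise-constant in distance: a pair record
// carries ascending wall radii r[0] < ... < r[L-1] and shell energies
// e[k] = energy for r in (r[k], r[k+1]), with e[L-1] the energy beyond
// r[L-1] (0 for nonbonded shells, +Inf for bonded square wells, which
// makes the outer wall impenetrable). Below r[0] is an infinite hard
// core. Particles move ballistically between events; at a wall the
// radial velocity component in the pair frame either carries the pair
// across (total energy conserved exactly) or reflects it elastically.
//
// All randomness (thermostat ghost collisions, initial velocities when
// requested) flows through R's RNG so runs are reproducible under
// set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

const double T_EPS = 1e-12;     // minimum admissible event horizon
const double INF = std::numeric_limits<double>::infinity();

struct PairPot {
  int i, j;
  std::vector<double> radii;    // ascending
  std::vector<double> energies; // energies[k]: shell (radii[k], radii[k+1]); last = beyond
  int shell;                    // current shell index, 0-based; shell k means
                                // radii[k] < r < radii[k+1] (or infinity)
  double t_event;               // absolute time of next predicted event
  int wall;                     // wall radius index hit at t_event (-1 none)
};

inline double shell_energy(const PairPot &p, int s) {
  return p.energies[s];
}

// Locate shell of distance r; returns -1 if inside the hard core.
inline int locate_shell(const PairPot &p, double r) {
  if (r < p.radii[0]) return -1;
  int s = 0;
  const int L = (int)p.radii.size();
  while (s + 1 < L && r >= p.radii[s + 1]) ++s;
  return s;
}

struct Engine {
  int n;
  std::vector<double> x, v, m;  // 3n coords, 3n velocities, n masses
  std::vector<PairPot> pairs;
  std::vector<std::vector<int>> by_atom; // pair indices touching each atom
  double t;                     // clock
  double pe;                    // running potential energy
  double thermo_T;              // thermostat temperature (<=0: off)
  double thermo_rate;           // total ghost-collision rate
  double t_ghost;               // next ghost collision time
  long n_events;

  double dist(const PairPot &p) const {
    const int a = 3 * p.i, b = 3 * p.j;
    const double dx = x[a] - x[b], dy = x[a + 1] - x[b + 1], dz = x[a + 2] - x[b + 2];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  double kinetic() const {
    double ke = 0;
    for (int i = 0; i < n; ++i) {
      const int a = 3 * i;
      ke += 0.5 * m[i] * (v[a] * v[a] + v[a + 1] * v[a + 1] + v[a + 2] * v[a + 2]);
    }
    return ke;
  }

  double recompute_pe() const {
    double u = 0;
    for (const PairPot &p : pairs) u += shell_energy(p, p.shell);
    return u;
  }

  // Predict the next wall crossing for pair p, as an absolute time.
  void predict(PairPot &p) {
    const int a = 3 * p.i, b = 3 * p.j;
    const double rx = x[a] - x[b], ry = x[a + 1] - x[b + 1], rz = x[a + 2] - x[b + 2];
    const double wx = v[a] - v[b], wy = v[a + 1] - v[b + 1], wz = v[a + 2] - v[b + 2];
    const double r2 = rx * rx + ry * ry + rz * rz;
    const double w2 = wx * wx + wy * wy + wz * wz;
    const double bdot = rx * wx + ry * wy + rz * wz;
    p.t_event = INF;
    p.wall = -1;
    if (w2 <= 0) return;
    const int L = (int)p.radii.size();
    if (bdot < 0) {
      // approaching: can we reach the inner wall?
      const double Ri = p.radii[p.shell];
      const double disc = bdot * bdot - w2 * (r2 - Ri * Ri);
      if (disc > 0) {
        const double dt = (-bdot - std::sqrt(disc)) / w2;
        if (dt > T_EPS) { p.t_event = t + dt; p.wall = p.shell; return; }
      }
    }
    // otherwise: outward crossing of the outer wall, if one exists
    if (p.shell + 1 < L) {
      const double Ro = p.radii[p.shell + 1];
      const double disc = bdot * bdot - w2 * (r2 - Ro * Ro);
      if (disc >= 0) {
        const double dt = (-bdot + std::sqrt(disc)) / w2;
        if (dt > T_EPS) { p.t_event = t + dt; p.wall = p.shell + 1; return; }
      }
    }
  }

  void predict_atom(int atom) {
    for (int k : by_atom[atom]) predict(pairs[k]);
  }

  void advance(double dt) {
    for (int i = 0; i < 3 * n; ++i) x[i] += v[i] * dt;
    t += dt;
  }

  // Resolve the event of pair p at its wall. Momentum is exchanged along
  // the line of centers only, so total momentum is conserved exactly; on
  // a crossing the radial kinetic energy pays for the potential step, so
  // total energy is conserved exactly as well.
  void resolve(PairPot &p) {
    const int a = 3 * p.i, b = 3 * p.j;
    double rx = x[a] - x[b], ry = x[a + 1] - x[b + 1], rz = x[a + 2] - x[b + 2];
    const double r = std::sqrt(rx * rx + ry * ry + rz * rz);
    const double R = p.radii[p.wall];
    // renormalize the pair onto the wall (suppresses ballistic round-off
    // drift; shifts both atoms symmetrically so momentum is untouched)
    if (r > 0) {
      const double corr = 0.5 * (R - r) / r;
      const double cx = corr * rx, cy = corr * ry, cz = corr * rz;
      x[a] += cx; x[a + 1] += cy; x[a + 2] += cz;
      x[b] -= cx; x[b + 1] -= cy; x[b + 2] -= cz;
      rx = x[a] - x[b]; ry = x[a + 1] - x[b + 1]; rz = x[a + 2] - x[b + 2];
    }
    const double nx = rx / R, ny = ry / R, nz = rz / R;
    const double wx = v[a] - v[b], wy = v[a + 1] - v[b + 1], wz = v[a + 2] - v[b + 2];
    const double vr = wx * nx + wy * ny + wz * nz; // radial closing speed
    const double mu = m[p.i] * m[p.j] / (m[p.i] + m[p.j]);
    const bool outward = (p.wall == p.shell + 1);
    const int new_shell = outward ? p.shell + 1 : p.shell - 1;
    double dU = INF; // crossing into the hard core is forbidden
    if (new_shell >= 0) dU = shell_energy(p, new_shell) - shell_energy(p, p.shell);
    double vr_new;
    bool crossed;
    const double ek_rad = 0.5 * mu * vr * vr;
    if (std::isfinite(dU) && ek_rad > dU) {
      crossed = true;
      const double s = std::sqrt(vr * vr - 2.0 * dU / mu);
      vr_new = (vr >= 0 ? s : -s);
    } else {
      crossed = false;
      vr_new = -vr;
    }
    const double imp = mu * (vr_new - vr); // impulse magnitude along n
    v[a]     += imp * nx / m[p.i];
    v[a + 1] += imp * ny / m[p.i];
    v[a + 2] += imp * nz / m[p.i];
    v[b]     -= imp * nx / m[p.j];
    v[b + 1] -= imp * ny / m[p.j];
    v[b + 2] -= imp * nz / m[p.j];
    if (crossed) {
      pe += dU;
      p.shell = new_shell;
    }
    ++n_events;
  }

  void ghost_collision() {
    const int atom = (int)std::floor(R::unif_rand() * n);
    const int a = 3 * std::min(atom, n - 1);
    const double sd = std::sqrt(thermo_T / m[std::min(atom, n - 1)]);
    v[a] = sd * R::norm_rand();
    v[a + 1] = sd * R::norm_rand();
    v[a + 2] = sd * R::norm_rand();
    t_ghost = t + R::exp_rand() / thermo_rate;
    predict_atom(std::min(atom, n - 1));
  }
};

} // namespace

// [[Rcpp::export(name = ".dmd_run_cpp")]]
List dmd_run_cpp(NumericMatrix positions, NumericMatrix velocities,
                 NumericVector masses, List pair_list,
                 double length, double frame_interval,
                 double thermo_T, double thermo_rate,
                 double max_events) {
  Engine eng;
  eng.n = positions.nrow();
  eng.t = 0;
  eng.n_events = 0;
  eng.m = as<std::vector<double>>(masses);
  eng.x.resize(3 * eng.n);
  eng.v.resize(3 * eng.n);
  for (int i = 0; i < eng.n; ++i)
    for (int d = 0; d < 3; ++d) {
      eng.x[3 * i + d] = positions(i, d);
      eng.v[3 * i + d] = velocities(i, d);
    }

  eng.by_atom.assign(eng.n, {});
  eng.pairs.reserve(pair_list.size());
  for (int k = 0; k < pair_list.size(); ++k) {
    List rec = pair_list[k];
    PairPot p;
    p.i = as<int>(rec["i"]);
    p.j = as<int>(rec["j"]);
    p.radii = as<std::vector<double>>(rec["radii"]);
    p.energies = as<std::vector<double>>(rec["energies"]);
    p.t_event = INF;
    p.wall = -1;
    p.shell = 0;
    eng.pairs.push_back(p);
  }
  for (size_t k = 0; k < eng.pairs.size(); ++k) {
    eng.by_atom[eng.pairs[k].i].push_back((int)k);
    eng.by_atom[eng.pairs[k].j].push_back((int)k);
  }

  // classify initial shells; hard-core overlap is an initialization error
  for (PairPot &p : eng.pairs) {
    const double r = eng.dist(p);
    const int s = locate_shell(p, r);
    if (s < 0)
      stop("initialization error: atoms %d and %d overlap their hard core (r = %.4f < %.4f)",
           p.i + 1, p.j + 1, r, p.radii[0]);
    if (!std::isfinite(shell_energy(p, s)))
      stop("initialization error: atoms %d and %d start in a forbidden shell (r = %.4f)",
           p.i + 1, p.j + 1, r);
    p.shell = s;
  }
  eng.pe = eng.recompute_pe();

  eng.thermo_T = thermo_T;
  eng.thermo_rate = thermo_rate;
  eng.t_ghost = (thermo_T > 0 && thermo_rate > 0)
    ? R::exp_rand() / thermo_rate : INF;

  for (PairPot &p : eng.pairs) eng.predict(p);

  const int n_frames = (int)std::floor(length / frame_interval) + 1;
  NumericVector f_time(n_frames), f_pe(n_frames), f_ke(n_frames);
  NumericVector f_coords(Dimension(n_frames, eng.n, 3));
  int frame = 0;
  double t_frame = 0;

  auto record = [&](int fr) {
    f_time[fr] = eng.t;
    f_pe[fr] = eng.pe;
    f_ke[fr] = eng.kinetic();
    for (int i = 0; i < eng.n; ++i)
      for (int d = 0; d < 3; ++d)
        f_coords[fr + n_frames * (i + eng.n * d)] = eng.x[3 * i + d];
  };
  record(frame++);
  t_frame = frame_interval;

  while (eng.t < length && eng.n_events < max_events) {
    // next pair event
    double t_pair = INF;
    int best = -1;
    for (size_t k = 0; k < eng.pairs.size(); ++k) {
      if (eng.pairs[k].t_event < t_pair) {
        t_pair = eng.pairs[k].t_event;
        best = (int)k;
      }
    }
    double t_next = std::min(t_pair, eng.t_ghost);
    // flush frames that fall before the next event
    while (frame < n_frames && t_frame <= std::min(t_next, length)) {
      eng.advance(t_frame - eng.t);
      record(frame++);
      t_frame += frame_interval;
    }
    if (t_next > length) { eng.advance(length - eng.t); break; }
    eng.advance(t_next - eng.t);
    if (t_pair <= eng.t_ghost) {
      PairPot &p = eng.pairs[best];
      eng.resolve(p);
      eng.predict_atom(p.i);
      eng.predict_atom(p.j);
    } else {
      eng.ghost_collision();
    }
  }

  NumericMatrix x_out(eng.n, 3), v_out(eng.n, 3);
  for (int i = 0; i < eng.n; ++i)
    for (int d = 0; d < 3; ++d) {
      x_out(i, d) = eng.x[3 * i + d];
      v_out(i, d) = eng.v[3 * i + d];
    }

  return List::create(
    _["time"] = f_time, _["pe"] = f_pe, _["ke"] = f_ke,
    _["coords"] = f_coords,
    _["final_positions"] = x_out, _["final_velocities"] = v_out,
    _["n_events"] = (double)eng.n_events,
    _["final_pe"] = eng.pe,
    _["recomputed_pe"] = eng.recompute_pe(),
    _["clock"] = eng.t);
}

// Static step-potential energy of a configuration: used by the repacking
// Monte Carlo and for cross-checking the engine's running total.
// [[Rcpp::export(name = ".step_energy_cpp")]]
double step_energy_cpp(NumericMatrix positions, List pair_list) {
  const int n = positions.nrow();
  double u = 0;
  for (int k = 0; k < pair_list.size(); ++k) {
    List rec = pair_list[k];
    const int i = as<int>(rec["i"]);
    const int j = as<int>(rec["j"]);
    if (i >= n || j >= n) stop("pair index out of range");
    std::vector<double> radii = as<std::vector<double>>(rec["radii"]);
    std::vector<double> energies = as<std::vector<double>>(rec["energies"]);
    const double dx = positions(i, 0) - positions(j, 0);
    const double dy = positions(i, 1) - positions(j, 1);
    const double dz = positions(i, 2) - positions(j, 2);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < radii[0]) return INF;
    int s = 0;
    const int L = (int)radii.size();
    while (s + 1 < L && r >= radii[s + 1]) ++s;
    u += energies[s];
    if (!std::isfinite(u)) return u;
  }
  return u;
}
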