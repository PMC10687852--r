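#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// NVT Metropolis Monte Carlo for a Lennard-Jones fluid in a periodic cubic
// box, with an optional immobilized solute whose pair interaction is scaled
// by a coupling parameter lambda (linear or Beutler-type soft-core path).
// Energies in kJ/mol, lengths in nm.

namespace {

// C2 smooth-step switch applied to the potential between r1 and rc
inline double switch_fn(double r, double r1, double rc) {
  if (r <= r1) return 1.0;
  if (r >= rc) return 0.0;
  double x = (r - r1) / (rc - r1);
  return 1.0 - x * x * x * (10.0 - 15.0 * x + 6.0 * x * x);
}

struct LJ {
  double sigma, eps, r1, rc;
};

// plain switched LJ from squared distance
inline double lj_sw(double r2, const LJ &p) {
  double rc2 = p.rc * p.rc;
  if (r2 >= rc2) return 0.0;
  double s2 = p.sigma * p.sigma / r2;
  double s6 = s2 * s2 * s2;
  double u = 4.0 * p.eps * (s6 * s6 - s6);
  if (r2 > p.r1 * p.r1) u *= switch_fn(std::sqrt(r2), p.r1, p.rc);
  return u;
}

// lambda-coupled solute-solvent pair energy and its lambda-derivative.
// Soft-core (Beutler): A = sigma^6 / (alpha sigma^6 (1-lambda) + r^6),
// U = 4 eps lambda (A^2 - A); reduces to lambda * LJ at lambda = 1.
inline void uv_pair(double r2, const LJ &p, double lambda, bool softcore,
                    double alpha, double &u, double &dudl) {
  double rc2 = p.rc * p.rc;
  if (r2 >= rc2) { u = 0.0; dudl = 0.0; return; }
  double sw = (r2 > p.r1 * p.r1) ? switch_fn(std::sqrt(r2), p.r1, p.rc) : 1.0;
  double s6 = std::pow(p.sigma, 6);
  if (softcore) {
    double denom = alpha * s6 * (1.0 - lambda) + r2 * r2 * r2;
    double A = s6 / denom;
    u = 4.0 * p.eps * lambda * (A * A - A);
    // dA/dlambda = alpha * s6^2 / D^2 = alpha * A^2
    dudl = 4.0 * p.eps * (A * A - A) +
           4.0 * p.eps * lambda * (2.0 * A - 1.0) * alpha * A * A;
    u *= sw; dudl *= sw;
  } else {
    double base = lj_sw(r2, p);
    u = lambda * base;
    dudl = base;
  }
}

inline double min_image2(const double *a, const double *b, double L) {
  double s = 0.0;
  for (int m = 0; m < 3; ++m) {
    double dx = std::fabs(a[m] - b[m]);
    if (dx > 0.5 * L) dx = L - dx;
    s += dx * dx;
  }
  return s;
}

// deterministic 64-bit RNG (splitmix-seeded xorshift)
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) {
    s = seed + 0x9E3779B97F4A7C15ULL;
    next(); next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

struct System {
  int N;
  double L;
  LJ vv, uv;
  bool has_solute;
  double sol[3];
  double lambda, alpha;
  bool softcore;

  // interaction energy of particle i at position xi with everything else
  void particle_energy(const std::vector<double> &x, int i, const double *xi,
                       double &evv, double &euv, double &eduv) const {
    evv = 0.0; euv = 0.0; eduv = 0.0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      double r2 = min_image2(xi, &x[3 * j], L);
      evv += lj_sw(r2, vv);
    }
    if (has_solute) {
      double r2 = min_image2(xi, sol, L);
      double u, du;
      uv_pair(r2, uv, lambda, softcore, alpha, u, du);
      euv = u; eduv = du;
    }
  }

  void total_energy(const std::vector<double> &x, double &Uvv, double &Uuv,
                    double &dUdl) const {
    Uvv = 0.0; Uuv = 0.0; dUdl = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j)
        Uvv += lj_sw(min_image2(&x[3 * i], &x[3 * j], L), vv);
      if (has_solute) {
        double u, du;
        uv_pair(min_image2(&x[3 * i], sol, L), uv, lambda, softcore, alpha, u, du);
        Uuv += u; dUdl += du;
      }
    }
  }
};

System make_system(NumericMatrix pos, double box, NumericVector vv_par,
                   NumericVector uv_par, NumericVector solute_pos,
                   double lambda, bool softcore, double alpha) {
  System sys;
  sys.N = pos.nrow();
  sys.L = box;
  sys.vv = LJ{vv_par[0], vv_par[1], vv_par[2], vv_par[3]};
  sys.has_solute = solute_pos.size() == 3;
  if (sys.has_solute) {
    sys.uv = LJ{uv_par[0], uv_par[1], uv_par[2], uv_par[3]};
    for (int m = 0; m < 3; ++m) sys.sol[m] = solute_pos[m];
  } else {
    sys.uv = LJ{0, 0, 0.5, 1.0};
  }
  sys.lambda = lambda;
  sys.softcore = softcore;
  sys.alpha = alpha;
  return sys;
}

} // namespace

// [[Rcpp::export]]
double lj_pair_cpp(double r, NumericVector par) {
  if (r <= 0) stop("r must be positive");
  LJ p{par[0], par[1], par[2], par[3]};
  return lj_sw(r * r, p);
}

// [[Rcpp::export]]
List total_energies_cpp(NumericMatrix pos, double box, NumericVector vv_par,
                        NumericVector uv_par, NumericVector solute_pos,
                        double lambda, bool softcore, double alpha) {
  System sys = make_system(pos, box, vv_par, uv_par, solute_pos, lambda,
                           softcore, alpha);
  std::vector<double> x(pos.nrow() * 3);
  for (int i = 0; i < pos.nrow(); ++i)
    for (int m = 0; m < 3; ++m) x[3 * i + m] = pos(i, m);
  double Uvv, Uuv, dUdl;
  sys.total_energy(x, Uvv, Uuv, dUdl);
  return List::create(_["U_vv"] = Uvv, _["U_uv"] = Uuv, _["dU_dlambda"] = dUdl);
}

// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix pos0, double box, NumericVector vv_par,
                NumericVector uv_par, NumericVector solute_pos, double lambda,
                bool softcore, double alpha, double beta, int n_steps,
                int equil_steps, int stride, double max_disp, uint64_t seed,
                bool store_frames) {
  System sys = make_system(pos0, box, vv_par, uv_par, solute_pos, lambda,
                           softcore, alpha);
  int N = sys.N;
  std::vector<double> x(N * 3);
  for (int i = 0; i < N; ++i)
    for (int m = 0; m < 3; ++m) x[3 * i + m] = pos0(i, m);
  RNG rng(seed);

  double Uvv, Uuv, dUdl;
  sys.total_energy(x, Uvv, Uuv, dUdl);

  long accepted = 0, attempted = 0;
  long acc_win = 0, att_win = 0;
  const int tune_every = 500;
  double bookkeep_err = 0.0;

  int n_frames = n_steps / stride;
  NumericVector fr;
  if (store_frames) fr = NumericVector((size_t)n_frames * N * 3);
  NumericVector eUvv(n_frames), eUuv(n_frames), edUdl(n_frames);
  int frame = 0;

  long total_steps = (long)equil_steps + n_steps;
  for (long step = 0; step < total_steps; ++step) {
    bool equil = step < equil_steps;
    int i = (int)(rng.unif() * N);
    if (i >= N) i = N - 1;
    double xold[3], xnew[3];
    for (int m = 0; m < 3; ++m) {
      xold[m] = x[3 * i + m];
      double xm = xold[m] + (2.0 * rng.unif() - 1.0) * max_disp;
      xm -= box * std::floor(xm / box);
      xnew[m] = xm;
    }
    double evv0, euv0, edu0, evv1, euv1, edu1;
    sys.particle_energy(x, i, xold, evv0, euv0, edu0);
    sys.particle_energy(x, i, xnew, evv1, euv1, edu1);
    double dU = (evv1 + euv1) - (evv0 + euv0);
    ++attempted; ++att_win;
    if (dU <= 0.0 || rng.unif() < std::exp(-beta * dU)) {
      for (int m = 0; m < 3; ++m) x[3 * i + m] = xnew[m];
      Uvv += evv1 - evv0;
      Uuv += euv1 - euv0;
      dUdl += edu1 - edu0;
      ++accepted; ++acc_win;
    }
    if (equil && att_win >= tune_every) {
      double rate = (double)acc_win / att_win;
      if (rate > 0.6) max_disp *= 1.1;
      else if (rate < 0.3) max_disp *= 0.9;
      if (max_disp > 0.25 * box) max_disp = 0.25 * box;
      acc_win = 0; att_win = 0;
    }
    if (equil && step == (long)equil_steps - 1) {
      accepted = 0; attempted = 0;  // count production acceptance only
    }
    long pstep = step - equil_steps + 1;
    if (!equil && pstep > 0 && pstep % stride == 0 && frame < n_frames) {
      double Uvv_f, Uuv_f, dUdl_f;
      sys.total_energy(x, Uvv_f, Uuv_f, dUdl_f);
      double err = std::fabs(Uvv_f - Uvv) + std::fabs(Uuv_f - Uuv);
      if (err > bookkeep_err) bookkeep_err = err;
      eUvv[frame] = Uvv_f;
      eUuv[frame] = Uuv_f;
      edUdl[frame] = dUdl_f;
      if (store_frames)
        for (int p = 0; p < N; ++p)
          for (int m = 0; m < 3; ++m)
            fr[(size_t)m * n_frames * N + (size_t)p * n_frames + frame] =
                x[3 * p + m];
      ++frame;
    }
  }
  NumericMatrix last(N, 3);
  for (int i = 0; i < N; ++i)
    for (int m = 0; m < 3; ++m) last(i, m) = x[3 * i + m];
  return List::create(
      _["frames"] = fr, _["n_frames"] = frame, _["U_vv"] = eUvv,
      _["U_uv"] = eUuv, _["dU_dlambda"] = edUdl,
      _["acceptance"] = attempted > 0 ? (double)accepted / attempted : NA_REAL,
      _["max_disp"] = max_disp, _["bookkeeping_error"] = bookkeep_err,
      _["final_positions"] = last);
}
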