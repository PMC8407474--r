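#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// State layout: y[0] = S; y[1 .. p*n] = P_{i,j} with index 1 + i*n + j
// (i = 0..p-1 pathway, j = 0..n-1 step); then Q[p], F[p], V[p] where
// V_i = cumulative final-step production (retained + secreted).
// Enzyme counts are piecewise constant between `breaks`; the integrator
// never steps across a breakpoint.

struct Sys {
  int p, n, nvar;
  double inflow;   // total substrate supply (sum of per-pathway S_in)
  double Km;
  const double *kcat;   // per pathway, overexpression factored in
  const double *sigma;  // secretion ratio per pathway
  const double *feed;   // import rate per pathway
};

static inline double mm(double x, double Km) {
  return x > 0.0 ? x / (x + Km) : 0.0;
}

static void deriv(const Sys &sys, const double *E, const double *y, double *dy) {
  const int p = sys.p, n = sys.n;
  double cons = 0.0;
  for (int i = 0; i < p; ++i)
    cons += sys.kcat[i] * E[i * n] * mm(y[0], sys.Km);
  dy[0] = sys.inflow - cons;
  for (int i = 0; i < p; ++i) {
    const double ki = sys.kcat[i];
    // v[j] = rate of step j (consumes product of step j-1; step 0 consumes S)
    double vprev = ki * E[i * n] * mm(y[0], sys.Km);
    for (int j = 0; j < n; ++j) {
      int idx = 1 + i * n + j;
      double vnext;
      if (j < n - 1) {
        vnext = ki * E[i * n + j + 1] * mm(y[idx], sys.Km);
        dy[idx] = vprev - vnext;
      } else {
        vnext = 0.0;
        dy[idx] = (1.0 - sys.sigma[i]) * vprev + sys.feed[i];
        dy[1 + p * n + i]         = sys.sigma[i] * vprev;  // dQ_i
        dy[1 + p * n + p + i]     = sys.feed[i];           // dF_i
        dy[1 + p * n + 2 * p + i] = vprev;                 // dV_i
      }
      vprev = vnext;
    }
  }
}

static void rk4_step(const Sys &sys, const double *E, double *y, double h,
                     std::vector<double> &k1, std::vector<double> &k2,
                     std::vector<double> &k3, std::vector<double> &k4,
                     std::vector<double> &tmp) {
  const int m = sys.nvar;
  deriv(sys, E, y, k1.data());
  for (int q = 0; q < m; ++q) tmp[q] = y[q] + 0.5 * h * k1[q];
  deriv(sys, E, tmp.data(), k2.data());
  for (int q = 0; q < m; ++q) tmp[q] = y[q] + 0.5 * h * k2[q];
  deriv(sys, E, tmp.data(), k3.data());
  for (int q = 0; q < m; ++q) tmp[q] = y[q] + h * k3[q];
  deriv(sys, E, tmp.data(), k4.data());
  for (int q = 0; q < m; ++q)
    y[q] += h / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
  // clamp tiny negative pools (Michaelis-Menten keeps rates >= 0 at 0)
  int npool = 1 + sys.p * sys.n;
  for (int q = 0; q < npool; ++q)
    if (y[q] < 0.0) y[q] = 0.0;
}

static bool all_met(const Sys &sys, const double *y, const double *targets) {
  for (int i = 0; i < sys.p; ++i)
    if (y[1 + i * sys.n + sys.n - 1] < targets[i]) return false;
  return true;
}

// Emat holds one COLUMN per enzyme segment (p*n rows, pathway-major), so
// a segment's counts are contiguous in memory.
// [[Rcpp::export]]
List integrate_cycle_cpp(NumericVector breaks, NumericMatrix Emat,
                         double S0, NumericVector P0,
                         int p, int n, double inflow,
                         NumericVector kcat, double Km,
                         NumericVector sigma, NumericVector feed,
                         NumericVector targets,
                         double h_max, double event_rel_tol,
                         double save_dt) {
  const int M = Emat.ncol();
  if (breaks.size() != M + 1)
    stop("breaks must have one more element than Emat has columns");
  if (Emat.nrow() != p * n)
    stop("Emat must have p*n rows");
  Sys sys;
  sys.p = p; sys.n = n; sys.nvar = 1 + p * n + 3 * p;
  sys.inflow = inflow; sys.Km = Km;
  sys.kcat = REAL(kcat); sys.sigma = REAL(sigma); sys.feed = REAL(feed);

  std::vector<double> y(sys.nvar, 0.0), ylo(sys.nvar), ymid(sys.nvar);
  std::vector<double> k1(sys.nvar), k2(sys.nvar), k3(sys.nvar), k4(sys.nvar),
      tmp(sys.nvar);
  y[0] = S0;
  for (int q = 0; q < p * n; ++q) y[1 + q] = P0[q];

  NumericVector crossing(p, NA_REAL);
  double t = breaks[0];
  bool divided = false;
  double div_time = NA_REAL;
  long nsteps = 0;

  std::vector<double> trajbuf;
  double next_save = (save_dt > 0.0) ? breaks[0] : R_PosInf;
  auto save_state = [&](double tt) {
    trajbuf.push_back(tt);
    for (int q = 0; q < sys.nvar; ++q) trajbuf.push_back(y[q]);
  };
  if (save_dt > 0.0) { save_state(t); next_save = t + save_dt; }

  // division may already hold at cycle start
  if (all_met(sys, y.data(), REAL(targets))) {
    divided = true;
    div_time = t;
    for (int i = 0; i < p; ++i) crossing[i] = t;
  }

  for (int seg = 0; seg < M && !divided; ++seg) {
    double ta = breaks[seg], tb = breaks[seg + 1];
    if (tb <= ta) continue;
    const double *E = &Emat(0, seg);
    // local stiffness bound: fastest linearised consumption rate ~ kcat*E/Km
    double lam = 0.0;
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < n; ++j) {
        double l = sys.kcat[i] * E[i * n + j] / Km;
        if (l > lam) lam = l;
      }
    double hseg = h_max;
    if (lam > 0.0 && 0.5 / lam < hseg) hseg = 0.5 / lam;
    int nsub = (int)std::ceil((tb - ta) / hseg);
    if (nsub < 1) nsub = 1;
    double h = (tb - ta) / nsub;
    for (int s = 0; s < nsub; ++s) {
      double tlo = ta + s * h;
      std::copy(y.begin(), y.end(), ylo.begin());
      rk4_step(sys, E, y.data(), h, k1, k2, k3, k4, tmp);
      ++nsteps;
      double thi = ta + (s + 1) * h;
      t = thi;
      if (!(y[0] == y[0]))  // NaN guard
        stop("non-finite state during integration at t=%g", t);
      // coarse per-pathway crossing times (final pools are non-decreasing)
      for (int i = 0; i < p; ++i)
        if (ISNA(crossing[i]) && y[1 + i * n + n - 1] >= targets[i])
          crossing[i] = thi;
      if (all_met(sys, y.data(), REAL(targets))) {
        // bisect [tlo, thi] for the event time
        double lo = tlo, hi = thi;
        double tol = event_rel_tol * std::max(hi, 1.0);
        if (tol < 1e-12) tol = 1e-12;
        while (hi - lo > tol) {
          double mid = 0.5 * (lo + hi);
          std::copy(ylo.begin(), ylo.end(), ymid.begin());
          rk4_step(sys, E, ymid.data(), mid - lo, k1, k2, k3, k4, tmp);
          if (all_met(sys, ymid.data(), REAL(targets))) {
            hi = mid;
          } else {
            lo = mid;
            std::copy(ymid.begin(), ymid.end(), ylo.begin());
          }
        }
        std::copy(ylo.begin(), ylo.end(), y.begin());
        rk4_step(sys, E, y.data(), hi - lo, k1, k2, k3, k4, tmp);
        t = hi;
        divided = true;
        div_time = hi;
        for (int i = 0; i < p; ++i)
          if (ISNA(crossing[i]) || crossing[i] > hi) crossing[i] = hi;
        break;
      }
      if (t >= next_save - 1e-12) { save_state(t); next_save += save_dt; }
    }
  }
  if (divided && save_dt > 0.0) save_state(t);

  NumericVector yend(sys.nvar);
  for (int q = 0; q < sys.nvar; ++q) yend[q] = y[q];

  int event_pathway = NA_INTEGER;
  if (divided) {
    // triggering pathway = last to cross; ties broken by lowest index
    double tmax = -1.0;
    for (int i = 0; i < p; ++i)
      if (crossing[i] > tmax) { tmax = crossing[i]; event_pathway = i + 1; }
  }

  List out = List::create(
      _["division_time"] = div_time, _["y_end"] = yend, _["t_end"] = t,
      _["event_pathway"] = event_pathway, _["crossing_times"] = crossing,
      _["n_steps"] = (double)nsteps);
  if (save_dt > 0.0) {
    int ncol = sys.nvar + 1, nrow = trajbuf.size() / ncol;
    NumericMatrix traj(nrow, ncol);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c < ncol; ++c) traj(r, c) = trajbuf[r * ncol + c];
    out["traj"] = traj;
  }
  return out;
}
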