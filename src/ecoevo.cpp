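// Compiled core of the eco-evolutionary model: per-capita growth rates,
// adaptive RK45 integration on log-densities, equilibrium solving with a
// Newton polish, finite-difference community Jacobian, the quantitative
// interaction-strength matrix, and simulated annealing for Barber-style
// weighted bipartite modularity.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Par {
  double rA, rP, h, kA, kP, xAmax, yPmax, sA, sP, sC, c;
  bool normK;
};

Par as_par(const List& p) {
  Par q;
  q.rA = p["r_A"];       q.rP = p["r_P"];     q.h = p["h"];
  q.kA = p["k_A"];       q.kP = p["k_P"];
  q.xAmax = p["x_Amax"]; q.yPmax = p["y_Pmax"];
  q.sA = p["sigma_A"];   q.sP = p["sigma_P"]; q.sC = p["sigma_C"];
  q.c = p["c"];
  q.normK = as<bool>(p["normalized_K"]);
  return q;
}

inline double gauss(double d, double s) {
  return std::exp(-d * d / (2.0 * s * s));
}

// Per-capita growth rates f_A, f_P for the full model: logistic growth with
// trait-mediated carrying capacity and Gaussian competition, plus a type II
// mutualistic functional response with adaptive (density-weighted)
// interaction preferences. smA holds sigma_m per animal morph (an alien
// carries its own tolerance; natives share the community value).
// Trait-dependent pieces are fixed within one solve (only densities move):
// precompute the competition kernels, carrying capacities and the benefit
// matrix once per exported call.
struct Cache {
  int n, m;
  Par pp;
  arma::mat gamA, gamP, b;  // n x n, m x m, n x m
  arma::vec KA, KP;
};

Cache make_cache(const arma::vec& xA, const arma::vec& xP,
                 const arma::vec& smA, const Par& pp) {
  Cache C;
  C.n = xA.n_elem; C.m = xP.n_elem; C.pp = pp;
  const double normA = pp.normK ? 1.0 / (pp.sA * std::sqrt(2.0 * M_PI)) : 1.0;
  const double normP = pp.normK ? 1.0 / (pp.sP * std::sqrt(2.0 * M_PI)) : 1.0;
  C.gamA.set_size(C.n, C.n); C.gamP.set_size(C.m, C.m);
  C.KA.set_size(C.n); C.KP.set_size(C.m);
  for (int i = 0; i < C.n; ++i) {
    for (int k = 0; k < C.n; ++k) C.gamA(i, k) = gauss(xA[i] - xA[k], pp.sC);
    C.KA[i] = pp.kA * normA * gauss(xA[i] - pp.xAmax, pp.sA);
  }
  for (int j = 0; j < C.m; ++j) {
    for (int k = 0; k < C.m; ++k) C.gamP(j, k) = gauss(xP[j] - xP[k], pp.sC);
    C.KP[j] = pp.kP * normP * gauss(xP[j] - pp.yPmax, pp.sP);
  }
  if (C.n && C.m && pp.c > 0.0) {
    C.b.set_size(C.n, C.m);
    for (int i = 0; i < C.n; ++i)
      for (int j = 0; j < C.m; ++j)
        C.b(i, j) = pp.c * gauss(xA[i] - xP[j], smA[i]);
  }
  return C;
}

void rates(const Cache& C, const arma::vec& A, const arma::vec& P,
           arma::vec& fA, arma::vec& fP) {
  const int n = C.n, m = C.m;
  const Par& pp = C.pp;
  fA.set_size(n); fP.set_size(m);
  if (n) fA = pp.rA - pp.rA * (C.gamA * A) / C.KA;
  if (m) fP = pp.rP - pp.rP * (C.gamP * P) / C.KP;
  if (n == 0 || m == 0 || pp.c <= 0.0) return;

  const double SA = arma::accu(A), SP = arma::accu(P);
  const arma::vec denomA = C.b.t() * A;  // plant j's density-weighted benefit from its animal suitors
  const arma::vec denomP = C.b * P;      // animal i's density-weighted benefit from its plant suitors

  for (int i = 0; i < n; ++i) {
    double num = 0.0, sat = 0.0;
    for (int j = 0; j < m; ++j) {
      const double w = (denomA[j] > 0.0 && SA > 0.0) ? C.b(i, j) * SA / denomA[j] : 0.0;
      num += C.b(i, j) * w * P[j];
      sat += w * P[j];
    }
    fA[i] += num / (1.0 + pp.h * sat);
  }
  for (int j = 0; j < m; ++j) {
    double num = 0.0, sat = 0.0;
    for (int i = 0; i < n; ++i) {
      const double w = (denomP[i] > 0.0 && SP > 0.0) ? C.b(i, j) * SP / denomP[i] : 0.0;
      num += C.b(i, j) * w * A[i];
      sat += w * A[i];
    }
    fP[j] += num / (1.0 + pp.h * sat);
  }
}

// residual of the relative rate test: max_i |N_i f_i| / max(N_i, 1)
double eq_residual(const arma::vec& N, const arma::vec& f) {
  double r = 0.0;
  for (arma::uword i = 0; i < N.n_elem; ++i) {
    const double d = std::abs(N[i] * f[i]) / std::max(N[i], 1.0);
    if (d > r) r = d;
  }
  return r;
}

void rates_stacked(const Cache& C, const arma::vec& N, arma::vec& f) {
  arma::vec A = N.head(C.n), P = N.tail(C.m), fA, fP;
  rates(C, A, P, fA, fP);
  f.set_size(C.n + C.m);
  if (C.n) f.head(C.n) = fA;
  if (C.m) f.tail(C.m) = fP;
}

// Dormand-Prince 5(4) on u = log N. Returns status: 0 reached t1,
// 1 equilibrium criterion met, 2 step-size collapse.
int dopri_log(const Cache& C, arma::vec& u, double& t, double t1,
              double rtol, double atol, bool stop_at_eq, double eq_tol) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                      e3 = 500.0 / 1113 - 7571.0 / 16695,
                      e4 = 125.0 / 192 - 393.0 / 640,
                      e5 = -2187.0 / 6784 + 92097.0 / 339200,
                      e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;
  const double UFLOOR = -690.0;  // exp underflow guard on log-densities

  const int d = C.n + C.m;
  arma::vec k1(d), k2(d), k3(d), k4(d), k5(d), k6(d), k7(d), ut(d), u5(d), err(d), N(d);

  auto deriv = [&](const arma::vec& uu, arma::vec& kk) {
    arma::vec NN = arma::exp(uu);
    rates_stacked(C, NN, kk);
    // morphs far outside the viable trait range have K(x) underflowing to
    // zero and unboundedly negative growth; cap the log-density slope so
    // they crash to the density floor without collapsing the step size
    for (arma::uword i = 0; i < kk.n_elem; ++i) {
      if (!std::isfinite(kk[i]) || kk[i] < -1e3) kk[i] = -1e3;
      else if (kk[i] > 1e3) kk[i] = 1e3;
    }
  };

  deriv(u, k1);
  double h = 0.01;
  int iter = 0;
  while (t < t1) {
    if (++iter > 1000000) return 2;
    if (h > t1 - t) h = t1 - t;
    ut = u + h * a21 * k1;                                           deriv(ut, k2);
    ut = u + h * (a31 * k1 + a32 * k2);                              deriv(ut, k3);
    ut = u + h * (a41 * k1 + a42 * k2 + a43 * k3);                   deriv(ut, k4);
    ut = u + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);        deriv(ut, k5);
    ut = u + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5); deriv(ut, k6);
    u5 = u + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);  deriv(u5, k7);
    err = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
    double en = 0.0;
    for (int i = 0; i < d; ++i) {
      const double sc = atol + rtol * std::max(std::abs(u[i]), std::abs(u5[i]));
      const double q = err[i] / sc;
      en += q * q;
    }
    en = std::sqrt(en / d);
    if (en <= 1.0) {  // accept
      t += h;
      u = u5;
      for (int i = 0; i < d; ++i) if (u[i] < UFLOOR) u[i] = UFLOOR;
      k1 = k7;  // FSAL
      if (stop_at_eq) {
        N = arma::exp(u);
        if (eq_residual(N, k1) < eq_tol) return 1;
      }
      (void)c2; (void)c3; (void)c4; (void)c5;
    }
    double fac = 0.9 * std::pow(std::max(en, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12) return 2;
  }
  return 0;
}

arma::mat num_jacobian(const Cache& C, const arma::vec& N) {
  const int d = C.n + C.m;
  arma::mat J(d, d);
  arma::vec Np, Nm_, fp, fm;
  for (int l = 0; l < d; ++l) {
    const double hl = std::max(1e-6, 1e-6 * N[l]);
    Np = N; Np[l] += hl;
    Nm_ = N; Nm_[l] = std::max(N[l] - hl, 0.0);
    const double dd = Np[l] - Nm_[l];
    rates_stacked(C, Np, fp);
    rates_stacked(C, Nm_, fm);
    for (int k = 0; k < d; ++k)
      J(k, l) = (Np[k] * fp[k] - Nm_[k] * fm[k]) / dd;
  }
  return J;
}

}  // namespace

// [[Rcpp::export]]
List cpp_rates(NumericVector A, NumericVector P,
               NumericVector xA, NumericVector xP,
               NumericVector smA, List par) {
  Par pp = as_par(par);
  Cache C = make_cache(as<arma::vec>(xA), as<arma::vec>(xP),
                       as<arma::vec>(smA), pp);
  arma::vec fA, fP;
  rates(C, as<arma::vec>(A), as<arma::vec>(P), fA, fP);
  return List::create(_["fA"] = NumericVector(fA.begin(), fA.end()),
                      _["fP"] = NumericVector(fP.begin(), fP.end()));
}

// Integrate the population dynamics from t0 to t1 on log-densities; optionally record the
// state at given times, optionally stop early once the relative rate test
// falls below eq_tol. All initial densities must be strictly positive.
// [[Rcpp::export]]
List cpp_integrate(NumericVector A0, NumericVector P0,
                   NumericVector xA, NumericVector xP,
                   NumericVector smA, List par,
                   double t0, double t1, double rtol, double atol,
                   bool stop_at_eq, double eq_tol,
                   Nullable<NumericVector> record_times = R_NilValue) {
  Par pp = as_par(par);
  const int n = A0.size(), m = P0.size(), d = n + m;
  arma::vec xAv = as<arma::vec>(xA), xPv = as<arma::vec>(xP), smv = as<arma::vec>(smA);
  Cache C = make_cache(xAv, xPv, smv, pp);
  arma::vec N0(d);
  for (int i = 0; i < n; ++i) N0[i] = A0[i];
  for (int j = 0; j < m; ++j) N0[n + j] = P0[j];
  if (N0.min() <= 0.0) stop("all densities must be strictly positive for integration");
  arma::vec u = arma::log(N0);
  double t = t0;
  int status = 0;

  arma::mat rec;
  std::vector<double> rect;
  if (record_times.isNotNull()) {
    NumericVector rt(record_times);
    rec.set_size(rt.size(), d);
    for (int s = 0; s < rt.size(); ++s) {
      const double tt = rt[s];
      if (tt > t) status = dopri_log(C, u, t, tt, rtol, atol, false, 0.0);
      rec.row(s) = arma::exp(u).t();
      rect.push_back(tt);
      if (status == 2) break;
    }
    if (status != 2 && t < t1)
      status = dopri_log(C, u, t, t1, rtol, atol, stop_at_eq, eq_tol);
  } else {
    status = dopri_log(C, u, t, t1, rtol, atol, stop_at_eq, eq_tol);
  }

  arma::vec N = arma::exp(u), f;
  rates_stacked(C, N, f);
  List out = List::create(
      _["A"] = NumericVector(N.begin(), N.begin() + n),
      _["P"] = NumericVector(N.begin() + n, N.end()),
      _["t"] = t,
      _["status"] = status,
      _["residual"] = eq_residual(N, f));
  if (record_times.isNotNull()) {
    out["record"] = wrap(rec);
    out["record_t"] = wrap(rect);
  }
  return out;
}

// Solve for an ecological equilibrium: integrate in growing chunks with the
// relative rate test max|N f| < tol*max(N,1); once the residual is small,
// polish with damped Newton iterations on N*f(N) = 0.
// [[Rcpp::export]]
List cpp_find_eq(NumericVector A0, NumericVector P0,
                 NumericVector xA, NumericVector xP,
                 NumericVector smA, List par,
                 double eq_tol, double t_max, double rtol, double atol,
                 bool use_newton = true) {
  Par pp = as_par(par);
  const int n = A0.size(), m = P0.size(), d = n + m;
  arma::vec xAv = as<arma::vec>(xA), xPv = as<arma::vec>(xP), smv = as<arma::vec>(smA);
  Cache C = make_cache(xAv, xPv, smv, pp);
  arma::vec N(d);
  for (int i = 0; i < n; ++i) N[i] = A0[i];
  for (int j = 0; j < m; ++j) N[n + j] = P0[j];
  if (N.min() <= 0.0) stop("all densities must be strictly positive");
  arma::vec u = arma::log(N), f;
  double t = 0.0, chunk = 5.0;
  bool converged = false;
  int status = 0;

  // damped Newton on N*f(N) = 0, polishing well past eq_tol: downstream
  // finite differences of fitness need equilibria at machine precision
  auto try_newton = [&](arma::vec& Nc) -> bool {
    const double target = std::min(eq_tol, 1e-13);
    arma::vec Nw = Nc, fw, G, dN;
    bool ok = true;
    double rw_prev = arma::datum::inf;
    arma::mat J;  // chord: build the Jacobian once, reuse until stalling
    bool haveJ = false;
    for (int it = 0; it < 40; ++it) {
      rates_stacked(C, Nw, fw);
      const double rw = eq_residual(Nw, fw);
      if (rw < target) break;
      if (rw > 10.0 * rw_prev) { ok = false; break; }  // diverging
      if (rw > 0.5 * rw_prev) haveJ = false;           // stalling: refresh J
      rw_prev = std::min(rw_prev, rw);
      if (it == 39) break;
      if (!haveJ) {
        // forward-difference Jacobian of G(N) = N*f(N)
        J.set_size(d, d);
        arma::vec Np, fp;
        for (int l = 0; l < d; ++l) {
          const double hl = std::max(1e-7, 1e-7 * Nw[l]);
          Np = Nw; Np[l] += hl;
          rates_stacked(C, Np, fp);
          for (int k = 0; k < d; ++k)
            J(k, l) = (Np[k] * fp[k] - Nw[k] * fw[k]) / hl;
        }
        haveJ = true;
      }
      G = Nw % fw;
      if (!arma::solve(dN, J, -G, arma::solve_opts::no_approx)) { ok = false; break; }
      arma::vec Nn = Nw + dN;
      for (int i = 0; i < d; ++i) {
        if (Nn[i] <= 0.0) {
          if (Nw[i] < 1e-10) Nn[i] = 1e-300; else { ok = false; break; }
        }
      }
      if (!ok) break;
      Nw = Nn;
    }
    if (!ok) return false;
    rates_stacked(C, Nw, fw);
    if (eq_residual(Nw, fw) < eq_tol && Nw.is_finite()) { Nc = Nw; return true; }
    return false;
  };

  rates_stacked(C, N, f);
  if (use_newton && eq_residual(N, f) < 0.5 && try_newton(N)) {
    converged = true;
  } else {
    while (t < t_max) {
      const double tnext = std::min(t + chunk, t_max);
      status = dopri_log(C, u, t, tnext, rtol, atol, true, eq_tol);
      N = arma::exp(u);
      if (status == 2) break;
      if (status == 1) converged = true;
      rates_stacked(C, N, f);
      if (use_newton && eq_residual(N, f) < 1e-3 && try_newton(N))
        converged = true;
      if (converged) break;
      chunk = std::min(chunk * 2.0, 2000.0);
    }
  }

  rates_stacked(C, N, f);
  return List::create(
      _["A"] = NumericVector(N.begin(), N.begin() + n),
      _["P"] = NumericVector(N.begin() + n, N.end()),
      _["converged"] = converged,
      _["residual"] = eq_residual(N, f),
      _["t"] = t,
      _["status"] = status);
}

// Community Jacobian d(N_k f_k)/dN_l by central differences,
// step max(1e-6, 1e-6*N_l).
// [[Rcpp::export]]
NumericMatrix cpp_jacobian(NumericVector A, NumericVector P,
                           NumericVector xA, NumericVector xP,
                           NumericVector smA, List par) {
  Par pp = as_par(par);
  const int n = A.size(), m = P.size();
  arma::vec N(n + m);
  for (int i = 0; i < n; ++i) N[i] = A[i];
  for (int j = 0; j < m; ++j) N[n + j] = P[j];
  Cache C = make_cache(as<arma::vec>(xA), as<arma::vec>(xP),
                       as<arma::vec>(smA), pp);
  arma::mat J = num_jacobian(C, N);
  return wrap(J);
}

// Quantitative interaction-strength matrix q_ij (symmetrized recruitment of
// animal i from plant j and vice versa); entries below q_threshold are 0.
// [[Rcpp::export]]
NumericMatrix cpp_interaction_matrix(NumericVector A, NumericVector P,
                                     NumericVector xA, NumericVector xP,
                                     NumericVector smA, List par,
                                     double q_threshold) {
  Par pp = as_par(par);
  const int n = A.size(), m = P.size();
  NumericMatrix Q(n, m);
  if (n == 0 || m == 0) return Q;
  arma::mat b(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      b(i, j) = pp.c * gauss(xA[i] - xP[j], smA[i]);
  double SA = 0.0, SP = 0.0;
  for (int i = 0; i < n; ++i) SA += A[i];
  for (int j = 0; j < m; ++j) SP += P[j];
  arma::vec denomA(m, arma::fill::zeros), denomP(n, arma::fill::zeros);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) denomA[j] += A[i] * b(i, j);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) denomP[i] += P[j] * b(i, j);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double wAP = (denomA[j] > 0.0 && SA > 0.0) ? b(i, j) * SA / denomA[j] : 0.0;
      const double wPA = (denomP[i] > 0.0 && SP > 0.0) ? b(i, j) * SP / denomP[i] : 0.0;
      double q = 0.5 * (A[i] * b(i, j) * wAP * P[j] / (1.0 + pp.h * wAP * P[j]) +
                        P[j] * b(i, j) * wPA * A[i] / (1.0 + pp.h * wPA * A[i]));
      if (q < q_threshold) q = 0.0;
      Q(i, j) = q;
    }
  }
  return Q;
}

// Barber weighted bipartite modularity of a label assignment, and its
// maximization by simulated annealing (node moves + module merges) with
// geometric cooling. Uses the R RNG so results are reproducible from
// set.seed().
// [[Rcpp::export]]
List cpp_modularity_sa(NumericMatrix Qm, int steps, double T0, double cooling,
                       int restarts) {
  const int n = Qm.nrow(), m = Qm.ncol();
  double F = 0.0;
  for (int i = 0; i < n; ++i) for (int j = 0; j < m; ++j) F += Qm(i, j);
  if (F <= 0.0) stop("interaction matrix has zero total");
  arma::mat S(n, m);
  std::vector<double> R(n, 0.0), C(m, 0.0);
  for (int i = 0; i < n; ++i) for (int j = 0; j < m; ++j) R[i] += Qm(i, j);
  for (int j = 0; j < m; ++j) for (int i = 0; i < n; ++i) C[j] += Qm(i, j);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      S(i, j) = Qm(i, j) / F - R[i] * C[j] / (F * F);

  const int L = std::max(2, std::min(n, m));  // label space
  std::vector<int> la(n), lp(m), bla(n), blp(m);
  double bestM = -1e18;

  auto modval = [&](const std::vector<int>& a, const std::vector<int>& p) {
    double M = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < m; ++j)
        if (a[i] == p[j]) M += S(i, j);
    return M;
  };

  for (int r = 0; r < restarts; ++r) {
    for (int i = 0; i < n; ++i) la[i] = (int)(unif_rand() * L) % L;
    for (int j = 0; j < m; ++j) lp[j] = (int)(unif_rand() * L) % L;
    double M = modval(la, lp);
    double T = T0;
    if (M > bestM) { bestM = M; bla = la; blp = lp; }
    for (int s = 0; s < steps; ++s) {
      double dM = 0.0;
      bool merge = unif_rand() < 0.1;
      if (!merge) {
        const int node = (int)(unif_rand() * (n + m)) % (n + m);
        const int newlab = (int)(unif_rand() * L) % L;
        if (node < n) {
          const int old = la[node];
          if (newlab == old) { T *= cooling; continue; }
          for (int j = 0; j < m; ++j) {
            if (lp[j] == newlab) dM += S(node, j);
            else if (lp[j] == old) dM -= S(node, j);
          }
          if (dM > 0 || unif_rand() < std::exp(dM / T)) { la[node] = newlab; M += dM; }
        } else {
          const int jn = node - n;
          const int old = lp[jn];
          if (newlab == old) { T *= cooling; continue; }
          for (int i = 0; i < n; ++i) {
            if (la[i] == newlab) dM += S(i, jn);
            else if (la[i] == old) dM -= S(i, jn);
          }
          if (dM > 0 || unif_rand() < std::exp(dM / T)) { lp[jn] = newlab; M += dM; }
        }
      } else {
        const int a = (int)(unif_rand() * L) % L;
        const int b = (int)(unif_rand() * L) % L;
        if (a == b) { T *= cooling; continue; }
        for (int i = 0; i < n; ++i) {
          if (la[i] != a) continue;
          for (int j = 0; j < m; ++j) if (lp[j] == b) dM += S(i, j);
        }
        for (int i = 0; i < n; ++i) {
          if (la[i] != b) continue;
          for (int j = 0; j < m; ++j) if (lp[j] == a) dM += S(i, j);
        }
        if (dM > 0 || unif_rand() < std::exp(dM / T)) {
          for (int i = 0; i < n; ++i) if (la[i] == a) la[i] = b;
          for (int j = 0; j < m; ++j) if (lp[j] == a) lp[j] = b;
          M += dM;
        }
      }
      if (M > bestM) { bestM = M; bla = la; blp = lp; }
      T *= cooling;
    }
  }

  return List::create(_["M"] = bestM,
                      _["labels_animals"] = wrap(bla),
                      _["labels_plants"] = wrap(blp));
}
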