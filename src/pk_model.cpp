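// Two-compartment infusion kinetics and the per-subject Laplace machinery.
// The inner conditional-mode search runs here because it dominates the
// cost of the marginal-likelihood evaluation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Advance the two-compartment state a = (A1, A2) [mg] over dt hours under a
// constant zero-order input `rate` [mg/h] into the central compartment, with
// micro constants k10, k12, k21 [1/h].  Exact matrix-exponential solution
// via Lagrange interpolation on the two disposition eigenvalues; switches to
// the repeated-eigenvalue limit when they nearly coincide to avoid
// catastrophic cancellation.
static inline void advance_state(double *a, double dt, double rate,
                                 double k10, double k12, double k21) {
  if (dt <= 0.0) return;

  if (k12 <= 0.0 || k21 <= 0.0) {
    // Q = 0: one-compartment central kinetics, peripheral amount frozen
    double e = std::exp(-k10 * dt);
    if (k10 > 0.0) {
      double ass = rate / k10;
      a[0] = ass + (a[0] - ass) * e;
    } else {
      a[0] += rate * dt;
    }
    return;
  }

  const double s = k10 + k12 + k21;
  const double p = k10 * k21;
  double disc = s * s - 4.0 * p;
  if (disc < 0.0) disc = 0.0;
  const double sq = std::sqrt(disc);
  const double l1 = 0.5 * (s + sq); // fast hybrid rate constant
  const double l2 = 0.5 * (s - sq); // slow (terminal) hybrid rate constant

  // infusion steady state: M ass = -(rate, 0)
  const double ss0 = rate / k10;
  const double ss1 = rate * k12 / p;

  const double d0 = a[0] - ss0;
  const double d1 = a[1] - ss1;

  // M = [[-(k10+k12), k21], [k12, -k21]], eigenvalues -l1, -l2
  const double m11 = -(k10 + k12), m12 = k21, m21 = k12, m22 = -k21;

  double e11, e12, e21, e22;
  if (sq > 1e-9 * l1) {
    const double e1 = std::exp(-l1 * dt), e2 = std::exp(-l2 * dt);
    const double inv = 1.0 / (l2 - l1);
    e11 = (e1 * (m11 + l2) - e2 * (m11 + l1)) * inv;
    e12 = (e1 - e2) * m12 * inv;
    e21 = (e1 - e2) * m21 * inv;
    e22 = (e1 * (m22 + l2) - e2 * (m22 + l1)) * inv;
  } else {
    // near-degenerate eigenvalues: expm(M dt) ~ e^{mu dt}(I + (M - mu I) dt)
    const double mu = -0.5 * (l1 + l2);
    const double e = std::exp(mu * dt);
    e11 = e * (1.0 + (m11 - mu) * dt);
    e12 = e * (m12 * dt);
    e21 = e * (m21 * dt);
    e22 = e * (1.0 + (m22 - mu) * dt);
  }

  a[0] = ss0 + e11 * d0 + e12 * d1;
  a[1] = ss1 + e21 * d0 + e22 * d1;
}

// Core profile computation.  obs_t must be sorted ascending.  Occasion k
// (0-based) spans [dose_t[k], dose_t[k+1]); parameters per occasion
// (K entries) or shared (1 entry).  out receives concentrations.
static void profile_core(const double *obs_t, int nobs, const double *dose_t,
                         const double *dose_amt, const double *dose_dur,
                         int nd, const double *CL, const double *V1,
                         const double *Q, const double *V2, int K,
                         double *out) {
  if (nd == 0) {
    std::fill(out, out + nobs, 0.0);
    return;
  }
  std::vector<double> bp;
  bp.reserve(2 * nd + nobs);
  for (int i = 0; i < nd; ++i) {
    bp.push_back(dose_t[i]);
    bp.push_back(dose_t[i] + dose_dur[i]);
  }
  for (int i = 0; i < nobs; ++i) bp.push_back(obs_t[i]);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end()), bp.end());

  auto occ_of = [&](double tt) {
    if (K == 1) return 0;
    int k = 0;
    while (k + 1 < nd && tt >= dose_t[k + 1]) ++k;
    return k;
  };

  double a[2] = {0.0, 0.0};
  double t = dose_t[0];
  int iobs = 0;
  while (iobs < nobs && obs_t[iobs] <= t) out[iobs++] = 0.0;

  size_t ib = 0;
  while (ib < bp.size() && bp[ib] <= t) ++ib;
  for (; ib < bp.size() && iobs < nobs; ++ib) {
    const double t1 = bp[ib];
    const int k = occ_of(t);
    const double k10 = CL[k] / V1[k];
    const double k12 = Q[k] / V1[k];
    const double k21 = (V2[k] > 0.0) ? Q[k] / V2[k] : 0.0;
    double rate = 0.0;
    for (int i = 0; i < nd; ++i)
      if (dose_t[i] <= t && t < dose_t[i] + dose_dur[i])
        rate += dose_amt[i] / dose_dur[i];
    advance_state(a, t1 - t, rate, k10, k12, k21);
    t = t1;
    while (iobs < nobs && obs_t[iobs] <= t) {
      out[iobs] = a[0] / V1[occ_of(obs_t[iobs])];
      ++iobs;
    }
  }
}

// Central-compartment concentration [mg/L = ug/ml] at obs_t (any order) for
// one subject under zero-order infusion doses, with per-occasion parameters
// (occasions delimited by dose times, amounts continuous across switches).
// [[Rcpp::export]]
NumericVector pk_profile_cpp(NumericVector obs_t, NumericVector dose_t,
                             NumericVector dose_amt, NumericVector dose_dur,
                             NumericVector CL, NumericVector V1,
                             NumericVector Q, NumericVector V2) {
  const int nobs = obs_t.size(), nd = dose_t.size(), K = CL.size();
  if (V1.size() != K || Q.size() != K || V2.size() != K)
    stop("occasion parameter vectors must have equal length");
  if (nd > 0 && K != 1 && K != nd)
    stop("need one parameter set per occasion (or a single shared set)");
  NumericVector out(nobs);
  if (nobs == 0) return out;

  std::vector<int> ord(nobs);
  for (int i = 0; i < nobs; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return obs_t[a] < obs_t[b]; });
  std::vector<double> ts(nobs), res(nobs);
  for (int i = 0; i < nobs; ++i) ts[i] = obs_t[ord[i]];
  profile_core(ts.data(), nobs, dose_t.begin(), dose_amt.begin(),
               dose_dur.begin(), nd, CL.begin(), V1.begin(), Q.begin(),
               V2.begin(), K, res.data());
  for (int i = 0; i < nobs; ++i) out[ord[i]] = res[i];
  return out;
}

// ---- per-subject Laplace machinery -----------------------------------------
//
// b layout (full, length 3 + 2K): (eta_CL, eta_V1, eta_V2,
// kappa_CL[1..K], kappa_V2[1..K]).  `idx` (0-based) selects the active
// components; `prior_var` holds their prior variances.

struct SubjectData {
  std::vector<double> obs_t, y, dose_t, amt, dur;
  int K;
  double thCL, thV1, thQ, thV2, s2p, sa2;
  std::vector<int> idx;
  std::vector<double> pvar;
};

static void predict_b(const SubjectData &S, const arma::vec &ba,
                      std::vector<double> &f) {
  const int K = S.K;
  std::vector<double> b(3 + 2 * K, 0.0);
  for (size_t j = 0; j < S.idx.size(); ++j) b[S.idx[j]] = ba(j);
  std::vector<double> CL(K), V1(K), Q(K), V2(K);
  for (int k = 0; k < K; ++k) {
    CL[k] = S.thCL * std::exp(b[0] + b[3 + k]);
    V1[k] = S.thV1 * std::exp(b[1]);
    Q[k] = S.thQ;
    V2[k] = S.thV2 * std::exp(b[2] + b[3 + K + k]);
  }
  profile_core(S.obs_t.data(), (int)S.obs_t.size(), S.dose_t.data(),
               S.amt.data(), S.dur.data(), (int)S.dose_t.size(), CL.data(),
               V1.data(), Q.data(), V2.data(), K, f.data());
}

static double h_value(const SubjectData &S, const std::vector<double> &f,
                      const arma::vec &ba) {
  double h = 0.0;
  for (size_t j = 0; j < S.y.size(); ++j) {
    double v = f[j] * f[j] * S.s2p + S.sa2;
    if (v < 1e-12) v = 1e-12;
    double r = S.y[j] - f[j];
    h += std::log(2.0 * M_PI * v) + r * r / v;
  }
  for (size_t j = 0; j < S.pvar.size(); ++j)
    h += ba(j) * ba(j) / S.pvar[j];
  return h;
}

static SubjectData build_subject(List sub, List pop, IntegerVector idx,
                                 NumericVector pvar) {
  SubjectData S;
  S.obs_t = as<std::vector<double>>(sub["obs_t"]);
  S.y = as<std::vector<double>>(sub["y"]);
  S.dose_t = as<std::vector<double>>(sub["dose_t"]);
  S.amt = as<std::vector<double>>(sub["amt"]);
  S.dur = as<std::vector<double>>(sub["dur"]);
  S.K = as<int>(sub["K"]);
  S.thCL = as<double>(pop["thCL"]);
  S.thV1 = as<double>(pop["thV1"]);
  S.thQ = as<double>(pop["thQ"]);
  S.thV2 = as<double>(pop["thV2"]);
  S.s2p = as<double>(pop["s2p"]);
  S.sa2 = as<double>(pop["sa2"]);
  S.idx = as<std::vector<int>>(idx); // already 0-based
  S.pvar = as<std::vector<double>>(pvar);
  return S;
}

struct LaplaceResult {
  arma::vec b;
  double h = 0.0, ofv = 0.0;
  bool converged = true, flagged = false;
  arma::mat J;
  std::vector<double> f;
};

// Damped Gauss-Newton search for the conditional mode of one subject's
// random effects, followed by the Laplace contribution to -2 log marginal
// likelihood.  The gradient is exact (interaction terms included); the
// curvature is Gauss-Newton with Levenberg damping.
static LaplaceResult laplace_one(const SubjectData &S,
                                 const NumericVector &start, double gtol,
                                 int max_iter, bool want_jac) {
  LaplaceResult R;
  const int d = (int)S.idx.size();
  const int n = (int)S.y.size();
  R.b = arma::vec(d, arma::fill::zeros);
  if (n == 0) return R;

  arma::vec ba(d, arma::fill::zeros);
  if (start.size() == d)
    for (int j = 0; j < d; ++j) ba(j) = start[j];

  std::vector<double> f(n), ftmp(n);
  predict_b(S, ba, f);
  double h = h_value(S, f, ba);
  if (!std::isfinite(h)) {
    ba.zeros();
    predict_b(S, ba, f);
    h = h_value(S, f, ba);
  }

  arma::mat J(n, d);
  arma::vec g(d);
  bool conv = (d == 0);
  const double fd = 1e-5;

  for (int it = 0; d > 0 && it < max_iter; ++it) {
    // forward-difference Jacobian of the prediction vector
    for (int j = 0; j < d; ++j) {
      arma::vec bp = ba;
      bp(j) += fd;
      predict_b(S, bp, ftmp);
      for (int i = 0; i < n; ++i) J(i, j) = (ftmp[i] - f[i]) / fd;
    }
    arma::vec v(n), r(n), wt(n);
    for (int i = 0; i < n; ++i) {
      v(i) = std::max(f[i] * f[i] * S.s2p + S.sa2, 1e-12);
      r(i) = S.y[i] - f[i];
      wt(i) = -2.0 * r(i) / v(i) +
              2.0 * f[i] * S.s2p * (1.0 / v(i) - r(i) * r(i) / (v(i) * v(i)));
    }
    g = J.t() * wt;
    for (int j = 0; j < d; ++j) g(j) += 2.0 * ba(j) / S.pvar[j];
    if (arma::abs(g).max() < gtol * (1.0 + std::fabs(h))) {
      conv = true;
      break;
    }
    arma::mat Jw = J;
    for (int i = 0; i < n; ++i) Jw.row(i) /= std::sqrt(v(i));
    arma::mat H = 2.0 * (Jw.t() * Jw);
    for (int j = 0; j < d; ++j) H(j, j) += 2.0 / S.pvar[j];

    bool improved = false;
    double hprev = h, lam = 0.0;
    for (int damp = 0; damp < 8 && !improved; ++damp) {
      arma::mat Hd = H;
      if (lam > 0.0)
        for (int j = 0; j < d; ++j) Hd(j, j) += lam * H(j, j) + lam;
      arma::vec delta;
      bool ok = arma::solve(delta, Hd, -g, arma::solve_opts::no_approx);
      if (ok) {
        double alpha = 1.0;
        for (int ls = 0; ls < 10; ++ls) {
          arma::vec ban = ba + alpha * delta;
          predict_b(S, ban, ftmp);
          double hn = h_value(S, ftmp, ban);
          if (std::isfinite(hn) && hn < h) {
            ba = ban;
            f = ftmp;
            h = hn;
            improved = true;
            break;
          }
          alpha *= 0.5;
        }
      }
      lam = (lam == 0.0) ? 1e-4 : lam * 10.0;
    }
    if (!improved) {
      conv = arma::abs(g).max() < 1e-3 * (1.0 + std::fabs(h));
      break;
    }
    if (hprev - h < 1e-10 * (std::fabs(h) + 1.0)) {
      conv = true;
      break;
    }
  }

  // Laplace term at the mode: log det(J' V^-1 J + diag(1/pvar)) + sum log pvar
  double ofv = h;
  bool flagged = false;
  if (d > 0) {
    // (the Jacobian is recomputed at the final mode)
    for (int j = 0; j < d; ++j) {
      arma::vec bp = ba;
      bp(j) += fd;
      predict_b(S, bp, ftmp);
      for (int i = 0; i < n; ++i) J(i, j) = (ftmp[i] - f[i]) / fd;
    }
    arma::mat Jw = J;
    for (int i = 0; i < n; ++i) {
      double v = std::max(f[i] * f[i] * S.s2p + S.sa2, 1e-12);
      Jw.row(i) /= std::sqrt(v);
    }
    arma::mat D = Jw.t() * Jw;
    double slogvar = 0.0;
    for (int j = 0; j < d; ++j) {
      D(j, j) += 1.0 / S.pvar[j];
      slogvar += std::log(S.pvar[j]);
    }
    arma::mat Rch;
    double ld;
    if (arma::chol(Rch, D)) {
      ld = 2.0 * arma::sum(arma::log(Rch.diag()));
    } else {
      flagged = true;
      arma::vec ev = arma::eig_sym(D); // floor eigenvalues when non-PD
      ld = 0.0;
      for (arma::uword j = 0; j < ev.n_elem; ++j)
        ld += std::log(std::max(ev(j), 1e-8));
    }
    ofv += slogvar + ld;
  }

  R.b = ba;
  R.h = h;
  R.ofv = ofv;
  R.converged = conv;
  R.flagged = flagged;
  if (want_jac) {
    R.J = J;
    R.f = f;
  }
  return R;
}

// Single-subject entry point (diagnostics, empirical Bayes estimates).
// [[Rcpp::export]]
List subject_laplace_cpp(List sub, List pop, IntegerVector idx,
                         NumericVector pvar, NumericVector start,
                         double gtol = 1e-6, int max_iter = 50,
                         bool want_jac = false) {
  SubjectData S = build_subject(sub, pop, idx, pvar);
  LaplaceResult R = laplace_one(S, start, gtol, max_iter, want_jac);
  List out = List::create(
      _["b"] = NumericVector(R.b.begin(), R.b.end()), _["h"] = R.h,
      _["ofv"] = R.ofv, _["converged"] = R.converged,
      _["flagged"] = R.flagged);
  if (want_jac && R.f.size()) {
    out["J"] = wrap(R.J);
    out["f"] = wrap(R.f);
  }
  return out;
}

// Whole-population objective: sum of subject Laplace contributions, with
// per-subject warm starts.  Returns the total OFV and the modes for reuse
// as the next iteration's starts.
// [[Rcpp::export]]
List population_ofv_cpp(List subs, List pop, List idxs, List pvars,
                        List starts, double gtol = 1e-6,
                        int max_iter = 50) {
  const int ns = subs.size();
  double total = 0.0;
  int nflag = 0;
  List modes(ns);
  for (int i = 0; i < ns; ++i) {
    SubjectData S = build_subject(subs[i], pop, idxs[i], pvars[i]);
    SEXP sti = starts[i];
    NumericVector st = Rf_isNull(sti) ? NumericVector(0)
                                      : NumericVector(sti);
    LaplaceResult R = laplace_one(S, st, gtol, max_iter, false);
    total += R.ofv;
    nflag += R.flagged ? 1 : 0;
    modes[i] = NumericVector(R.b.begin(), R.b.end());
    if (!std::isfinite(total)) {
      total = 1e10;
      break;
    }
  }
  return List::create(_["total"] = total, _["modes"] = modes,
                      _["n_flagged"] = nflag);
}
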