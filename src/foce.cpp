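// FOCE-with-interaction objective for the two-compartment, zero-order
// absorption, linear elimination model with continuous zero-order
// endogenous production.
//
// Per subject the conditional mode of the log-scale random effects
// (eta on V1, CL, D1, R1) is found by damped Newton iteration with an
// analytic gradient (the proportional-error variance is evaluated at the
// conditional prediction -- the "interaction"). The marginal -2 log
// likelihood is then the first-order linearization at the mode:
//   y ~ N(f(eta^) - G eta^, G Omega G' + diag(sigma^2 f(eta^)^2))
// The n*log(2*pi) constant is included, so the objective is directly
// comparable to exact quadrature of the marginal likelihood.
//
// The mode is resolved to a gradient norm ~1e-7 so that the objective is
// smooth enough for finite-difference gradients in the outer optimization
// (the linearized OFV depends on the mode to first order).

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

struct SubjectData {
  vec times;   // observation times (h)
  vec y;       // observations (ug/mL)
  vec amt;     // dose amounts (g)
  vec dstart;  // dose start times (h)
  double lw;   // log(weight / 70), for the optional covariate power model
};

// Central concentration (ug/mL) for individual parameters.
// Zero-order input of each dose over duration D1; endogenous steady state
// R1/CL superposed. th = (V1, CL, V2, Q, D1, R1).
static void pred_conc_into(const SubjectData& s, const double* th, vec& out) {
  const double V1 = th[0], CL = th[1], V2 = th[2], Q = th[3],
               D1 = th[4], R1 = th[5];
  const double k10 = CL / V1;
  const bool one_cpt = (Q <= 0.0 || V2 <= 0.0);
  double alpha = k10, beta = 0.0, A = 1.0, B = 0.0, k21 = 0.0;
  if (!one_cpt) {
    const double k12 = Q / V1;
    k21 = Q / V2;
    const double ssum = k10 + k12 + k21;
    const double disc = std::sqrt(ssum * ssum - 4.0 * k10 * k21);
    alpha = 0.5 * (ssum + disc);
    beta  = 0.5 * (ssum - disc);
    A = (alpha - k21) / (alpha - beta);
    B = (k21 - beta) / (alpha - beta);
  }
  out.set_size(s.times.n_elem);
  out.fill(1000.0 * R1 / CL);
  for (uword d = 0; d < s.amt.n_elem; ++d) {
    if (s.amt(d) <= 0.0) continue;
    const double rate = s.amt(d) / D1;
    for (uword j = 0; j < s.times.n_elem; ++j) {
      const double te = s.times(j) - s.dstart(d);
      if (te <= 0.0) continue;
      const double t1 = std::min(te, D1);
      const double t2 = std::max(te - D1, 0.0);
      double c;
      if (one_cpt) {
        c = (rate / CL) * (1.0 - std::exp(-k10 * t1)) * std::exp(-k10 * t2);
      } else {
        const double ca = (A / alpha) * (1.0 - std::exp(-alpha * t1)) *
                          std::exp(-alpha * t2);
        const double cb = (B / beta) * (1.0 - std::exp(-beta * t1)) *
                          std::exp(-beta * t2);
        c = (rate / V1) * (ca + cb);
      }
      out(j) += 1000.0 * c;
    }
  }
}

static vec pred_conc(const SubjectData& s, const double* th) {
  vec out;
  pred_conc_into(s, th, out);
  return out;
}

// Individual parameters from population theta and eta (active subset).
// Eta slots map 0->V1, 1->CL, 2->D1, 3->R1. When theta has 8 entries the
// last two are power-of-weight exponents on CL (theta 6) and V1 (theta 7).
static void ind_theta(const vec& theta, const vec& eta, const uvec& act,
                      double lw, double* th) {
  th[0] = theta(0); th[1] = theta(1); th[2] = theta(2);
  th[3] = theta(3); th[4] = theta(4); th[5] = theta(5);
  if (theta.n_elem >= 8) {
    th[1] *= std::exp(theta(6) * lw);
    th[0] *= std::exp(theta(7) * lw);
  }
  static const int slot[4] = {0, 1, 4, 5};
  for (uword k = 0; k < act.n_elem; ++k)
    th[slot[act(k)]] *= std::exp(eta(k));
}

static void pred_at_into(const SubjectData& s, const vec& theta,
                         const vec& eta, const uvec& act, vec& out) {
  double th[6];
  ind_theta(theta, eta, act, s.lw, th);
  pred_conc_into(s, th, out);
}

static vec pred_at(const SubjectData& s, const vec& theta, const vec& eta,
                   const uvec& act) {
  vec out;
  pred_at_into(s, theta, eta, act, out);
  return out;
}

// Prediction sensitivity wrt eta (n x m), central differences on the
// analytic prediction (smooth, no optimization inside).
// workspace for repeated inner evaluations (single-threaded)
struct ModeWork {
  vec f, fc, ftmp1, ftmp2, coef, grad, step, eta_c, e;
  mat G, Gc, H;
};

static void pred_grad_into(const SubjectData& s, const vec& theta,
                           const vec& eta, const uvec& act, double h,
                           ModeWork& w, mat& G) {
  const uword m = eta.n_elem;
  G.set_size(s.y.n_elem, m);
  w.e = eta;
  for (uword k = 0; k < m; ++k) {
    w.e(k) = eta(k) + h;
    pred_at_into(s, theta, w.e, act, w.ftmp1);
    w.e(k) = eta(k) - h;
    pred_at_into(s, theta, w.e, act, w.ftmp2);
    w.e(k) = eta(k);
    G.col(k) = (w.ftmp1 - w.ftmp2) / (2.0 * h);
  }
}

static mat pred_grad(const SubjectData& s, const vec& theta, const vec& eta,
                     const uvec& act, double h) {
  ModeWork w;
  mat G;
  pred_grad_into(s, theta, eta, act, h, w, G);
  return G;
}

// -2 log joint density (up to the Omega normalizing constant, which does
// not depend on eta): residual part + eta' Oinv eta.
static double inner_obj(const SubjectData& s, const vec& f, const vec& eta,
                        const mat& Oinv, double sig2) {
  double val = 0.0;
  for (uword j = 0; j < f.n_elem; ++j) {
    double v = sig2 * f(j) * f(j);
    if (v < 1e-300) v = 1e-300;
    const double r = s.y(j) - f(j);
    val += std::log(v) + r * r / v;
  }
  return val + as_scalar(eta.t() * Oinv * eta);
}

// Analytic gradient of the inner objective given f and G:
//   d/deta [log v + r^2/v] = f_eta * (2/f - 2 r/v - 2 r^2/(v f)),
// with v = sig2 f^2, r = y - f.
static void inner_grad_into(const SubjectData& s, const vec& f, const mat& G,
                            const vec& eta, const mat& Oinv, double sig2,
                            ModeWork& w, vec& out) {
  w.coef.set_size(f.n_elem);
  for (uword j = 0; j < f.n_elem; ++j) {
    double fj = f(j);
    if (std::abs(fj) < 1e-150) fj = (fj < 0 ? -1e-150 : 1e-150);
    const double v = std::max(sig2 * fj * fj, 1e-300);
    const double r = s.y(j) - fj;
    w.coef(j) = 2.0 / fj - 2.0 * r / v - 2.0 * r * r / (v * fj);
  }
  out = G.t() * w.coef + 2.0 * Oinv * eta;
}

// Gauss-Newton Hessian of the inner objective: the second derivative of
// the residual part wrt the prediction, times f_eta f_eta', dropping the
// curvature of f itself. Exact at the mode to the order the line search
// needs; the analytic gradient governs final precision.
static mat inner_hess_gn(const SubjectData& s, const vec& f, const mat& G,
                         const mat& Oinv, double sig2) {
  vec dcoef(f.n_elem);
  for (uword j = 0; j < f.n_elem; ++j) {
    double fj = f(j);
    if (std::abs(fj) < 1e-150) fj = (fj < 0 ? -1e-150 : 1e-150);
    const double r = s.y(j) - fj;
    const double f2 = fj * fj;
    dcoef(j) = -2.0 / f2 +
               (2.0 / sig2) * (1.0 / f2 + 2.0 * r / (f2 * fj)) +
               (2.0 / sig2) * (2.0 * r / (f2 * fj) + 3.0 * r * r / (f2 * f2));
  }
  return G.t() * diagmat(dcoef) * G + 2.0 * Oinv;
}

// Damped (Gauss-)Newton minimization of the inner objective with analytic
// gradient; steps are accepted on objective decrease or, near the
// numerical floor of the objective, on gradient-norm decrease.
static vec find_mode(const SubjectData& s, const vec& theta, const uvec& act,
                     const mat& Oinv, double sig2, vec eta, bool& ok,
                     double& gval, ModeWork& w) {
  const uword m = eta.n_elem;
  const double hg = 1e-5;  // FD step for G inside gradient evaluations
  ok = true;
  pred_at_into(s, theta, eta, act, w.f);
  double g0 = inner_obj(s, w.f, eta, Oinv, sig2);
  pred_grad_into(s, theta, eta, act, hg, w, w.G);
  inner_grad_into(s, w.f, w.G, eta, Oinv, sig2, w, w.grad);
  const double gtol = 1e-7 * std::max(1.0, std::abs(g0) / 100.0);
  for (int iter = 0; iter < 150; ++iter) {
    if (norm(w.grad, "inf") < gtol) { gval = g0; return eta; }
    w.H = inner_hess_gn(s, w.f, w.G, Oinv, sig2);
    double ridge = 0.0;
    for (int t = 0; t < 12; ++t) {
      mat Hr = w.H + ridge * eye(m, m);
      bool solved = solve(w.step, Hr, -w.grad, solve_opts::no_approx);
      if (solved && dot(w.step, w.grad) < 0.0) break;
      ridge = (ridge == 0.0) ? 1.0 : ridge * 10.0;
      w.step.zeros(m);
    }
    // trust-region style cap: eta is log-scale, steps beyond ~1 unit are
    // never meaningful and invite basin hopping
    const double snorm = norm(w.step, 2);
    if (snorm > 1.0) w.step *= 1.0 / snorm;
    bool moved = false;
    double lam = 1.0;
    const double gn0 = norm(w.grad, "inf");
    for (int t = 0; t < 40; ++t) {
      w.eta_c = eta + lam * w.step;
      pred_at_into(s, theta, w.eta_c, act, w.fc);
      double gc = inner_obj(s, w.fc, w.eta_c, Oinv, sig2);
      if (gc < g0 - 1e-12 * std::max(1.0, std::abs(g0))) {
        eta = w.eta_c; w.f = w.fc; g0 = gc;
        pred_grad_into(s, theta, eta, act, hg, w, w.G);
        inner_grad_into(s, w.f, w.G, eta, Oinv, sig2, w, w.grad);
        moved = true;
        break;
      }
      // near the numerical floor of the objective only: accept tiny steps
      // on gradient-norm decrease (quadratic convergence regime)
      if (lam * norm(w.step, 2) < 1e-6) {
        pred_grad_into(s, theta, w.eta_c, act, hg, w, w.Gc);
        vec gcand;
        inner_grad_into(s, w.fc, w.Gc, w.eta_c, Oinv, sig2, w, gcand);
        if (norm(gcand, "inf") < 0.9 * gn0) {
          eta = w.eta_c; w.f = w.fc; g0 = gc; w.grad = gcand; w.G = w.Gc;
          moved = true;
          break;
        }
      }
      lam *= 0.5;
    }
    if (!moved) {
      gval = g0;
      if (norm(w.grad, "inf") < 1e4 * gtol) return eta;  // close enough
      ok = false;
      return eta;
    }
  }
  gval = g0;
  if (norm(w.grad, "inf") >= 1e4 * gtol) ok = false;
  return eta;
}

// Linearized (FOCE-I) -2 log marginal likelihood contribution at eta-hat.
static double subject_ofv(const SubjectData& s, const vec& theta,
                          const uvec& act, const mat& Omega, const mat& Oinv,
                          double sig2, vec& eta, bool& ok, ModeWork& w,
                          bool multistart) {
  const uword n = s.y.n_elem;
  if (act.n_elem == 0) {
    vec e0;
    vec f = pred_at(s, theta, e0, act);  // covariate scaling inside
    double val = n * LOG2PI;
    for (uword j = 0; j < n; ++j) {
      double v = sig2 * f(j) * f(j);
      if (v < 1e-300) v = 1e-300;
      const double r = s.y(j) - f(j);
      val += std::log(v) + r * r / v;
    }
    return val;
  }
  // the inner problem can be (shallowly) multimodal -- chiefly a D1/V1
  // trade-off with sparse absorption-phase sampling. Always solve from a
  // deterministic start set (zero, +/- offsets on the absorption eta) plus
  // the warm start, and keep the lowest joint objective, so the selected
  // mode is a stable function of the population parameters
  const uword m = eta.n_elem;
  std::vector<vec> starts;
  // multistart (zero + warm) keeps mode selection a stable function of the
  // population parameters, which gradient-based outer steps need; simplex
  // -only refits (bootstrap replicates) may use the warm start alone
  const bool have_warm = norm(eta, "inf") > 1e-12;
  if (multistart || !have_warm) starts.push_back(zeros<vec>(m));
  if (have_warm) starts.push_back(eta);
  vec best_eta;
  double best_gv = datum::inf;
  bool best_ok = false;
  for (size_t q = 0; q < starts.size(); ++q) {
    double gv = datum::inf;
    bool okq = true;
    vec mq = find_mode(s, theta, act, Oinv, sig2, starts[q], okq, gv, w);
    if (gv < best_gv - 1e-10 || (okq && !best_ok && gv < best_gv + 1e-10)) {
      best_gv = gv; best_eta = mq; best_ok = okq;
    }
  }
  eta = best_eta;
  ok = best_ok;
  vec f = pred_at(s, theta, eta, act);
  mat G = pred_grad(s, theta, eta, act, 1e-5);
  vec v = sig2 * square(f);
  v.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });
  mat V = G * Omega * G.t();
  V.diag() += v;
  vec r = s.y - f + G * eta;
  mat L;
  if (!chol(L, V, "lower")) { ok = false; return datum::inf; }
  vec z = solve(trimatl(L), r);
  double logdet = 2.0 * sum(log(L.diag()));
  return n * LOG2PI + logdet + dot(z, z);
}

static std::vector<SubjectData> convert_subjects(Rcpp::List subjects) {
  std::vector<SubjectData> out(subjects.size());
  for (int i = 0; i < subjects.size(); ++i) {
    Rcpp::List sub = subjects[i];
    out[i].times = Rcpp::as<vec>(sub["times"]);
    out[i].y = Rcpp::as<vec>(sub["y"]);
    out[i].amt = Rcpp::as<vec>(sub["amt"]);
    out[i].dstart = Rcpp::as<vec>(sub["dstart"]);
    out[i].lw = 0.0;
    if (sub.containsElementNamed("wt")) {
      double wt = Rcpp::as<double>(sub["wt"]);
      if (R_finite(wt) && wt > 0) out[i].lw = std::log(wt / 70.0);
    }
  }
  return out;
}

static Rcpp::List foce_ofv_impl(const std::vector<SubjectData>& data,
                                const vec& theta, const mat& omega,
                                double sigma, const vec& weights,
                                const mat& eta_start, bool multistart) {
  const int N = (int)data.size();
  const double sig2 = sigma * sigma;
  std::vector<uword> actv;
  for (uword k = 0; k < 4; ++k)
    if (omega(k, k) > 1e-12) actv.push_back(k);
  uvec act(actv);
  mat Om, Oinv;
  if (act.n_elem > 0) {
    Om = omega.submat(act, act);
    if (!inv_sympd(Oinv, Om))
      Rcpp::stop("omega is numerically singular");
  }
  mat eta_out(N, 4, fill::zeros);
  vec ofv_i(N, fill::zeros);
  double total = 0.0;
  int n_fail = 0;
  ModeWork w;
  for (int i = 0; i < N; ++i) {
    if (weights(i) == 0.0) continue;
    vec eta(act.n_elem, fill::zeros);
    for (uword k = 0; k < act.n_elem; ++k) eta(k) = eta_start(i, act(k));
    bool ok = true;
    double o = subject_ofv(data[i], theta, act, Om, Oinv, sig2, eta, ok, w,
                           multistart);
    if (!ok || !std::isfinite(o)) n_fail++;
    ofv_i(i) = o;
    total += weights(i) * o;
    for (uword k = 0; k < act.n_elem; ++k) eta_out(i, act(k)) = eta(k);
  }
  return Rcpp::List::create(Rcpp::Named("ofv") = total,
                            Rcpp::Named("ofv_i") = ofv_i,
                            Rcpp::Named("eta") = eta_out,
                            Rcpp::Named("n_fail") = n_fail);
}

// [[Rcpp::export]]
Rcpp::List foce_ofv_cpp(Rcpp::List subjects, arma::vec theta,
                        arma::mat omega, double sigma,
                        arma::vec weights, arma::mat eta_start,
                        bool multistart = true) {
  return foce_ofv_impl(convert_subjects(subjects), theta, omega, sigma,
                       weights, eta_start, multistart);
}

// Pre-converted dataset handle for repeated objective evaluations during
// optimization (avoids R list conversion per call).
// [[Rcpp::export]]
SEXP foce_data_ptr(Rcpp::List subjects) {
  auto* p = new std::vector<SubjectData>(convert_subjects(subjects));
  return Rcpp::XPtr<std::vector<SubjectData>>(p, true);
}

// [[Rcpp::export]]
Rcpp::List foce_ofv_ptr(SEXP ptr, arma::vec theta, arma::mat omega,
                        double sigma, arma::vec weights,
                        arma::mat eta_start, bool multistart = true) {
  Rcpp::XPtr<std::vector<SubjectData>> xp(ptr);
  return foce_ofv_impl(*xp, theta, omega, sigma, weights, eta_start,
                       multistart);
}

// [[Rcpp::export]]
arma::vec predict_conc_cpp(arma::vec times, arma::vec amt, arma::vec dstart,
                           arma::vec th6, bool include_endogenous) {
  SubjectData s;
  s.times = times;
  s.y = zeros<vec>(times.n_elem);
  s.amt = amt;
  s.dstart = dstart;
  double th[6];
  for (int k = 0; k < 6; ++k) th[k] = th6(k);
  vec f = pred_conc(s, th);
  if (!include_endogenous) f -= 1000.0 * th6(5) / th6(1);
  return f;
}
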