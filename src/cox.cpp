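// Cox partial-likelihood machinery shared by cox_fit(), fine_gray_fit() and
// the per-variant GWAS drivers.  Supports case weights, delayed entry
// (start, stop] risk sets and Efron or Breslow tie handling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct CoxData {
  arma::vec start;       // entry times; -inf when no delayed entry
  arma::vec stop;
  arma::ivec status;     // 1 = event
  arma::vec w;           // case weights
  arma::uvec ord_stop;   // indices sorted by stop, descending
  arma::uvec ord_start;  // indices sorted by start, descending
  bool has_start;
};

CoxData make_cox_data(const arma::vec& start, const arma::vec& stop,
                      const arma::ivec& status, const arma::vec& w,
                      bool has_start) {
  CoxData d;
  d.start = start; d.stop = stop; d.status = status; d.w = w;
  d.has_start = has_start;
  d.ord_stop = arma::sort_index(stop, "descend");
  if (has_start) d.ord_start = arma::sort_index(start, "descend");
  return d;
}

// Partial log-likelihood, score and observed information at beta.
// Processes event times in decreasing order, maintaining running risk-set
// sums; individuals enter when t <= stop and leave when t <= start.
// Inner updates are hand-rolled over the (small) covariate dimension to
// avoid per-row heap temporaries: this routine dominates the per-variant
// GWAS cost.
void cox_eval(const CoxData& d, const arma::mat& X, const arma::vec& beta,
              bool efron, double& ll, arma::vec& U, arma::mat& I) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec eta = X * beta;
  eta = arma::clamp(eta, -500.0, 500.0);
  arma::vec ew = d.w % arma::exp(eta);

  double r0 = 0.0;
  arma::vec r1(p, arma::fill::zeros);
  arma::mat r2(p, p, arma::fill::zeros);
  ll = 0.0; U.zeros(p); I.zeros(p, p);

  arma::uword i = 0, j = 0;
  std::vector<arma::uword> tied;
  arma::vec s1t(p), mu(p), xr(p);
  arma::mat s2t(p, p);
  double* r1p = r1.memptr();
  double* r2p = r2.memptr();
  double* xrp = xr.memptr();

  while (i < n) {
    const double t = d.stop(d.ord_stop(i));
    tied.clear();
    while (i < n && d.stop(d.ord_stop(i)) == t) {
      const arma::uword k = d.ord_stop(i);
      const double e = ew(k);
      r0 += e;
      for (arma::uword a = 0; a < p; ++a) xrp[a] = X(k, a);
      for (arma::uword a = 0; a < p; ++a) {
        r1p[a] += e * xrp[a];
        const double exa = e * xrp[a];
        for (arma::uword b = a; b < p; ++b) r2p[a + b * p] += exa * xrp[b];
      }
      if (d.status(k) == 1) tied.push_back(k);
      ++i;
    }
    if (d.has_start) {
      while (j < n && d.start(d.ord_start(j)) >= t) {
        const arma::uword k = d.ord_start(j);
        const double e = ew(k);
        r0 -= e;
        for (arma::uword a = 0; a < p; ++a) xrp[a] = X(k, a);
        for (arma::uword a = 0; a < p; ++a) {
          r1p[a] -= e * xrp[a];
          const double exa = e * xrp[a];
          for (arma::uword b = a; b < p; ++b) r2p[a + b * p] -= exa * xrp[b];
        }
        ++j;
      }
    }
    if (tied.empty()) continue;

    const arma::uword dn = tied.size();
    double wsum = 0.0, s0t = 0.0;
    s1t.zeros(); s2t.zeros();
    for (arma::uword q = 0; q < dn; ++q) {
      const arma::uword k = tied[q];
      const double e = ew(k), wk = d.w(k);
      wsum += wk;
      s0t += e;
      for (arma::uword a = 0; a < p; ++a) xrp[a] = X(k, a);
      for (arma::uword a = 0; a < p; ++a) {
        s1t(a) += e * xrp[a];
        U(a) += wk * xrp[a];
        for (arma::uword b = a; b < p; ++b)
          s2t(a, b) += e * xrp[a] * xrp[b];
      }
      ll += wk * eta(k);
    }
    if (efron && dn > 1) {
      const double wbar = wsum / dn;
      for (arma::uword q = 0; q < dn; ++q) {
        const double f = static_cast<double>(q) / dn;
        const double d0 = r0 - f * s0t;
        ll -= wbar * std::log(d0);
        for (arma::uword a = 0; a < p; ++a) mu(a) = (r1p[a] - f * s1t(a)) / d0;
        for (arma::uword a = 0; a < p; ++a) {
          U(a) -= wbar * mu(a);
          for (arma::uword b = a; b < p; ++b)
            I(a, b) += wbar * ((r2p[a + b * p] - f * s2t(a, b)) / d0 -
                               mu(a) * mu(b));
        }
      }
    } else {
      ll -= wsum * std::log(r0);
      for (arma::uword a = 0; a < p; ++a) mu(a) = r1p[a] / r0;
      for (arma::uword a = 0; a < p; ++a) {
        U(a) -= wsum * mu(a);
        for (arma::uword b = a; b < p; ++b)
          I(a, b) += wsum * (r2p[a + b * p] / r0 - mu(a) * mu(b));
      }
    }
  }
  // fill the symmetric lower triangles
  for (arma::uword a = 0; a < p; ++a)
    for (arma::uword b = a + 1; b < p; ++b) I(b, a) = I(a, b);
}

struct CoxFitResult {
  arma::vec beta, score;
  arma::mat imat, var;
  std::vector<double> ll_trace;
  int iter;
  bool converged, monotone, singular;
};

// Newton-Raphson with step-halving.  Convergence: max |score| < eps_score
// or relative loglik change < eps_loglik.
CoxFitResult cox_newton(const CoxData& d, const arma::mat& X,
                        const arma::vec& init, bool efron, int maxit,
                        double eps_score, double eps_loglik) {
  const arma::uword p = X.n_cols;
  CoxFitResult r;
  r.beta = init;
  r.iter = 0; r.converged = false; r.monotone = false; r.singular = false;

  double ll;
  arma::vec U(p);
  arma::mat I(p, p);
  cox_eval(d, X, r.beta, efron, ll, U, I);
  r.ll_trace.push_back(ll);

  for (int it = 1; it <= maxit; ++it) {
    r.iter = it;
    if (arma::abs(U).max() < eps_score) { r.converged = true; break; }
    arma::vec step;
    bool ok = arma::solve(step, I, U, arma::solve_opts::likely_sympd +
                                          arma::solve_opts::no_approx);
    if (!ok) {
      ok = arma::solve(step, I + 1e-8 * arma::eye(p, p), U);
      if (!ok) { r.singular = true; break; }
    }
    double ll_new;
    arma::vec U_new(p);
    arma::mat I_new(p, p);
    arma::vec beta_new = r.beta + step;
    cox_eval(d, X, beta_new, efron, ll_new, U_new, I_new);
    int halvings = 0;
    while ((!std::isfinite(ll_new) || ll_new < ll - 1e-12) && halvings < 25) {
      step *= 0.5;
      beta_new = r.beta + step;
      cox_eval(d, X, beta_new, efron, ll_new, U_new, I_new);
      ++halvings;
    }
    const double rel = std::fabs(ll_new - ll) / (std::fabs(ll) + 1e-4);
    r.beta = beta_new; ll = ll_new; U = U_new; I = I_new;
    r.ll_trace.push_back(ll);
    if (rel < eps_loglik) {
      r.converged = true;
      break;
    }
  }
  if (arma::abs(U).max() < eps_score) r.converged = true;
  // monotone partial likelihood: estimates drift to +/- infinity
  if (arma::abs(r.beta).max() > 15.0) {
    r.monotone = true;
    r.converged = false;
  }
  r.score = U; r.imat = arma::symmatu(I);
  I = r.imat;
  arma::mat V;
  if (arma::inv_sympd(V, I)) {
    r.var = V;
  } else if (arma::inv(V, I)) {
    r.var = V;
  } else {
    r.singular = true;
    r.var = arma::mat(p, p, arma::fill::value(NA_REAL));
  }
  return r;
}

}  // namespace

// [[Rcpp::export]]
List cox_fit_cpp(NumericVector start, NumericVector stop,
                 IntegerVector status, NumericMatrix X,
                 NumericVector weights, bool efron, NumericVector init,
                 int maxit, double eps_score, double eps_loglik) {
  const bool has_start = start.size() > 0;
  arma::vec st = has_start ? as<arma::vec>(start)
                           : arma::vec(stop.size(), arma::fill::value(-1e300));
  CoxData d = make_cox_data(st, as<arma::vec>(stop),
                            as<arma::ivec>(status), as<arma::vec>(weights),
                            has_start);
  arma::mat Xm = as<arma::mat>(X);
  // centring covariates leaves the partial likelihood unchanged but
  // improves conditioning
  arma::rowvec ctr = arma::mean(Xm, 0);
  Xm.each_row() -= ctr;
  CoxFitResult r = cox_newton(d, Xm, as<arma::vec>(init), efron, maxit,
                              eps_score, eps_loglik);
  return List::create(
      _["coefficients"] = r.beta, _["var"] = r.var, _["imat"] = r.imat,
      _["score"] = r.score, _["loglik_trace"] = r.ll_trace,
      _["iter"] = r.iter, _["converged"] = r.converged,
      _["monotone"] = r.monotone, _["singular"] = r.singular);
}

// Per-variant Cox GWAS: one fit per genotype column, dosage coefficient
// reported.  Shared risk-set ordering computed once.
// [[Rcpp::export]]
NumericMatrix cox_gwas_cpp(NumericVector stop, IntegerVector status,
                           IntegerMatrix G, Nullable<NumericMatrix> covar,
                           bool efron, int maxit, double eps_score,
                           double eps_loglik) {
  const int n = stop.size(), m = G.ncol();
  arma::vec st(n, arma::fill::value(-1e300));
  arma::vec w(n, arma::fill::ones);
  CoxData d = make_cox_data(st, as<arma::vec>(stop), as<arma::ivec>(status),
                            w, false);
  arma::mat C;
  int q = 0;
  if (covar.isNotNull()) {
    C = as<arma::mat>(covar.get());
    q = C.n_cols;
    C.each_row() -= arma::mean(C, 0);
  }
  const int p = 1 + q;
  arma::mat X(n, p);
  if (q > 0) X.cols(1, q) = C;
  NumericMatrix out(m, 4);  // beta, se, converged, estimable
  colnames(out) = CharacterVector::create("beta", "se", "converged",
                                          "estimable");
  // warm start: covariate coefficients from the no-dosage null model
  arma::vec init(p, arma::fill::zeros);
  if (q > 0) {
    CoxFitResult nullfit = cox_newton(d, C, arma::vec(q, arma::fill::zeros),
                                      efron, maxit, eps_score, eps_loglik);
    if (nullfit.converged) init.subvec(1, q) = nullfit.beta;
  }
  for (int j = 0; j < m; ++j) {
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += G(i, j);
    mean /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      X(i, 0) = G(i, j) - mean;
      ss += X(i, 0) * X(i, 0);
    }
    if (ss <= 0.0) {  // monomorphic: non-estimable
      out(j, 0) = 0.0; out(j, 1) = NA_REAL; out(j, 2) = 0; out(j, 3) = 0;
      continue;
    }
    CoxFitResult r = cox_newton(d, X, init, efron, maxit, eps_score,
                                eps_loglik);
    const bool ok = r.converged && !r.singular;
    out(j, 0) = ok ? r.beta(0) : NA_REAL;
    out(j, 1) = ok ? std::sqrt(r.var(0, 0)) : NA_REAL;
    out(j, 2) = ok ? 1 : 0;
    out(j, 3) = 1;
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Per-variant logistic regression (incidence GWAS): IRLS on
// [intercept, dosage, covariates]; dosage coefficient reported.
// [[Rcpp::export]]
NumericMatrix logistic_gwas_cpp(IntegerVector y, IntegerMatrix G,
                                Nullable<NumericMatrix> covar, int maxit,
                                double tol) {
  const int n = y.size(), m = G.ncol();
  arma::mat C;
  int q = 0;
  if (covar.isNotNull()) {
    C = as<arma::mat>(covar.get());
    q = C.n_cols;
  }
  const int p = 2 + q;
  arma::mat X(n, p, arma::fill::ones);
  if (q > 0) X.cols(2, 1 + q) = C;
  arma::vec yv(n);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) { yv(i) = y[i]; ybar += y[i]; }
  ybar /= n;
  const double b0 = std::log(ybar / (1.0 - ybar));

  // warm start: fit the no-dosage null model once (dosage column zeroed)
  arma::vec null_init(p, arma::fill::zeros);
  null_init(0) = b0;
  {
    arma::mat X0 = X;
    X0.col(1).zeros();
    arma::vec beta = null_init;
    for (int it = 0; it < maxit; ++it) {
      arma::vec eta = arma::clamp(X0 * beta, -30.0, 30.0);
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec score = X0.t() * (yv - mu);
      score(1) = 0.0;
      if (arma::abs(score).max() < tol) break;
      arma::mat info = X0.t() * (X0.each_col() % (mu % (1.0 - mu)));
      info(1, 1) = 1.0;  // keep the zeroed dosage column solvable
      arma::vec step;
      if (!arma::solve(step, info, score)) break;
      beta += step;
    }
    beta(1) = 0.0;
    null_init = beta;
  }

  NumericMatrix out(m, 4);
  colnames(out) = CharacterVector::create("beta", "se", "converged",
                                          "estimable");
  for (int j = 0; j < m; ++j) {
    double mean = 0.0, ss = 0.0;
    for (int i = 0; i < n; ++i) mean += G(i, j);
    mean /= n;
    for (int i = 0; i < n; ++i) {
      X(i, 1) = G(i, j) - mean;
      ss += X(i, 1) * X(i, 1);
    }
    if (ss <= 0.0) {
      out(j, 0) = 0.0; out(j, 1) = NA_REAL; out(j, 2) = 0; out(j, 3) = 0;
      continue;
    }
    arma::vec beta = null_init;
    bool conv = false, bad = false;
    arma::mat info(p, p);
    for (int it = 0; it < maxit; ++it) {
      arma::vec eta = X * beta;
      eta = arma::clamp(eta, -30.0, 30.0);
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec wt = mu % (1.0 - mu);
      arma::vec score = X.t() * (yv - mu);
      info = X.t() * (X.each_col() % wt);
      if (arma::abs(score).max() < tol) { conv = true; break; }
      arma::vec step;
      if (!arma::solve(step, info, score,
                       arma::solve_opts::likely_sympd +
                           arma::solve_opts::no_approx)) {
        bad = true;
        break;
      }
      beta += step;
      if (arma::abs(beta).max() > 30.0) { bad = true; break; }
    }
    if (conv && !bad) {
      arma::mat V;
      info = arma::symmatu(info);
      if (arma::inv_sympd(V, info)) {
        out(j, 0) = beta(1);
        out(j, 1) = std::sqrt(V(1, 1));
        out(j, 2) = 1; out(j, 3) = 1;
        continue;
      }
    }
    out(j, 0) = NA_REAL; out(j, 1) = NA_REAL; out(j, 2) = 0; out(j, 3) = 1;
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Per-variant simple linear regression (exposure GWAS), closed form.
// [[Rcpp::export]]
NumericMatrix linear_gwas_cpp(NumericVector y, IntegerMatrix G) {
  const int n = y.size(), m = G.ncol();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double syy = 0.0;
  for (int i = 0; i < n; ++i) syy += (y[i] - ybar) * (y[i] - ybar);
  NumericMatrix out(m, 4);
  colnames(out) = CharacterVector::create("beta", "se", "converged",
                                          "estimable");
  for (int j = 0; j < m; ++j) {
    double gbar = 0.0;
    for (int i = 0; i < n; ++i) gbar += G(i, j);
    gbar /= n;
    double sxx = 0.0, sxy = 0.0;
    for (int i = 0; i < n; ++i) {
      const double gc = G(i, j) - gbar;
      sxx += gc * gc;
      sxy += gc * (y[i] - ybar);
    }
    if (sxx <= 0.0) {
      out(j, 0) = 0.0; out(j, 1) = NA_REAL; out(j, 2) = 0; out(j, 3) = 0;
      continue;
    }
    const double beta = sxy / sxx;
    const double rss = syy - beta * sxy;
    const double s2 = rss / (n - 2);
    out(j, 0) = beta;
    out(j, 1) = std::sqrt(s2 / sxx);
    out(j, 2) = 1; out(j, 3) = 1;
  }
  return out;
}

// Hardy-Weinberg genotype dosages: two independent Bernoulli(maf) draws
// per individual, i.e. Binomial(2, maf).  Uses R's RNG stream.
// [[Rcpp::export]]
IntegerMatrix sim_genotypes_cpp(int n, NumericVector maf) {
  const int m = maf.size();
  IntegerMatrix G(n, m);
  for (int j = 0; j < m; ++j) {
    const double p = maf[j];
    const double p2 = p * p;           // P(dosage 2)
    const double p12 = p2 + 2.0 * p * (1.0 - p);  // P(dosage >= 1)
    for (int i = 0; i < n; ++i) {
      const double u = unif_rand();
      G(i, j) = u < p2 ? 2 : (u < p12 ? 1 : 0);
    }
  }
  return G;
}

// Risk-set statistics at a fixed beta for (start, stop] weighted data:
// unique event times (descending) with weighted event counts, S0 and the
// risk-set mean covariate vector.  Used for score residuals.
// [[Rcpp::export]]
List cox_riskset_stats_cpp(NumericVector start, NumericVector stop,
                           IntegerVector status, NumericMatrix X,
                           NumericVector weights, NumericVector beta) {
  const bool has_start = start.size() > 0;
  arma::vec st = has_start ? as<arma::vec>(start)
                           : arma::vec(stop.size(), arma::fill::value(-1e300));
  CoxData d = make_cox_data(st, as<arma::vec>(stop),
                            as<arma::ivec>(status), as<arma::vec>(weights),
                            has_start);
  arma::mat Xm = as<arma::mat>(X);
  const arma::uword n = Xm.n_rows, p = Xm.n_cols;
  arma::vec eta = Xm * as<arma::vec>(beta);
  eta = arma::clamp(eta, -500.0, 500.0);
  arma::vec ew = d.w % arma::exp(eta);

  std::vector<double> times, dwk, s0s;
  std::vector<arma::vec> xbars;
  double r0 = 0.0;
  arma::vec r1(p, arma::fill::zeros);
  arma::uword i = 0, j = 0;
  while (i < n) {
    const double t = d.stop(d.ord_stop(i));
    double dw = 0.0;
    while (i < n && d.stop(d.ord_stop(i)) == t) {
      const arma::uword k = d.ord_stop(i);
      r0 += ew(k);
      r1 += ew(k) * Xm.row(k).t();
      if (d.status(k) == 1) dw += d.w(k);
      ++i;
    }
    if (has_start) {
      while (j < n && d.start(d.ord_start(j)) >= t) {
        const arma::uword k = d.ord_start(j);
        r0 -= ew(k);
        r1 -= ew(k) * Xm.row(k).t();
        ++j;
      }
    }
    if (dw > 0.0) {
      times.push_back(t);
      dwk.push_back(dw);
      s0s.push_back(r0);
      xbars.push_back(r1 / r0);
    }
  }
  const arma::uword E = times.size();
  arma::mat xbar(E, p);
  for (arma::uword k = 0; k < E; ++k) xbar.row(k) = xbars[k].t();
  return List::create(_["time"] = times, _["dwk"] = dwk, _["s0"] = s0s,
                      _["xbar"] = xbar);
}

// [[Rcpp::export]]
NumericVector genetic_score_cpp(IntegerMatrix G, NumericVector effects) {
  const int n = G.nrow(), m = G.ncol();
  NumericVector s(n);
  for (int j = 0; j < m; ++j) {
    const double e = effects[j];
    if (e == 0.0) continue;
    for (int i = 0; i < n; ++i) s[i] += e * G(i, j);
  }
  return s;
}
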