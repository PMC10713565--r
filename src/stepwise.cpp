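// Logistic-regression IRLS and stepwise-AIC search on raw design matrices.
// The stepwise search runs inside every cross-validation training fold, so
// it works directly on column indices (no formula re-parsing) and warm-starts
// each candidate refit from the current coefficients.

#include <RcppArmadillo.h>
#include <algorithm>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct FitResult {
  vec beta;
  double loglik;
  bool converged;
  bool ridged;
  mat xtwx_inv;  // (X'WX)^-1 at the optimum (possibly ridged)
};

double loglik_logistic(const mat& X, const vec& y, const vec& beta) {
  vec eta = X * beta;
  // log(1+exp(eta)) computed stably
  vec lse(eta.n_elem);
  for (uword i = 0; i < eta.n_elem; ++i) {
    double e = eta[i];
    lse[i] = (e > 0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
  }
  return dot(y, eta) - accu(lse);
}

// IRLS with optional ridge fallback when the weighted normal equations are
// singular or the fit diverges (quasi-separation).
FitResult irls(const mat& X, const vec& y, vec beta0,
               int maxit = 50, double tol = 1e-9) {
  const uword p = X.n_cols;
  FitResult res;
  res.ridged = false;
  res.converged = false;
  if (beta0.n_elem != p) beta0 = zeros<vec>(p);
  vec beta = beta0;
  double ridge = 0.0;
  double ll_old = loglik_logistic(X, y, beta);

  for (int attempt = 0; attempt < 2; ++attempt) {
    for (int it = 0; it < maxit; ++it) {
      vec eta = X * beta;
      eta = clamp(eta, -30.0, 30.0);
      vec mu = 1.0 / (1.0 + exp(-eta));
      vec w = mu % (1.0 - mu);
      w = clamp(w, 1e-10, 0.25);
      mat xs = X.each_col() % sqrt(w);
      mat xtwx = xs.t() * xs;  // syrk path, symmetric half-cost
      if (ridge > 0) xtwx.diag() += ridge;
      vec score = X.t() * (y - mu);
      if (ridge > 0) score -= ridge * beta;  // penalised score
      vec step;
      bool ok = solve(step, xtwx, score, solve_opts::no_approx);
      if (!ok || !step.is_finite()) { beta = beta0; break; }
      // step-halving to keep the likelihood monotone
      double ll_new = datum::nan;
      double fac = 1.0;
      vec cand;
      for (int h = 0; h < 8; ++h) {
        cand = beta + fac * step;
        ll_new = loglik_logistic(X, y, cand);
        if (ridge > 0) ll_new -= 0.5 * ridge * dot(cand, cand);
        if (std::isfinite(ll_new) &&
            ll_new >= ll_old - 1e-12) break;
        fac *= 0.5;
      }
      if (!std::isfinite(ll_new)) { beta = beta0; break; }
      beta = cand;
      bool done = std::abs(ll_new - ll_old) < tol * (std::abs(ll_old) + 1.0);
      ll_old = ll_new;
      if (done) { res.converged = true; break; }
    }
    // |beta| at the working-response clamp scale indicates (quasi-)
    // separation even when the iteration technically converged
    if (res.converged && beta.is_finite() && abs(beta).max() < 15.0) break;
    if (attempt == 0) {       // retry once with a ridge-stabilised fit
      ridge = 1e-2;
      res.ridged = true;
      res.converged = false;
      beta = zeros<vec>(p);
      ll_old = loglik_logistic(X, y, beta);
    }
  }

  res.beta = beta;
  res.loglik = loglik_logistic(X, y, beta);
  vec eta = clamp(X * beta, -30.0, 30.0);
  vec mu = 1.0 / (1.0 + exp(-eta));
  vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
  mat xtwx = X.t() * (X.each_col() % w);
  if (res.ridged) xtwx.diag() += ridge;
  mat inv_ok;
  if (inv_sympd(inv_ok, xtwx)) res.xtwx_inv = inv_ok;
  else res.xtwx_inv = pinv(xtwx);
  return res;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_logistic_fit(const arma::mat& X, const arma::vec& y,
                            int maxit = 50, double tol = 1e-9) {
  FitResult f = irls(X, y, zeros<vec>(X.n_cols), maxit, tol);
  double aic = -2.0 * f.loglik + 2.0 * X.n_cols;
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = f.beta,
      Rcpp::Named("loglik") = f.loglik,
      Rcpp::Named("aic") = aic,
      Rcpp::Named("converged") = f.converged,
      Rcpp::Named("ridged") = f.ridged);
}

// Bidirectional stepwise AIC over `selectable` columns, `forced` columns
// always retained. Starts from forced + all selectable. Candidates are
// scanned in the order of their estimated AIC change (Wald statistic for
// drops, Rao score statistic for adds); the first candidate whose *exact*
// refit strictly lowers AIC is accepted. The search terminates only when an
// exhaustive scan finds no single add or drop that lowers AIC, so the result
// is a genuine local minimum of AIC.
//
// Indices are 0-based columns of X. Column 0 is expected to be the
// intercept and passed in `forced`.
// [[Rcpp::export]]
Rcpp::List cpp_stepwise_aic(const arma::mat& X, const arma::vec& y,
                            const arma::uvec& forced,
                            const arma::uvec& selectable,
                            int max_steps = 500) {
  const uword n = X.n_rows;
  std::vector<uword> in_model(forced.begin(), forced.end());
  for (uword j : selectable) in_model.push_back(j);
  std::set<uword> forced_set(forced.begin(), forced.end());
  std::set<uword> current(in_model.begin(), in_model.end());

  auto fit_cols = [&](const std::vector<uword>& cols, const vec& start) {
    uvec ucols(cols.size());
    for (size_t i = 0; i < cols.size(); ++i) ucols[i] = cols[i];
    mat Xs = X.cols(ucols);
    return irls(Xs, y, start, 50, 1e-9);
  };

  std::vector<uword> cols(current.begin(), current.end());
  FitResult fit = fit_cols(cols, vec());
  double aic = -2.0 * fit.loglik + 2.0 * cols.size();
  std::vector<double> aic_trace;
  aic_trace.push_back(aic);
  bool any_ridged = fit.ridged;

  struct Cand { double est; uword col; bool drop; };

  for (int step = 0; step < max_steps; ++step) {
    // working quantities of the current fit
    uvec ucols(cols.size());
    for (size_t i = 0; i < cols.size(); ++i) ucols[i] = cols[i];
    mat Xc = X.cols(ucols);
    vec eta = clamp(Xc * fit.beta, -30.0, 30.0);
    vec mu = 1.0 / (1.0 + exp(-eta));
    vec w = clamp(mu % (1.0 - mu), 1e-10, 0.25);
    vec resid = y - mu;

    std::vector<Cand> cands;
    // drop candidates: estimated dAIC = z^2 - 2
    for (size_t i = 0; i < cols.size(); ++i) {
      uword j = cols[i];
      if (forced_set.count(j)) continue;
      double se2 = fit.xtwx_inv(i, i);
      double z2 = (se2 > 0) ? fit.beta[i] * fit.beta[i] / se2 : 1e10;
      cands.push_back({z2 - 2.0, j, true});
    }
    // add candidates: estimated dAIC = 2 - score statistic
    mat XtW = Xc.each_col() % w;  // n x p
    for (uword j : selectable) {
      if (current.count(j)) continue;
      vec xj = X.col(j);
      double u = dot(xj, resid);
      vec a = XtW.t() * xj;                    // X'W xj
      double v = dot(xj, w % xj) - as_scalar(a.t() * fit.xtwx_inv * a);
      double s = (v > 1e-12) ? u * u / v : 0.0;
      cands.push_back({2.0 - s, j, false});
    }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand& a, const Cand& b) {
                       if (a.est != b.est) return a.est < b.est;
                       return a.col < b.col;
                     });

    bool accepted = false;
    for (const Cand& c : cands) {
      std::vector<uword> trial = cols;
      vec start;
      if (c.drop) {
        size_t pos = 0;
        while (trial[pos] != c.col) ++pos;
        trial.erase(trial.begin() + pos);
        start = fit.beta;
        start.shed_row(pos);
      } else {
        trial.push_back(c.col);
        start = join_cols(fit.beta, vec({0.0}));
      }
      FitResult f2 = fit_cols(trial, start);
      double aic2 = -2.0 * f2.loglik + 2.0 * trial.size();
      if (aic2 < aic - 1e-7) {
        cols = trial;
        fit = f2;
        aic = aic2;
        any_ridged = any_ridged || f2.ridged;
        current = std::set<uword>(cols.begin(), cols.end());
        aic_trace.push_back(aic);
        accepted = true;
        break;
      }
    }
    if (!accepted) break;  // exhaustive scan found nothing: local minimum
    (void)n;
  }

  uvec out(cols.size());
  for (size_t i = 0; i < cols.size(); ++i) out[i] = cols[i];
  return Rcpp::List::create(
      Rcpp::Named("selected") = out,
      Rcpp::Named("coefficients") = fit.beta,
      Rcpp::Named("aic") = aic,
      Rcpp::Named("loglik") = fit.loglik,
      Rcpp::Named("aic_trace") = aic_trace,
      Rcpp::Named("ridged") = any_ridged);
}
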