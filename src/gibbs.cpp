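// Systematic-scan Gibbs sampler for the geo-additive logistic model:
//   eta = X alpha + sum_j f_j(x_j) + f_str(zone) + f_uns(zone)
// Polya-Gamma augmentation makes every coefficient block conditionally
// Gaussian; variances get conjugate inverse-Gamma updates.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include "pg.h"

using namespace Rcpp;

// draw from N(Prec^{-1} b, Prec^{-1}) given the precision and linear shift
static arma::vec mvn_prec_draw(const arma::mat& prec, const arma::vec& b,
                               const char* block) {
  arma::mat U;
  if (!arma::chol(U, prec))
    stop("singular posterior precision in block '%s'", block);
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  arma::vec z(prec.n_rows);
  for (arma::uword i = 0; i < z.n_elem; ++i) z[i] = norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

static arma::vec group_sum(const arma::vec& v, const arma::uvec& idx,
                           arma::uword m) {
  arma::vec out(m, arma::fill::zeros);
  for (arma::uword i = 0; i < idx.n_elem; ++i) out[idx[i]] += v[i];
  return out;
}

static double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// inverse-Gamma(shape, rate) draw; negative quadratic forms (numerical
// noise) are clamped at zero upstream
static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(const arma::vec& y,
                     const arma::mat& X,
                     const List& sm_idx,
                     const List& sm_K,
                     const IntegerVector& sm_rank,
                     bool spatial,
                     const IntegerVector& zone,
                     const arma::mat& Q,
                     const IntegerVector& comp,
                     const IntegerVector& degree,
                     double a, double b,
                     int iterations, int burn_in, int thin,
                     List init,
                     bool center_smooths,
                     int verbose_every) {
  const arma::uword n = y.n_elem;
  const arma::uword p = X.n_cols;
  const int nsm = sm_idx.size();
  const arma::uword nz = spatial ? Q.n_rows : 0;
  const arma::vec kappa = y - 0.5;

  // unpack smooth designs
  std::vector<arma::uvec> idx(nsm);
  std::vector<arma::mat> K(nsm);
  std::vector<arma::uword> msm(nsm);
  for (int j = 0; j < nsm; ++j) {
    IntegerVector iv = sm_idx[j];
    arma::uvec u(iv.size());
    for (int i = 0; i < iv.size(); ++i) u[i] = iv[i] - 1;
    idx[j] = u;
    K[j] = as<arma::mat>(sm_K[j]);
    msm[j] = K[j].n_rows;
  }
  arma::uvec zidx;
  int ncomp = 0;
  if (spatial) {
    zidx.set_size(n);
    for (arma::uword i = 0; i < n; ++i) zidx[i] = zone[i] - 1;
    for (int i = 0; i < comp.size(); ++i) ncomp = std::max(ncomp, comp[i]);
  }
  const int rank_str = spatial ? (int)nz - ncomp : 0;

  // state: neutral start unless an initial state is supplied
  arma::vec alpha(p, arma::fill::zeros);
  std::vector<arma::vec> f(nsm);
  for (int j = 0; j < nsm; ++j) f[j] = arma::vec(msm[j], arma::fill::zeros);
  arma::vec fstr(nz, arma::fill::zeros), funs(nz, arma::fill::zeros);
  arma::vec tau2_sm(nsm, arma::fill::ones);
  double tau2_str = 1.0, tau2_uns = 1.0;
  if (init.size() > 0) {
    if (init.containsElementNamed("alpha")) alpha = as<arma::vec>(init["alpha"]);
    if (init.containsElementNamed("f")) {
      List fi = init["f"];
      for (int j = 0; j < nsm; ++j) f[j] = as<arma::vec>(fi[j]);
    }
    if (init.containsElementNamed("fstr")) fstr = as<arma::vec>(init["fstr"]);
    if (init.containsElementNamed("funs")) funs = as<arma::vec>(init["funs"]);
    if (init.containsElementNamed("tau2_sm")) tau2_sm = as<arma::vec>(init["tau2_sm"]);
    if (init.containsElementNamed("tau2_str")) tau2_str = as<double>(init["tau2_str"]);
    if (init.containsElementNamed("tau2_uns")) tau2_uns = as<double>(init["tau2_uns"]);
  }

  arma::vec eta(n, arma::fill::zeros);
  if (p > 0) eta = X * alpha;
  for (int j = 0; j < nsm; ++j)
    for (arma::uword i = 0; i < n; ++i) eta[i] += f[j][idx[j][i]];
  if (spatial)
    for (arma::uword i = 0; i < n; ++i) eta[i] += fstr[zidx[i]] + funs[zidx[i]];

  const int ndraw = (iterations - burn_in) / thin;
  arma::mat alpha_out(ndraw, p);
  std::vector<arma::mat> f_out(nsm);
  for (int j = 0; j < nsm; ++j) f_out[j].set_size(ndraw, msm[j]);
  arma::mat fstr_out(ndraw, nz), funs_out(ndraw, nz);
  arma::mat tau2_out(ndraw, nsm);
  arma::vec tau2str_out(ndraw), tau2uns_out(ndraw), dev_out(ndraw);
  arma::vec eta_mean(n, arma::fill::zeros);

  // component indicator matrix for the sum-to-zero projection
  arma::mat A;
  if (spatial) {
    A.zeros(ncomp, nz);
    for (arma::uword i = 0; i < nz; ++i) A(comp[i] - 1, i) = 1.0;
  }

  arma::vec omega(n);
  int kept = 0;
  for (int it = 1; it <= iterations; ++it) {
    // --- Polya-Gamma auxiliaries ---
    for (arma::uword i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

    // --- fixed effects (diffuse/flat prior) ---
    if (p > 0) {
      arma::vec eta_minus = eta - X * alpha;
      arma::vec bvec = X.t() * (kappa - omega % eta_minus);
      arma::mat Xw = X;
      Xw.each_col() %= omega;
      arma::mat prec = X.t() * Xw;
      alpha = mvn_prec_draw(prec, bvec, "fixed");
      eta = eta_minus + X * alpha;
    }

    // --- RW2 smooth blocks ---
    for (int j = 0; j < nsm; ++j) {
      arma::vec contrib(n);
      for (arma::uword i = 0; i < n; ++i) contrib[i] = f[j][idx[j][i]];
      arma::vec eta_minus = eta - contrib;
      arma::vec g = group_sum(omega, idx[j], msm[j]);
      arma::vec bvec = group_sum(kappa - omega % eta_minus, idx[j], msm[j]);
      arma::mat prec = K[j] / tau2_sm[j];
      prec.diag() += g;
      arma::vec fnew = mvn_prec_draw(prec, bvec, "smooth");
      for (arma::uword i = 0; i < n; ++i) eta_minus[i] += fnew[idx[j][i]];
      eta = eta_minus;
      if (center_smooths) {
        // constants live in the RW2 null space; shift them into the
        // intercept (flat prior) so the smooth is identified
        double m = arma::mean(fnew);
        fnew -= m;
        alpha[0] += m;
      }
      f[j] = fnew;
    }

    if (spatial) {
      // --- structured (ICAR) effect, sum-to-zero per component by
      //     conditioning-by-kriging: exact draw under the constraint ---
      arma::vec contrib(n);
      for (arma::uword i = 0; i < n; ++i) contrib[i] = fstr[zidx[i]];
      arma::vec eta_minus = eta - contrib;
      arma::vec g = group_sum(omega, zidx, nz);
      arma::vec bvec = group_sum(kappa - omega % eta_minus, zidx, nz);
      arma::mat prec = Q / tau2_str;
      prec.diag() += g;
      for (arma::uword i = 0; i < nz; ++i)
        if (degree[i] == 0) prec(i, i) += 1.0; // isolated zone: pinned to 0 below
      arma::mat U;
      if (!arma::chol(U, prec))
        stop("singular posterior precision in block 'structured spatial'");
      arma::vec mu = arma::solve(arma::trimatu(U),
                                 arma::solve(arma::trimatl(U.t()), bvec));
      arma::vec z(nz);
      for (arma::uword i = 0; i < nz; ++i) z[i] = norm_rand();
      arma::vec x = mu + arma::solve(arma::trimatu(U), z);
      arma::mat W = arma::solve(arma::trimatu(U),
                                arma::solve(arma::trimatl(U.t()), A.t()));
      fstr = x - W * arma::solve(A * W, A * x);
      for (arma::uword i = 0; i < n; ++i) eta_minus[i] += fstr[zidx[i]];
      eta = eta_minus;

      // --- unstructured effect: diagonal conditional ---
      for (arma::uword i = 0; i < n; ++i) eta[i] -= funs[zidx[i]];
      arma::vec g2 = group_sum(omega, zidx, nz);
      arma::vec b2 = group_sum(kappa - omega % eta, zidx, nz);
      for (arma::uword k = 0; k < nz; ++k) {
        double pv = g2[k] + 1.0 / tau2_uns;
        funs[k] = b2[k] / pv + norm_rand() / std::sqrt(pv);
      }
      for (arma::uword i = 0; i < n; ++i) eta[i] += funs[zidx[i]];
    }

    // --- conjugate inverse-Gamma variance updates ---
    for (int j = 0; j < nsm; ++j) {
      double quad = arma::as_scalar(f[j].t() * K[j] * f[j]);
      if (quad < 0) quad = 0;
      tau2_sm[j] = rinvgamma(a + 0.5 * sm_rank[j], b + 0.5 * quad);
    }
    if (spatial) {
      double quad = arma::as_scalar(fstr.t() * Q * fstr);
      if (quad < 0) quad = 0;
      tau2_str = rinvgamma(a + 0.5 * rank_str, b + 0.5 * quad);
      tau2_uns = rinvgamma(a + 0.5 * nz, b + 0.5 * arma::dot(funs, funs));
    }

    if (!eta.is_finite())
      stop("non-finite linear predictor at iteration %d", it);

    if (verbose_every > 0 && it % verbose_every == 0)
      Rcout << "iteration " << it << " / " << iterations << "\n";

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < ndraw) {
      for (arma::uword k = 0; k < p; ++k) alpha_out(kept, k) = alpha[k];
      for (int j = 0; j < nsm; ++j) f_out[j].row(kept) = f[j].t();
      if (spatial) {
        fstr_out.row(kept) = fstr.t();
        funs_out.row(kept) = funs.t();
        tau2str_out[kept] = tau2_str;
        tau2uns_out[kept] = tau2_uns;
      }
      for (int j = 0; j < nsm; ++j) tau2_out(kept, j) = tau2_sm[j];
      double dev = 0.0;
      for (arma::uword i = 0; i < n; ++i)
        dev += y[i] * eta[i] - softplus(eta[i]);
      dev_out[kept] = -2.0 * dev;
      eta_mean += eta;
      ++kept;
    }
    if (it % 256 == 0) checkUserInterrupt();
  }
  if (kept > 0) eta_mean /= kept;

  List f_list(nsm), tau2_list(nsm);
  for (int j = 0; j < nsm; ++j) f_list[j] = f_out[j];
  List state = List::create(
      _["alpha"] = alpha, _["fstr"] = fstr, _["funs"] = funs,
      _["tau2_sm"] = tau2_sm, _["tau2_str"] = tau2_str,
      _["tau2_uns"] = tau2_uns);
  List fstate(nsm);
  for (int j = 0; j < nsm; ++j) fstate[j] = f[j];
  state["f"] = fstate;

  return List::create(
      _["alpha"] = alpha_out, _["f"] = f_list,
      _["fstr"] = fstr_out, _["funs"] = funs_out,
      _["tau2_sm"] = tau2_out, _["tau2_str"] = tau2str_out,
      _["tau2_uns"] = tau2uns_out, _["deviance"] = dev_out,
      _["eta_mean"] = eta_mean, _["state"] = state);
}
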