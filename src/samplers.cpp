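#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Metropolis-within-Gibbs samplers for spatial Poisson disease-mapping
// models:  O_i ~ Poisson(E_i * theta_i),  log theta_i = eta_i.
//   bym:    eta = alpha + u + v,  u ~ ICAR(tau_u), v ~ N(0, 1/tau_v)
//   icar:   eta = alpha + u
//   iid:    eta = alpha + v
//   leroux: eta = alpha + phi,  phi ~ N(0, [tau((1-l)I + l Q)]^{-1})
// Precisions get conjugate gamma updates; fields, intercept and logit(l)
// get adaptive single-site random walks.  All randomness comes from R's
// RNG, so set.seed() in R makes runs bit-reproducible.

static inline double loglik_site(double O, double E, double eta) {
  return O * eta - E * std::exp(eta);
}

// adapt a random-walk sd toward 44% acceptance
static inline void adapt_sd(double &sd, int acc, int window) {
  double rate = (double)acc / window;
  sd *= std::exp(rate - 0.44);
  if (sd < 1e-4) sd = 1e-4;
  if (sd > 10.0) sd = 10.0;
}

struct Graph {
  int n;
  std::vector<std::vector<int>> nbr;
  std::vector<int> comp;     // 0-based component label
  int ncomp;
  std::vector<int> ei, ej;   // edge list i<j
  Graph(List nbr_, IntegerVector comp_) {
    n = nbr_.size();
    nbr.resize(n);
    comp.resize(n);
    ncomp = 0;
    for (int i = 0; i < n; ++i) {
      IntegerVector v = nbr_[i];
      nbr[i].assign(v.begin(), v.end());
      comp[i] = comp_[i];
      if (comp[i] + 1 > ncomp) ncomp = comp[i] + 1;
      for (int j : nbr[i]) if (i < j) { ei.push_back(i); ej.push_back(j); }
    }
  }
  // subtract the component mean from x (sum-to-zero constraint)
  void center(std::vector<double> &x) const {
    std::vector<double> s(ncomp, 0.0);
    std::vector<int> c(ncomp, 0);
    for (int i = 0; i < n; ++i) { s[comp[i]] += x[i]; c[comp[i]]++; }
    for (int i = 0; i < n; ++i) x[i] -= s[comp[i]] / c[comp[i]];
  }
  double edge_quad(const std::vector<double> &x) const {  // x' Q x
    double q = 0.0;
    for (size_t k = 0; k < ei.size(); ++k) {
      double d = x[ei[k]] - x[ej[k]];
      q += d * d;
    }
    return q;
  }
};

// [[Rcpp::export]]
List car_mcmc_cpp(NumericVector O, NumericVector E, IntegerVector in_lik,
                  List nbr, IntegerVector comp, std::string model,
                  double a_tau, double b_tau, double alpha_var,
                  int n_iter, int n_burn, int thin,
                  double fix_lambda, NumericVector eigQ, List inits) {
  Graph g(nbr, comp);
  const int n = g.n;
  const bool has_u = (model == "bym" || model == "icar");
  const bool has_v = (model == "bym" || model == "iid");
  const bool is_ler = (model == "leroux");
  const bool lam_fixed = !ISNA(fix_lambda);

  double alpha = as<double>(inits["alpha"]);
  std::vector<double> u = as<std::vector<double>>(inits["u"]);
  std::vector<double> v = as<std::vector<double>>(inits["v"]);
  double tau_u = as<double>(inits["tau_u"]);
  double tau_v = as<double>(inits["tau_v"]);
  double lambda = lam_fixed ? fix_lambda : as<double>(inits["lambda"]);

  std::vector<double> sd_u(n, 0.3), sd_v(n, 0.3);
  double sd_alpha = 0.05, sd_lam = 0.5;
  std::vector<int> acc_u(n, 0), acc_v(n, 0);
  int acc_alpha = 0, acc_lam = 0;
  const int window = 50;

  int nkeep = (n_iter - n_burn) / thin;
  NumericMatrix theta_draws(n, nkeep);
  NumericVector alpha_draws(nkeep), tau_u_draws(nkeep), tau_v_draws(nkeep),
                lambda_draws(nkeep);
  int kept = 0;

  // eta_i = alpha + (u_i if structured) + (v_i if unstructured); for leroux
  // the single field lives in u and tau_u
  auto eta_at = [&](int i) {
    double e = alpha;
    if (has_u || is_ler) e += u[i];
    if (has_v) e += v[i];
    return e;
  };

  for (int iter = 0; iter < n_iter; ++iter) {
    bool burn = iter < n_burn;

    // -- structured / leroux field --------------------------------------
    if (has_u || is_ler) {
      for (int i = 0; i < n; ++i) {
        int d = g.nbr[i].size();
        if (!is_ler && d == 0) continue;     // island: pure unstructured
        double S = 0.0;
        for (int j : g.nbr[i]) S += u[j];
        double cur = u[i], prop = cur + sd_u[i] * R::norm_rand();
        double dprior;
        if (is_ler) {
          double c = (1.0 - lambda) + lambda * d;
          dprior = -0.5 * tau_u * (c * (prop * prop - cur * cur)
                                   - 2.0 * lambda * S * (prop - cur));
        } else {
          dprior = -0.5 * tau_u * ((double)d * (prop * prop - cur * cur)
                                   - 2.0 * S * (prop - cur));
        }
        double dlik = 0.0;
        if (in_lik[i]) {
          double base = eta_at(i) - cur;
          dlik = loglik_site(O[i], E[i], base + prop)
               - loglik_site(O[i], E[i], base + cur);
        }
        if (std::log(R::unif_rand()) < dprior + dlik) {
          u[i] = prop;
          acc_u[i]++;
        }
      }
      // sum-to-zero constraint (intrinsic prior); leroux only needs it in
      // the improper lambda = 1 limit
      if (has_u || (is_ler && lam_fixed && fix_lambda == 1.0)) g.center(u);
    }

    // -- unstructured field ---------------------------------------------
    if (has_v) {
      for (int i = 0; i < n; ++i) {
        double cur = v[i], prop = cur + sd_v[i] * R::norm_rand();
        double dprior = -0.5 * tau_v * (prop * prop - cur * cur);
        double dlik = 0.0;
        if (in_lik[i]) {
          double base = eta_at(i) - cur;
          dlik = loglik_site(O[i], E[i], base + prop)
               - loglik_site(O[i], E[i], base + cur);
        }
        if (std::log(R::unif_rand()) < dprior + dlik) {
          v[i] = prop;
          acc_v[i]++;
        }
      }
    }

    // -- intercept -------------------------------------------------------
    {
      double prop = alpha + sd_alpha * R::norm_rand();
      double dlik = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!in_lik[i]) continue;
        double base = eta_at(i) - alpha;
        dlik += loglik_site(O[i], E[i], base + prop)
              - loglik_site(O[i], E[i], base + alpha);
      }
      double dprior = -0.5 * (prop * prop - alpha * alpha) / alpha_var;
      if (std::log(R::unif_rand()) < dlik + dprior) { alpha = prop; acc_alpha++; }
    }

    // -- precisions (conjugate gamma) -------------------------------------
    if (has_u) {
      double quad = g.edge_quad(u);
      double shape = a_tau + 0.5 * (n - g.ncomp);
      tau_u = R::rgamma(shape, 1.0 / (b_tau + 0.5 * quad));
    }
    if (is_ler) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += u[i] * u[i];
      double quad = (1.0 - lambda) * ss + lambda * g.edge_quad(u);
      double rank = (lam_fixed && fix_lambda == 1.0) ? (n - g.ncomp) : n;
      tau_u = R::rgamma(a_tau + 0.5 * rank, 1.0 / (b_tau + 0.5 * quad));
    }
    if (has_v) {
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += v[i] * v[i];
      tau_v = R::rgamma(a_tau + 0.5 * n, 1.0 / (b_tau + 0.5 * ss));
    }

    // -- leroux mixing parameter (logit random walk, uniform prior) -------
    if (is_ler && !lam_fixed) {
      double l = std::log(lambda / (1.0 - lambda));
      double lp = l + sd_lam * R::norm_rand();
      double lam_p = 1.0 / (1.0 + std::exp(-lp));
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += u[i] * u[i];
      double eq = g.edge_quad(u);
      auto logpost = [&](double lm) {
        double det = 0.0;
        for (int k = 0; k < n; ++k)
          det += std::log((1.0 - lm) + lm * eigQ[k]);
        double quad = (1.0 - lm) * ss + lm * eq;
        return 0.5 * det - 0.5 * tau_u * quad
               + std::log(lm) + std::log(1.0 - lm);  // logit Jacobian
      };
      if (std::log(R::unif_rand()) < logpost(lam_p) - logpost(lambda)) {
        lambda = lam_p;
        acc_lam++;
      }
    }

    // -- adaptation during burn-in ----------------------------------------
    if (burn && (iter + 1) % window == 0) {
      for (int i = 0; i < n; ++i) {
        if (has_u || is_ler) { adapt_sd(sd_u[i], acc_u[i], window); acc_u[i] = 0; }
        if (has_v) { adapt_sd(sd_v[i], acc_v[i], window); acc_v[i] = 0; }
      }
      adapt_sd(sd_alpha, acc_alpha, window); acc_alpha = 0;
      if (is_ler && !lam_fixed) { adapt_sd(sd_lam, acc_lam, window); acc_lam = 0; }
    }

    // -- storage -----------------------------------------------------------
    if (!burn && (iter - n_burn) % thin == 0 && kept < nkeep) {
      for (int i = 0; i < n; ++i) theta_draws(i, kept) = std::exp(eta_at(i));
      alpha_draws[kept] = alpha;
      tau_u_draws[kept] = tau_u;
      tau_v_draws[kept] = tau_v;
      lambda_draws[kept] = lambda;
      kept++;
    }
  }

  return List::create(_["theta"] = theta_draws, _["alpha"] = alpha_draws,
                      _["tau_u"] = tau_u_draws, _["tau_v"] = tau_v_draws,
                      _["lambda"] = lambda_draws);
}

// Shared-component joint model for two sexes:
//   log theta_m = alpha_m + kappa   * delta + v_m
//   log theta_f = alpha_f + (1/kappa) * delta + v_f
// delta ~ ICAR(tau_d); v_s ~ N(0, 1/tau_vs); log kappa ~ N(0, sdlog^2).

// [[Rcpp::export]]
List shared_mcmc_cpp(NumericVector Om, NumericVector Em,
                     NumericVector Of, NumericVector Ef,
                     IntegerVector in_m, IntegerVector in_f,
                     List nbr, IntegerVector comp,
                     double a_tau, double b_tau, double alpha_var,
                     double sdlog_kappa,
                     int n_iter, int n_burn, int thin,
                     double fix_kappa, bool unstructured, List inits) {
  Graph g(nbr, comp);
  const int n = g.n;
  const bool kap_fixed = !ISNA(fix_kappa);

  double am = as<double>(inits["alpha_m"]), af = as<double>(inits["alpha_f"]);
  std::vector<double> del = as<std::vector<double>>(inits["delta"]);
  std::vector<double> vm = as<std::vector<double>>(inits["v_m"]);
  std::vector<double> vf = as<std::vector<double>>(inits["v_f"]);
  double tau_d = as<double>(inits["tau_d"]);
  double tau_vm = as<double>(inits["tau_vm"]), tau_vf = as<double>(inits["tau_vf"]);
  double kappa = kap_fixed ? fix_kappa : as<double>(inits["kappa"]);

  std::vector<double> sd_d(n, 0.3), sd_vm(n, 0.3), sd_vf(n, 0.3);
  double sd_am = 0.05, sd_af = 0.05, sd_k = 0.1, sd_sc = 0.1, sd_kc = 0.1;
  std::vector<int> ad(n, 0), avm(n, 0), avf(n, 0);
  int aam = 0, aaf = 0, ak = 0, asc = 0, akc = 0;
  const int window = 50;

  auto eta_m = [&](int i) { return am + kappa * del[i] + (unstructured ? vm[i] : 0.0); };
  auto eta_f = [&](int i) { return af + del[i] / kappa + (unstructured ? vf[i] : 0.0); };

  int nkeep = (n_iter - n_burn) / thin;
  NumericMatrix th_m(n, nkeep), th_f(n, nkeep), del_draws(n, nkeep);
  NumericVector k_draws(nkeep), taud_draws(nkeep), tauvm_draws(nkeep),
                tauvf_draws(nkeep), am_draws(nkeep), af_draws(nkeep);
  int kept = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    bool burn = iter < n_burn;

    // shared spatial field
    for (int i = 0; i < n; ++i) {
      int d = g.nbr[i].size();
      if (d == 0) continue;
      double S = 0.0;
      for (int j : g.nbr[i]) S += del[j];
      double cur = del[i], prop = cur + sd_d[i] * R::norm_rand();
      double dprior = -0.5 * tau_d * ((double)d * (prop * prop - cur * cur)
                                      - 2.0 * S * (prop - cur));
      double dlik = 0.0;
      if (in_m[i]) {
        double base = eta_m(i) - kappa * cur;
        dlik += loglik_site(Om[i], Em[i], base + kappa * prop)
              - loglik_site(Om[i], Em[i], base + kappa * cur);
      }
      if (in_f[i]) {
        double base = eta_f(i) - cur / kappa;
        dlik += loglik_site(Of[i], Ef[i], base + prop / kappa)
              - loglik_site(Of[i], Ef[i], base + cur / kappa);
      }
      if (std::log(R::unif_rand()) < dprior + dlik) { del[i] = prop; ad[i]++; }
    }
    g.center(del);

    // sex-specific unstructured fields
    if (unstructured) {
      for (int i = 0; i < n; ++i) {
        double cur = vm[i], prop = cur + sd_vm[i] * R::norm_rand();
        double dpr = -0.5 * tau_vm * (prop * prop - cur * cur);
        double dlik = 0.0;
        if (in_m[i]) {
          double base = eta_m(i) - cur;
          dlik = loglik_site(Om[i], Em[i], base + prop)
               - loglik_site(Om[i], Em[i], base + cur);
        }
        if (std::log(R::unif_rand()) < dpr + dlik) { vm[i] = prop; avm[i]++; }
      }
      for (int i = 0; i < n; ++i) {
        double cur = vf[i], prop = cur + sd_vf[i] * R::norm_rand();
        double dpr = -0.5 * tau_vf * (prop * prop - cur * cur);
        double dlik = 0.0;
        if (in_f[i]) {
          double base = eta_f(i) - cur;
          dlik = loglik_site(Of[i], Ef[i], base + prop)
               - loglik_site(Of[i], Ef[i], base + cur);
        }
        if (std::log(R::unif_rand()) < dpr + dlik) { vf[i] = prop; avf[i]++; }
      }
    }

    // intercepts
    {
      double prop = am + sd_am * R::norm_rand();
      double dlik = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!in_m[i]) continue;
        double base = eta_m(i) - am;
        dlik += loglik_site(Om[i], Em[i], base + prop)
              - loglik_site(Om[i], Em[i], base + am);
      }
      dlik += -0.5 * (prop * prop - am * am) / alpha_var;
      if (std::log(R::unif_rand()) < dlik) { am = prop; aam++; }
    }
    {
      double prop = af + sd_af * R::norm_rand();
      double dlik = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!in_f[i]) continue;
        double base = eta_f(i) - af;
        dlik += loglik_site(Of[i], Ef[i], base + prop)
              - loglik_site(Of[i], Ef[i], base + af);
      }
      dlik += -0.5 * (prop * prop - af * af) / alpha_var;
      if (std::log(R::unif_rand()) < dlik) { af = prop; aaf++; }
    }

    // precisions
    {
      double quad = g.edge_quad(del);
      tau_d = R::rgamma(a_tau + 0.5 * (n - g.ncomp), 1.0 / (b_tau + 0.5 * quad));
    }
    if (unstructured) {
      double sm = 0.0, sf = 0.0;
      for (int i = 0; i < n; ++i) { sm += vm[i] * vm[i]; sf += vf[i] * vf[i]; }
      tau_vm = R::rgamma(a_tau + 0.5 * n, 1.0 / (b_tau + 0.5 * sm));
      tau_vf = R::rgamma(a_tau + 0.5 * n, 1.0 / (b_tau + 0.5 * sf));
    }

    // joint field-scale move: delta -> c * delta (the overall spatial
    // amplitude mixes slowly under single-site updates alone)
    {
      double lc = sd_sc * R::norm_rand();
      double c = std::exp(lc);
      double quad = g.edge_quad(del);
      double dpost = -0.5 * tau_d * (c * c - 1.0) * quad
                     + (n - g.ncomp) * lc;          // scaling Jacobian
      for (int i = 0; i < n; ++i) {
        if (in_m[i]) {
          double base = am + (unstructured ? vm[i] : 0.0);
          dpost += loglik_site(Om[i], Em[i], base + kappa * c * del[i])
                 - loglik_site(Om[i], Em[i], base + kappa * del[i]);
        }
        if (in_f[i]) {
          double base = af + (unstructured ? vf[i] : 0.0);
          dpost += loglik_site(Of[i], Ef[i], base + c * del[i] / kappa)
                 - loglik_site(Of[i], Ef[i], base + del[i] / kappa);
        }
      }
      if (std::log(R::unif_rand()) < dpost) {
        for (int i = 0; i < n; ++i) del[i] *= c;
        asc++;
      }
    }

    // kappa-compensating move: kappa -> c*kappa, delta -> delta/c leaves the
    // male predictor unchanged and rescales only the female spatial loading
    if (!kap_fixed) {
      double lc = sd_kc * R::norm_rand();
      double c = std::exp(lc);
      double quad = g.edge_quad(del);
      double lk = std::log(kappa);
      double dpost = -0.5 * tau_d * (1.0 / (c * c) - 1.0) * quad
                     - (n - g.ncomp) * lc
                     - 0.5 * ((lk + lc) * (lk + lc) - lk * lk) /
                       (sdlog_kappa * sdlog_kappa);
      for (int i = 0; i < n; ++i) {
        if (!in_f[i]) continue;
        double base = af + (unstructured ? vf[i] : 0.0);
        dpost += loglik_site(Of[i], Ef[i], base + del[i] / (c * c * kappa))
               - loglik_site(Of[i], Ef[i], base + del[i] / kappa);
      }
      if (std::log(R::unif_rand()) < dpost) {
        kappa *= c;
        for (int i = 0; i < n; ++i) del[i] /= c;
        akc++;
      }
    }

    // sharing parameter (random walk on log kappa)
    if (!kap_fixed) {
      double lk = std::log(kappa);
      double lkp = lk + sd_k * R::norm_rand();
      double kp = std::exp(lkp);
      double dpost = 0.0;
      for (int i = 0; i < n; ++i) {
        if (in_m[i]) {
          double base = am + (unstructured ? vm[i] : 0.0);
          dpost += loglik_site(Om[i], Em[i], base + kp * del[i])
                 - loglik_site(Om[i], Em[i], base + kappa * del[i]);
        }
        if (in_f[i]) {
          double base = af + (unstructured ? vf[i] : 0.0);
          dpost += loglik_site(Of[i], Ef[i], base + del[i] / kp)
                 - loglik_site(Of[i], Ef[i], base + del[i] / kappa);
        }
      }
      dpost += -0.5 * (lkp * lkp - lk * lk) / (sdlog_kappa * sdlog_kappa);
      if (std::log(R::unif_rand()) < dpost) { kappa = kp; ak++; }
    }

    if (burn && (iter + 1) % window == 0) {
      for (int i = 0; i < n; ++i) {
        adapt_sd(sd_d[i], ad[i], window); ad[i] = 0;
        if (unstructured) {
          adapt_sd(sd_vm[i], avm[i], window); avm[i] = 0;
          adapt_sd(sd_vf[i], avf[i], window); avf[i] = 0;
        }
      }
      adapt_sd(sd_am, aam, window); aam = 0;
      adapt_sd(sd_af, aaf, window); aaf = 0;
      adapt_sd(sd_sc, asc, window); asc = 0;
      if (!kap_fixed) {
        adapt_sd(sd_k, ak, window); ak = 0;
        adapt_sd(sd_kc, akc, window); akc = 0;
      }
    }

    if (!burn && (iter - n_burn) % thin == 0 && kept < nkeep) {
      for (int i = 0; i < n; ++i) {
        th_m(i, kept) = std::exp(eta_m(i));
        th_f(i, kept) = std::exp(eta_f(i));
        del_draws(i, kept) = del[i];
      }
      k_draws[kept] = kappa;
      taud_draws[kept] = tau_d;
      tauvm_draws[kept] = tau_vm;
      tauvf_draws[kept] = tau_vf;
      am_draws[kept] = am;
      af_draws[kept] = af;
      kept++;
    }
  }

  return List::create(_["theta_m"] = th_m, _["theta_f"] = th_f,
                      _["delta"] = del_draws, _["kappa"] = k_draws,
                      _["tau_d"] = taud_draws, _["tau_vm"] = tauvm_draws,
                      _["tau_vf"] = tauvf_draws,
                      _["alpha_m"] = am_draws, _["alpha_f"] = af_draws);
}
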