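// Marginalized likelihood and adaptive Metropolis-within-Gibbs sampler.
//
// The latent occupancy (Z), availability (A) and group size (N) states
// are summed out of the likelihood per site-year (N up to Nmax), so the
// sampler moves only over the global parameters and the site random
// effects.  Conditional deviance is monitored by imputing (A, N) from
// their exact conditional distribution at each saved draw.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NPAR = 16;
enum ParIdx { IC = 0, ICSET2, IG1, IG2, IG3, IALPHA, IB1, IB2, IB3, IB4,
              IB5, IB6, IB7, ISIG, IP, ID };

struct ModelData {
  int S;                       // study sites
  std::vector<int> set;        // 1, 2, 3
  std::vector<int> work;
  std::vector<double> dist_s, tree1_s, tree2_s;
  std::vector<int> y1, y2, y3; // -1 = missing
  IntegerMatrix ydet;          // detection panel, 0 rows if absent
  int Nmax;
  bool include_b5, set2_linear, random_effect;
};

// sum_{N=max(1,y)}^{Nmax} ZTPois(N; lambda) * Binom(y; N, d)
static double q_sum(int y, double lambda, double d, int Nmax) {
  if (!(lambda > 0.0) || lambda > 1e8 || !std::isfinite(lambda)) return 0.0;
  int N0 = std::max(1, y);
  if (N0 > Nmax) return 0.0;
  double pois = std::exp(-lambda + N0 * std::log(lambda) -
                         R::lgammafn((double)N0 + 1.0));
  double bin = (y == 0) ? std::pow(1.0 - d, (double)N0)
                        : std::pow(d, (double)y);
  double acc = 0.0;
  const double omd = 1.0 - d;
  for (int N = N0;;) {
    acc += pois * bin;
    ++N;
    if (N > Nmax) break;
    pois *= lambda / N;
    if (y == 0) bin *= omd;
    else bin *= (double)N * omd / (double)(N - y);
  }
  return acc / (-std::expm1(-lambda));
}

static inline double safe_log(double x) {
  return (x > 0.0) ? std::log(x) : R_NegInf;
}

static double site_loglik(const ModelData& D, const double* th, double eps,
                          int i) {
  const double d = th[ID], p = th[IP];
  const double b5 = D.include_b5 ? th[IB5] : 0.0;
  double ll = 0.0;
  const int w = D.work[i];
  if (D.set[i] == 3) {
    double lam2 = std::exp(th[IALPHA] + th[IB3] + (th[IB4] + b5) * w + eps);
    if (D.y2[i] >= 0) ll += safe_log(q_sum(D.y2[i], lam2, d, D.Nmax));
    if (D.y3[i] >= 0) {
      double lam3 = lam2 * std::exp(th[IB6] * w + th[IB7]);
      ll += safe_log(q_sum(D.y3[i], lam3, d, D.Nmax));
    }
    return ll;
  }
  const double dist = D.dist_s[i], t1 = D.tree1_s[i], t2 = D.tree2_s[i];
  if (D.set[i] == 1 && D.y1[i] >= 0) {
    double lam1 = std::exp(th[IALPHA] + th[IB1] * dist + th[IB2] * t1 +
                           b5 * w + eps);
    ll += safe_log(q_sum(D.y1[i], lam1, d, D.Nmax));
  }
  if (D.y2[i] >= 0) {
    double eta;
    if (D.set[i] == 1) {
      eta = th[IC] + th[IG1] * dist + th[IG2] * t2 + th[IG3] * w;
    } else if (D.set2_linear) {
      eta = th[ICSET2] + th[IG1] * dist + th[IG2] * t2 + th[IG3] * w;
    } else {
      eta = th[ICSET2];
    }
    double psi = 1.0 / (1.0 + std::exp(-eta));
    double lam2 = std::exp(th[IALPHA] + th[IB1] * dist + th[IB2] * t2 +
                           th[IB3] + (th[IB4] + b5) * w + eps);
    double q = q_sum(D.y2[i], lam2, d, D.Nmax);
    double zero = (D.y2[i] == 0) ? 1.0 : 0.0;
    double m = psi * ((1.0 - p) * zero + p * q) + (1.0 - psi) * zero;
    ll += safe_log(m);
  }
  return ll;
}

// Detection-calibration panel: one N per site shared by all visits,
// availability independent per visit.
static double det_loglik(const ModelData& D, const double* th) {
  const int S = D.ydet.nrow();
  if (S == 0) return 0.0;
  const int J = D.ydet.ncol();
  const double p = th[IP], d = th[ID];
  double lam = std::exp(th[IALPHA] + th[IB3]);
  if (!(lam > 0.0) || lam > 1e8) return R_NegInf;
  const double omd = 1.0 - d;
  const double norm = -std::expm1(-lam);
  double ll = 0.0;
  std::vector<double> b(J);
  std::vector<int> yv(J);
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < J; ++j) { yv[j] = D.ydet(s, j); b[j] = 0.0; }
    double acc = 0.0;
    double pois = std::exp(-lam) * lam;  // N = 1
    for (int N = 1; N <= D.Nmax; ++N) {
      if (N > 1) pois *= lam / N;
      double prod = 1.0;
      for (int j = 0; j < J; ++j) {
        const int y = yv[j];
        if (y == 0) {
          b[j] = (N == 1) ? omd : b[j] * omd;
        } else if (N < y) {
          b[j] = 0.0;
        } else if (N == y) {
          b[j] = std::pow(d, (double)y);
        } else {
          b[j] *= (double)N * omd / (double)(N - y);
        }
        prod *= (1.0 - p) * (y == 0 ? 1.0 : 0.0) + p * b[j];
      }
      acc += (pois / norm) * prod;
    }
    ll += safe_log(acc);
  }
  return ll;
}

static double prior_logdens(int k, double x, const NumericMatrix& pr) {
  const int type = (int)pr(k, 0);
  const double a = pr(k, 1), b = pr(k, 2);
  if (type == 0) return R::dnorm(x, a, b, 1);
  if (type == 1) return R::dcauchy(x, a, b, 1);
  return (x >= a && x <= b) ? -std::log(b - a) : R_NegInf;  // uniform
}

// Sample N from p(N | y, available) over max(1,y)..Nmax
static int sample_N(int y, double lambda, double d, int Nmax) {
  int N0 = std::max(1, y);
  if (N0 > Nmax || !(lambda > 0.0) || lambda > 1e8) return N0;
  std::vector<double> wgt(Nmax - N0 + 1);
  double pois = std::exp(-lambda + N0 * std::log(lambda) -
                         R::lgammafn((double)N0 + 1.0));
  double bin = (y == 0) ? std::pow(1.0 - d, (double)N0)
                        : std::pow(d, (double)y);
  const double omd = 1.0 - d;
  double tot = 0.0;
  for (int N = N0;;) {
    wgt[N - N0] = pois * bin;
    tot += wgt[N - N0];
    ++N;
    if (N > Nmax) break;
    pois *= lambda / N;
    if (y == 0) bin *= omd;
    else bin *= (double)N * omd / (double)(N - y);
  }
  if (!(tot > 0.0)) return N0;
  double u = unif_rand() * tot;
  for (int N = N0; N <= Nmax; ++N) {
    u -= wgt[N - N0];
    if (u <= 0.0) return N;
  }
  return Nmax;
}

// Conditional deviance: -2 sum log Binom(y; N, d*A) with (Z, A, N)
// imputed from their exact conditionals given y and the parameters.
static double deviance_draw(const ModelData& D, const double* th,
                            const std::vector<double>& eps) {
  const double d = th[ID], p = th[IP];
  const double b5 = D.include_b5 ? th[IB5] : 0.0;
  double dev = 0.0;

  // constrained (available by design) year: A = 1, impute N
  auto dev_avail = [&](int y, double lam) {
    int N = sample_N(y, lam, d, D.Nmax);
    dev += -2.0 * R::dbinom((double)y, (double)N, d, 1);
  };

  for (int i = 0; i < D.S; ++i) {
    const int w = D.work[i];
    if (D.set[i] == 3) {
      double lam2 = std::exp(th[IALPHA] + th[IB3] + (th[IB4] + b5) * w +
                             eps[i]);
      if (D.y2[i] >= 0) dev_avail(D.y2[i], lam2);
      if (D.y3[i] >= 0) {
        dev_avail(D.y3[i], lam2 * std::exp(th[IB6] * w + th[IB7]));
      }
      continue;
    }
    const double dist = D.dist_s[i], t1 = D.tree1_s[i], t2 = D.tree2_s[i];
    if (D.set[i] == 1 && D.y1[i] >= 0) {
      dev_avail(D.y1[i], std::exp(th[IALPHA] + th[IB1] * dist +
                                  th[IB2] * t1 + b5 * w + eps[i]));
    }
    if (D.y2[i] >= 0) {
      double eta;
      if (D.set[i] == 1) {
        eta = th[IC] + th[IG1] * dist + th[IG2] * t2 + th[IG3] * w;
      } else if (D.set2_linear) {
        eta = th[ICSET2] + th[IG1] * dist + th[IG2] * t2 + th[IG3] * w;
      } else {
        eta = th[ICSET2];
      }
      double psi = 1.0 / (1.0 + std::exp(-eta));
      double lam2 = std::exp(th[IALPHA] + th[IB1] * dist + th[IB2] * t2 +
                             th[IB3] + (th[IB4] + b5) * w + eps[i]);
      const int y = D.y2[i];
      if (y > 0) {
        dev_avail(y, lam2);  // Z = A = 1 given a positive count
      } else {
        // P(A=1 | y=0) among {Z=0}, {Z=1,A=0}, {Z=1,A=1}
        double q0 = q_sum(0, lam2, d, D.Nmax);
        double w_avail = psi * p * q0;
        double w_rest = (1.0 - psi) + psi * (1.0 - p);
        if (unif_rand() * (w_avail + w_rest) < w_avail) {
          int N = sample_N(0, lam2, d, D.Nmax);
          dev += -2.0 * (double)N * std::log(1.0 - d);
        }
        // unavailable: point mass at zero, contributes log 1
      }
    }
  }

  // detection panel: impute shared N, then per-visit availability
  const int Sdet = D.ydet.nrow();
  if (Sdet > 0) {
    const int J = D.ydet.ncol();
    double lam = std::exp(th[IALPHA] + th[IB3]);
    const double norm = -std::expm1(-lam);
    const double omd = 1.0 - d;
    std::vector<double> wgt(D.Nmax);
    std::vector<double> b(J);
    std::vector<int> yv(J);
    for (int s = 0; s < Sdet; ++s) {
      int ymax = 0;
      for (int j = 0; j < J; ++j) {
        yv[j] = D.ydet(s, j);
        if (yv[j] > ymax) ymax = yv[j];
        b[j] = 0.0;
      }
      double pois = std::exp(-lam) * lam;
      double tot = 0.0;
      for (int N = 1; N <= D.Nmax; ++N) {
        if (N > 1) pois *= lam / N;
        double prod = 1.0;
        for (int j = 0; j < J; ++j) {
          const int y = yv[j];
          if (y == 0) b[j] = (N == 1) ? omd : b[j] * omd;
          else if (N < y) b[j] = 0.0;
          else if (N == y) b[j] = std::pow(d, (double)y);
          else b[j] *= (double)N * omd / (double)(N - y);
          prod *= (1.0 - p) * (y == 0 ? 1.0 : 0.0) + p * b[j];
        }
        wgt[N - 1] = (pois / norm) * prod;
        tot += wgt[N - 1];
      }
      int Ns = std::max(1, ymax);
      if (tot > 0.0) {
        double u = unif_rand() * tot;
        for (int N = 1; N <= D.Nmax; ++N) {
          u -= wgt[N - 1];
          if (u <= 0.0) { Ns = N; break; }
        }
        if (Ns < ymax) Ns = ymax;
      }
      for (int j = 0; j < J; ++j) {
        const int y = yv[j];
        if (y > 0) {
          dev += -2.0 * R::dbinom((double)y, (double)Ns, d, 1);
        } else {
          double pa = p * std::pow(omd, (double)Ns);
          double w0 = (1.0 - p) + pa;
          if (unif_rand() * w0 < pa) {
            dev += -2.0 * (double)Ns * std::log(omd);
          }
        }
      }
    }
  }
  return dev;
}

// [[Rcpp::export]]
List cpp_fit_chain(List data, NumericMatrix priors, NumericVector init,
                   LogicalVector update, int n_burn, int n_save, int thin,
                   bool prior_only, bool save_eps, double init_eps_sd,
                   Nullable<NumericVector> eps_init = R_NilValue) {
  ModelData D;
  D.set = as<std::vector<int> >(data["set"]);
  D.S = (int)D.set.size();
  D.work = as<std::vector<int> >(data["work"]);
  D.dist_s = as<std::vector<double> >(data["dist_s"]);
  D.tree1_s = as<std::vector<double> >(data["tree1_s"]);
  D.tree2_s = as<std::vector<double> >(data["tree2_s"]);
  D.y1 = as<std::vector<int> >(data["y1"]);
  D.y2 = as<std::vector<int> >(data["y2"]);
  D.y3 = as<std::vector<int> >(data["y3"]);
  D.ydet = as<IntegerMatrix>(data["ydet"]);
  D.Nmax = as<int>(data["n_max"]);
  D.include_b5 = as<bool>(data["include_b5"]);
  D.set2_linear = as<bool>(data["set2_linear"]);
  D.random_effect = as<bool>(data["random_effect"]);

  double th[NPAR];
  for (int k = 0; k < NPAR; ++k) th[k] = init[k];
  std::vector<double> eps(D.S, 0.0);
  if (eps_init.isNotNull()) {
    NumericVector e(eps_init);
    if ((int)e.size() == D.S) {
      for (int i = 0; i < D.S; ++i) eps[i] = e[i];
    }
  } else if (D.random_effect && init_eps_sd > 0.0) {
    for (int i = 0; i < D.S; ++i) eps[i] = norm_rand() * init_eps_sd;
  }

  const bool use_lik = !prior_only;
  std::vector<double> sll(D.S, 0.0);
  double dll = 0.0;
  if (use_lik) {
    for (int i = 0; i < D.S; ++i) sll[i] = site_loglik(D, th, eps[i], i);
    dll = det_loglik(D, th);
  }

  // adaptive step sizes, tuned in batches of 50 during burn-in
  std::vector<double> step(NPAR, 0.1);
  step[ISIG] = 0.1; step[IP] = 0.05; step[ID] = 0.05;
  std::vector<double> eps_step(D.S, 0.3);
  std::vector<int> acc(NPAR, 0), try_(NPAR, 0);
  std::vector<int> eps_acc(D.S, 0), eps_try(D.S, 0);

  const int n_iter = n_burn + n_save * thin;
  const int n_out = NPAR + 1 + (save_eps ? D.S : 0);
  NumericMatrix out(n_save, n_out);
  int saved = 0;

  std::vector<double> prop_sll(D.S);

  for (int it = 0; it < n_iter; ++it) {
    // --- global parameters -------------------------------------------
    for (int k = 0; k < NPAR; ++k) {
      if (!update[k]) continue;
      const double cur = th[k];
      const double prop = cur + step[k] * norm_rand();
      ++try_[k];
      double lr = prior_logdens(k, prop, priors) -
                  prior_logdens(k, cur, priors);
      if (std::isfinite(lr)) {
        if (k == ISIG) {
          if (D.random_effect) {
            for (int i = 0; i < D.S; ++i) {
              lr += R::dnorm(eps[i], 0.0, prop, 1) -
                    R::dnorm(eps[i], 0.0, cur, 1);
            }
          }
        } else if (use_lik) {
          th[k] = prop;
          double dnew = 0.0;
          const bool det_dep = (k == IALPHA || k == IB3 || k == IP || k == ID);
          double dll_new = det_dep ? det_loglik(D, th) : dll;
          for (int i = 0; i < D.S; ++i) {
            prop_sll[i] = site_loglik(D, th, eps[i], i);
            dnew += prop_sll[i] - sll[i];
          }
          dnew += dll_new - dll;
          th[k] = cur;
          lr += dnew;
          if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
            th[k] = prop;
            for (int i = 0; i < D.S; ++i) sll[i] = prop_sll[i];
            dll = dll_new;
            ++acc[k];
          }
          continue;  // accept/reject already done
        }
      }
      if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
        th[k] = prop;
        ++acc[k];
      }
    }

    // --- site random effects -----------------------------------------
    if (D.random_effect && update[ISIG]) {
      const double sig = th[ISIG];
      for (int i = 0; i < D.S; ++i) {
        const double cur = eps[i];
        const double prop = cur + eps_step[i] * norm_rand();
        ++eps_try[i];
        double lr = R::dnorm(prop, 0.0, sig, 1) - R::dnorm(cur, 0.0, sig, 1);
        double sll_new = 0.0;
        if (use_lik) {
          sll_new = site_loglik(D, th, prop, i);
          lr += sll_new - sll[i];
        }
        if (std::isfinite(lr) && std::log(unif_rand()) < lr) {
          eps[i] = prop;
          if (use_lik) sll[i] = sll_new;
          ++eps_acc[i];
        }
      }
    }

    // --- adaptation during burn-in -----------------------------------
    if (it < n_burn && (it + 1) % 50 == 0) {
      const double delta = std::min(0.25, 2.0 / std::sqrt((it + 1.0) / 50.0));
      for (int k = 0; k < NPAR; ++k) {
        if (try_[k] == 0) continue;
        const double rate = (double)acc[k] / try_[k];
        step[k] *= std::exp(delta * (rate - 0.44));
        acc[k] = 0; try_[k] = 0;
      }
      for (int i = 0; i < D.S; ++i) {
        if (eps_try[i] == 0) continue;
        const double rate = (double)eps_acc[i] / eps_try[i];
        eps_step[i] *= std::exp(delta * (rate - 0.44));
        eps_acc[i] = 0; eps_try[i] = 0;
      }
    }

    // --- save ---------------------------------------------------------
    if (it >= n_burn && (it - n_burn) % thin == 0 && saved < n_save) {
      for (int k = 0; k < NPAR; ++k) out(saved, k) = th[k];
      out(saved, NPAR) = use_lik ? deviance_draw(D, th, eps) : 0.0;
      if (save_eps) {
        for (int i = 0; i < D.S; ++i) out(saved, NPAR + 1 + i) = eps[i];
      }
      ++saved;
    }
  }

  NumericVector acc_rate(NPAR);
  for (int k = 0; k < NPAR; ++k) {
    acc_rate[k] = try_[k] > 0 ? (double)acc[k] / try_[k] : NA_REAL;
  }
  return List::create(_["draws"] = out, _["accept"] = acc_rate,
                      _["step"] = NumericVector(step.begin(), step.end()));
}

// Exposed for cross-checking the C++ likelihood against the pure-R
// enumeration oracle.
// [[Rcpp::export]]
double cpp_total_loglik(List data, NumericVector theta, NumericVector eps) {
  ModelData D;
  D.set = as<std::vector<int> >(data["set"]);
  D.S = (int)D.set.size();
  D.work = as<std::vector<int> >(data["work"]);
  D.dist_s = as<std::vector<double> >(data["dist_s"]);
  D.tree1_s = as<std::vector<double> >(data["tree1_s"]);
  D.tree2_s = as<std::vector<double> >(data["tree2_s"]);
  D.y1 = as<std::vector<int> >(data["y1"]);
  D.y2 = as<std::vector<int> >(data["y2"]);
  D.y3 = as<std::vector<int> >(data["y3"]);
  D.ydet = as<IntegerMatrix>(data["ydet"]);
  D.Nmax = as<int>(data["n_max"]);
  D.include_b5 = as<bool>(data["include_b5"]);
  D.set2_linear = as<bool>(data["set2_linear"]);
  D.random_effect = as<bool>(data["random_effect"]);
  double th[NPAR];
  for (int k = 0; k < NPAR; ++k) th[k] = theta[k];
  double ll = 0.0;
  for (int i = 0; i < D.S; ++i) ll += site_loglik(D, th, eps[i], i);
  ll += det_loglik(D, th);
  return ll;
}
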