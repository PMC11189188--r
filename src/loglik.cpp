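#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// lookup tables for log(n) and lgamma(n + 1), n = 0..TAB_N-1
#define TAB_N 1100
static std::vector<double> lognat_tab, lgam_tab;
static void ensure_tables() {
  if (!lognat_tab.empty()) return;
  lognat_tab.resize(TAB_N);
  lgam_tab.resize(TAB_N);
  lognat_tab[0] = R_NegInf;
  lgam_tab[0] = 0.0;
  for (int i = 1; i < TAB_N; ++i) {
    lognat_tab[i] = std::log((double)i);
    lgam_tab[i] = lgam_tab[i - 1] + lognat_tab[i]; // lgamma(i + 1)
  }
}

// Marginal log-likelihood of one species x point x year cell.
//
// L = (1 - psi) * 1{all y = 0}
//   + psi * sum_{M = max(y)}^{K} Pois(M; lambda) prod_v Binom(y_v; M, phi_v)
//
// The latent inclusion indicator a and latent abundance M are summed out
// exactly.  The sum starts at max(y) and stops once terms are declining
// (past the mode) and relatively negligible (per-term contribution below
// tail * 1e-3 of the running sum, so the truncation error is a small
// multiple of that), capped at Kcap.  Kforce >= 0 forces a fixed upper
// limit instead.
//
// eta = log(lambda); lphi / l1mphi are per-visit log(phi), log(1 - phi);
// sl1m = sum of l1mphi; lpsi / l1mpsi are log(psi), log(1 - psi).
static double cell_ll(const int *y, int V, double eta, double lambda,
                      const double *lphi, const double *l1mphi, double sl1m,
                      double psi, double lpsi, double l1mpsi, double ltail,
                      int Kcap, int Kforce) {
  int maxy = 0;
  for (int v = 0; v < V; ++v)
    if (y[v] > maxy) maxy = y[v];

  // initial term at M = max(y)
  double lterm = maxy * eta - lambda - lgam_tab[maxy];
  for (int v = 0; v < V; ++v)
    lterm += lgam_tab[maxy] - lgam_tab[y[v]] - lgam_tab[maxy - y[v]] +
             y[v] * lphi[v] + (maxy - y[v]) * l1mphi[v];

  int Kstop = (Kforce >= 0) ? Kforce : Kcap;
  double lmax = lterm, Ssc = 1.0, lprev = lterm;
  int M = maxy;
  while (M < Kstop) {
    ++M;
    double lstep = eta + (V - 1) * lognat_tab[M] + sl1m;
    for (int v = 0; v < V; ++v) lstep -= lognat_tab[M - y[v]];
    lterm += lstep;
    if (lterm > lmax) {
      Ssc = Ssc * std::exp(lmax - lterm) + 1.0;
      lmax = lterm;
    } else {
      Ssc += std::exp(lterm - lmax);
    }
    if (Kforce < 0 && lterm < lprev &&
        (lterm - (lmax + std::log(Ssc))) < ltail)
      break;
    lprev = lterm;
  }
  double lS = lmax + std::log(Ssc); // log sum over M | a = 1

  if (psi >= 1.0) return lS;
  if (maxy == 0) {
    if (psi <= 0.0) return 0.0;
    double a = l1mpsi;
    double b = lpsi + lS;
    double m = (a > b) ? a : b;
    return m + std::log1p(std::exp(-std::fabs(a - b)));
  }
  if (psi <= 0.0) return R_NegInf;
  return lpsi + lS;
}

static inline double clamp01(double p) {
  if (p < 1e-12) return 1e-12;
  if (p > 1.0 - 1e-12) return 1.0 - 1e-12;
  return p;
}

// accuracy-path wrapper taking natural-scale lambda/phi/psi
static double cell_ll_raw(const int *y, int V, double lambda,
                          const double *phi, double psi, double tail,
                          int Kcap, int Kforce) {
  ensure_tables();
  std::vector<double> lphi(V), l1m(V);
  double sl1m = 0.0;
  for (int v = 0; v < V; ++v) {
    double p = clamp01(phi[v]);
    lphi[v] = std::log(p);
    l1m[v] = std::log1p(-p);
    sl1m += l1m[v];
  }
  double lpsi = (psi > 0) ? std::log(psi) : R_NegInf;
  double l1mpsi = (psi < 1) ? std::log1p(-psi) : R_NegInf;
  return cell_ll(y, V, std::log(lambda), lambda, &lphi[0], &l1m[0], sl1m, psi,
                 lpsi, l1mpsi, std::log(tail) - 6.9, Kcap, Kforce);
}

// [[Rcpp::export]]
double cpp_cell_loglik(IntegerVector y, double lambda, NumericVector phi,
                       double psi, double tail, int Kcap, int Kforce) {
  int V = y.size();
  if (phi.size() != V) stop("y and phi must have the same length");
  if (Kcap >= TAB_N - 1) stop("Kcap too large");
  return cell_ll_raw(&y[0], V, lambda, &phi[0], psi, tail, Kcap, Kforce);
}

// Yt, phi are V x n (one column per cell).
// [[Rcpp::export]]
NumericVector cpp_cells_loglik(IntegerMatrix Yt, NumericVector lambda,
                               NumericMatrix phi, double psi, double tail,
                               int Kcap) {
  int V = Yt.nrow(), n = Yt.ncol();
  if (phi.nrow() != V || phi.ncol() != n || lambda.size() != n)
    stop("dimension mismatch between counts, lambda and phi");
  if (Kcap >= TAB_N - 1) stop("Kcap too large");
  NumericVector out(n);
  for (int c = 0; c < n; ++c)
    out[c] = cell_ll_raw(&Yt(0, c), V, lambda[c], &phi(0, c), psi, tail,
                         Kcap, -1);
  return out;
}

// detection logs from the logit-scale predictor:
// log(1 - phi) = -log1p(exp(eta)), log(phi) = eta + log(1 - phi)
static inline void det_logs(double eta, double &lp, double &l1m) {
  if (eta > 0) {
    l1m = -eta - std::log1p(std::exp(-eta));
  } else {
    l1m = -std::log1p(std::exp(eta));
  }
  lp = eta + l1m;
}

// One full Metropolis-within-Gibbs sweep over species-level coefficients,
// zero-inflation probabilities (logit scale) and shared site effects.
// Community hyper-parameters are updated on the R side between sweeps.
//
// Yt: list of V x n integer matrices, one per species.
// Xab: n x p abundance design matrix; Xdet: (n*V) x q detection design
// matrix, visit-major (row c + v*n is cell c, visit v).  site: 0-based
// site index per cell.
// [[Rcpp::export]]
List cpp_mcmc_sweep(List Yt, NumericMatrix Xab, NumericMatrix Xdet,
                    IntegerVector site, int n_site, NumericMatrix beta_in,
                    NumericMatrix alpha_in, NumericVector lpsi_in,
                    NumericVector gamma_in, NumericVector mu_b,
                    NumericVector sd_b, NumericVector mu_a, NumericVector sd_a,
                    double sigma_site, NumericMatrix prop_b,
                    NumericMatrix prop_a, NumericVector prop_p,
                    NumericVector prop_g, NumericMatrix Lb, NumericMatrix La,
                    NumericVector prop_blkb, NumericVector prop_blka,
                    double tail, int Kcap) {
  ensure_tables();
  const int n = Xab.nrow(), p = Xab.ncol(), q = Xdet.ncol();
  const int S = Yt.size();
  const int V = (n > 0) ? Xdet.nrow() / n : 1;
  const int T = n_site;
  const double ltail = std::log(tail) - 6.9;
  if (Kcap >= TAB_N - 1) stop("Kcap too large");

  NumericMatrix beta = clone(beta_in), alpha = clone(alpha_in);
  NumericVector lpsi = clone(lpsi_in), gamma = clone(gamma_in);
  IntegerMatrix accB(p, S), accA(q, S);
  IntegerVector accP(S), accG(T), accBlkB(S), accBlkA(S);

  NumericMatrix EtaAb(n, S), cellLL(n, S);
  // per-species detection log tables, V x n layout
  std::vector<NumericMatrix> LPhi(S), L1m(S);
  NumericMatrix Sl1m(n, S);
  for (int s = 0; s < S; ++s) {
    LPhi[s] = NumericMatrix(V, n);
    L1m[s] = NumericMatrix(V, n);
  }
  std::vector<double> newll(n), lp2(V), l1m2(V), etaDet(n * V);
  NumericVector psi_s(S), lpsi_log(S), l1mpsi_log(S);
  std::vector<double> eta2(n), dv(p > q ? p : q), sl1mN(n);
  NumericMatrix lphN(V, n), l1mN(V, n);

  std::vector<std::vector<int> > bysite(T);
  for (int c = 0; c < n; ++c) bysite[site[c]].push_back(c);

  for (int s = 0; s < S; ++s) {
    IntegerMatrix Ys = Yt[s];
    double *etaAb = &EtaAb(0, s);
    for (int c = 0; c < n; ++c) {
      double e = gamma[site[c]];
      for (int k = 0; k < p; ++k) e += Xab(c, k) * beta(k, s);
      etaAb[c] = e;
    }
    for (int r = 0; r < n * V; ++r) {
      double e = 0.0;
      for (int k = 0; k < q; ++k) e += Xdet(r, k) * alpha(k, s);
      etaDet[r] = e;
    }
    NumericMatrix &lph = LPhi[s], &l1m = L1m[s];
    for (int c = 0; c < n; ++c) {
      double ssum = 0.0;
      for (int v = 0; v < V; ++v) {
        det_logs(etaDet[c + v * n], lph(v, c), l1m(v, c));
        ssum += l1m(v, c);
      }
      Sl1m(c, s) = ssum;
    }
    double psi = 1.0 / (1.0 + std::exp(-lpsi[s]));
    double lps, l1ps;
    det_logs(lpsi[s], lps, l1ps);
    double cur = 0.0;
    for (int c = 0; c < n; ++c) {
      double ll = cell_ll(&Ys(0, c), V, etaAb[c], std::exp(etaAb[c]),
                          &lph(0, c), &l1m(0, c), Sl1m(c, s), psi, lps, l1ps,
                          ltail, Kcap, -1);
      cellLL(c, s) = ll;
      cur += ll;
    }

    // abundance coefficients
    for (int k = 0; k < p; ++k) {
      double d = prop_b(k, s) * norm_rand();
      double bnew = beta(k, s) + d;
      double nsum = 0.0;
      for (int c = 0; c < n; ++c) {
        double e = etaAb[c] + d * Xab(c, k);
        newll[c] = cell_ll(&Ys(0, c), V, e, std::exp(e), &lph(0, c),
                           &l1m(0, c), Sl1m(c, s), psi, lps, l1ps, ltail,
                           Kcap, -1);
        nsum += newll[c];
      }
      double lr = nsum - cur + R::dnorm(bnew, mu_b[k], sd_b[k], 1) -
                  R::dnorm(beta(k, s), mu_b[k], sd_b[k], 1);
      if (std::log(unif_rand()) < lr) {
        beta(k, s) = bnew;
        for (int c = 0; c < n; ++c) {
          etaAb[c] += d * Xab(c, k);
          cellLL(c, s) = newll[c];
        }
        cur = nsum;
        accB(k, s) = 1;
      }
    }

    // detection coefficients
    for (int k = 0; k < q; ++k) {
      double d = prop_a(k, s) * norm_rand();
      double anew = alpha(k, s) + d;
      double nsum = 0.0;
      for (int c = 0; c < n; ++c) {
        double ssum = 0.0;
        for (int v = 0; v < V; ++v) {
          int r = c + v * n;
          det_logs(etaDet[r] + d * Xdet(r, k), lp2[v], l1m2[v]);
          ssum += l1m2[v];
        }
        newll[c] = cell_ll(&Ys(0, c), V, etaAb[c], std::exp(etaAb[c]),
                           &lp2[0], &l1m2[0], ssum, psi, lps, l1ps, ltail,
                           Kcap, -1);
        nsum += newll[c];
      }
      double lr = nsum - cur + R::dnorm(anew, mu_a[k], sd_a[k], 1) -
                  R::dnorm(alpha(k, s), mu_a[k], sd_a[k], 1);
      if (std::log(unif_rand()) < lr) {
        alpha(k, s) = anew;
        for (int c = 0; c < n; ++c) {
          cellLL(c, s) = newll[c];
          double ssum = 0.0;
          for (int v = 0; v < V; ++v) {
            int r = c + v * n;
            etaDet[r] += d * Xdet(r, k);
            det_logs(etaDet[r], lph(v, c), l1m(v, c));
            ssum += l1m(v, c);
          }
          Sl1m(c, s) = ssum;
        }
        cur = nsum;
        accA(k, s) = 1;
      }
    }

    // zero-inflation probability (logit scale, Beta(1,1) prior on psi)
    {
      double lpn = lpsi[s] + prop_p[s] * norm_rand();
      double psin = 1.0 / (1.0 + std::exp(-lpn));
      double lpsn, l1psn;
      det_logs(lpn, lpsn, l1psn);
      double nsum = 0.0;
      for (int c = 0; c < n; ++c) {
        newll[c] = cell_ll(&Ys(0, c), V, etaAb[c], std::exp(etaAb[c]),
                           &lph(0, c), &l1m(0, c), Sl1m(c, s), psin, lpsn,
                           l1psn, ltail, Kcap, -1);
        nsum += newll[c];
      }
      // log prior on the logit scale: log psi + log(1 - psi)
      double lr = nsum - cur + (lpsn + l1psn) - (lps + l1ps);
      if (std::log(unif_rand()) < lr) {
        lpsi[s] = lpn;
        psi = psin;
        lps = lpsn;
        l1ps = l1psn;
        for (int c = 0; c < n; ++c) cellLL(c, s) = newll[c];
        cur = nsum;
        accP[s] = 1;
      }
    }
    // block update of the abundance coefficient vector with proposal
    // covariance ~ (X'X)^-1 (handles design collinearity, e.g. the
    // treatment flag vs the vegetation covariates it shifts)
    if (prop_blkb[s] > 0) {
      for (int k = 0; k < p; ++k) dv[k] = 0.0;
      for (int k = 0; k < p; ++k) {
        double z = norm_rand();
        for (int l = k; l < p; ++l) // Lb lower-triangular: dv += Lb[,k] * z
          dv[l] += Lb(l, k) * z;
      }
      double lpr = 0.0;
      for (int k = 0; k < p; ++k) {
        dv[k] *= prop_blkb[s];
        double bn = beta(k, s) + dv[k];
        lpr += R::dnorm(bn, mu_b[k], sd_b[k], 1) -
               R::dnorm(beta(k, s), mu_b[k], sd_b[k], 1);
      }
      double nsum = 0.0;
      for (int c = 0; c < n; ++c) {
        double e = etaAb[c];
        for (int k = 0; k < p; ++k) e += Xab(c, k) * dv[k];
        eta2[c] = e;
        newll[c] = cell_ll(&Ys(0, c), V, e, std::exp(e), &lph(0, c),
                           &l1m(0, c), Sl1m(c, s), psi, lps, l1ps, ltail,
                           Kcap, -1);
        nsum += newll[c];
      }
      if (std::log(unif_rand()) < nsum - cur + lpr) {
        for (int k = 0; k < p; ++k) beta(k, s) += dv[k];
        for (int c = 0; c < n; ++c) {
          etaAb[c] = eta2[c];
          cellLL(c, s) = newll[c];
        }
        cur = nsum;
        accBlkB[s] = 1;
      }
    }

    // block update of the detection coefficient vector
    if (prop_blka[s] > 0) {
      for (int k = 0; k < q; ++k) dv[k] = 0.0;
      for (int k = 0; k < q; ++k) {
        double z = norm_rand();
        for (int l = k; l < q; ++l) dv[l] += La(l, k) * z;
      }
      double lpr = 0.0;
      for (int k = 0; k < q; ++k) {
        dv[k] *= prop_blka[s];
        double an = alpha(k, s) + dv[k];
        lpr += R::dnorm(an, mu_a[k], sd_a[k], 1) -
               R::dnorm(alpha(k, s), mu_a[k], sd_a[k], 1);
      }
      double nsum = 0.0;
      for (int c = 0; c < n; ++c) {
        double ssum = 0.0;
        for (int v = 0; v < V; ++v) {
          int r = c + v * n;
          double e = etaDet[r];
          for (int k = 0; k < q; ++k) e += Xdet(r, k) * dv[k];
          det_logs(e, lphN(v, c), l1mN(v, c));
          ssum += l1mN(v, c);
        }
        sl1mN[c] = ssum;
        newll[c] = cell_ll(&Ys(0, c), V, etaAb[c], std::exp(etaAb[c]),
                           &lphN(0, c), &l1mN(0, c), ssum, psi, lps, l1ps,
                           ltail, Kcap, -1);
        nsum += newll[c];
      }
      if (std::log(unif_rand()) < nsum - cur + lpr) {
        for (int k = 0; k < q; ++k) alpha(k, s) += dv[k];
        for (int c = 0; c < n; ++c) {
          cellLL(c, s) = newll[c];
          Sl1m(c, s) = sl1mN[c];
          for (int v = 0; v < V; ++v) {
            int r = c + v * n;
            double e = etaDet[r];
            for (int k = 0; k < q; ++k) e += Xdet(r, k) * dv[k];
            etaDet[r] = e;
            lph(v, c) = lphN(v, c);
            l1m(v, c) = l1mN(v, c);
          }
        }
        cur = nsum;
        accBlkA[s] = 1;
      }
    }

    psi_s[s] = psi;
    lpsi_log[s] = lps;
    l1mpsi_log[s] = l1ps;
  }

  // shared site random effects
  std::vector<double> tmp;
  for (int t = 0; t < T; ++t) {
    const std::vector<int> &cs = bysite[t];
    if (cs.empty()) continue;
    double d = prop_g[t] * norm_rand();
    double gnew = gamma[t] + d;
    tmp.assign(cs.size() * S, 0.0);
    double delta = 0.0;
    for (int s = 0; s < S; ++s) {
      IntegerMatrix Ys = Yt[s];
      NumericMatrix &lph = LPhi[s], &l1m = L1m[s];
      for (size_t ci = 0; ci < cs.size(); ++ci) {
        int c = cs[ci];
        double e = EtaAb(c, s) + d;
        double ll = cell_ll(&Ys(0, c), V, e, std::exp(e), &lph(0, c),
                            &l1m(0, c), Sl1m(c, s), psi_s[s], lpsi_log[s],
                            l1mpsi_log[s], ltail, Kcap, -1);
        tmp[s * cs.size() + ci] = ll;
        delta += ll - cellLL(c, s);
      }
    }
    double lr = delta + R::dnorm(gnew, 0.0, sigma_site, 1) -
                R::dnorm(gamma[t], 0.0, sigma_site, 1);
    if (std::log(unif_rand()) < lr) {
      gamma[t] = gnew;
      for (int s = 0; s < S; ++s)
        for (size_t ci = 0; ci < cs.size(); ++ci) {
          int c = cs[ci];
          EtaAb(c, s) += d;
          cellLL(c, s) = tmp[s * cs.size() + ci];
        }
      accG[t] = 1;
    }
  }

  double total = 0.0;
  for (int s = 0; s < S; ++s)
    for (int c = 0; c < n; ++c) total += cellLL(c, s);

  return List::create(
      _["beta"] = beta, _["alpha"] = alpha, _["lpsi"] = lpsi,
      _["gamma"] = gamma, _["acc_beta"] = accB, _["acc_alpha"] = accA,
      _["acc_psi"] = accP, _["acc_gamma"] = accG,
      _["acc_blk_beta"] = accBlkB, _["acc_blk_alpha"] = accBlkA,
      _["loglik"] = total);
}
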